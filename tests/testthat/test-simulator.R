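test_that("behaviour respects block modes and degenerate profiles", {
  sch <- generate_level("Learn", seed = 21)
  beh <- simulate_behavior(sch, seed = 1)
  passive <- sch$trials$block_mode == "passive"
  expect_true(all(beh$button[passive] == "none"))
  expect_true(all(beh$button[sch$trials$kind == "baseline"] == "none"))
  # perfect accuracy and fast RTs: every active trial correct, no misses
  prof <- default_profile(rt_median_ms = 300, rt_spread = 0.01,
                          accuracy = c(Learn = 1, Who = 1, Discern = 1))
  beh2 <- simulate_behavior(sch, prof, seed = 2)
  active <- sch$trials$expected_button != "none"
  expect_true(all(beh2$accuracy[active] == "correct"))
  expect_equal(beh2$button[active], sch$trials$expected_button[active])
})

test_that("Discern draws more errors than Who, with post-reversal lapses", {
  err <- function(level, seed) {
    sch <- generate_level(level, seed = seed)
    beh <- simulate_behavior(sch, seed = seed + 500)
    resp <- beh$accuracy %in% c("correct", "incorrect")
    list(k = sum(beh$accuracy == "incorrect"), n = sum(resp), beh = beh, sch = sch)
  }
  # pool three runs of each level (> 1000 active trials per level)
  who <- lapply(1:3, function(s) err("Who", s))
  disc <- lapply(1:3, function(s) err("Discern", s))
  k_who <- sum(vapply(who, `[[`, numeric(1), "k"))
  n_who <- sum(vapply(who, `[[`, numeric(1), "n"))
  k_disc <- sum(vapply(disc, `[[`, numeric(1), "k"))
  n_disc <- sum(vapply(disc, `[[`, numeric(1), "n"))
  p <- prop.test(c(k_disc, k_who), c(n_disc, n_who), alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # the first post-reversal block is the lapse hotspot
  d1 <- disc[[1]]
  first_rev <- min(d1$sch$trials$block[d1$sch$trials$block_mode == "rule_B"])
  in_rev <- d1$sch$trials$block == first_rev
  err_rev <- mean(d1$beh$accuracy[in_rev] == "incorrect", na.rm = TRUE)
  err_rest <- mean(d1$beh$accuracy[!in_rev & d1$beh$accuracy != "na"] == "incorrect")
  expect_gt(err_rev, err_rest)
})

test_that("pink noise has 1/f spectrum, exact determinism and silent zero", {
  x <- pink_noise(2, 250 * 60, 250, amplitude_uV = 5, seed = 3)
  ps <- power_spectrum(x[1, ], srate = 250, nfft = 1024)
  slope <- spectral_slope(ps, band = c(1, 40))
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
  expect_equal(sd(x[1, ]), 5, tolerance = 1e-6)
  expect_identical(pink_noise(2, 250 * 60, 250, 5, seed = 3), x)
  expect_true(all(pink_noise(2, 20000, 250, 0, seed = 1) == 0))
  expect_error(pink_noise(1, 100, 250, 5), "exceed")
})

test_that("rendering is linear, condition-aware and bounds-safe", {
  tmpl <- default_templates()
  ev <- data.frame(event_type = "stimulus", sample = c(500, 900),
                   distractor = c("top", "bottom"), stringsAsFactors = FALSE)
  chans <- default_montage()$channel
  sig <- render_component(tmpl$C1, ev, chans, 1500, 250)
  poz <- which(chans == "POz")
  expect_lt(sig[poz, 500 + 20], 0)       # top distractor: negative at POz
  expect_gt(sig[poz, 900 + 20], 0)       # bottom: positive
  expect_equal(max(abs(sig[poz, ])), 1, tolerance = 1e-3)
  # zero-amplitude template renders silence
  zero <- erp_template("zero", "stimulus", function(e) e$event_type == "stimulus",
                       100, 30, function(row) 0, c(POz = 1))
  expect_true(all(render_component(zero, ev, chans, 1500, 250) == 0))
  # event past the recording end is skipped with a warning
  ev2 <- data.frame(event_type = "stimulus", sample = 10000,
                    distractor = "top", stringsAsFactors = FALSE)
  expect_warning(out <- render_component(tmpl$C1, ev2, chans, 1500, 250),
                 "skipped")
  expect_true(all(out == 0))
  # corollary-discharge attenuation for self-triggered tones
  expect_equal(tmpl$N1$amp_fun(list(block_mode = "cd_immediate")), -2)
  expect_equal(tmpl$N1$amp_fun(list(block_mode = "cd_random")), -4)
})

test_that("recordings compose schedule, behaviour and noise deterministically", {
  sch <- generate_level("Learn", seed = 31, config = small_config())
  rec1 <- simulate_recording(sch, seed = 5)
  rec2 <- simulate_recording(sch, seed = 5)
  expect_identical(rec1$signal, rec2$signal)
  expect_identical(rec1$events, rec2$events)
  # duration matches the schedule span plus padding
  span_s <- sum(sch$trials$duration_ms) / 1000
  expect_equal(ncol(rec1$signal) / rec1$srate, span_s + 4, tolerance = 0.01)
  expect_true(all(diff(rec1$events$sample) >= 0))
  expect_error(simulate_recording(sch, seed = 1, srate = 50), "too low")
})

test_that("noiseless epoch averages reproduce the injected template", {
  sch <- generate_level("Who", seed = 41, config = small_config())
  tmpl <- default_templates()["P300"]
  rec <- simulate_recording(sch, profile = default_profile(noise_uV = 0),
                            templates = tmpl, seed = 6)
  ev <- rec$events[rec$events$event_type == "stimulus" &
                     rec$events$category == "rare", ]
  ep <- epoch(rec, ev, window_ms = c(-200, 800))
  w <- average_erp(ep, NULL, "Pz")
  peak_t <- w$time_ms[which.max(w$mean_uV)]
  expect_equal(max(w$mean_uV), 5, tolerance = 0.01)
  expect_equal(peak_t, 400, tolerance = 10)
  # no-noise average IS the template: compare to the analytic Gaussian
  gauss <- 5 * exp(-((w$time_ms - 400) / 80)^2 / 2)
  expect_lt(max(abs(w$mean_uV - gauss)), 0.05)
})

test_that("condition-average P300 recovers the injected amplitude from noise", {
  rec <- cached_filtered("Who")
  ev <- rec$events[rec$events$event_type == "stimulus", ]
  ep <- baseline_correct(epoch(rec, ev, channels = "Pz"), c(-200, 0))
  rare <- average_erp(ep, function(l) l$category == "rare", "Pz")
  expect_gte(rare$n, 80)
  peak <- amplitude_measure(rare, c(300, 500), "peak")
  expect_lt(abs(peak - 5) / 5, 0.2)
})
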