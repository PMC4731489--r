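make_rec <- function(signal, srate = 250) {
  structure(list(signal = signal, srate = srate,
                 channels = paste0("ch", seq_len(nrow(signal))),
                 events = data.frame(), montage = NULL, level = "Learn",
                 seed = 0L),
            class = "erp_recording")
}

test_that("band-pass removes DC, keeps the passband, kills the stopband", {
  srate <- 250
  t <- seq(0, 20, by = 1 / srate)[-1]
  s10 <- sin(2 * pi * 10 * t)
  s60 <- sin(2 * pi * 60 * t)
  rec <- make_rec(rbind(s10 + 7, s60, s10 + s60))
  out <- filter_band(rec)$signal
  mid <- seq(2 * srate, length(t) - 2 * srate)   # avoid edge transients
  expect_lt(abs(mean(out[1, ])), 0.05)           # constant offset removed
  amp10 <- max(abs(out[1, mid]))
  expect_lt(abs(amp10 - 1), 0.05)                # 10 Hz preserved within 5%
  amp60 <- max(abs(out[2, mid]))
  expect_lt(amp60, 10^(-20 / 20))                # >= 20 dB attenuation at 60 Hz
  # linearity: filter(a + b) = filter(a) + filter(b); the DC offset on
  # channel 1 is removed before filtering so the superposition matches
  expect_equal(out[3, mid], out[1, mid] + out[2, mid], tolerance = 1e-6)
  expect_error(filter_band(make_rec(rbind(s10)), lp_hz = 130), "Nyquist")
})

test_that("epoching selects, windows and drops out-of-bounds events", {
  rec <- cached_filtered("Who")
  stim <- rec$events[rec$events$event_type == "stimulus", ]
  ep <- epoch(rec, stim)
  expect_equal(dim(ep$data)[1], 400)             # 16 x 25 stimulus trials
  expect_equal(dim(ep$data)[3], 751)             # -1..2 s at 250 Hz
  # an event too close to the start is dropped and counted
  stim2 <- stim
  stim2$sample[1] <- 10
  ep2 <- epoch(rec, stim2)
  expect_equal(dim(ep2$data)[1], 399)
  expect_equal(ep2$n_dropped, 1)
  expect_error(epoch(rec, stim[0, ]), "selection error")
  # response-locked selection only contains responded trials
  resp <- rec$events[rec$events$event_type == "response", ]
  epr <- epoch(rec, resp, lock = "response", window_ms = c(-500, 800))
  expect_true(all(epr$labels$button %in% c("left", "right")))
})

test_that("baseline correction zeroes the baseline and ignores offsets", {
  ep <- synthetic_epochs(array(3, dim = c(2, 2, 100)))
  out <- baseline_correct(ep, c(-200, 0))
  expect_true(all(out$data == 0))
  x <- array(rnorm(2 * 2 * 100), dim = c(2, 2, 100))
  a <- baseline_correct(synthetic_epochs(x), c(-150, -50))
  b <- baseline_correct(synthetic_epochs(x + 5), c(-150, -50))
  expect_equal(a$data, b$data)
  idx <- a$times_ms >= -150 & a$times_ms <= -50
  expect_lt(max(abs(apply(a$data[, , idx], c(1, 2), mean))), 1e-12)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  rec <- make_rec(matrix(rnorm(5 * 100), 5))
  ar <- average_reference(rec)
  expect_lt(max(abs(colMeans(ar$signal))), 1e-12)
  expect_equal(average_reference(ar)$signal, ar$signal)
  # between-channel differences unchanged by the reference shift
  expect_equal(ar$signal[1, ] - ar$signal[2, ], rec$signal[1, ] - rec$signal[2, ])
  expect_error(average_reference(make_rec(matrix(1, 1, 50))), ">= 2 channels")
  ep <- synthetic_epochs(array(rnorm(3 * 4 * 50), dim = c(3, 4, 50)))
  are <- average_reference(ep)
  expect_lt(max(abs(apply(are$data, c(1, 3), mean))), 1e-12)
})

test_that("threshold rejection is targeted and monotone", {
  x <- array(rnorm(10 * 2 * 50), dim = c(10, 2, 50))
  x[4, 1, 25] <- 500
  ep <- synthetic_epochs(x)
  out <- reject_epochs(ep, 100)
  expect_equal(attr(out, "rejected"), 4L)
  expect_equal(dim(out$data)[1], 9)
  loose <- reject_epochs(ep, 600)
  expect_length(attr(loose, "rejected"), 0)
  # monotone: tighter thresholds reject supersets
  r50 <- attr(reject_epochs(ep, 50), "rejected")
  expect_true(all(attr(out, "rejected") %in% r50))
  expect_error(reject_epochs(ep, 1e-9), "all epochs rejected")
  expect_error(reject_epochs(ep, -1), "positive")
  # a clean default simulation passes a 100 uV budget untouched
  rec <- cached_filtered("Who")
  stim <- rec$events[rec$events$event_type == "stimulus", ][1:50, ]
  epc <- epoch(rec, stim, channels = c("Pz", "Cz"))
  expect_length(attr(reject_epochs(epc, 100), "rejected"), 0)
})

test_that("epoch pooling concatenates compatible sets only", {
  a <- synthetic_epochs(array(1, dim = c(2, 2, 10)))
  b <- synthetic_epochs(array(2, dim = c(3, 2, 10)))
  pooled <- pool_epochs(a, b)
  expect_equal(dim(pooled$data)[1], 5)
  expect_equal(pooled$data[3, 1, 1], 2)
  bad <- synthetic_epochs(array(0, dim = c(2, 2, 11)))
  expect_error(pool_epochs(a, bad), "not compatible")
})
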