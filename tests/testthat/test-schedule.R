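test_that("configuration invariants are enforced", {
  expect_s3_class(paradigm_config(), "paradigm_config")
  expect_error(paradigm_config(frequent_fraction = 0.77), "not an integer")
  expect_error(paradigm_config(blocks_per_level = 15), "even")
  expect_error(paradigm_config(stim_duration_ms = -1), "positive")
  expect_error(paradigm_config(tone_slot_period = 3), ">= 4")
  expect_error(paradigm_config(tone_pair_mix = c(std_std = 0.81, std_dev = 0.1,
                                                 silent = 0.09)),
               "integer counts")
})

test_that("a generated level has the full three-tier structure", {
  sch <- generate_level("Learn", seed = 1)
  tr <- sch$trials
  expect_equal(nrow(tr), 448)
  expect_equal(length(unique(tr$block)), 16)
  for (b in 1:16) {
    kinds <- tr$kind[tr$block == b]
    expect_identical(kinds, c(rep("stimulus", 25), rep("baseline", 3)))
  }
  stim <- tr[tr$kind == "stimulus", ]
  expect_equal(sum(stim$category == "frequent"), 320)
  expect_equal(sum(stim$category == "rare"), 80)
  # each rare slot totals exactly 10% of stimulus trials over the level
  rare_counts <- vapply(1:16, function(b) {
    tb <- stim[stim$block == b & stim$category == "rare", ]
    sort(table(tb$image), decreasing = TRUE)
  }, numeric(2))
  expect_true(all(colSums(rare_counts) == 5))
  expect_true(all(rare_counts[1, ] %in% c(2, 3)))
  expect_equal(sum(rare_counts), 80)
  # per block: 20 frequent, rare on the opposite side, first two frequent
  for (b in 1:16) {
    sb <- stim[stim$block == b, ]
    expect_equal(sum(sb$category == "frequent"), 20)
    expect_length(intersect(sb$side[sb$category == "rare"],
                            sb$side[sb$category == "frequent"]), 0)
    expect_false(sb$image[1] %in% sb$image[sb$category == "rare"])
    expect_equal(sb$category[1:2], c("frequent", "frequent"))
  }
  expect_length(validate_schedule(sch)$violations, 0)
})

test_that("block modes follow the per-level rules", {
  learn <- generate_level("Learn", seed = 3)
  expect_identical(learn$blocks$mode,
                   ifelse(seq_len(16) %% 2 == 1, "passive", "active"))
  who <- generate_level("Who", seed = 7)
  expect_equal(as.vector(table(who$blocks$mode)[c("cd_immediate", "cd_random")]),
               c(8L, 8L))
  disc <- generate_level("Discern", seed = 2)
  expect_identical(disc$blocks$mode, rep(c("rule_A", "rule_B"), each = 8))
})

test_that("generation is seed-deterministic but varies across seeds", {
  a <- generate_level("Who", seed = 42)
  b <- generate_level("Who", seed = 42)
  expect_identical(a, b)
  sides <- vapply(1:5, function(s)
    paste(generate_level("Learn", seed = s)$blocks$frequent_side, collapse = ""),
    character(1))
  expect_gt(length(unique(sides)), 1)
})

test_that("tone slots are spaced, mixed exactly and S2 trails S1 by 500 ms", {
  sch <- generate_level("Discern", seed = 9)
  tr <- sch$trials
  slot_at <- which(tr$tone_slot)
  expect_true(all(diff(slot_at) >= 4))
  mix <- table(tr$tone_pair_type[tr$tone_slot])
  expect_equal(as.vector(mix[c("std_std", "std_dev", "silent")]), c(64L, 8L, 8L))
  expect_equal(100 * sum(tr$tone_pair_type == "std_dev") / sum(tr$tone_slot), 10)
  expect_true(all(tr$tone_offset_ms[tr$tone_slot] %in% c(-240, -40, 160)))
  # baseline trials never carry tones or images
  expect_true(all(!tr$tone_slot[tr$kind == "baseline"]))
  ev <- events_table(sch)
  s1 <- ev[ev$event_type == "tone_s1", ]
  s2 <- ev[ev$event_type == "tone_s2", ]
  expect_equal(s2$onset_ms - s1$onset_ms, rep(500, nrow(s1)))
  # a sequence too short for the slot pattern errors
  expect_error(assign_tone_events(tr[1:2, ], paradigm_config()), "too short")
})

test_that("trial timing has the documented bounds, mean and cumulative onsets", {
  sch <- generate_level("Who", seed = 5)
  d <- sch$trials$duration_ms
  expect_gte(min(d), 1200)
  expect_lte(max(d), 1900)
  se <- sd(0:700) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1550), 3 * se)
  expect_equal(sch$trials$onset_ms, cumsum(c(0, d[-length(d)])))
})

test_that("response rules map level, mode and image to buttons", {
  # Discern rule A: meaningful left; rule B reversed
  expect_equal(response_rule("Discern", "rule_A", "stimulus", "kanizsa", "left"), "left")
  expect_equal(response_rule("Discern", "rule_B", "stimulus", "kanizsa", "right"), "right")
  expect_equal(response_rule("Discern", "rule_A", "stimulus", "mooney_distorted", "left"), "right")
  expect_equal(response_rule("Learn", "passive", "stimulus", "mooney_face", "left"), "none")
  expect_equal(response_rule("Learn", "active", "stimulus", "mooney_face", "right"), "right")
  expect_equal(response_rule("Who", "cd_random", "stimulus", "kanizsa", "left"), "left")
  expect_error(response_rule("Learn", "active", "baseline", "none", "none"), "rule error")
})

test_that("feedback is a total monotone step function with verbatim bands", {
  expect_equal(feedback_message(80), "Well tried! Try to respond more accurately.")
  expect_equal(feedback_message(90), "Good job, Keep it up!")
  expect_equal(feedback_message(96), "Outstanding! Now try to respond a bit faster.")
  # band edges inclusive in the middle band
  expect_equal(feedback_message(85), feedback_message(95))
  msgs <- feedback_message(seq(0, 100, by = 0.5))
  expect_equal(length(unique(msgs)), 3)
  expect_true(!is.unsorted(match(msgs, unique(msgs))))  # monotone steps
  expect_error(feedback_message(101), "domain error")
  expect_error(feedback_message(-1), "domain error")
})

test_that("event markers are reversible, injective and number over 500", {
  sch <- generate_level("Who", seed = 4)
  tr <- sch$trials
  dec <- decode_event_marker(tr$marker_code)
  expect_equal(dec$image, tr$image)
  expect_equal(dec$block, tr$block)
  expect_equal(dec$side, tr$side)
  # two trials differing only in distractor position get different codes
  t2 <- tr[1, ]
  t2$distractor <- setdiff(c("top", "bottom"), tr$distractor[1])
  expect_false(encode_event_marker(t2) == tr$marker_code[1])
  codes <- unlist(lapply(c("Learn", "Who", "Discern"), function(lv) {
    g <- generate_level(lv, seed = 8)
    b <- simulate_behavior(g, seed = 9)
    encode_event_marker(g$trials, b$button, b$accuracy)
  }))
  expect_gt(length(unique(codes)), 500)
  reg <- marker_registry(codes)
  expect_equal(nrow(reg), length(unique(codes)))
  expect_equal(reg$numeric_alias, seq_len(nrow(reg)))
  expect_error(encode_event_marker(data.frame(level = "Learn")), "unresolved")
})

test_that("validate_schedule reports constructed violations without raising", {
  sch <- generate_level("Learn", seed = 6)
  sch$trials$tone_slot[2:3] <- TRUE  # adjacent paired-tone trials
  v <- validate_schedule(sch)
  expect_true(any(grepl("spacing", v$violations)))
  expect_equal(v$stats$n_trials, 448)
  expect_equal(v$stats$frequent_pct, 80)
})

test_that("events tables round-trip through TSV and rebuild the schedule", {
  sch <- generate_level("Discern", seed = 11, config = small_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sch, path)
  ev <- read_events_tsv(path)
  expect_true(all(c("onset_ms", "marker_code") %in% names(ev)))
  back <- schedule_from_events(ev, small_config())
  for (col in c("level", "block", "block_mode", "kind", "image", "side",
                "category", "distractor", "tone_pair_type", "duration_ms",
                "onset_ms", "expected_button")) {
    expect_equal(back$trials[[col]], sch$trials[[col]], label = col)
  }
})
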