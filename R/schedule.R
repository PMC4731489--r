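#' Generate the full trial schedule for one game level
#'
#' Deterministically (given `seed`) builds the complete ordered event plan
#' for one game level: 16 blocks, each holding 25 stimulus trials followed
#' by 3 fixation-only baseline trials (448 trials with defaults). Every
#' block realises a fresh oddball: one of the four salient image types is
#' frequent (80% of stimulus trials) on a pseudo-randomly chosen side, two
#' of the remaining types are rare (20% total) on the opposite side. Paired
#' tones, bilateral top/bottom checkerboard distractors, trial timing with
#' uniform end-baseline jitter, expected responses and structured condition
#' markers are all resolved here.
#'
#' Block modes by level: `Learn` alternates passive (odd blocks, no button
#' press) and active; `Who` splits the blocks pseudo-randomly into
#' `cd_immediate` (response triggers a tone immediately) and `cd_random`
#' (tone after a random delay, or at timeout); `Discern` uses response rule
#' A for blocks 1-8 and the reversed rule B for blocks 9-16.
#'
#' @param level one of `"Learn"`, `"Who"`, `"Discern"`.
#' @param config a [paradigm_config()].
#' @param seed integer seed; identical `(level, config, seed)` give
#'   byte-identical schedules.
#' @return an object of class `erp_schedule`: a list with elements
#'   `trials` (one row per trial, in presentation order), `blocks`
#'   (per-block oddball assignment), `level`, `seed` and `config`.
#' @examples
#' sch <- generate_level("Learn", seed = 1)
#' nrow(sch$trials)            # 448
#' validate_schedule(sch)$stats$frequent_pct
#' @export
generate_level <- function(level, config = paradigm_config(), seed = 1) {
  level <- match.arg(level, GAME_LEVELS)
  validate_config(config)
  with_seed(seed, {
    blocks <- do.call(rbind, lapply(seq_len(config$blocks_per_level), function(b) {
      as.data.frame(assign_block_oddball(b, level, config), stringsAsFactors = FALSE)
    }))
    # Who: pseudo-random half/half mode allocation decided level-wide
    if (level == "Who") {
      nb <- config$blocks_per_level
      blocks$mode <- sample(rep(c("cd_immediate", "cd_random"), nb / 2))
    }
    trials <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
      build_block_trials(blocks[b, ], config)
    }))
    trials$trial <- seq_len(nrow(trials))
    trials <- assign_tone_events(trials, config)
    trials <- compute_trial_timing(trials, config)
    trials$expected_button <- "none"
    stim <- trials$kind == "stimulus"
    trials$expected_button[stim] <-
      response_rule(level, trials$block_mode[stim], trials$kind[stim],
                    trials$image[stim], trials$side[stim])
    trials$marker_code <- encode_event_marker(trials)
    rownames(trials) <- NULL
    structure(list(trials = trials, blocks = blocks, level = level,
                   seed = as.integer(seed), config = config),
              class = "erp_schedule")
  })
}

#' Assign the oddball structure of one block
#'
#' Draws (from the current RNG stream) the frequent image type and its side,
#' and the two rare image types shown on the opposite side. The per-block
#' rare counts alternate 3/2 and 2/3 across blocks so that each rare slot
#' totals exactly 10% of stimulus trials over a level.
#'
#' @param block_index block number within the level (1-based).
#' @param level game level name.
#' @param config a [paradigm_config()].
#' @return a list (one block spec): `index`, `level`, `mode`,
#'   `frequent_image`, `frequent_side`, `rare_image_1`, `rare_image_2`,
#'   `n_rare_1`.
#' @export
assign_block_oddball <- function(block_index, level, config = paradigm_config()) {
  level <- match.arg(level, GAME_LEVELS)
  abort_if(!(block_index %in% seq_len(config$blocks_per_level)),
           "block_index %s outside 1..%d", block_index, config$blocks_per_level)
  mode <- switch(level,
    Learn = if (block_index %% 2 == 1) "passive" else "active",
    Who = "cd_immediate",  # provisional; level-wide shuffle happens in generate_level()
    Discern = if (block_index <= config$blocks_per_level / 2) "rule_A" else "rule_B")
  frequent_image <- sample(IMAGE_TYPES, 1)
  frequent_side <- sample(SIDES, 1)
  rare <- sample(setdiff(IMAGE_TYPES, frequent_image), 2)
  n_stim <- config$stim_trials_per_block
  n_rare <- round((1 - config$frequent_fraction) * n_stim)
  n_rare_1 <- if (block_index %% 2 == 1) ceiling(n_rare / 2) else floor(n_rare / 2)
  list(index = block_index, level = level, mode = mode,
       frequent_image = frequent_image, frequent_side = frequent_side,
       rare_image_1 = rare[1], rare_image_2 = rare[2], n_rare_1 = n_rare_1)
}

# One block's trial rows: 25 stimulus trials (rare positions uniform among
# 3..25; the first two trials of a block are always frequent) then 3
# baseline trials. Distractor checkerboards top/bottom uniformly per
# stimulus trial.
build_block_trials <- function(block, config) {
  n_stim <- config$stim_trials_per_block
  n_base <- config$baseline_trials_per_block
  n_rare <- round((1 - config$frequent_fraction) * n_stim)
  image <- rep(block$frequent_image, n_stim)
  rare_pos <- sample(3:n_stim, n_rare)
  rare_types <- sample(c(rep(block$rare_image_1, block$n_rare_1),
                         rep(block$rare_image_2, n_rare - block$n_rare_1)))
  image[rare_pos] <- rare_types
  category <- ifelse(image == block$frequent_image, "frequent", "rare")
  side <- ifelse(category == "frequent", block$frequent_side,
                 setdiff(SIDES, block$frequent_side))
  data.frame(
    level = block$level,
    block = block$index,
    block_mode = block$mode,
    trial_in_block = seq_len(n_stim + n_base),
    kind = c(rep("stimulus", n_stim), rep("baseline", n_base)),
    image = c(image, rep("none", n_base)),
    side = c(side, rep("none", n_base)),
    category = c(category, rep("none", n_base)),
    distractor = c(sample(c("top", "bottom"), n_stim, replace = TRUE),
                   rep("none", n_base)),
    stringsAsFactors = FALSE
  )
}

#' Annotate a trial sequence with paired-tone events
#'
#' Marks tone slots on every `tone_slot_period`-th stimulus trial of each
#' block (so each paired-tone trial is followed by at least three toneless
#' trials), draws one first-tone offset from the configured set
#' (-240/-40/+160 ms relative to visual onset; the second tone follows
#' 500 ms later) and assigns pair types with the exact level-wide mix
#' (80% standard-standard, 10% standard-deviant, 10% silent). Deviant tones
#' are restricted to the second (S2) position.
#'
#' @param trials trial data frame as built by [generate_level()] (columns
#'   `block`, `trial_in_block`, `kind` required).
#' @param config a [paradigm_config()].
#' @return `trials` with columns `tone_slot` (logical), `tone_offset_ms`
#'   and `tone_pair_type` added.
#' @export
assign_tone_events <- function(trials, config = paradigm_config()) {
  slot_positions <- 1 + (seq_len(config$tone_slots_per_block) - 1) * config$tone_slot_period
  abort_if(max(slot_positions) > config$stim_trials_per_block,
           "generation error: trial sequence too short to honor tone-slot spacing")
  stim_idx <- trials$kind == "stimulus"
  # stimulus-trial index within block
  stim_rank <- stats::ave(as.numeric(stim_idx), trials$block, FUN = cumsum)
  abort_if(max(slot_positions) > max(stim_rank[stim_idx], 0),
           "generation error: trial sequence too short to honor tone-slot spacing")
  trials$tone_slot <- stim_idx & stim_rank %in% slot_positions
  n_slots <- sum(trials$tone_slot)
  counts <- round(config$tone_pair_mix * n_slots)
  abort_if(sum(counts) != n_slots,
           "generation error: tone_pair_mix does not partition %d slots", n_slots)
  pair_types <- sample(rep(names(counts), counts))
  trials$tone_offset_ms <- NA_integer_
  trials$tone_pair_type <- "none"
  trials$tone_offset_ms[trials$tone_slot] <-
    sample(config$tone_offsets_ms, n_slots, replace = TRUE)
  trials$tone_pair_type[trials$tone_slot] <- pair_types
  trials
}

#' Draw trial durations and cumulative onsets
#'
#' Each trial lasts `pre_mask + stim + response_window + end_baseline_min`
#' (1200 ms with defaults) plus a discrete uniform jitter of 0..700 ms
#' appended to the end baseline, giving durations in 1200..1900 ms with
#' mean 1550 ms. Onsets are cumulative from 0 within the level.
#'
#' @param trials trial data frame.
#' @param config a [paradigm_config()].
#' @return `trials` with `jitter_ms`, `duration_ms` and `onset_ms` columns.
#' @export
compute_trial_timing <- function(trials, config = paradigm_config()) {
  fixed <- config$pre_mask_ms + config$stim_duration_ms +
    config$response_window_ms + config$end_baseline_min_ms
  n <- nrow(trials)
  trials$jitter_ms <- sample(0:config$jitter_max_ms, n, replace = TRUE)
  trials$duration_ms <- fixed + trials$jitter_ms
  trials$onset_ms <- cumsum(c(0, trials$duration_ms[-n]))
  trials
}

#' Expected response button for a trial
#'
#' Encodes the per-level response rules: passive Learn blocks require no
#' response; active Learn blocks and all Who blocks require the button on
#' the side of the salient image; Discern rule A maps meaningful (intact
#' face or Kanizsa) to the left button and ambiguous (distorted) to the
#' right, and rule B (after the mid-level reversal) swaps the mapping.
#'
#' @param level game level name (scalar).
#' @param block_mode block mode(s).
#' @param kind trial kind(s); baseline trials raise a rule error.
#' @param image,side trial image type(s) and presentation side(s).
#' @return character vector of `"left"`, `"right"` or `"none"`.
#' @export
response_rule <- function(level, block_mode, kind, image, side) {
  level <- match.arg(level, GAME_LEVELS)
  abort_if(any(kind != "stimulus"), "rule error: response rule undefined for baseline trials")
  n <- length(block_mode)
  meaningful <- image %in% c("mooney_face", "kanizsa")
  out <- switch(level,
    Learn = ifelse(block_mode == "passive", "none", side),
    Who = side,
    Discern = ifelse(block_mode == "rule_A",
                     ifelse(meaningful, "left", "right"),
                     ifelse(meaningful, "right", "left")))
  rep_len(out, n)
}

#' Performance feedback message
#'
#' Total, monotone step function of block accuracy shown after every two
#' blocks: below 85% encourages accuracy, 85-95% (both inclusive)
#' encourages keeping it up, above 95% encourages speed.
#'
#' @param accuracy_pct accuracy in percent, in \[0, 100\].
#' @param config a [paradigm_config()] (band edges).
#' @return character vector of feedback messages.
#' @export
feedback_message <- function(accuracy_pct, config = paradigm_config()) {
  abort_if(any(!is.finite(accuracy_pct)) || any(accuracy_pct < 0 | accuracy_pct > 100),
           "domain error: accuracy_pct must be in [0, 100]")
  ifelse(accuracy_pct < config$feedback_low_pct,
         "Well tried! Try to respond more accurately.",
         ifelse(accuracy_pct <= config$feedback_high_pct,
                "Good job, Keep it up!",
                "Outstanding! Now try to respond a bit faster."))
}

MARKER_FIELDS <- c("level", "block", "block_mode", "image", "side", "category",
                   "tone", "distractor", "button", "accuracy")

#' Encode structured condition markers
#'
#' Builds one reversible, pipe-separated condition code per trial covering
#' level, block index, block mode, image type, side, oddball category, tone
#' condition (pair type and offset), distractor position, response button
#' and accuracy. Codes are bijective with their condition tuples; a full
#' three-level run realises well over 500 distinct codes.
#'
#' @param trials trial data frame (tone columns must be present).
#' @param button response button per trial (default `"na"`, i.e. not yet
#'   resolved).
#' @param accuracy response accuracy per trial (`"correct"`, `"incorrect"`,
#'   `"miss"` or `"na"`).
#' @return character vector of marker codes.
#' @seealso [decode_event_marker()], [marker_registry()]
#' @export
encode_event_marker <- function(trials, button = "na", accuracy = "na") {
  need <- c("level", "block", "block_mode", "image", "side", "category",
            "tone_pair_type", "tone_offset_ms", "distractor")
  missing_cols <- setdiff(need, names(trials))
  abort_if(length(missing_cols) > 0, "encoding error: unresolved fields: %s",
           paste(missing_cols, collapse = ", "))
  tone <- ifelse(trials$tone_pair_type == "none", "none",
                 paste0(trials$tone_pair_type, "@", trials$tone_offset_ms))
  paste(trials$level, trials$block, trials$block_mode, trials$image,
        trials$side, trials$category, tone, trials$distractor,
        rep_len(button, nrow(trials)), rep_len(accuracy, nrow(trials)),
        sep = "|")
}

#' Decode a condition marker back to its field tuple
#'
#' @param code marker code(s) produced by [encode_event_marker()].
#' @return data frame with one column per marker field.
#' @export
decode_event_marker <- function(code) {
  parts <- strsplit(code, "|", fixed = TRUE)
  abort_if(any(lengths(parts) != length(MARKER_FIELDS)),
           "encoding error: malformed marker code")
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- MARKER_FIELDS
  out$block <- as.integer(out$block)
  out
}

#' Sequential numeric aliases for marker codes
#'
#' Maps the distinct marker codes of a run to stable small integers
#' (sorted-order registry, no hashing) so codes stay portable across tools
#' that require numeric triggers.
#'
#' @param codes character vector of marker codes.
#' @return data frame `code`, `numeric_alias`.
#' @export
marker_registry <- function(codes) {
  u <- sort(unique(codes))
  data.frame(code = u, numeric_alias = seq_along(u), stringsAsFactors = FALSE)
}

#' Validate a generated schedule
#'
#' Recomputes the structural invariants of a level schedule (block/trial
#' counts, oddball proportions, tone-slot spacing and pair-type mix,
#' duration bounds, cumulative onsets, baseline-trial purity) and reports
#' violations rather than raising.
#'
#' @param schedule an `erp_schedule`.
#' @return list with `stats` (a `schedule_stats` list) and `violations`
#'   (character vector, empty iff all invariants hold).
#' @export
validate_schedule <- function(schedule) {
  tr <- schedule$trials
  cfg <- schedule$config
  v <- character(0)
  note <- function(fmt, ...) v <<- c(v, sprintf(fmt, ...))

  n_per_block <- cfg$stim_trials_per_block + cfg$baseline_trials_per_block
  if (nrow(tr) != cfg$blocks_per_level * n_per_block)
    note("trial count %d != %d", nrow(tr), cfg$blocks_per_level * n_per_block)
  if (length(unique(tr$block)) != cfg$blocks_per_level)
    note("block count %d != %d", length(unique(tr$block)), cfg$blocks_per_level)

  for (b in unique(tr$block)) {
    tb <- tr[tr$block == b, ]
    if (!identical(tb$kind,
                   c(rep("stimulus", cfg$stim_trials_per_block),
                     rep("baseline", cfg$baseline_trials_per_block))))
      note("block %d: trial kinds not 25 stimulus then 3 baseline", b)
    sb <- tb[tb$kind == "stimulus", ]
    n_freq <- sum(sb$category == "frequent")
    if (n_freq != round(cfg$frequent_fraction * cfg$stim_trials_per_block))
      note("block %d: %d frequent trials", b, n_freq)
    if (length(unique(sb$side[sb$category == "frequent"])) > 1 ||
        length(unique(sb$side[sb$category == "rare"])) > 1 ||
        any(sb$side[sb$category == "rare"] %in% sb$side[sb$category == "frequent"]))
      note("block %d: rare trials not all on the side opposite the frequent image", b)
    if (any(sb$image[sb$category == "rare"] %in% sb$image[sb$category == "frequent"]))
      note("block %d: frequent image appears among rare images", b)
  }

  bl <- tr[tr$kind == "baseline", ]
  if (any(bl$image != "none") || any(bl$tone_slot) || any(bl$distractor != "none"))
    note("baseline trials carry images, tones or distractors")

  slot_at <- which(tr$tone_slot)
  if (length(slot_at) > 1 && any(diff(slot_at) < 4))
    note("tone-slot spacing violation: paired-tone trial not followed by >= 3 toneless trials")
  n_slots <- length(slot_at)
  mix <- table(factor(tr$tone_pair_type[tr$tone_slot], levels = TONE_PAIR_TYPES))
  expected <- round(cfg$tone_pair_mix[TONE_PAIR_TYPES] * n_slots)
  if (n_slots > 0 && any(mix != expected))
    note("tone pair mix %s != expected %s",
         paste(mix, collapse = "/"), paste(expected, collapse = "/"))
  if (any(!tr$tone_offset_ms[tr$tone_slot] %in% cfg$tone_offsets_ms))
    note("tone offset outside configured set")

  fixed <- cfg$pre_mask_ms + cfg$stim_duration_ms + cfg$response_window_ms +
    cfg$end_baseline_min_ms
  if (any(tr$duration_ms < fixed | tr$duration_ms > fixed + cfg$jitter_max_ms))
    note("trial duration outside [%d, %d] ms", fixed, fixed + cfg$jitter_max_ms)
  if (any(abs(tr$onset_ms - cumsum(c(0, tr$duration_ms[-nrow(tr)]))) > 0))
    note("onsets not cumulative")

  list(stats = schedule_stats(schedule), violations = v)
}

#' Summary statistics of a schedule
#'
#' @param schedule an `erp_schedule`.
#' @return list: `n_trials`, `n_blocks`, `frequent_pct`, `rare_pct`
#'   (percent of stimulus trials), `deviant_tone_pct_of_tone_slots`,
#'   `mean_duration_ms`, `min_duration_ms`, `max_duration_ms`.
#' @export
schedule_stats <- function(schedule) {
  tr <- schedule$trials
  stim <- tr[tr$kind == "stimulus", ]
  n_slots <- sum(tr$tone_slot)
  list(
    n_trials = nrow(tr),
    n_blocks = length(unique(tr$block)),
    frequent_pct = 100 * mean(stim$category == "frequent"),
    rare_pct = 100 * mean(stim$category == "rare"),
    deviant_tone_pct_of_tone_slots =
      if (n_slots > 0) 100 * sum(tr$tone_pair_type == "std_dev") / n_slots else NA_real_,
    mean_duration_ms = mean(tr$duration_ms),
    min_duration_ms = min(tr$duration_ms),
    max_duration_ms = max(tr$duration_ms)
  )
}

#' @export
print.erp_schedule <- function(x, ...) {
  s <- schedule_stats(x)
  cat(sprintf("<erp_schedule> level %s, seed %d: %d trials in %d blocks\n",
              x$level, x$seed, s$n_trials, s$n_blocks))
  cat(sprintf("  frequent %.1f%% / rare %.1f%% of stimulus trials; deviant tones %.1f%% of tone slots\n",
              s$frequent_pct, s$rare_pct, s$deviant_tone_pct_of_tone_slots))
  cat(sprintf("  trial duration %d-%d ms (mean %.1f)\n",
              s$min_duration_ms, s$max_duration_ms, s$mean_duration_ms))
  invisible(x)
}
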