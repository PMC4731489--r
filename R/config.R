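#' Game levels, image types and response buttons
#'
#' Constants shared across the package. The paradigm runs in three game
#' levels of increasing complexity: passive/active observation (`Learn`),
#' agency detection with corollary-discharge tones (`Who`), and
#' meaningful-vs-ambiguous discrimination with a mid-level rule reversal
#' (`Discern`). Four two-tone salient image types are used: an intact
#' Mooney-style face stand-in, its distorted version, a Kanizsa triangle and
#' a distorted Kanizsa figure.
#'
#' @name paradigm-constants
#' @keywords internal
NULL

GAME_LEVELS <- c("Learn", "Who", "Discern")
IMAGE_TYPES <- c("mooney_face", "mooney_distorted", "kanizsa", "kanizsa_distorted")
SIDES <- c("left", "right")
TONE_PAIR_TYPES <- c("std_std", "std_dev", "silent")

#' Paradigm configuration
#'
#' Builds the timing/structure configuration for the three-level gamified
#' oddball paradigm. Defaults encode the reference design: a 240 ms salient
#' stimulus replacing one of two flanking checkerboards, up to 700 ms to
#' respond, a fixed 200 ms end-of-trial baseline extended by a uniform jitter
#' of up to 700 ms (trials therefore last 1200-1900 ms, mean 1550 ms),
#' 16 blocks of 25 stimulus + 3 baseline trials per level, an 80/20
#' frequent/rare visual oddball split, and paired 15 ms tones (1000 Hz
#' standard, 1500 Hz deviant, second tone 500 ms after the first) timed at
#' -240, -40 or +160 ms relative to visual onset.
#'
#' Paired tones occupy dedicated "tone slots": every fourth stimulus trial
#' within a block, each followed by at least three toneless trials. The
#' stated tone percentages are interpreted as fractions of tone slots:
#' 80% standard-standard pairs, 10% pairs with a deviant second tone, 10%
#' silent slots, enforced exactly per level.
#'
#' @param stim_duration_ms salient-image duration (ms).
#' @param response_window_ms post-stimulus response window (ms).
#' @param end_baseline_min_ms fixed minimum masked baseline at trial end (ms).
#' @param jitter_max_ms maximum random extension of the end baseline (ms).
#' @param pre_mask_ms pre-stimulus mask duration (ms).
#' @param tone_offsets_ms possible first-tone onsets relative to visual onset.
#' @param s1_s2_gap_ms separation of the paired tones (ms).
#' @param standard_tone_hz,deviant_tone_hz tone frequencies (Hz).
#' @param tone_duration_ms paired-tone duration (ms).
#' @param cd_tone_duration_ms corollary-discharge tone duration (ms).
#' @param blocks_per_level number of blocks per game level (must be even).
#' @param stim_trials_per_block stimulus trials per block.
#' @param baseline_trials_per_block fixation-only trials appended per block.
#' @param frequent_fraction fraction of stimulus trials showing the frequent
#'   image; `frequent_fraction * stim_trials_per_block` must be an integer.
#' @param feedback_low_pct,feedback_high_pct accuracy band edges (percent)
#'   for the between-block feedback messages (both edges inclusive in the
#'   middle band).
#' @param tone_slot_period spacing of tone slots in stimulus trials (a slot
#'   every `tone_slot_period` trials; must be >= 4 to leave three blank
#'   trials after each pair).
#' @param tone_slots_per_block number of tone slots per block.
#' @param tone_pair_mix named fractions (std_std/std_dev/silent) of tone
#'   slots; each count over a level must be an integer.
#' @param cd_random_delay_ms range (ms after stimulus offset) of the random
#'   corollary-discharge tone delay in `cd_random` blocks.
#'
#' @return a list of class `paradigm_config`.
#' @examples
#' cfg <- paradigm_config()
#' cfg$blocks_per_level * (cfg$stim_trials_per_block + cfg$baseline_trials_per_block)
#' @export
paradigm_config <- function(stim_duration_ms = 240,
                            response_window_ms = 700,
                            end_baseline_min_ms = 200,
                            jitter_max_ms = 700,
                            pre_mask_ms = 60,
                            tone_offsets_ms = c(-240, -40, 160),
                            s1_s2_gap_ms = 500,
                            standard_tone_hz = 1000,
                            deviant_tone_hz = 1500,
                            tone_duration_ms = 15,
                            cd_tone_duration_ms = 230,
                            blocks_per_level = 16,
                            stim_trials_per_block = 25,
                            baseline_trials_per_block = 3,
                            frequent_fraction = 0.8,
                            feedback_low_pct = 85,
                            feedback_high_pct = 95,
                            tone_slot_period = 4,
                            tone_slots_per_block = 5,
                            tone_pair_mix = c(std_std = 0.8, std_dev = 0.1, silent = 0.1),
                            cd_random_delay_ms = c(100, 500)) {
  cfg <- list(
    stim_duration_ms = stim_duration_ms,
    response_window_ms = response_window_ms,
    end_baseline_min_ms = end_baseline_min_ms,
    jitter_max_ms = jitter_max_ms,
    pre_mask_ms = pre_mask_ms,
    tone_offsets_ms = tone_offsets_ms,
    s1_s2_gap_ms = s1_s2_gap_ms,
    standard_tone_hz = standard_tone_hz,
    deviant_tone_hz = deviant_tone_hz,
    tone_duration_ms = tone_duration_ms,
    cd_tone_duration_ms = cd_tone_duration_ms,
    blocks_per_level = blocks_per_level,
    stim_trials_per_block = stim_trials_per_block,
    baseline_trials_per_block = baseline_trials_per_block,
    frequent_fraction = frequent_fraction,
    feedback_low_pct = feedback_low_pct,
    feedback_high_pct = feedback_high_pct,
    tone_slot_period = tone_slot_period,
    tone_slots_per_block = tone_slots_per_block,
    tone_pair_mix = tone_pair_mix,
    cd_random_delay_ms = cd_random_delay_ms
  )
  class(cfg) <- "paradigm_config"
  validate_config(cfg)
  cfg
}

#' Validate a paradigm configuration
#'
#' Checks the structural invariants required by the schedule generator and
#' raises a configuration error if any fails.
#'
#' @param config a `paradigm_config`.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  durs <- c(config$stim_duration_ms, config$response_window_ms,
            config$end_baseline_min_ms, config$pre_mask_ms,
            config$tone_duration_ms, config$cd_tone_duration_ms,
            config$s1_s2_gap_ms)
  abort_if(any(durs <= 0), "configuration error: all durations must be positive")
  abort_if(config$jitter_max_ms < 0, "configuration error: jitter must be >= 0")
  n_freq <- config$frequent_fraction * config$stim_trials_per_block
  abort_if(abs(n_freq - round(n_freq)) > 1e-9,
           "configuration error: frequent_fraction * stim_trials_per_block (%g) is not an integer",
           n_freq)
  abort_if(config$blocks_per_level %% 2 != 0,
           "configuration error: blocks_per_level must be even (passive/active and mode halving)")
  mix <- config$tone_pair_mix
  abort_if(!setequal(names(mix), TONE_PAIR_TYPES) || abs(sum(mix) - 1) > 1e-9,
           "configuration error: tone_pair_mix must be named std_std/std_dev/silent and sum to 1")
  n_slots <- config$tone_slots_per_block * config$blocks_per_level
  counts <- mix * n_slots
  abort_if(any(abs(counts - round(counts)) > 1e-9),
           "configuration error: tone_pair_mix * level slot count must give integer counts")
  abort_if(config$tone_slot_period < 4,
           "configuration error: tone_slot_period must be >= 4 (three blank trials after each pair)")
  last_slot <- 1 + (config$tone_slots_per_block - 1) * config$tone_slot_period
  abort_if(last_slot > config$stim_trials_per_block,
           "configuration error: block too short for %d tone slots at period %d",
           config$tone_slots_per_block, config$tone_slot_period)
  invisible(config)
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("<paradigm_config>\n")
  cat(sprintf("  %d blocks/level x (%d stimulus + %d baseline) trials\n",
              x$blocks_per_level, x$stim_trials_per_block, x$baseline_trials_per_block))
  cat(sprintf("  trial: %d mask + %d stim + %d response + %d baseline + U{0..%d} jitter ms\n",
              x$pre_mask_ms, x$stim_duration_ms, x$response_window_ms,
              x$end_baseline_min_ms, x$jitter_max_ms))
  cat(sprintf("  oddball: %.0f%% frequent; tones: %d slots/block, mix %s\n",
              100 * x$frequent_fraction, x$tone_slots_per_block,
              paste(sprintf("%s=%.0f%%", names(x$tone_pair_mix), 100 * x$tone_pair_mix),
                    collapse = " ")))
  invisible(x)
}
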