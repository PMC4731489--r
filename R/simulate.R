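#' Default 19-channel montage
#'
#' A 10-20-style montage containing every channel referenced by the
#' built-in contrasts (POz, PO7, PO8, Pz, FCz, Cz, C3, C4) plus fillers,
#' with approximate 2-D layout positions (unit head circle, nose up).
#'
#' @return an `erp_montage`: data frame with `channel`, `x`, `y`.
#' @export
default_montage <- function() {
  m <- data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FCz",
                "C3", "Cz", "C4", "P3", "Pz", "P4", "PO7", "POz", "PO8",
                "O1", "O2"),
    x = c(-0.3, 0.3, -0.7, -0.35, 0, 0.35, 0.7, 0,
          -0.4, 0, 0.4, -0.35, 0, 0.35, -0.55, 0, 0.55, -0.3, 0.3),
    y = c(0.9, 0.9, 0.5, 0.5, 0.5, 0.5, 0.5, 0.3,
          0, 0, 0, -0.5, -0.5, -0.5, -0.7, -0.7, -0.7, -0.9, -0.9),
    stringsAsFactors = FALSE
  )
  class(m) <- c("erp_montage", "data.frame")
  m
}

#' Construct an ERP component template
#'
#' A template adds a Gaussian-envelope deflection, time-locked to a class
#' of events, with a condition-dependent amplitude and a fixed (or
#' condition-dependent) scalp topography. Superposition is linear: the
#' simulated EEG is the sum of noise and all rendered templates, which is
#' what makes injected amplitudes recoverable ground truth.
#'
#' @param name component name.
#' @param lock `"stimulus"`, `"tone"` or `"response"` (metadata; the event
#'   class actually matched is given by `event_filter`).
#' @param event_filter function(events df) -> logical; which events receive
#'   the deflection.
#' @param peak_latency_ms peak latency relative to the locking event (may
#'   be negative, e.g. for motor preparation).
#' @param width_ms Gaussian envelope standard deviation (ms).
#' @param amp_fun function(event row) -> amplitude in microvolts.
#' @param topo named numeric vector of channel weights, or a
#'   function(event row) -> named weights for lateralised components.
#' @return an `erp_template`.
#' @export
erp_template <- function(name, lock, event_filter, peak_latency_ms, width_ms,
                         amp_fun, topo) {
  abort_if(width_ms <= 0, "template %s: width must be positive", name)
  topo_fun <- if (is.function(topo)) topo else function(row) topo
  if (!is.function(topo))
    abort_if(any(!is.finite(topo)), "template %s: topography weights must be finite", name)
  structure(list(name = name, lock = lock, event_filter = event_filter,
                 peak_latency_ms = peak_latency_ms, width_ms = width_ms,
                 amp_fun = amp_fun, topo_fun = topo_fun),
            class = "erp_template")
}

#' Default component templates (simulation ground truth)
#'
#' The ten injected components with amplitudes, latencies and topographies
#' chosen inside the qualitative windows the paradigm targets. These values
#' are configuration, not empirical claims: they serve as ground truth for
#' the recovery tests.
#'
#' * C1: stimulus-locked, 80 ms, POz; polarity flips with the top/bottom
#'   distractor position (-1 uV top, +1 uV bottom).
#' * P50: tone-locked, 55 ms, fronto-central; S1 +2 uV, S2 +1 uV
#'   (sensory-gating attenuation of the second click).
#' * MMN: locked to the second tone, 200 ms; deviant -3 uV vs standard
#'   -0.5 uV.
#' * N1 / P2: locked to the corollary-discharge tone (Who level); -4 / +3
#'   uV, attenuated by `cd_attenuation` when the tone is self-triggered
#'   (`cd_immediate` blocks).
#' * N170: stimulus-locked, 220 ms, PO8; shapes stronger than faces
#'   (kanizsa -6, distorted kanizsa -5, face -4, distorted face -3 uV),
#'   scaled by game-level complexity (`level_scale`).
#' * N2pc: stimulus-locked, 250 ms; -1.5 uV over the hemisphere
#'   contralateral to the salient image.
#' * LRP: response-locked, peak 50 ms before the press; -2 uV over the
#'   motor cortex contralateral to the responding hand.
#' * P300: stimulus-locked, 400 ms, Pz; rare +5 uV vs frequent +1 uV.
#' * ERN: response-locked, 60 ms, FCz; incorrect -4 uV vs correct -1 uV.
#'
#' All topographies are zero-sum across the 19-channel montage (dipolar
#' fields with return weights over unmeasured frontal/occipital channels),
#' as real scalp potentials are under an average reference; this keeps
#' average re-referencing from mixing components into each other's
#' measurement channels.
#'
#' @param cd_attenuation multiplicative attenuation of N1/P2 for
#'   self-triggered (cd_immediate) tones; 0.5 by default.
#' @param level_scale named multipliers of the N170 amplitude per game
#'   level, encoding the complexity effect.
#' @return named list of [erp_template()] objects.
#' @export
default_templates <- function(cd_attenuation = 0.5,
                              level_scale = c(Learn = 0.7, Who = 0.85, Discern = 1)) {
  cd_scale <- function(row) if (row$block_mode == "cd_immediate") cd_attenuation else 1
  list(
    C1 = erp_template("C1", "stimulus",
      function(ev) ev$event_type == "stimulus",
      peak_latency_ms = 80, width_ms = 25,
      amp_fun = function(row) if (row$distractor == "top") -1 else 1,
      topo = c(POz = 1, PO7 = 0.4, PO8 = 0.4, Fz = -0.6, F3 = -0.6, F4 = -0.6)),
    P50 = erp_template("P50", "tone",
      function(ev) ev$event_type %in% c("tone_s1", "tone_s2"),
      peak_latency_ms = 55, width_ms = 15,
      amp_fun = function(row) if (row$event_type == "tone_s1") 2 else 1,
      topo = c(FCz = 1, Cz = 0.8, O1 = -0.9, O2 = -0.9)),
    MMN = erp_template("MMN", "tone",
      function(ev) ev$event_type == "tone_s2",
      peak_latency_ms = 200, width_ms = 40,
      amp_fun = function(row) if (row$tone_pair_type == "std_dev") -3 else -0.5,
      topo = c(FCz = 1, Cz = 0.8, O1 = -0.9, O2 = -0.9)),
    N1 = erp_template("N1", "tone",
      function(ev) ev$event_type == "tone_cd",
      peak_latency_ms = 100, width_ms = 30,
      amp_fun = function(row) -4 * cd_scale(row),
      topo = c(Cz = 1, FCz = 0.8, O1 = -0.9, O2 = -0.9)),
    P2 = erp_template("P2", "tone",
      function(ev) ev$event_type == "tone_cd",
      peak_latency_ms = 200, width_ms = 45,
      amp_fun = function(row) 3 * cd_scale(row),
      topo = c(Cz = 1, FCz = 0.8, O1 = -0.9, O2 = -0.9)),
    N170 = erp_template("N170", "stimulus",
      function(ev) ev$event_type == "stimulus",
      peak_latency_ms = 220, width_ms = 35,
      amp_fun = function(row) {
        base <- switch(row$image, kanizsa = -6, kanizsa_distorted = -5,
                       mooney_face = -4, mooney_distorted = -3, 0)
        base * level_scale[[row$level]]
      },
      topo = c(PO8 = 1, PO7 = 0.8, Fz = -0.6, F3 = -0.6, F4 = -0.6)),
    N2pc = erp_template("N2pc", "stimulus",
      function(ev) ev$event_type == "stimulus",
      peak_latency_ms = 250, width_ms = 40,
      amp_fun = function(row) -1.5,
      topo = function(row) if (row$side == "left") c(PO8 = 1, F8 = -1) else c(PO7 = 1, F7 = -1)),
    LRP = erp_template("LRP", "response",
      function(ev) ev$event_type == "response",
      peak_latency_ms = -50, width_ms = 60,
      amp_fun = function(row) -2,
      topo = function(row) if (row$button == "left") c(C4 = 1, Fp2 = -1) else c(C3 = 1, Fp1 = -1)),
    P300 = erp_template("P300", "stimulus",
      function(ev) ev$event_type == "stimulus",
      peak_latency_ms = 400, width_ms = 80,
      amp_fun = function(row) if (row$category == "rare") 5 else 1,
      topo = c(Pz = 1, POz = 0.6, Fp1 = -0.8, Fp2 = -0.8)),
    ERN = erp_template("ERN", "response",
      function(ev) ev$event_type == "response",
      peak_latency_ms = 60, width_ms = 30,
      amp_fun = function(row) if (row$accuracy == "incorrect") -4 else -1,
      topo = c(FCz = 1, O1 = -0.5, O2 = -0.5))
  )
}

#' Default behavioural profile of the simulated subject
#'
#' Reaction times are log-normal (median `rt_median_ms`, log-sd
#' `rt_spread`), truncated by the 700 ms response window (slower draws
#' become misses). Accuracy is high in the first two levels and lower in
#' the discrimination level; the first block after the Discern rule
#' reversal suffers an additional lapse probability. `noise_uV` is the RMS
#' of the 1/f background in each channel.
#'
#' @param rt_median_ms median reaction time (ms).
#' @param rt_spread log-normal sigma of the RT distribution.
#' @param accuracy named per-level probability of a correct response.
#' @param reversal_lapse_p extra error probability in the first
#'   post-reversal block of Discern.
#' @param noise_uV RMS amplitude of the pink background noise.
#' @return a `subject_profile` list.
#' @export
default_profile <- function(rt_median_ms = 420, rt_spread = 0.25,
                            accuracy = c(Learn = 0.97, Who = 0.95, Discern = 0.85),
                            reversal_lapse_p = 0.25, noise_uV = 2) {
  abort_if(any(accuracy <= 0 | accuracy > 1), "accuracies must be in (0, 1]")
  structure(list(rt_median_ms = rt_median_ms, rt_spread = rt_spread,
                 accuracy = accuracy, reversal_lapse_p = reversal_lapse_p,
                 noise_uV = noise_uV),
            class = "subject_profile")
}

#' Simulate button responses for a schedule
#'
#' Applies the behavioural model to every trial: passive blocks and
#' baseline trials yield no response; active trials draw a truncated
#' log-normal RT (draws beyond the response window are misses) and a
#' correct/incorrect button according to the per-level accuracy, with
#' elevated lapses in the first post-reversal Discern block.
#'
#' @param schedule an `erp_schedule`.
#' @param profile a [default_profile()].
#' @param seed integer seed.
#' @return data frame: `trial`, `button` (`"left"`/`"right"`/`"none"`),
#'   `rt_ms` (NA when no response) and `accuracy` (`"correct"`,
#'   `"incorrect"`, `"miss"`, `"na"`).
#' @export
simulate_behavior <- function(schedule, profile = default_profile(), seed = 1) {
  with_seed(seed, simulate_behavior_rng(schedule, profile))
}

# behaviour using the current RNG stream (so simulate_recording can nest it)
simulate_behavior_rng <- function(schedule, profile) {
  tr <- schedule$trials
  cfg <- schedule$config
  n <- nrow(tr)
  button <- rep("none", n)
  rt <- rep(NA_real_, n)
  acc <- rep("na", n)
  active <- tr$kind == "stimulus" & tr$expected_button != "none"
  p <- unname(profile$accuracy[tr$level[active]])
  if (schedule$level == "Discern") {
    first_rev <- min(tr$block[tr$block_mode == "rule_B"])
    p <- ifelse(tr$block[active] == first_rev,
                pmax(0.05, p - profile$reversal_lapse_p), p)
  }
  rts <- stats::rlnorm(sum(active), meanlog = log(profile$rt_median_ms),
                       sdlog = profile$rt_spread)
  correct <- stats::runif(sum(active)) < p
  miss <- rts > cfg$response_window_ms
  idx <- which(active)
  expected <- tr$expected_button[idx]
  other <- ifelse(expected == "left", "right", "left")
  button[idx] <- ifelse(miss, "none", ifelse(correct, expected, other))
  rt[idx] <- ifelse(miss, NA_real_, rts)
  acc[idx] <- ifelse(miss, "miss", ifelse(correct, "correct", "incorrect"))
  data.frame(trial = tr$trial, button = button, rt_ms = rt, accuracy = acc,
             stringsAsFactors = FALSE)
}

#' Pink (1/f) background noise
#'
#' Spectral synthesis: independent Gaussian spectra per channel shaped by
#' 1/sqrt(f), giving a log-log spectral power slope of approximately -1,
#' scaled to the requested per-channel RMS.
#'
#' @param n_channels,n_samples output dimensions.
#' @param srate sampling rate (Hz); `n_samples` must exceed `srate`.
#' @param amplitude_uV per-channel RMS in microvolts (0 gives silence).
#' @param seed integer seed.
#' @return `n_channels x n_samples` matrix.
#' @export
pink_noise <- function(n_channels, n_samples, srate, amplitude_uV, seed = 1) {
  abort_if(n_samples <= srate, "parameter error: n_samples must exceed srate")
  with_seed(seed, pink_noise_rng(n_channels, n_samples, srate, amplitude_uV))
}

pink_noise_rng <- function(n_channels, n_samples, srate, amplitude_uV) {
  if (amplitude_uV == 0) return(matrix(0, n_channels, n_samples))
  # synthesise at a power-of-two length (mixed-radix FFTs degrade badly
  # for awkward lengths) and keep the first n_samples
  n <- stats::nextn(n_samples, 2)
  k <- seq_len(n) - 1
  f <- k * srate / n
  f <- pmin(f, srate - f)          # mirrored bin frequencies
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    x <- stats::rnorm(n)
    y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE))[seq_len(n_samples)] / n
    out[ch, ] <- y * amplitude_uV / stats::sd(y)
  }
  out
}

#' Render one component template into a signal array
#'
#' Every event matched by the template's filter adds a Gaussian-envelope
#' deflection at `lock time + peak latency`, scaled by the condition rule
#' and the topography weights. Components superpose linearly. Events whose
#' envelope would extend past the recording end are skipped with a warning.
#'
#' @param template an [erp_template()].
#' @param events event data frame with a `sample` column plus condition
#'   fields.
#' @param channels montage channel names (row order of the output).
#' @param n_samples length of the recording in samples.
#' @param srate sampling rate (Hz).
#' @return `length(channels) x n_samples` matrix of microvolts.
#' @export
render_component <- function(template, events, channels, n_samples, srate) {
  sig <- matrix(0, length(channels), n_samples)
  hit <- which(template$event_filter(events))
  if (length(hit) == 0) return(sig)
  width_smp <- template$width_ms * srate / 1000
  half <- ceiling(4 * width_smp)
  n_skipped <- 0
  for (i in hit) {
    row <- events[i, ]
    amp <- template$amp_fun(row)
    if (amp == 0) next
    center <- row$sample + template$peak_latency_ms * srate / 1000
    i0 <- floor(center - half)
    i1 <- ceiling(center + half)
    if (i0 > n_samples || i1 < 1) { n_skipped <- n_skipped + 1; next }
    i0 <- max(i0, 1); i1 <- min(i1, n_samples)
    g <- exp(-((i0:i1 - center) / width_smp)^2 / 2)
    w <- template$topo_fun(row)
    ch_idx <- match(names(w), channels)
    ok <- !is.na(ch_idx)
    for (j in which(ok)) {
      sig[ch_idx[j], i0:i1] <- sig[ch_idx[j], i0:i1] + amp * w[j] * g
    }
  }
  if (n_skipped > 0)
    warning(sprintf("template %s: %d events beyond recording bounds skipped",
                    template$name, n_skipped))
  sig
}

#' Simulate a multichannel EEG recording for a schedule
#'
#' Composes the full simulation: behavioural responses, a sample-accurate
#' event list (trial onsets, visual onsets, paired tones with the second
#' tone 500 ms after the first, corollary-discharge tones, responses),
#' pink background noise, and the linear superposition of all component
#' templates.
#'
#' @param schedule an `erp_schedule` from [generate_level()].
#' @param montage an `erp_montage` (default [default_montage()]).
#' @param profile a [default_profile()].
#' @param templates list of [erp_template()]s (default
#'   [default_templates()]).
#' @param seed integer seed driving behaviour, event jitter and noise.
#' @param srate sampling rate in Hz (250 by default, the analysis rate the
#'   pipeline targets).
#' @param pad_s silent padding (noise only) before the first and after the
#'   last trial, so edge epochs survive windowing.
#' @return an `erp_recording`: list with `signal` (channels x samples,
#'   microvolts), `srate`, `channels`, `events`, `montage`, `level`,
#'   `seed`.
#' @export
simulate_recording <- function(schedule, montage = default_montage(),
                               profile = default_profile(),
                               templates = default_templates(),
                               seed = 1, srate = 250, pad_s = 2) {
  min_width <- min(vapply(templates, function(t) t$width_ms, numeric(1)))
  abort_if(srate < 1000 / min_width,
           "parameter error: srate %g Hz too low for component width %g ms",
           srate, min_width)
  with_seed(seed, {
    behavior <- simulate_behavior_rng(schedule, profile)
    events <- build_event_list(schedule, behavior, srate, pad_s)
    n_samples <- max(events$sample) + pad_s * srate
    channels <- montage$channel
    signal <- pink_noise_rng(length(channels), n_samples, srate, profile$noise_uV)
    for (tp in templates) {
      signal <- signal + render_component(tp, events, channels, n_samples, srate)
    }
    structure(list(signal = signal, srate = srate, channels = channels,
                   events = events, montage = montage, level = schedule$level,
                   seed = as.integer(seed), profile = profile),
              class = "erp_recording")
  })
}

# Sample-accurate event list. Uses the current RNG stream for the random
# corollary-discharge delays.
build_event_list <- function(schedule, behavior, srate, pad_s) {
  tr <- schedule$trials
  cfg <- schedule$config
  pad_ms <- pad_s * 1000
  tr$button <- behavior$button
  tr$rt_ms <- behavior$rt_ms
  tr$accuracy <- behavior$accuracy
  tr$marker_code <- encode_event_marker(tr, button = tr$button, accuracy = tr$accuracy)

  ev <- function(rows, type, ms, duration_ms) {
    if (length(ms) == 0 || nrow(rows) == 0) return(NULL)
    data.frame(event_type = type, ms = ms, duration_ms = duration_ms,
               rows[, c("level", "block", "block_mode", "trial", "trial_in_block",
                        "kind", "image", "side", "category", "tone_slot",
                        "tone_offset_ms", "tone_pair_type", "distractor",
                        "expected_button", "button", "rt_ms", "accuracy",
                        "marker_code")],
               stringsAsFactors = FALSE)
  }

  out <- list(ev(tr, "trial_onset", pad_ms + tr$onset_ms, tr$duration_ms))

  stim <- tr[tr$kind == "stimulus", ]
  vis_ms <- pad_ms + stim$onset_ms + cfg$pre_mask_ms
  out <- c(out, list(ev(stim, "stimulus", vis_ms, cfg$stim_duration_ms)))

  tone <- stim[stim$tone_slot & stim$tone_pair_type != "silent", ]
  if (nrow(tone) > 0) {
    t_vis <- pad_ms + tone$onset_ms + cfg$pre_mask_ms
    s1 <- t_vis + tone$tone_offset_ms
    out <- c(out, list(ev(tone, "tone_s1", s1, cfg$tone_duration_ms),
                       ev(tone, "tone_s2", s1 + cfg$s1_s2_gap_ms, cfg$tone_duration_ms)))
  }

  if (schedule$level == "Who") {
    resp <- stim[stim$block_mode == "cd_immediate" & stim$button != "none", ]
    if (nrow(resp) > 0) {
      cd_ms <- pad_ms + resp$onset_ms + cfg$pre_mask_ms + resp$rt_ms
      out <- c(out, list(ev(resp, "tone_cd", cd_ms, cfg$cd_tone_duration_ms)))
    }
    rnd <- stim[stim$block_mode == "cd_random", ]
    if (nrow(rnd) > 0) {
      delay <- stats::runif(nrow(rnd), cfg$cd_random_delay_ms[1], cfg$cd_random_delay_ms[2])
      cd_ms <- pad_ms + rnd$onset_ms + cfg$pre_mask_ms +
        ifelse(rnd$button == "none", cfg$response_window_ms,
               cfg$stim_duration_ms + delay)
      out <- c(out, list(ev(rnd, "tone_cd", cd_ms, cfg$cd_tone_duration_ms)))
    }
  }

  responded <- tr[tr$button != "none", ]
  if (nrow(responded) > 0) {
    resp_ms <- pad_ms + responded$onset_ms + cfg$pre_mask_ms + responded$rt_ms
    out <- c(out, list(ev(responded, "response", resp_ms, 0)))
  }

  events <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  events$sample <- round(events$ms * srate / 1000) + 1L
  events <- events[order(events$sample, events$event_type), ]
  rownames(events) <- NULL
  events
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<erp_recording> level %s: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              x$level, nrow(x$signal), ncol(x$signal), x$srate,
              ncol(x$signal) / x$srate, nrow(x$events)))
  invisible(x)
}
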