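#' Registry of the ten built-in ERP contrasts
#'
#' One entry per targeted component, each holding the locking event class,
#' the measurement channel(s), the analysis window, the condition
#' predicates and the contrast arithmetic:
#'
#' * `C1`: top vs bottom distractor at POz, 40-120 ms (polarity flip).
#' * `P50`: first (S1) vs second (S2) paired tone, fronto-central,
#'   30-80 ms post-tone (sensory gating; gating metric = S2/S1 amplitude
#'   ratio).
#' * `MMN`: deviant vs standard S2 tone, fronto-central, 150-250 ms.
#' * `N1`, `P2`: externally-triggered (`cd_random`) vs self-triggered
#'   (`cd_immediate`) corollary-discharge tone, Cz, 70-130 / 160-240 ms.
#' * `N170`: four-level image factor (FacePresent = intact face stand-in,
#'   FaceAbsent = distorted face, ShapePresent = Kanizsa, ShapeAbsent =
#'   distorted Kanizsa) at PO8, 170-250 ms.
#' * `N2pc`: contralateral minus ipsilateral to the salient image at
#'   PO7/PO8, 200-300 ms.
#' * `LRP`: double subtraction over C3/C4 by response hand,
#'   response-locked, -150..50 ms.
#' * `P300`: rare vs frequent at Pz, 300-500 ms.
#' * `ERN`: incorrect vs correct response at FCz, response-locked,
#'   0-100 ms.
#'
#' @return named list of `contrast_spec` lists with fields `name`, `lock`,
#'   `event_type`, `channels`, `window_ms`, `epoch_window_ms`,
#'   `baseline_ms`, `arithmetic`, and predicates `cond_A`/`cond_B` (or
#'   `factor_fun` for N170).
#' @export
builtin_contrasts <- function() {
  spec <- function(name, lock, event_type, channels, window_ms, arithmetic,
                   cond_A = NULL, cond_B = NULL, factor_fun = NULL,
                   epoch_window_ms, baseline_ms, measure = "mean",
                   balance = NULL) {
    structure(list(name = name, lock = lock, event_type = event_type,
                   channels = channels, window_ms = window_ms,
                   arithmetic = arithmetic, cond_A = cond_A, cond_B = cond_B,
                   factor_fun = factor_fun, epoch_window_ms = epoch_window_ms,
                   baseline_ms = baseline_ms, measure = measure,
                   balance = balance),
              class = "contrast_spec")
  }
  stim_win <- c(-1000, 2000); stim_base <- c(-200, 0)
  resp_win <- c(-500, 800); resp_base <- c(-450, -250)
  tone_win <- c(-200, 600); tone_base <- c(-100, 0)
  list(
    C1 = spec("C1", "stimulus", "stimulus", "POz", c(40, 120), "difference",
              cond_A = function(l) l$distractor == "top",
              cond_B = function(l) l$distractor == "bottom",
              epoch_window_ms = stim_win, baseline_ms = stim_base),
    P50 = spec("P50", "tone", c("tone_s1", "tone_s2"), "Cz", c(30, 80), "difference",
               cond_A = function(l) l$event_type == "tone_s1",
               cond_B = function(l) l$event_type == "tone_s2",
               epoch_window_ms = tone_win, baseline_ms = tone_base),
    MMN = spec("MMN", "tone", "tone_s2", "Cz", c(150, 250), "difference",
               cond_A = function(l) l$tone_pair_type == "std_dev",
               cond_B = function(l) l$tone_pair_type == "std_std",
               epoch_window_ms = tone_win, baseline_ms = tone_base),
    N1 = spec("N1", "tone", "tone_cd", "Cz", c(70, 130), "difference",
              cond_A = function(l) l$block_mode == "cd_random",
              cond_B = function(l) l$block_mode == "cd_immediate",
              epoch_window_ms = tone_win, baseline_ms = tone_base),
    P2 = spec("P2", "tone", "tone_cd", "Cz", c(160, 240), "difference",
              cond_A = function(l) l$block_mode == "cd_random",
              cond_B = function(l) l$block_mode == "cd_immediate",
              epoch_window_ms = tone_win, baseline_ms = tone_base),
    N170 = spec("N170", "stimulus", "stimulus", "PO8", c(170, 250), "factor",
                factor_fun = function(l) {
                  factor(c(mooney_face = "FacePresent",
                           mooney_distorted = "FaceAbsent",
                           kanizsa = "ShapePresent",
                           kanizsa_distorted = "ShapeAbsent")[l$image],
                         levels = c("FacePresent", "FaceAbsent",
                                    "ShapePresent", "ShapeAbsent"))
                },
                # image type correlates with presentation side within a
                # block, so condition means are computed side-balanced to
                # keep the lateralised N2pc out of the image factor
                balance = function(l) l$side,
                epoch_window_ms = stim_win, baseline_ms = stim_base),
    N2pc = spec("N2pc", "stimulus", "stimulus", c("PO7", "PO8"), c(200, 300),
                "contra_minus_ipsi",
                cond_A = function(l) l$side == "left",
                cond_B = function(l) l$side == "right",
                epoch_window_ms = stim_win, baseline_ms = stim_base),
    LRP = spec("LRP", "response", "response", c("C3", "C4"), c(-150, 50),
               "double_subtraction",
               cond_A = function(l) l$button == "left",
               cond_B = function(l) l$button == "right",
               epoch_window_ms = resp_win, baseline_ms = resp_base),
    P300 = spec("P300", "stimulus", "stimulus", "Pz", c(300, 500), "difference",
                cond_A = function(l) l$category == "rare",
                cond_B = function(l) l$category == "frequent",
                epoch_window_ms = stim_win, baseline_ms = stim_base),
    ERN = spec("ERN", "response", "response", "FCz", c(0, 100), "difference",
               cond_A = function(l) l$accuracy == "incorrect",
               cond_B = function(l) l$accuracy == "correct",
               epoch_window_ms = resp_win, baseline_ms = resp_base)
  )
}

#' Condition-average ERP waveform
#'
#' Pointwise mean over the epochs matching a predicate, at one channel.
#'
#' @param epochs an `erp_epochs`.
#' @param predicate logical vector over epochs, or function(labels) ->
#'   logical; `NULL` keeps all epochs.
#' @param channel channel name.
#' @return an `erp_waveform`: list `time_ms`, `mean_uV`, `n`, `channel`.
#' @export
average_erp <- function(epochs, predicate = NULL, channel) {
  ch <- match(channel, epochs$channels)
  abort_if(is.na(ch), "selection error: channel %s not in epochs", channel)
  keep <- resolve_predicate(predicate, epochs$labels)
  abort_if(sum(keep) == 0, "selection error: no epochs match the predicate")
  erp_waveform(epochs$times_ms,
               apply(epochs$data[keep, ch, , drop = FALSE], 3, mean),
               n = sum(keep), channel = channel)
}

resolve_predicate <- function(predicate, labels) {
  if (is.null(predicate)) rep(TRUE, nrow(labels))
  else if (is.function(predicate)) {
    k <- predicate(labels); k & !is.na(k)
  } else {
    predicate & !is.na(predicate)
  }
}

#' Construct an ERP waveform container
#'
#' @param time_ms time grid (ms).
#' @param mean_uV mean amplitude per time point (microvolts; negative =
#'   downward by the stored-value sign convention).
#' @param n number of epochs averaged.
#' @param channel channel (or derivation) label.
#' @return an `erp_waveform`.
#' @export
erp_waveform <- function(time_ms, mean_uV, n, channel) {
  structure(list(time_ms = time_ms, mean_uV = as.numeric(mean_uV), n = n,
                 channel = channel), class = "erp_waveform")
}

#' Lateralised readiness potential (double subtraction)
#'
#' Classic LRP derivation over the motor channels: the mean of (C3 - C4)
#' for right-hand responses and (C4 - C3) for left-hand responses, halved,
#' on response-locked epochs. Hemisphere-symmetric activity cancels;
#' swapping the channel labels flips the sign.
#'
#' @param epochs response-locked `erp_epochs`.
#' @param left_pred,right_pred predicates selecting left- and right-hand
#'   response epochs (default: `button` label).
#' @param c3,c4 channel names.
#' @return an `erp_waveform` (channel `"LRP"`).
#' @export
lrp <- function(epochs, left_pred = function(l) l$button == "left",
                right_pred = function(l) l$button == "right",
                c3 = "C3", c4 = "C4") {
  left <- resolve_predicate(left_pred, epochs$labels)
  right <- resolve_predicate(right_pred, epochs$labels)
  abort_if(sum(left) == 0 || sum(right) == 0,
           "selection error: both response hands must be represented")
  w_c3_r <- average_erp(epochs, right, c3)$mean_uV
  w_c4_r <- average_erp(epochs, right, c4)$mean_uV
  w_c3_l <- average_erp(epochs, left, c3)$mean_uV
  w_c4_l <- average_erp(epochs, left, c4)$mean_uV
  erp_waveform(epochs$times_ms, ((w_c3_r - w_c4_r) + (w_c4_l - w_c3_l)) / 2,
               n = sum(left) + sum(right), channel = "LRP")
}

#' N2pc derivation (contralateral minus ipsilateral)
#'
#' Averages the posterior-lateral channels with side-matched assignment:
#' for left-side targets the contralateral channel is the right-hemisphere
#' one (PO8), and vice versa; the N2pc is the mean of the two
#' contralateral-minus-ipsilateral differences.
#'
#' @param epochs stimulus-locked `erp_epochs`.
#' @param left_pred,right_pred predicates for target side.
#' @param po7,po8 left- and right-hemisphere channel names.
#' @return an `erp_waveform` (channel `"N2pc"`).
#' @export
n2pc <- function(epochs, left_pred = function(l) l$side == "left",
                 right_pred = function(l) l$side == "right",
                 po7 = "PO7", po8 = "PO8") {
  left <- resolve_predicate(left_pred, epochs$labels)
  right <- resolve_predicate(right_pred, epochs$labels)
  abort_if(sum(left) == 0 || sum(right) == 0,
           "selection error: both target sides must be represented")
  contra_l <- average_erp(epochs, left, po8)$mean_uV -
    average_erp(epochs, left, po7)$mean_uV
  contra_r <- average_erp(epochs, right, po7)$mean_uV -
    average_erp(epochs, right, po8)$mean_uV
  erp_waveform(epochs$times_ms, (contra_l + contra_r) / 2,
               n = sum(left) + sum(right), channel = "N2pc")
}

#' Amplitude measure over a window
#'
#' @param waveform an `erp_waveform`.
#' @param window_ms two-element window inside the time grid.
#' @param mode `"mean"` (window mean) or `"peak"` (signed extremum, i.e.
#'   the value of largest magnitude in the window).
#' @return amplitude in microvolts.
#' @export
amplitude_measure <- function(waveform, window_ms, mode = c("mean", "peak")) {
  mode <- match.arg(mode)
  idx <- which(waveform$time_ms >= window_ms[1] & waveform$time_ms <= window_ms[2])
  abort_if(length(idx) == 0, "parameter error: empty measurement window")
  v <- waveform$mean_uV[idx]
  if (mode == "mean") mean(v) else v[which.max(abs(v))]
}

#' One-sample Cohen's d against baseline
#'
#' Effect size of baseline-corrected amplitudes: d = mean / SD (one-sample
#' test against zero). d is invariant under positive rescaling of the
#' amplitudes; use `abs()` when comparing magnitudes across components of
#' opposite polarity.
#'
#' @param per_subject_amplitudes numeric vector (n >= 2).
#' @return Cohen's d.
#' @export
cohens_d_vs_baseline <- function(per_subject_amplitudes) {
  x <- per_subject_amplitudes
  abort_if(length(x) < 2, "degenerate error: need n >= 2 amplitudes")
  s <- stats::sd(x)
  abort_if(s == 0, "degenerate error: zero variance in amplitudes")
  mean(x) / s
}

#' Compute a registered contrast from a recording
#'
#' Runs the standard chain for one contrast: select locking events, filter
#' (optional, on by default), epoch, average-reference, baseline-correct,
#' reject extreme epochs, then apply the contrast arithmetic.
#'
#' @param recording an `erp_recording` (or a pre-filtered one).
#' @param spec one entry of [builtin_contrasts()].
#' @param filter apply [filter_band()] first (set `FALSE` if the recording
#'   is already filtered).
#' @param reject_uV rejection threshold, `NULL` to skip.
#' @return list with `name`, per-condition waveforms (`waves`), the
#'   contrast waveform `contrast` (NULL for the pure factor arithmetic),
#'   window `amplitude` of the contrast, and per-condition window
#'   amplitudes `cond_amplitudes`.
#' @export
compute_contrast <- function(recording, spec, filter = TRUE, reject_uV = 100) {
  if (filter) recording <- filter_band(recording)
  ev <- recording$events[recording$events$event_type %in% spec$event_type, ]
  abort_if(nrow(ev) == 0, "selection error: no %s events in recording",
           paste(spec$event_type, collapse = "/"))
  ep <- epoch(recording, ev, lock = spec$lock, window_ms = spec$epoch_window_ms)
  ep <- average_reference(ep)
  ep <- baseline_correct(ep, spec$baseline_ms)
  if (!is.null(reject_uV)) ep <- reject_epochs(ep, reject_uV)
  contrast_from_epochs(ep, spec)
}

#' Apply contrast arithmetic to prepared epochs
#'
#' @param ep baseline-corrected `erp_epochs` locked to the contrast's
#'   events.
#' @param spec a `contrast_spec`.
#' @return see [compute_contrast()].
#' @export
contrast_from_epochs <- function(ep, spec) {
  out <- list(name = spec$name, window_ms = spec$window_ms)
  if (spec$arithmetic == "difference") {
    wA <- average_erp(ep, spec$cond_A, spec$channels[1])
    wB <- average_erp(ep, spec$cond_B, spec$channels[1])
    diff <- erp_waveform(ep$times_ms, wA$mean_uV - wB$mean_uV,
                         n = min(wA$n, wB$n), channel = spec$channels[1])
    out$waves <- list(A = wA, B = wB)
    out$contrast <- diff
  } else if (spec$arithmetic == "contra_minus_ipsi") {
    out$contrast <- n2pc(ep, spec$cond_A, spec$cond_B,
                         po7 = spec$channels[1], po8 = spec$channels[2])
    out$waves <- list()
  } else if (spec$arithmetic == "double_subtraction") {
    out$contrast <- lrp(ep, spec$cond_A, spec$cond_B,
                        c3 = spec$channels[1], c4 = spec$channels[2])
    out$waves <- list()
  } else if (spec$arithmetic == "factor") {
    f <- spec$factor_fun(ep$labels)
    strata <- if (is.null(spec$balance)) factor(rep("all", nrow(ep$labels)))
              else factor(spec$balance(ep$labels))
    out$waves <- lapply(stats::setNames(levels(f), levels(f)), function(lv) {
      # unweighted mean over strata of the stratum-condition averages
      ws <- lapply(levels(strata), function(st) {
        sel <- !is.na(f) & f == lv & strata == st
        if (sum(sel) == 0) return(NULL)
        average_erp(ep, sel, spec$channels[1])
      })
      ws <- ws[!vapply(ws, is.null, logical(1))]
      erp_waveform(ep$times_ms,
                   rowMeans(vapply(ws, function(w) w$mean_uV,
                                   numeric(length(ep$times_ms)))),
                   n = sum(vapply(ws, function(w) w$n, numeric(1))),
                   channel = spec$channels[1])
    })
    # summary contrast: strongest minus weakest injected condition
    amps <- vapply(out$waves, amplitude_measure, numeric(1),
                   window_ms = spec$window_ms)
    hi <- names(which.max(abs(amps)))
    lo <- names(which.min(abs(amps)))
    out$contrast <- erp_waveform(ep$times_ms,
                                 out$waves[[hi]]$mean_uV - out$waves[[lo]]$mean_uV,
                                 n = min(out$waves[[hi]]$n, out$waves[[lo]]$n),
                                 channel = spec$channels[1])
    out$contrast_pair <- c(hi, lo)
  } else {
    stop("unknown contrast arithmetic: ", spec$arithmetic)
  }
  out$cond_amplitudes <- if (length(out$waves) > 0)
    vapply(out$waves, amplitude_measure, numeric(1), window_ms = spec$window_ms)
  else NULL
  out$amplitude <- amplitude_measure(out$contrast, spec$window_ms)
  out$n_epochs <- c(vapply(out$waves, function(w) w$n, numeric(1)),
                    contrast = out$contrast$n)
  out
}

#' P50 sensory-gating ratio
#'
#' The amplitude reduction from the first (S1) to the second (S2) click of
#' a tone pair, expressed as the S2/S1 window-amplitude ratio: 1 means no
#' gating, smaller values mean stronger suppression of the repeated sound.
#'
#' @param contrast_result result of computing the `P50` registry entry
#'   (see [compute_contrast()]), whose condition A is S1 and B is S2.
#' @return the S2/S1 amplitude ratio.
#' @export
p50_gating_ratio <- function(contrast_result) {
  amps <- contrast_result$cond_amplitudes
  abort_if(is.null(amps) || !all(c("A", "B") %in% names(amps)),
           "parameter error: need a two-condition P50 contrast result")
  abort_if(amps[["A"]] == 0, "degenerate error: zero S1 amplitude")
  amps[["B"]] / amps[["A"]]
}

#' Cross-level complexity comparison of a contrast
#'
#' Computes the same contrast in each supplied level and reports the
#' aligned waveforms, the per-level window amplitudes, and whether the
#' amplitude magnitudes are monotone in the supplied level order
#' (monotonicity is reported, never assumed). Levels where the contrast is
#' undefined (e.g. no corollary-discharge tones outside Who) are skipped
#' with a note.
#'
#' @param erp_name name of a registered contrast.
#' @param recordings named list of `erp_recording`s, one per level, in
#'   increasing complexity order.
#' @param wave_name for factor contrasts, which condition wave to track
#'   across levels (default `"FacePresent"` for N170).
#' @param ... passed to [compute_contrast()].
#' @return list with `levels`, `amplitudes`, `waveforms`, `monotone`
#'   (logical or NA for < 2 levels), `skipped`.
#' @export
complexity_comparison <- function(erp_name, recordings,
                                  wave_name = "FacePresent", ...) {
  specs <- builtin_contrasts()
  abort_if(!erp_name %in% names(specs), "unknown ERP contrast: %s", erp_name)
  spec <- specs[[erp_name]]
  waves <- list(); amps <- numeric(0); skipped <- character(0)
  for (lv in names(recordings)) {
    res <- tryCatch(compute_contrast(recordings[[lv]], spec, ...),
                    error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, lv); next }
    w <- if (spec$arithmetic == "factor" && wave_name %in% names(res$waves))
      res$waves[[wave_name]] else res$contrast
    waves[[lv]] <- w
    amps[lv] <- amplitude_measure(w, spec$window_ms)
  }
  mono <- if (length(amps) >= 2) !is.unsorted(abs(amps), strictly = FALSE) else NA
  list(levels = names(waves), amplitudes = amps, waveforms = waves,
       monotone = mono, skipped = skipped)
}

#' Analytic expectation of an injected contrast
#'
#' Closed-form value of the contrast a noiseless pipeline would measure:
#' the injected amplitude difference times the effective channel weight
#' after average referencing, times the window mean of the Gaussian
#' envelope. Serves as the independent ground-truth oracle for the
#' recovery tests; it never touches the simulated signal.
#'
#' @param template the relevant [erp_template()].
#' @param amp_diff injected amplitude difference (condition A minus B, in
#'   microvolts).
#' @param channel_weight template topography weight at the measurement
#'   channel.
#' @param mean_weight mean topography weight across the montage (0 for
#'   reference-free derivations such as LRP/N2pc).
#' @param window_ms measurement window.
#' @return expected window-mean amplitude in microvolts.
#' @export
injected_contrast_value <- function(template, amp_diff, channel_weight,
                                    mean_weight, window_ms) {
  mu <- template$peak_latency_ms
  s <- template$width_ms
  a <- window_ms[1]; b <- window_ms[2]
  env_mean <- s * sqrt(2 * pi) * (stats::pnorm((b - mu) / s) - stats::pnorm((a - mu) / s)) / (b - a)
  amp_diff * (channel_weight - mean_weight) * env_mean
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s, %d epochs, %g..%g ms, range [%.2f, %.2f] uV\n",
              x$channel, x$n, min(x$time_ms), max(x$time_ms),
              min(x$mean_uV), max(x$mean_uV)))
  invisible(x)
}
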