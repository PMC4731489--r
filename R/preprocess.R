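#' Band-pass filter a recording
#'
#' Zero-phase filtering mirroring the analysis chain: channel means are
#' removed, a first-order Butterworth high-pass (default 0.1 Hz) is applied
#' forward and backward, and a Hamming windowed-sinc FIR low-pass (default
#' 40 Hz) is applied with its symmetric (zero-phase) alignment. Zero-phase
#' application is chosen over the acquisition system's causal first-order
#' filter to preserve ERP latencies.
#'
#' @param recording an `erp_recording`.
#' @param hp_hz high-pass cutoff (Hz); 0 disables (mean still removed).
#' @param lp_hz low-pass cutoff (Hz); must be below Nyquist.
#' @param n_taps FIR length for the low-pass (odd).
#' @return the filtered recording.
#' @export
filter_band <- function(recording, hp_hz = 0.1, lp_hz = 40, n_taps = 101) {
  srate <- recording$srate
  abort_if(lp_hz >= srate / 2, "parameter error: low-pass %g Hz >= Nyquist %g Hz",
           lp_hz, srate / 2)
  x <- recording$signal
  x <- x - rowMeans(x)
  if (hp_hz > 0) {
    for (ch in seq_len(nrow(x))) x[ch, ] <- filtfilt_hp1(x[ch, ], hp_hz, srate)
  }
  h <- fir_lowpass_taps(lp_hz, srate, n_taps)
  for (ch in seq_len(nrow(x))) x[ch, ] <- fir_apply(x[ch, ], h)
  recording$signal <- x
  recording
}

# first-order Butterworth high-pass, forward-backward (zero phase)
filtfilt_hp1 <- function(x, fc, fs) {
  k <- tan(pi * fc / fs)
  b0 <- 1 / (1 + k)
  ar <- (1 - k) / (1 + k)
  pass <- function(v) {
    u <- b0 * (v - c(0, v[-length(v)]))
    as.numeric(stats::filter(u, ar, method = "recursive"))
  }
  rev(pass(rev(pass(x))))
}

fir_lowpass_taps <- function(fc, fs, n_taps) {
  abort_if(n_taps %% 2 == 0, "parameter error: n_taps must be odd")
  m <- (n_taps - 1) / 2
  k <- seq_len(n_taps) - 1 - m
  h <- ifelse(k == 0, 2 * fc / fs, sin(2 * pi * fc / fs * k) / (pi * k))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_taps - 1)) / (n_taps - 1))  # Hamming
  h <- h * w
  h / sum(h)
}

# zero-phase application of a symmetric FIR via FFT convolution with
# reflection padding
fir_apply <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  xp <- c(rev(x[2:(m + 1)]), x, rev(x[(n - m):(n - 1)]))
  np <- length(xp)
  nfft <- stats::nextn(np + length(h) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - np))) *
                     stats::fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[(2 * m + 1):(2 * m + n)]
}

#' Extract epochs around events
#'
#' Cuts one epoch per selected event. Events whose window would extend
#' beyond the recording are dropped and reported (attribute `n_dropped`).
#'
#' @param recording an `erp_recording`.
#' @param events subset of `recording$events` rows to lock to (e.g. all
#'   `event_type == "stimulus"` rows).
#' @param lock locking label stored with the epochs (`"stimulus"`,
#'   `"response"` or `"tone"`).
#' @param window_ms two-element window around each event (default the
#'   peri-stimulus analysis window -1000..2000 ms; response-locked analyses
#'   conventionally use -500..800 ms).
#' @param channels optional channel subset to retain (apply
#'   [average_reference()] to the recording first if it is wanted, since
#'   the reference needs the full montage).
#' @return an `erp_epochs` object: `data` (epochs x channels x time,
#'   microvolts), `times_ms`, `srate`, `channels`, `labels` (the retained
#'   event rows), `lock`, `baseline_ms`.
#' @export
epoch <- function(recording, events, lock = "stimulus",
                  window_ms = c(-1000, 2000), channels = NULL) {
  abort_if(nrow(events) == 0, "selection error: no events selected")
  if (!is.null(channels)) {
    ch_idx <- match(channels, recording$channels)
    abort_if(any(is.na(ch_idx)), "selection error: channel(s) not in recording")
    recording$signal <- recording$signal[ch_idx, , drop = FALSE]
    recording$channels <- channels
  }
  srate <- recording$srate
  i0 <- round(window_ms[1] * srate / 1000)
  i1 <- round(window_ms[2] * srate / 1000)
  times_ms <- (i0:i1) * 1000 / srate
  n_samp <- ncol(recording$signal)
  start <- events$sample + i0
  stop <- events$sample + i1
  keep <- start >= 1 & stop <= n_samp
  n_dropped <- sum(!keep)
  abort_if(!any(keep), "selection error: all selected events out of bounds")
  events <- events[keep, ]
  data <- array(0, dim = c(nrow(events), nrow(recording$signal), length(times_ms)))
  for (e in seq_len(nrow(events))) {
    data[e, , ] <- recording$signal[, (events$sample[e] + i0):(events$sample[e] + i1)]
  }
  structure(list(data = data, times_ms = times_ms, srate = srate,
                 channels = recording$channels, labels = events, lock = lock,
                 baseline_ms = NULL, n_dropped = n_dropped),
            class = "erp_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window, so
#' the corrected baseline mean is exactly zero.
#'
#' @param epochs an `erp_epochs`.
#' @param baseline_ms two-element window inside the epoch window.
#' @return corrected `erp_epochs` (with `baseline_ms` recorded).
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-200, 0)) {
  idx <- which(epochs$times_ms >= baseline_ms[1] & epochs$times_ms <= baseline_ms[2])
  abort_if(length(idx) == 0, "parameter error: empty baseline window")
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over the time dim
  epochs$baseline_ms <- baseline_ms
  epochs
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels, making the per-sample
#' channel mean zero. Idempotent; between-channel differences are
#' unchanged.
#'
#' @param x an `erp_recording` or `erp_epochs`.
#' @return same type, re-referenced.
#' @export
average_reference <- function(x) UseMethod("average_reference")

#' @export
average_reference.erp_recording <- function(x) {
  abort_if(nrow(x$signal) < 2, "parameter error: average reference needs >= 2 channels")
  x$signal <- sweep(x$signal, 2, colMeans(x$signal))
  x
}

#' @export
average_reference.erp_epochs <- function(x) {
  abort_if(dim(x$data)[2] < 2, "parameter error: average reference needs >= 2 channels")
  chan_mean <- apply(x$data, c(1, 3), mean)
  x$data <- x$data - aperm(array(chan_mean, dim = dim(x$data)[c(1, 3, 2)]), c(1, 3, 2))
  x
}

#' Threshold-based epoch rejection
#'
#' Removes epochs containing any sample exceeding the absolute amplitude
#' threshold. This is the desk-scale stand-in for subspace-reconstruction
#' artifact cleaning: the simulator's artifacts are amplitude excursions,
#' for which a threshold is sufficient and dependency-free.
#'
#' @param epochs an `erp_epochs`.
#' @param abs_threshold_uV positive rejection threshold in microvolts.
#' @return surviving `erp_epochs`; attribute `rejected` lists the dropped
#'   epoch indices.
#' @export
reject_epochs <- function(epochs, abs_threshold_uV = 100) {
  abort_if(abs_threshold_uV <= 0, "parameter error: threshold must be positive")
  peak <- apply(abs(epochs$data), 1, max)
  bad <- which(peak > abs_threshold_uV)
  abort_if(length(bad) == dim(epochs$data)[1],
           "degenerate output: all epochs rejected at %g uV", abs_threshold_uV)
  if (length(bad) > 0) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
    epochs$labels <- epochs$labels[-bad, ]
  }
  attr(epochs, "rejected") <- bad
  epochs
}

#' Concatenate compatible epoch sets
#'
#' Pools epochs (e.g. across simulated runs or levels) sharing the same
#' time grid, channels and locking.
#'
#' @param ... `erp_epochs` objects, or a single list of them.
#' @return one pooled `erp_epochs`.
#' @export
pool_epochs <- function(...) {
  eps <- list(...)
  if (length(eps) == 1 && !inherits(eps[[1]], "erp_epochs")) eps <- eps[[1]]
  ref <- eps[[1]]
  for (e in eps[-1]) {
    abort_if(!identical(e$times_ms, ref$times_ms) ||
             !identical(e$channels, ref$channels) ||
             !identical(e$lock, ref$lock),
             "pooling error: epoch sets are not compatible")
  }
  n_tot <- sum(vapply(eps, function(e) dim(e$data)[1], numeric(1)))
  data <- array(0, dim = c(n_tot, dim(ref$data)[2], dim(ref$data)[3]))
  at <- 1
  for (e in eps) {
    n <- dim(e$data)[1]
    data[at:(at + n - 1), , ] <- e$data
    at <- at + n
  }
  ref$data <- data
  ref$labels <- do.call(rbind, lapply(eps, function(e) e$labels))
  ref
}

#' @export
print.erp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<erp_epochs> %d epochs x %d channels x %d samples (%s-locked, %g..%g ms)\n",
              d[1], d[2], d[3], x$lock, min(x$times_ms), max(x$times_ms)))
  invisible(x)
}
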