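#' Default time-frequency grid
#'
#' Log-spaced frequencies from 3 to 40 Hz (30 points), matching the
#' theta-to-beta range the time-frequency figures cover.
#'
#' @param from,to frequency range (Hz).
#' @param n number of points.
#' @return numeric vector of frequencies.
#' @export
default_freqs <- function(from = 3, to = 40, n = 30) {
  exp(seq(log(from), log(to), length.out = n))
}

# complex Morlet decomposition of one channel: epochs x freqs x time
morlet_decompose <- function(epochs, channel, freqs, n_cycles = 5) {
  ch <- match(channel, epochs$channels)
  abort_if(is.na(ch), "selection error: channel %s not in epochs", channel)
  abort_if(any(freqs >= epochs$srate / 2),
           "parameter error: frequency above Nyquist (%g Hz)", epochs$srate / 2)
  srate <- epochs$srate
  n_t <- length(epochs$times_ms)
  n_ep <- dim(epochs$data)[1]
  wavelets <- lapply(freqs, function(f) {
    s_t <- n_cycles / (2 * pi * f)               # seconds
    half <- ceiling(3 * s_t * srate)
    t <- (-half:half) / srate
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * s_t^2))
    w / sum(abs(w))
  })
  max_len <- max(lengths(wavelets))
  nfft <- stats::nextn(n_t + max_len - 1, 2)
  wf <- lapply(wavelets, function(w) stats::fft(c(w, rep(0, nfft - length(w)))))
  halves <- vapply(wavelets, function(w) (length(w) - 1) / 2, numeric(1))
  out <- array(0i, dim = c(n_ep, length(freqs), n_t))
  for (e in seq_len(n_ep)) {
    xf <- stats::fft(c(epochs$data[e, ch, ], rep(0, nfft - n_t)))
    for (k in seq_along(freqs)) {
      conv <- stats::fft(xf * wf[[k]], inverse = TRUE) / nfft
      out[e, k, ] <- conv[(halves[k] + 1):(halves[k] + n_t)]
    }
  }
  out
}

tf_map <- function(freqs_hz, times_ms, values, kind, baseline_ms = NULL) {
  structure(list(freqs_hz = freqs_hz, times_ms = times_ms, values = values,
                 kind = kind, baseline_ms = baseline_ms),
            class = "tf_map")
}

#' Event-related spectral perturbation (ERSP)
#'
#' Morlet-wavelet power per epoch, averaged over epochs and expressed in
#' decibels relative to the mean baseline power at each frequency:
#' `10*log10(P(f,t) / mean_t_baseline P(f,t))`. Stationary input therefore
#' yields approximately 0 dB everywhere.
#'
#' @param epochs an `erp_epochs`.
#' @param channel channel name.
#' @param freqs frequency grid (Hz), default [default_freqs()].
#' @param baseline_ms baseline window (defaults to the epochs' baseline or
#'   all pre-zero times).
#' @param n_cycles Morlet cycles (fixed 5).
#' @return a `tf_map` with dB values (freqs x times).
#' @export
ersp <- function(epochs, channel, freqs = default_freqs(),
                 baseline_ms = NULL, n_cycles = 5) {
  baseline_ms <- baseline_ms %||% epochs$baseline_ms %||%
    c(min(epochs$times_ms), 0)
  w <- morlet_decompose(epochs, channel, freqs, n_cycles)
  p <- apply(abs(w)^2, c(2, 3), mean)            # freqs x time
  b_idx <- which(epochs$times_ms >= baseline_ms[1] & epochs$times_ms <= baseline_ms[2])
  abort_if(length(b_idx) == 0, "parameter error: baseline outside epoch window")
  base <- rowMeans(p[, b_idx, drop = FALSE])
  tf_map(freqs, epochs$times_ms, 10 * log10(p / base), "ersp", baseline_ms)
}

#' Inter-trial coherence (ITC)
#'
#' Resultant length of the per-epoch unit phase vectors in each
#' time-frequency cell: 0 for random phase, 1 for perfect phase locking.
#'
#' @inheritParams ersp
#' @return a `tf_map` with values in \[0,1\].
#' @export
itc <- function(epochs, channel, freqs = default_freqs(), n_cycles = 5) {
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 2)
    warning("single epoch: ITC is degenerate (identically 1)")
  w <- morlet_decompose(epochs, channel, freqs, n_cycles)
  u <- w / abs(w)
  u[!is.finite(u)] <- 0i
  vals <- abs(apply(u, c(2, 3), mean))
  tf_map(freqs, epochs$times_ms, pmin(vals, 1), "itc")
}

#' Welch power spectrum over epochs
#'
#' Hann-windowed averaged periodogram, averaged across segments within
#' each epoch and across epochs. One-sided density scaling, so the
#' integral over frequency approximates the signal variance (Parseval).
#'
#' @param epochs an `erp_epochs` (or numeric vector with `srate` given).
#' @param channel channel name (ignored for vector input).
#' @param srate sampling rate; taken from `epochs` when available.
#' @param nfft segment length (samples).
#' @param overlap fractional segment overlap.
#' @return list `freqs_hz`, `power` (uV^2/Hz).
#' @export
power_spectrum <- function(epochs, channel = NULL, srate = NULL, nfft = 256,
                           overlap = 0.5) {
  if (inherits(epochs, "erp_epochs")) {
    ch <- match(channel, epochs$channels)
    abort_if(is.na(ch), "selection error: channel %s not in epochs", channel)
    xs <- lapply(seq_len(dim(epochs$data)[1]), function(e) epochs$data[e, ch, ])
    srate <- epochs$srate
  } else {
    abort_if(is.null(srate), "parameter error: srate required for vector input")
    xs <- list(as.numeric(epochs))
  }
  nfft <- min(nfft, min(lengths(xs)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))  # Hann
  scale <- 1 / (srate * sum(win^2))
  step <- max(1, round(nfft * (1 - overlap)))
  acc <- 0; n_seg <- 0
  for (x in xs) {
    starts <- seq(1, length(x) - nfft + 1, by = step)
    for (s in starts) {
      seg <- x[s:(s + nfft - 1)] * win
      acc <- acc + abs(stats::fft(seg))^2 * scale
      n_seg <- n_seg + 1
    }
  }
  p <- acc / n_seg
  half <- floor(nfft / 2) + 1
  p_one <- p[1:half]
  if (nfft %% 2 == 0) p_one[2:(half - 1)] <- 2 * p_one[2:(half - 1)]
  else p_one[2:half] <- 2 * p_one[2:half]
  list(freqs_hz = (0:(half - 1)) * srate / nfft, power = p_one)
}

#' Fit the log-log spectral slope
#'
#' Regression of log10 power on log10 frequency over a band; pink (1/f)
#' noise has slope near -1.
#'
#' @param spectrum output of [power_spectrum()].
#' @param band frequency band (Hz) used for the fit.
#' @return slope estimate.
#' @export
spectral_slope <- function(spectrum, band = c(1, 40)) {
  keep <- spectrum$freqs_hz >= band[1] & spectrum$freqs_hz <= band[2] &
    spectrum$power > 0
  stats::coef(stats::lm(log10(spectrum$power[keep]) ~ log10(spectrum$freqs_hz[keep])))[[2]]
}

#' Pointwise paired permutation t-test
#'
#' Two-sided sign-flip permutation test of paired differences, per time
#' (or time-frequency) point. Exact under symmetry of the paired-difference
#' distribution; with `n_perm` permutations the smallest attainable p is
#' `1/(n_perm + 1)`.
#'
#' @param data_A,data_B matrices `units x points` (vectors treated as one
#'   point per column... i.e. a single-column matrix), paired by row.
#' @param n_perm number of sign-flip permutations (2000 by default).
#' @param seed integer seed.
#' @return list `p` (per point), `t_obs`, `n_perm`, `method`.
#' @export
perm_paired_test <- function(data_A, data_B, n_perm = 2000, seed = 1) {
  abort_if(n_perm < 1, "parameter error: n_perm must be >= 1")
  A <- as.matrix(data_A); B <- as.matrix(data_B)
  abort_if(!all(dim(A) == dim(B)), "pairing error: data_A and data_B differ in shape")
  n <- nrow(A)
  abort_if(n < 5, "pairing error: need >= 5 paired units")
  D <- A - B
  P <- ncol(D)
  ssq <- colSums(D^2)
  t_of <- function(m) {
    v <- (rep(ssq, each = nrow(m)) - n * m^2) / (n - 1)
    dim(v) <- dim(m)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  m_obs <- matrix(colMeans(D), 1, P)
  t_obs <- t_of(m_obs)[1, ]
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    t_perm <- t_of(S %*% D / n)
    exceed <- colSums(abs(t_perm) >= rep(abs(t_obs), each = n_perm))
    list(p = (1 + exceed) / (n_perm + 1), t_obs = t_obs, n_perm = n_perm,
         method = "paired t, sign-flip permutation")
  })
}

#' Pointwise one-way repeated-measures permutation ANOVA
#'
#' F statistic of the condition factor after removing the unit (subject)
#' means, with a permutation null obtained by shuffling condition labels
#' independently within each unit. Used for factors with k >= 3 levels
#' (the four-condition image factor); for k = 2 use
#' [perm_paired_test()].
#'
#' @param conditions list of k matrices `units x points`, paired by row.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list `p`, `F_obs`, `n_perm`, `method`.
#' @export
perm_rm_anova <- function(conditions, n_perm = 2000, seed = 1) {
  k <- length(conditions)
  abort_if(k < 3, "parameter error: k >= 3 conditions required (use perm_paired_test for k = 2)")
  mats <- lapply(conditions, as.matrix)
  dims <- vapply(mats, dim, integer(2))
  abort_if(any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]),
           "pairing error: condition matrices differ in shape")
  n <- dims[1, 1]; P <- dims[2, 1]
  X <- array(unlist(mats), dim = c(n, P, k))   # units x points x conditions
  f_stat <- function(X) {
    unit_mean <- apply(X, c(1, 2), mean)
    Xc <- X - array(unit_mean, dim = dim(X))   # remove unit effect
    cond_mean <- apply(Xc, c(2, 3), mean)      # points x conditions
    ss_cond <- n * rowSums(cond_mean^2)
    resid <- Xc - aperm(array(t(cond_mean), dim = c(k, P, n)), c(3, 2, 1))
    ss_err <- apply(resid^2, 2, sum)
    (ss_cond / (k - 1)) / pmax(ss_err / ((k - 1) * (n - 1)), .Machine$double.eps)
  }
  F_obs <- f_stat(X)
  with_seed(seed, {
    exceed <- numeric(P)
    for (b in seq_len(n_perm)) {
      Xp <- X
      for (i in seq_len(n)) Xp[i, , ] <- X[i, , sample(k)]
      exceed <- exceed + (f_stat(Xp) >= F_obs)
    }
    list(p = (1 + exceed) / (n_perm + 1), F_obs = F_obs, n_perm = n_perm,
         method = "repeated-measures one-way ANOVA, within-unit label permutation")
  })
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up FDR control across all tested points; the mask shape matches
#' the input.
#'
#' @param pvals numeric vector, matrix or `tf_map`-shaped matrix of
#'   p-values in \[0,1\].
#' @param q FDR level.
#' @param n_permutations recorded with the mask (metadata).
#' @return a `significance_mask`: list `mask` (logical, same shape),
#'   `alpha`, `n_permutations`, `method`.
#' @export
fdr_bh <- function(pvals, q = 0.05, n_permutations = NA_integer_) {
  abort_if(length(pvals) == 0, "parameter error: empty p-value input")
  abort_if(any(pvals < 0 | pvals > 1, na.rm = TRUE),
           "parameter error: p-values outside [0, 1]")
  adj <- stats::p.adjust(as.vector(pvals), method = "BH")
  mask <- adj <= q
  if (!is.null(dim(pvals))) dim(mask) <- dim(pvals)
  structure(list(mask = mask, alpha = q, n_permutations = n_permutations,
                 method = "Benjamini-Hochberg step-up"),
            class = "significance_mask")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map:%s> %d freqs (%.1f..%.1f Hz) x %d times, range [%.2f, %.2f]\n",
              x$kind, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_ms), min(x$values), max(x$values)))
  invisible(x)
}
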