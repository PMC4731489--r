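noise_epochs <- function(n_ep, n_t = 500, srate = 250, seed = 1, t0_ms = -1000) {
  set.seed(seed)
  synthetic_epochs(array(rnorm(n_ep * n_t), dim = c(n_ep, 1, n_t)),
                   srate = srate, channels = "Cz", t0_ms = t0_ms)
}

test_that("ERSP is ~0 dB on stationary noise and tracks injected bursts", {
  ep <- noise_epochs(80, seed = 2)
  ep$baseline_ms <- c(-900, -100)
  m <- ersp(ep, "Cz")
  # discard wavelet edge columns before judging the baseline identity
  inner <- m$times_ms > -800 & m$times_ms < 800
  expect_lt(mean(abs(m$values[, inner])), 1)
  # injected post-stimulus 10 Hz burst shows as a positive blob, and
  # doubling its amplitude adds ~6 dB
  blob <- function(gain) {
    ep2 <- noise_epochs(60, seed = 3)
    t <- ep2$times_ms
    burst <- gain * sin(2 * pi * 10 * t / 1000) * (t > 100 & t < 600)
    for (i in seq_len(dim(ep2$data)[1])) ep2$data[i, 1, ] <- ep2$data[i, 1, ] + burst
    ep2$baseline_ms <- c(-900, -100)
    ersp(ep2, "Cz")
  }
  m1 <- blob(3); m2 <- blob(6)
  f10 <- which.min(abs(m1$freqs_hz - 10))
  in_burst <- m1$times_ms > 200 & m1$times_ms < 500
  expect_gt(mean(m1$values[f10, in_burst]), 3)
  expect_equal(mean(m2$values[f10, in_burst]) - mean(m1$values[f10, in_burst]),
               6, tolerance = 1)
  expect_error(ersp(ep, "Cz", freqs = c(10, 130)), "Nyquist")
})

test_that("ITC is bounded, 1 for identical epochs, ~Rayleigh for noise", {
  one <- noise_epochs(1, seed = 4)
  d <- one$data[1, 1, ]
  ident <- synthetic_epochs(array(rep(d, each = 10), dim = c(10, 1, length(d))),
                            channels = "Cz", t0_ms = -1000)
  expect_warning(itc(one, "Cz"), "degenerate")
  m_id <- itc(ident, "Cz")
  expect_equal(max(abs(m_id$values - 1)), 0, tolerance = 1e-9)
  m_noise <- itc(noise_epochs(100, seed = 5), "Cz")
  expect_true(all(m_noise$values >= 0 & m_noise$values <= 1))
  inner <- m_noise$times_ms > -800 & m_noise$times_ms < 800
  expected <- sqrt(pi / 4) / sqrt(100)
  expect_lt(abs(mean(m_noise$values[, inner]) - expected) / expected, 0.3)
  # a phase-locked component drives ITC toward 1 in its region
  ep <- noise_epochs(40, seed = 6)
  t <- ep$times_ms
  comp <- 5 * sin(2 * pi * 8 * t / 1000) * exp(-((t - 300) / 150)^2 / 2)
  for (i in 1:40) ep$data[i, 1, ] <- ep$data[i, 1, ] + comp
  m_lock <- itc(ep, "Cz")
  f8 <- which.min(abs(m_lock$freqs_hz - 8))
  expect_gt(mean(m_lock$values[f8, t > 200 & t < 400]), 0.9)
})

test_that("Welch spectra localise tones, obey Parseval, see pink slopes", {
  srate <- 250
  t <- seq_len(srate * 30) / srate
  x <- sin(2 * pi * 10 * t)
  ps <- power_spectrum(x, srate = srate, nfft = 512)
  expect_equal(ps$freqs_hz[which.max(ps$power)], 10, tolerance = 0.5)
  set.seed(7)
  y <- rnorm(srate * 30)
  psy <- power_spectrum(y, srate = srate, nfft = 256)
  df <- diff(psy$freqs_hz[1:2])
  expect_equal(sum(psy$power) * df, var(y), tolerance = 0.05 * var(y))
  slope <- spectral_slope(power_spectrum(pink_noise(1, srate * 60, srate, 3, seed = 8)[1, ],
                                         srate = srate, nfft = 1024))
  expect_lt(abs(slope + 1), 0.3)
})

test_that("sign-flip paired test is calibrated under the null and powered", {
  set.seed(11)
  A <- matrix(rnorm(12 * 40), 12)
  B <- matrix(rnorm(12 * 40), 12)
  res <- perm_paired_test(A, B, n_perm = 999, seed = 1)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0)            # null p-values roughly uniform:
  expect_lt(frac, 0.12)          # no excess of small p
  expect_gt(mean(res$p), 0.35)
  # a d ~ 3 shift is detected almost everywhere
  shift <- B + 3
  res2 <- perm_paired_test(shift, B, n_perm = 999, seed = 2)
  expect_gte(mean(res2$p < 0.05), 0.9)
  expect_error(perm_paired_test(A, B, n_perm = 0), "n_perm")
  expect_error(perm_paired_test(A[1:3, ], B[1:3, ]), ">= 5")
  expect_error(perm_paired_test(A, B[, 1:10]), "shape")
})

test_that("permutation RM-ANOVA separates flat from deviant conditions", {
  set.seed(12)
  n <- 14; P <- 25
  flat <- lapply(1:4, function(k) matrix(rnorm(n * P), n))
  res <- perm_rm_anova(flat, n_perm = 500, seed = 3)
  expect_lt(mean(res$p < 0.05), 0.15)
  dev <- flat
  dev[[4]] <- dev[[4]] + 2
  res2 <- perm_rm_anova(dev, n_perm = 500, seed = 4)
  expect_gte(mean(res2$p < 0.05), 0.9)
  expect_error(perm_rm_anova(flat[1:2]), "k >= 3")
})

test_that("BH-FDR reproduces the hand-worked example and is monotone in q", {
  p <- c(0.001, 0.002, 0.2, 0.9)
  mask <- fdr_bh(p, q = 0.05)
  expect_equal(mask$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(fdr_bh(rep(0.9, 6), q = 0.05)$mask))
  set.seed(13)
  pr <- runif(200)^2
  m1 <- fdr_bh(pr, q = 0.01)$mask
  m5 <- fdr_bh(pr, q = 0.05)$mask
  expect_true(all(m5[m1]))               # q = 0.01 mask nested in q = 0.05
  pm <- matrix(pr[1:20], 4, 5)
  expect_equal(dim(fdr_bh(pm, 0.05)$mask), c(4, 5))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "outside")
})
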