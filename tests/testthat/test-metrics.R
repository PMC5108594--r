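# Evaluation statistics: predictive power, coherence, contrast-adaptation
# LN analysis, sliding-window statistics.

make_trials <- function(signal, n, noise_sd, seed = 1) {
  set.seed(seed)
  sapply(seq_len(n), function(i)
    signal + rnorm(length(signal), 0, noise_sd))
}

test_that("predictive power is 1 for the true signal and ~0 for unrelated predictions", {
  sig <- as.numeric(bandlimited_noise(3000, 1, 30))
  trials <- make_trials(sig, 10, noise_sd = sd(sig) * sqrt(2 / 3), seed = 61)
  # explainable fraction here is 0.6 = Var(sig)/(Var(sig) + noise^2)
  expect_equal(predictive_power(sig, trials), 1, tolerance = 0.05)
  # trial mean as prediction on noiseless trials
  clean <- make_trials(sig, 5, 0)
  expect_equal(predictive_power(rowMeans(clean), clean), 1,
               tolerance = 1e-10)
  # independent prediction
  set.seed(62)
  indep <- as.numeric(bandlimited_noise(3000, 1, 30))
  expect_lt(abs(predictive_power(indep, trials)), 0.05)
  expect_error(predictive_power(sig, matrix(sig)), "trials")
})

test_that("coherence is 1 for a perfect prediction and bounded in [0,1]", {
  sig <- as.numeric(bandlimited_noise(3000, 1, 30))
  trials <- sapply(1:5, function(i) sig)
  co <- coherence(sig, trials)
  expect_true(all(abs(co$gamma2 - 1) < 1e-9))
  noisy <- make_trials(sig, 8, sd(sig), seed = 63)
  co2 <- coherence(sig, noisy)
  expect_true(all(co2$gamma2 >= 0 & co2$gamma2 <= 1))
  expect_true(all(co2$noise_bound >= 0 & co2$noise_bound <= 1))
  expect_error(coherence(sig[1:100], noisy), "misaligned")
})

test_that("coherence of signal plus in-band noise follows SNR/(1+SNR)", {
  # signal and per-trial noise band-limited to the same band with flat
  # spectra, so the in-band coherence has the closed form SNR/(1+SNR)
  set.seed(64)
  n <- 40000
  sig <- as.numeric(bandlimited_noise(n, 1, 100))
  snr <- 2
  trials <- sapply(1:20, function(i)
    sig + as.numeric(bandlimited_noise(n, 1, 100)) / sqrt(snr))
  co <- coherence(sig, trials, seg_s = 0.5)
  inband <- co$freq_hz > 10 & co$freq_hz < 90
  expect_equal(mean(co$gamma2[inband]), snr / (1 + snr), tolerance = 0.05)
})

test_that("sliding-window statistics track mean and SD", {
  x <- rep(c(0, 5), each = 3000)
  bs <- block_stats(matrix(x), window_s = 1)
  expect_equal(min(bs$mean), 0, tolerance = 1e-9)
  expect_equal(max(bs$mean), 5, tolerance = 1e-9)
  expect_equal(bs$sd[bs$time_s < 1], rep(0, sum(bs$time_s < 1)),
               tolerance = 1e-9)
  set.seed(66)
  z <- rnorm(5000)
  bz <- block_stats(matrix(z), window_s = 1)
  expect_equal(median(bz$sd), 1, tolerance = 0.1)
  expect_error(block_stats(matrix(z[1:100]), window_s = 1), "window")
})

test_that("contrast gain is 1 for a purely linear ground truth", {
  b <- temporal_basis(12, 200, 1)
  kk <- divsenc:::canonical_kernels(b)
  f <- temporal_filter(kk$ae, b, TRUE)
  st <- contrast_switching_stimulus(n_cycles = 4, seed = 67)
  g <- as.numeric(apply_filter(f, st))
  set.seed(68)
  y <- 2 * g + 0.5 + rnorm(length(g), sd = sd(g) / sqrt(20))
  ad <- contrast_ln_analysis(st, y)
  expect_equal(ad$contrast_gain, 1, tolerance = 0.05)
})

test_that("biphasic index is |min/max|", {
  k <- c(0.2, 1.0, -0.5, -0.1)
  expect_equal(biphasic_index(k), 0.5)
})

test_that("divisive suppression produces contrast gain above 1", {
  gt <- fix_divs_truth()
  st <- contrast_switching_stimulus(n_cycles = 4, seed = 69)
  y <- as.numeric(predict_current(gt, st))
  ad <- contrast_ln_analysis(st, y)
  expect_gt(ad$contrast_gain, 1)
})

test_that("contrast analysis requires both contrasts", {
  st <- contrast_switching_stimulus(n_cycles = 2, seed = 70)
  st$schedule$label[] <- "HC"
  expect_error(contrast_ln_analysis(st, rnorm(st$n_time)), "contrast")
})
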