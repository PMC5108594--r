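# Point-process machinery: Poisson likelihood, softplus output, seeded
# simulation with spike history.

test_that("poisson_ll matches direct substitution and the log-pmf oracle", {
  # one spike in one bin at constant rate
  lam <- 0.04; Tbins <- 50
  y <- rep(0, Tbins); y[17] <- 1
  expect_equal(poisson_ll(rep(lam, Tbins), y), log(lam) - Tbins * lam)
  # no spikes anywhere
  r <- runif(30, 0.01, 0.1)
  expect_equal(poisson_ll(r, rep(0, 30)), -sum(r))
  # random rates/counts vs dpois plus the factorial constant
  set.seed(12)
  r <- runif(200, 0.01, 2)
  y <- rpois(200, r)
  oracle <- sum(dpois(y, r, log = TRUE)) + sum(lgamma(y + 1))
  expect_equal(poisson_ll(r, y), oracle, tolerance = 1e-10)
  # zero rate with observed spike
  expect_identical(poisson_ll(c(0, 0.1), c(1, 0)), -Inf)
})

test_that("softplus has the right limits", {
  expect_equal(softplus(0), log(2))
  expect_lt(abs(softplus(50) - 50), 1e-9)
  expect_lt(softplus(-50), 1e-9)
})

test_that("spike simulation is seeded and Poisson without history", {
  m <- make_ground_truth("divs_spike", overrides = list(hist_scale = 0))
  m$history <- NULL
  st <- contrast_switching_stimulus(n_cycles = 1, cycle_s = 4,
                                    unique_s = 3, seed = 14)
  s1 <- simulate_spikes(m, st, n_repeats = 500, seed = 3)
  s2 <- simulate_spikes(m, st, n_repeats = 500, seed = 3)
  expect_identical(s1$counts, s2$counts)
  # across-repeat total counts are Poisson: Fano ~ 1
  tot <- colSums(s1$counts)
  expect_gt(mean(tot), 5)
  expect_equal(var(tot) / mean(tot), 1, tolerance = 0.1)
})

test_that("a strong brief history term suppresses short ISIs", {
  m <- make_ground_truth("divs_spike")
  m$history$kernel <- c(rep(-10, 2), rep(0, 98))
  st <- contrast_switching_stimulus(n_cycles = 1, cycle_s = 6,
                                    unique_s = 5, seed = 15)
  sim <- simulate_spikes(m, st, n_repeats = 100, seed = 4)
  isis <- unlist(lapply(sim$spikes$trials, diff))
  expect_gt(length(isis), 200)
  expect_lt(mean(isis <= 2), 0.01)
})

test_that("spike containers validate their invariants", {
  expect_error(spike_train_set(list(c(5, 3)), 10), "increasing")
  expect_error(spike_train_set(list(c(-1, 3)), 10), "lie in")
  s <- spike_train_set(list(c(0.5, 3), numeric(0)), 10)
  bc <- bin_spikes(s)
  expect_equal(dim(bc), c(10, 2))
  expect_equal(sum(bc[, 1]), 2)
  expect_equal(sum(bc[, 2]), 0)
})

test_that("history basis covers 1-100 ms and excludes the self-bin", {
  hb <- history_basis()
  expect_equal(nrow(hb$matrix), 100)
  expect_equal(hb$lags_ms[1], 1)     # lag 0 absent
  expect_true(all(colSums(hb$matrix) > 0))
  # partition-like coverage: every lag touched by some bump
  expect_true(all(rowSums(hb$matrix) > 0))
})

test_that("removing the history term and refitting preserves the subunit", {
  rec <- fix_spk_recording()
  full <- fix_divs_spike_fit()
  refit <- refit_without_history(full, rec$stim, rec$spikes,
                                 quick_cfg(max_outer_iters = 5))
  expect_null(refit$history)
  # refitting can only improve on simply zeroing the history term
  zeroed <- full
  zeroed$history <- NULL
  mask <- training_mask(rec$stim, 200)
  ll_zero <- model_ll(zeroed, rec$stim, rec$spikes, mask)$ll
  ll_refit <- model_ll(refit, rec$stim, rec$spikes, mask)$ll
  expect_gte(ll_refit, ll_zero)
  expect_error(refit_without_history(refit, rec$stim, rec$spikes),
               "history")
})
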