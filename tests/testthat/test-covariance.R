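# Response-weighted covariance analysis and subspace comparisons.

test_that("white-noise linear response gives a mean kernel proportional to the filter", {
  b <- temporal_basis(10, 200, 1)
  kk <- divsenc:::canonical_kernels(b)
  f <- temporal_filter(kk$ae, b, TRUE)
  set.seed(51)
  s <- rnorm(1e5, sd = 0.5)
  st <- stimulus(matrix(s), 1, 0)
  y <- as.numeric(apply_filter(f, st))
  cv <- response_weighted_moments(st, y, n_lags = 200)
  expect_gt(cosine_sim(cv$mean_kernel, filter_kernel(f)[, 1]), 0.99)
})

test_that("covariance difference is symmetric and vanishes for unmodulated responses", {
  set.seed(52)
  st <- stimulus(matrix(rnorm(20000)), 1, 0)
  y <- abs(rnorm(20000))
  cv <- response_weighted_moments(st, y, n_lags = 50)
  expect_identical(cv$covdiff, t(cv$covdiff))
  # constant response: weighted covariance equals the prior exactly
  cvc <- response_weighted_moments(st, rep(2, 20000), n_lags = 50)
  prior_scale <- mean(diag(crossprod(stats::embed(st$values[, 1], 50)) /
                             19951))
  expect_lt(max(abs(cvc$covdiff)), 1e-3 * prior_scale)
  expect_error(response_weighted_moments(st, rep(0, 20000)), "degenerate")
})

test_that("eigenvectors are orthonormal and reproduce the covariance difference", {
  rec <- fix_divs_recording()
  cv <- response_weighted_moments(rec$stim, rec$currents$trace,
                                  n_lags = 200)
  V <- cv$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  reco <- V %*% diag(cv$eigenvalues) %*% t(V)
  expect_lt(max(abs(reco - cv$covdiff)), 1e-8 * max(abs(cv$covdiff)))
  # sign canonicalization: largest-magnitude element positive
  for (j in 1:3)
    expect_gt(V[which.max(abs(V[, j])), j], 0)
})

test_that("top covariance eigenvectors span the DivS filter subspace", {
  # white-noise stimulus and noiseless response isolate the analysis
  # itself (covariance analysis assumes uncorrelated stimuli; correlated
  # protocols rotate the eigenvectors by the stimulus covariance)
  gt <- fix_divs_truth()
  set.seed(56)
  stw <- stimulus(matrix(rnorm(4e5, sd = 1.2)), 1, 0)
  cv <- response_weighted_moments(stw, as.numeric(predict_current(gt, stw)),
                                  n_lags = 200)
  ke <- filter_kernel(gt$exc$filter)[, 1]
  ks <- filter_kernel(gt$sup$filter)[, 1]
  # the generating filters project strongly onto the top-2 eigenvector
  # span, and vice versa (shared subspace)
  pr <- subspace_projection(list(ke, ks),
                            list(cv$eigenvectors[, 1],
                                 cv$eigenvectors[, 2]))
  pr_rev <- subspace_projection(list(cv$eigenvectors[, 1],
                                     cv$eigenvectors[, 2]),
                                list(ke, ks))
  expect_true(all(pr >= 0.95))
  expect_true(all(pr_rev >= 0.95))
})

test_that("subspace projection matches the normal-equations oracle", {
  set.seed(53)
  B <- matrix(rnorm(60), 20, 3)
  f_in <- B %*% rnorm(3)
  expect_equal(unname(subspace_projection(list(as.numeric(f_in)), B)), 1,
               tolerance = 1e-10)
  # orthogonal complement
  f_perp <- residuals(lm.fit(B, rnorm(20)))
  expect_equal(unname(subspace_projection(list(f_perp), B)), 0,
               tolerance = 1e-10)
  # random filter: compare against explicit least squares
  f <- rnorm(20); f <- f / sqrt(sum(f^2))
  beta <- solve(crossprod(B), crossprod(B, f))
  oracle <- sqrt(sum((B %*% beta)^2))
  expect_equal(unname(subspace_projection(list(f), B)), oracle,
               tolerance = 1e-10)
  expect_error(subspace_projection(list(f), cbind(B[, 1], B[, 1])),
               "dependent")
})
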