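# Current-response cascade models: LN, DivS, AddS. Heavy fits come from
# the shared fixtures (canonical DivS ground truth, ~80 s at SNR 10).

test_that("LN fitting recovers a linear-Gaussian ground truth filter", {
  b <- temporal_basis(12, 200, 1)
  kk <- divsenc:::canonical_kernels(b)
  truth <- temporal_filter(kk$ae, b, TRUE)
  st <- contrast_switching_stimulus(n_cycles = 2, seed = 21)
  g <- apply_filter(truth, st)
  set.seed(22)
  y <- g + rnorm(length(g), sd = sd(g) / sqrt(10))
  m <- fit_ln(st, y, fit_config(max_outer_iters = 15, n_random_inits = 0))
  expect_gt(cosine_sim(filter_kernel(m$filter), filter_kernel(truth)), 0.99)
  expect_true(all(diff(m$mse_log) <= 1e-12))
})

test_that("LN fitting captures a softplus nonlinearity on held-out repeats", {
  gt <- make_ground_truth("ln")
  rec <- generate_recording(gt, snr = 10, seed = 23, n_cycles = 2)
  m <- fit_ln(rec$stim, rec$currents, quick_cfg(max_outer_iters = 30))
  expect_gte(heldout_r2(m, rec$stim, rec$currents, "HC"), 0.95)
})

test_that("degenerate constant stimulus raises a singular-design error", {
  st <- stimulus(matrix(1, 2000, 1), 1, 1)
  expect_error(fit_ln(st, rnorm(2000), fit_config()), "degenerate|singular")
})

test_that("DivS fit satisfies its constraints exactly", {
  m <- fix_divs_fit()
  fs <- m$sup$nonlinearity
  expect_gte(min(fs$weights), 0)
  expect_lte(max(fs$weights), 1)
  expect_equal(nl_eval(fs, 0), 1, tolerance = 1e-6)
  expect_true(all(diff(m$exc$nonlinearity$weights) >= -1e-9))
  expect_true(all(diff(m$mse_log) <= 1e-12))
})

test_that("DivS recovers the canonical ground truth", {
  rep_ <- recovery_report(fix_divs_truth(), fix_divs_fit())
  expect_gt(rep_$cosine["exc"], 0.95)
  expect_gt(rep_$cosine["sup"], 0.95)
  expect_lte(abs(rep_$delay_error_ms), 2)
  rec <- fix_divs_recording()
  expect_gt(heldout_r2(fix_divs_fit(), rec$stim, rec$currents, "HC"), 0.9)
})

test_that("the fitted suppressive gain is ON-OFF (falls on both sides of zero)", {
  fs <- fix_divs_fit()$sup$nonlinearity
  kn <- fs$basis$knots
  lo <- kn < -0.25 * max(abs(kn))
  hi <- kn > 0.25 * max(abs(kn))
  expect_lt(min(fs$weights[lo]), 0.85)
  expect_lt(min(fs$weights[hi]), 0.85)
})

test_that("DivS nests the LN model on LN-generated data", {
  gt <- make_ground_truth("ln")
  rec <- generate_recording(gt, snr = 10, seed = 24, n_cycles = 2)
  cfg <- quick_cfg(max_outer_iters = 25)
  ml <- fit_ln(rec$stim, rec$currents, cfg)
  md <- fit_divs(rec$stim, rec$currents, cfg)
  r2l <- heldout_r2(ml, rec$stim, rec$currents, "HC")
  r2d <- heldout_r2(md, rec$stim, rec$currents, "HC")
  expect_gt(r2d, r2l - 0.01)
  # nesting on training MSE: DivS starts from the LN solution with fs = 1
  expect_lte(utils::tail(md$mse_log, 1),
             utils::tail(ml$mse_log, 1) * (1 + 1e-6))
})

test_that("AddS respects its nonpositive-suppression constraint", {
  m <- fix_adds_fit_on_divs()
  expect_lte(max(m$sup$nonlinearity$weights), 1e-9)
  expect_true(all(diff(m$mse_log) <= 1e-12))
})

test_that("AddS recovers additive ground truth but loses to DivS on DivS data", {
  gt_a <- make_ground_truth("adds")
  rec_a <- generate_recording(gt_a, snr = 10, seed = 25, n_cycles = 2)
  ma <- fit_adds(rec_a$stim, rec_a$currents, quick_cfg(max_outer_iters = 30))
  expect_gte(heldout_r2(ma, rec_a$stim, rec_a$currents, "HC"), 0.95)
  # model mismatch: on DivS-generated data AddS underperforms DivS
  rec <- fix_divs_recording()
  r2_adds <- heldout_r2(fix_adds_fit_on_divs(), rec$stim, rec$currents, "HC")
  r2_divs <- heldout_r2(fix_divs_fit(), rec$stim, rec$currents, "HC")
  expect_lt(r2_adds, r2_divs)
})

test_that("prediction identities hold", {
  m <- fix_divs_fit()
  st <- contrast_switching_stimulus(n_cycles = 1, cycle_s = 3, unique_s = 2,
                                    seed = 26)
  # fs = 1 reduces DivS to its excitatory LN branch
  m1 <- m
  m1$sup$nonlinearity$weights[] <- 1
  ln_equiv <- structure(list(filter = m$exc$filter,
                             nonlinearity = m$exc$nonlinearity,
                             offset = m$offset, mse_log = numeric(0),
                             kind = "ln"), class = "ln_model")
  expect_equal(as.numeric(predict_current(m1, st)),
               as.numeric(predict_current(ln_equiv, st)), tolerance = 1e-12)
  # identity nonlinearity reduces LN to the bare filter output
  b <- temporal_basis(8, 200, 1)
  f <- temporal_filter(rnorm(8), b, TRUE)
  kn <- seq(-3, 3, length.out = 11)
  ident <- nonlinearity(tent_basis(kn), kn)
  ml <- structure(list(filter = f, nonlinearity = ident, offset = 0,
                       mse_log = numeric(0), kind = "ln"),
                  class = "ln_model")
  g <- apply_filter(f, st)
  inside <- abs(g) <= 3
  expect_equal(as.numeric(predict_current(ml, st))[inside],
               as.numeric(g)[inside], tolerance = 1e-10)
  # zero-variance stimulus gives constant output
  stc <- stimulus(matrix(1, 1000, 1), 1, 1)
  expect_equal(diff(range(predict_current(m, stc))), 0)
})

test_that("the unit-norm convention removes filter-amplitude degeneracy", {
  m <- fix_divs_fit()
  st <- contrast_switching_stimulus(n_cycles = 1, cycle_s = 3, unique_s = 2,
                                    seed = 27)
  m2 <- m
  m2$exc$filter <- temporal_filter(2 * m$exc$filter$coeffs,
                                   m$exc$filter$basis, normalize = TRUE)
  expect_equal(as.numeric(predict_current(m2, st)),
               as.numeric(predict_current(m, st)), tolerance = 1e-12)
})
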