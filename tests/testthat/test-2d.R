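# Nonparametric 2-D nonlinearity model and its separability analysis.

test_that("fitted 2-D surface is monotone along the excitatory axis", {
  rec <- fix_divs_recording()
  md <- fix_divs_fit()
  m2 <- fit_2d(rec$stim, rec$currents,
               list(md$exc$filter, md$sup$filter),
               quick_cfg(max_outer_iters = 10))
  expect_true(all(apply(m2$weights, 2, diff) >= -1e-8))
  expect_true(all(diff(m2$mse_log) <= 1e-12))
  # separable (DivS) truth: the 2-D generalization gains nothing
  r2_2d <- heldout_r2(m2, rec$stim, rec$currents, "HC")
  r2_divs <- heldout_r2(md, rec$stim, rec$currents, "HC")
  expect_lte(r2_2d - r2_divs, 0.01)
  # and the surface is close to the separable product
  expect_gt(separability_r2(m2, md), 0.9)
})

test_that("a non-separable ground truth favors the 2-D model", {
  gt <- fix_divs_truth()
  st <- contrast_switching_stimulus(n_cycles = 2, seed = 41)
  ge <- apply_filter(gt$exc$filter, st)
  gs <- apply_filter(gt$sup$filter, st)
  # truth F(x,y) = x * (1 + 0.5 sin y) with gain clipped to [0.5, 1.5]:
  # monotone in x but not a separable product of 1-D curves
  sig <- pmax(ge, 0) * (1 + 0.5 * sin(2 * gs))
  set.seed(42)
  y <- sig + rnorm(length(sig), sd = sd(sig) / sqrt(20))
  cfg <- quick_cfg(max_outer_iters = 30)
  md <- fit_divs(st, y, cfg)
  m2 <- fit_2d(st, y, list(md$exc$filter, md$sup$filter),
               quick_cfg(max_outer_iters = 10))
  r2d <- heldout_r2(md, st, y, "HC")
  r22 <- heldout_r2(m2, st, y, "HC")
  expect_gt(r22, r2d + 0.02)
})

test_that("separability of an exactly separable surface is 1", {
  md <- fix_divs_fit()
  pb <- pyramid_basis_2d(seq(-2, 2, length.out = 9),
                         seq(-2, 2, length.out = 9))
  W <- outer(nl_eval(md$exc$nonlinearity, pb$grid_x),
             nl_eval(md$sup$nonlinearity, pb$grid_y)) + md$offset
  surf <- structure(list(filters = list(exc = md$exc$filter,
                                        sup = md$sup$filter),
                         basis = pb, weights = W,
                         density = matrix(1, 9, 9), mse_log = numeric(0),
                         kind = "2d"), class = "model2d")
  expect_equal(separability_r2(surf, md), 1, tolerance = 1e-10)
})

test_that("density weighting with all mass on one cell is degenerate but defined", {
  md <- fix_divs_fit()
  pb <- pyramid_basis_2d(seq(-1, 1, length.out = 5),
                         seq(-1, 1, length.out = 5))
  W <- matrix(rnorm(25), 5, 5)
  dens <- matrix(0, 5, 5); dens[3, 3] <- 1
  surf <- structure(list(filters = list(exc = md$exc$filter,
                                        sup = md$sup$filter),
                         basis = pb, weights = W, density = dens,
                         mse_log = numeric(0), kind = "2d"),
                    class = "model2d")
  # single-cell weighting: total weighted variance is 0, so the statistic
  # is decided entirely by that cell (bounded in [0, 1] by construction)
  r2 <- separability_r2(surf, md)
  expect_true(r2 >= 0 && r2 <= 1)
})
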