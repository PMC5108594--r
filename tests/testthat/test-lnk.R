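# Three-state kinetic (LNK) model: conservation, steady state, limit
# behavior and the extended two-channel variants.

test_that("occupancies are conserved and bounded in every simulation", {
  m <- make_ground_truth("lnk")
  st <- contrast_switching_stimulus(n_cycles = 1, seed = 4)
  sim <- simulate_lnk(m, st)
  expect_lt(max(abs(rowSums(sim$states) - 1)), 1e-9)
  expect_true(all(sim$states >= -1e-12 & sim$states <= 1 + 1e-12))
})

test_that("constant drive converges to the closed-form steady state", {
  for (u0 in c(2, 20, 120)) {
    st <- divsenc:::lnk_propagate_cpp(rep(u0, 8000), 50, 15, 1e-3, c(1, 0, 0))
    expect_equal(st[8000, 2], unname(lnk_steady_state(u0, 50, 15)["A"]),
                 tolerance = 1e-6)
  }
})

test_that("fast recovery removes depression: output matches depression-free kinetics", {
  # with very fast I -> R recovery the inactivated pool never accumulates,
  # so the 3-state chain reduces to the depression-free 2-state dynamics
  # dA/dt = u (1 - A) - k_ai A; integrate that oracle directly (same
  # trapezoidal rule, independent code path) and compare
  m <- make_ground_truth("lnk",
    overrides = list(u_max = 40, k_ai = 60, k_ir = 190))
  st <- contrast_switching_stimulus(n_cycles = 1, seed = 6)
  sim <- simulate_lnk(m, st)
  g <- apply_filter(m$filter, st)
  u <- m$u_max * pmax(nl_eval(m$input_nl, g), 0)
  h <- 0.001 / 2
  A <- numeric(length(u)); a <- 0
  for (t in seq_along(u)) {
    a <- (a + h * (u[t] - (u[t] + m$k_ai) * a)) /
      (1 + h * (u[t] + m$k_ai))
    A[t] <- a
  }
  keep <- 300:st$n_time
  expect_gt(cor(sim$current[keep], A[keep])^2, 0.99)
  # and the inactivated pool is indeed nearly empty
  expect_lt(max(sim$states[keep, "I"]), 0.2)
})

test_that("too-coarse integration steps are rejected", {
  m <- make_ground_truth("lnk", overrides = list(u_max = 300))
  st <- contrast_switching_stimulus(n_cycles = 1, seed = 1)
  expect_error(simulate_lnk(m, st), "step size|transition")
})

test_that("shared-depression variant with zero surround weight equals the single-channel model", {
  m <- make_ground_truth("lnk")
  st2 <- spot_annulus_stimulus(duration_s = 20, seed = 8)
  st1 <- stimulus(st2$values[, 1, drop = FALSE], st2$dt, st2$mean_level)
  # single-channel reference with the same rectified drive
  comp <- list(
    list(filter = m$filter,
         rectifier = function(x) m$u_max * pmax(nl_eval(m$input_nl, x), 0),
         weight = 1),
    list(filter = m$filter, rectifier = function(x) pmax(x, 0),
         weight = 0))
  ext <- extended_lnk_simulate("shared_depression", comp,
                               m$k_ai, m$k_ir, st2,
                               gain = m$gain, offset = m$offset)
  ref <- simulate_lnk(m, st1)
  expect_equal(as.numeric(ext$current), as.numeric(ref$current),
               tolerance = 1e-10)
  expect_lt(max(abs(rowSums(ext$states[[1]]) - 1)), 1e-9)
})

test_that("independent-depression variant conserves occupancy per stage", {
  b <- temporal_basis(8, 200, 1)
  set.seed(9)
  f1 <- temporal_filter(rnorm(8), b, TRUE)
  f2 <- temporal_filter(rnorm(8), b, TRUE)
  st2 <- spot_annulus_stimulus(duration_s = 10, seed = 10)
  comp <- list(list(filter = f1, weight = 1, rectifier = function(x) 40 * pmax(x, 0)),
               list(filter = f2, weight = 1, rectifier = function(x) 40 * pmax(x, 0)))
  ext <- extended_lnk_simulate("independent_depression", comp, 50, 15, st2)
  for (s in ext$states)
    expect_lt(max(abs(rowSums(s) - 1)), 1e-9)
  expect_error(extended_lnk_simulate("shared_depression",
    list(list(filter = f1, weight = -1)), 50, 15, st2), "nonnegative")
})
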