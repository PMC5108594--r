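# Function bases: orthonormal temporal sinusoids, tent and pyramid
# interpolators.

test_that("raw temporal basis functions vanish at both ends of support", {
  for (n in c(1, 3, 7, 12)) {
    expect_equal(temporal_basis_raw(0, n), 0)
    expect_equal(temporal_basis_raw(200, n, t_max = 200), 0,
                 tolerance = 1e-12)
  }
})

test_that("temporal basis columns are orthonormal and span the raw family", {
  for (nf in c(2, 8, 12, 20)) {
    b <- temporal_basis(nf, t_max = 200, dt = 1)
    gram <- crossprod(b$matrix)
    expect_lt(max(abs(gram - diag(nf))), 1e-8)
    # same column space as the raw sinusoids: projecting the raw functions
    # onto the orthonormal columns reproduces them
    raw <- sapply(seq_len(nf), function(n)
      temporal_basis_raw(b$times, n, 200))
    proj <- b$matrix %*% crossprod(b$matrix, raw)
    expect_lt(max(abs(proj - raw)), 1e-8)
  }
})

test_that("temporal basis rejects invalid arguments", {
  expect_error(temporal_basis(0), "positive")
  expect_error(temporal_basis(5, t_max = -10), "positive")
  expect_error(temporal_basis(5, t_max = 200, dt = 0), "positive")
})

test_that("tent basis is an exact partition-of-unity interpolator", {
  kn <- c(-2, -1, -0.2, 0.5, 1, 3)
  tb <- tent_basis(kn)
  # 1 at own knot, 0 at the others
  M <- tent_eval(tb, kn)
  expect_equal(M, diag(length(kn)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # partition of unity at arbitrary points
  x <- seq(-2, 3, length.out = 57)
  expect_equal(rowSums(tent_eval(tb, x)), rep(1, 57), tolerance = 1e-12)
  # exact reproduction of a linear function against the direct
  # interpolation oracle
  f <- function(x) 2 * x + 1
  w <- f(kn)
  set.seed(4)
  xr <- runif(100, -2, 3)
  oracle <- approx(kn, w, xout = xr)$y
  expect_equal(tent_interp(tb, w, xr), f(xr), tolerance = 1e-12)
  expect_equal(tent_interp(tb, w, xr), oracle, tolerance = 1e-12)
})

test_that("tent evaluation clamps outside the knot range", {
  tb <- tent_basis(c(0, 1, 2))
  w <- c(5, 7, -1)
  expect_equal(tent_interp(tb, w, c(-10, 10)), c(5, -1))
  expect_equal(divsenc:::tent_interp_deriv(tb, w, c(-10, 0.5, 10)), c(0, 2, 0))
})

test_that("tent basis rejects unsorted knots", {
  expect_error(tent_basis(c(1, 0, 2)), "increasing")
  expect_error(tent_basis(c(0, 1)), "increasing|3 points")
})

test_that("pyramid basis interpolates vertices and sums to one", {
  pb <- pyramid_basis_2d(seq(-1, 1, length.out = 5),
                         seq(0, 2, length.out = 4))
  # vertex evaluation: 1 at own vertex, 0 elsewhere
  gx <- rep(pb$grid_x, times = pb$ny)
  gy <- rep(pb$grid_y, each = pb$nx)
  M <- as.matrix(pyramid_eval(pb, gx, gy))
  expect_equal(M, diag(pb$nx * pb$ny), tolerance = 1e-12,
               ignore_attr = TRUE)
  # partition of unity and <= 3 nonzeros at interior points
  set.seed(5)
  x <- runif(200, -1, 1); y <- runif(200, 0, 2)
  Mi <- as.matrix(pyramid_eval(pb, x, y))
  expect_equal(rowSums(Mi), rep(1, 200), tolerance = 1e-12)
  expect_true(all(rowSums(Mi > 1e-12) <= 3))
})

test_that("pyramid basis reproduces planar functions exactly", {
  pb <- pyramid_basis_2d(seq(-2, 2, length.out = 7),
                         seq(-1, 3, length.out = 6))
  W <- outer(pb$grid_x, rep(1, pb$ny)) * 3 -
    outer(rep(1, pb$nx), pb$grid_y) * 2
  set.seed(6)
  x <- runif(100, -2, 2); y <- runif(100, -1, 3)
  expect_equal(pyramid_interp(pb, W, x, y), 3 * x - 2 * y,
               tolerance = 1e-10)
})

test_that("pyramid evaluation flags clamped points", {
  pb <- pyramid_basis_2d(0:3, 0:3)
  M <- pyramid_eval(pb, c(1, -5), c(1, 1))
  expect_equal(attr(M, "clamped"), c(FALSE, TRUE))
})

test_that("interpolants are piecewise linear between knots", {
  tb <- tent_basis(seq(-1, 1, by = 0.5))
  w <- c(0, 2, 1, -1, 3)
  # second differences of a dense sampling within one segment are 0
  x <- seq(-0.45, -0.05, by = 0.01)
  v <- tent_interp(tb, w, x)
  expect_lt(max(abs(diff(diff(v)))), 1e-12)
})
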