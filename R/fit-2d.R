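# Nonparametric 2-D nonlinearity model: c(t) = F[ke.s(t), ks.s(t)] with F a
# piecewise-planar surface on a pyramid basis, constrained monotonically
# increasing along the excitatory (first) axis to resolve the degeneracy
# under linear remixing of the two filters.

#' Fit the 2-D nonlinearity model
#'
#' Estimates the surface \eqn{F[x, y]} over the joint generator signals of an
#' excitatory/suppressive filter pair, as weights on a hexagonal-pyramid
#' basis, by least squares under the constraint that \eqn{F} is
#' non-decreasing along the first (excitatory) axis. Filters are typically
#' taken from a fitted DivS model; with \code{refine_filters = TRUE}
#' (default) they are then refined jointly with the surface by
#' block-coordinate descent under the same constraint.
#'
#' @inheritParams fit_ln
#' @param filters list of two \code{temporal_filter}s (excitatory,
#'   suppressive), e.g. \code{list(divs$exc$filter, divs$sup$filter)}.
#' @param refine_filters refine the filters jointly with the surface.
#' @return object of class \code{"model2d"}: \code{filters}, \code{basis}
#'   (a \code{pyramid_basis}), \code{weights} (\code{grid_n x grid_n}
#'   surface values), \code{density} (training-sample counts per vertex,
#'   used for separability weighting), \code{mse_log}.
#' @export
fit_2d <- function(stim, response, filters, cfg = fit_config(),
                   refine_filters = TRUE) {
  pp <- fit_prepare(stim, response, cfg)
  y <- pp$y; mask <- pp$mask; G <- pp$G
  Gm <- G[mask, , drop = FALSE]; ym <- y[mask]
  ae <- as.numeric(filters[[1]]$coeffs); ae <- ae / sqrt(sum(ae^2))
  as_ <- as.numeric(filters[[2]]$coeffs); as_ <- as_ / sqrt(sum(as_^2))
  ge <- as.numeric(Gm %*% ae); gs <- as.numeric(Gm %*% as_)
  pb <- pyramid_basis_2d(default_knots(ge, cfg$grid_n),
                         default_knots(gs, cfg$grid_n))
  nx <- pb$nx; ny <- pb$ny
  Pmap <- surface_increment_map(nx, ny)
  lower <- c(rep(-Inf, ny), rep(0, (nx - 1) * ny))
  W <- matrix(0, nx, ny)
  mse_log <- numeric(0)
  best <- NULL
  n_outer <- if (refine_filters) cfg$max_outer_iters else 1L
  for (it in seq_len(n_outer)) {
    X <- pyramid_eval(pb, ge, gs)
    XP <- X %*% Pmap
    A <- as.matrix(Matrix::crossprod(XP))
    b <- as.numeric(Matrix::crossprod(XP, ym))
    sol <- qp_box(A, b, lower = lower,
                  init = surface_to_increments(W))
    W <- matrix(as.numeric(Pmap %*% sol), nx, ny)
    pred <- as.numeric(X %*% as.numeric(W))
    mse <- mean((pred - ym)^2)
    if (is.null(best) || mse <= best$mse)
      best <- list(ae = ae, as_ = as_, pb = pb, W = W, mse = mse)
    mse_log <- c(mse_log, best$mse)
    if (!refine_filters) break
    if (length(mse_log) > 2 &&
        mse_log[length(mse_log) - 2] - mse_log[length(mse_log)] <
          cfg$rel_tol * mse_log[1]) break
    # filter refinement blocks (surface held fixed)
    ae <- filter_block_update(ae, Gm, ym,
      resid_fun = function(g) pyramid_interp(pb, W, g, gs) - ym,
      weight_fun = function(g) pyramid_grad_x(pb, W, g, gs),
      maxit = cfg$filter_maxit)
    sc <- sqrt(sum(ae^2)); ae <- ae / sc
    pb <- pyramid_basis_2d(pb$grid_x / sc, pb$grid_y)
    ge <- as.numeric(Gm %*% ae)
    as_ <- filter_block_update(as_, Gm, ym,
      resid_fun = function(g) pyramid_interp(pb, W, ge, g) - ym,
      weight_fun = function(g) pyramid_grad_y(pb, W, ge, g),
      maxit = cfg$filter_maxit)
    sc <- sqrt(sum(as_^2)); as_ <- as_ / sc
    pb <- pyramid_basis_2d(pb$grid_x, pb$grid_y / sc)
    gs <- as.numeric(Gm %*% as_)
  }
  ge <- as.numeric(Gm %*% best$ae); gs <- as.numeric(Gm %*% best$as_)
  dens <- vertex_density(best$pb, ge, gs)
  exc_f <- temporal_filter(matrix(best$ae, ncol = pp$nch), pp$basis, TRUE)
  sup_f <- temporal_filter(matrix(best$as_, ncol = pp$nch), pp$basis, TRUE)
  structure(list(filters = list(exc = exc_f, sup = sup_f),
                 basis = best$pb, weights = best$W, density = dens,
                 mse_log = mse_log, cfg = cfg, kind = "2d"),
            class = "model2d")
}

# Parameterization enforcing monotonicity along x: W[i, j] = b_j +
# sum_{i' = 2..i} d_{i'j} with d >= 0. Columns: ny free b's then the
# (nx-1)*ny increments.
surface_increment_map <- function(nx, ny) {
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  vid <- function(i, j) (j - 1L) * nx + i
  for (j in seq_len(ny)) {
    rows <- c(rows, vid(seq_len(nx), j))
    cols <- c(cols, rep(j, nx)); vals <- c(vals, rep(1, nx))
  }
  col0 <- ny
  for (j in seq_len(ny)) for (i2 in 2:nx) {
    k <- col0 + (j - 1L) * (nx - 1L) + (i2 - 1L)
    rows <- c(rows, vid(i2:nx, j))
    cols <- c(cols, rep(k, nx - i2 + 1L))
    vals <- c(vals, rep(1, nx - i2 + 1L))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nx * ny, ny + (nx - 1L) * ny))
}

surface_to_increments <- function(W) {
  nx <- nrow(W); ny <- ncol(W)
  c(W[1, ], as.numeric(pmax(apply(W, 2, diff), 0)))
}

# Directional slopes of the piecewise-planar surface within the enclosing
# triangle (used for filter refinement gradients).
pyramid_grad_x <- function(basis, W, x, y) pyramid_grad(basis, W, x, y, 1L)
pyramid_grad_y <- function(basis, W, x, y) pyramid_grad(basis, W, x, y, 2L)

pyramid_grad <- function(basis, W, x, y, axis) {
  gx <- basis$grid_x; gy <- basis$grid_y
  nx <- basis$nx; ny <- basis$ny
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  inside <- if (axis == 1L) x >= gx[1] & x <= gx[nx] else
    y >= gy[1] & y <= gy[ny]
  x <- pmin(pmax(x, gx[1]), gx[nx]); y <- pmin(pmax(y, gy[1]), gy[ny])
  i <- pmin(pmax(findInterval(x, gx, rightmost.closed = TRUE), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(y, gy, rightmost.closed = TRUE), 1L), ny - 1L)
  u <- (x - gx[i]) / (gx[i + 1L] - gx[i])
  v <- (y - gy[j]) / (gy[j + 1L] - gy[j])
  lower <- (u + v) <= 1
  if (axis == 1L) {
    hx <- gx[i + 1L] - gx[i]
    sl <- ifelse(lower, W[cbind(i + 1L, j)] - W[cbind(i, j)],
                 W[cbind(i + 1L, j + 1L)] - W[cbind(i, j + 1L)]) / hx
  } else {
    hy <- gy[j + 1L] - gy[j]
    sl <- ifelse(lower, W[cbind(i, j + 1L)] - W[cbind(i, j)],
                 W[cbind(i + 1L, j + 1L)] - W[cbind(i + 1L, j)]) / hy
  }
  sl[!inside] <- 0
  sl
}

vertex_density <- function(basis, x, y) {
  i <- sapply(x, function(v) which.min(abs(basis$grid_x - v)))
  j <- sapply(y, function(v) which.min(abs(basis$grid_y - v)))
  tab <- table(factor(i, levels = seq_len(basis$nx)),
               factor(j, levels = seq_len(basis$ny)))
  matrix(as.numeric(tab), basis$nx, basis$ny)
}

#' Separability of a fitted 2-D nonlinearity
#'
#' Fraction of (density-weighted) variance of the 2-D surface explained by
#' the separable DivS form \eqn{f_e(x) f_s(y) + c_0} evaluated on the same
#' grid. A value near 1 means the joint nonlinearity is captured by the
#' multiplicative decomposition.
#'
#' @param surface a \code{model2d}.
#' @param divs a \code{divs_model} sharing the filter pair.
#' @param density optional weight matrix over grid vertices; defaults to the
#'   training-sample density stored in \code{surface}.
#' @return R-squared in [0, 1] (negative values truncated at 0).
#' @export
separability_r2 <- function(surface, divs, density = NULL) {
  pb <- surface$basis
  W <- surface$weights
  P <- outer(nl_eval(divs$exc$nonlinearity, pb$grid_x),
             nl_eval(divs$sup$nonlinearity, pb$grid_y)) + divs$offset
  w <- density %||% surface$density
  w <- w / sum(w)
  mu <- sum(w * W)
  ss_tot <- sum(w * (W - mu)^2)
  ss_res <- sum(w * (W - P)^2)
  max(0, min(1, 1 - ss_res / ss_tot))
}
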