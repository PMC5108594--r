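# Function bases: orthonormalized temporal sinusoids for filters, tent
# (piecewise-linear) bases for 1-D nonlinearities, and hexagonal-pyramid
# bases for nonparametric 2-D nonlinearities.

#' Orthonormalized temporal filter basis
#'
#' Constructs the family of time-warped sinusoids
#' \eqn{\zeta_n(t) = \sin[\pi n (2t/t_F - (t/t_F)^2)]}, \eqn{n = 1..n_funcs},
#' sampled on \code{t = 0, dt, ..., t_max - dt}, then orthonormalized. Every
#' raw function vanishes at \eqn{t = 0} and \eqn{t = t_F}, so filters built on
#' this basis are smooth, causal and vanish at the ends of their support. The
#' warping concentrates oscillations at short lags, giving finer temporal
#' resolution where retinal filters have structure.
#'
#' Orthonormalization is ordered Gram-Schmidt over \eqn{n = 1..n_funcs} at the
#' working \code{dt} (computed via a sign-fixed QR decomposition, which is the
#' same map), so the column span equals that of the raw sinusoids.
#'
#' @param n_funcs number of basis functions (default 12).
#' @param t_max filter duration \eqn{t_F} in ms (default 200).
#' @param dt sample bin in ms (default 1).
#' @return An object of class \code{"temporal_basis"}: list with \code{matrix}
#'   (\code{t_max/dt} rows, one column per function, orthonormal columns),
#'   \code{n_funcs}, \code{t_max}, \code{dt}, \code{times}.
#' @examples
#' b <- temporal_basis(6)
#' max(abs(crossprod(b$matrix) - diag(6)))  # ~ 1e-15
#' @export
temporal_basis <- function(n_funcs = 12, t_max = 200, dt = 1) {
  if (n_funcs < 1 || t_max <= 0 || dt <= 0)
    stop_invalid("n_funcs, t_max and dt must be positive")
  L <- round(t_max / dt)
  if (abs(L * dt - t_max) > dt)
    stop_invalid("dt must divide t_max to within one bin")
  tt <- (seq_len(L) - 1) * dt
  raw <- sapply(seq_len(n_funcs), function(n) temporal_basis_raw(tt, n, t_max))
  raw <- matrix(raw, nrow = L)
  qrd <- qr(raw)
  Q <- qr.Q(qrd)
  sg <- sign(diag(qr.R(qrd)))
  sg[sg == 0] <- 1
  Q <- sweep(Q, 2, sg, `*`)
  structure(list(matrix = Q, n_funcs = n_funcs, t_max = t_max, dt = dt,
                 times = tt),
            class = "temporal_basis")
}

#' Raw (un-orthonormalized) temporal basis function
#'
#' @param t times in ms (vector).
#' @param n function index (1-based).
#' @param t_max duration \eqn{t_F} in ms.
#' @return \eqn{\sin[\pi n (2t/t_F - (t/t_F)^2)]}.
#' @export
temporal_basis_raw <- function(t, n, t_max = 200) {
  u <- t / t_max
  sin(pi * n * (2 * u - u^2))
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat(sprintf("Temporal basis: %d orthonormal functions over %g ms (dt = %g ms)\n",
              x$n_funcs, x$t_max, x$dt))
  invisible(x)
}

#' Tent (piecewise-linear hat) basis for 1-D nonlinearities
#'
#' Hat functions on an ordered knot grid: each basis function is 1 at its own
#' knot, 0 at all others, and linear in between, so any weight vector defines
#' the piecewise-linear interpolant through \code{(knots, weights)}. Inputs
#' outside the knot range are clamped to the boundary (constant
#' extrapolation).
#'
#' @param knots strictly increasing numeric vector, length >= 3.
#' @return An object of class \code{"tent_basis"}.
#' @export
tent_basis <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3 || any(diff(knots) <= 0))
    stop_invalid("knots must be strictly increasing with >= 3 points")
  structure(list(knots = knots, n = length(knots)), class = "tent_basis")
}

#' Evaluate a tent basis
#'
#' @param basis a \code{tent_basis}.
#' @param x numeric vector of evaluation points.
#' @return matrix \code{length(x)} x \code{n_knots} of hat-function values;
#'   rows sum to 1 (partition of unity).
#' @export
tent_eval <- function(basis, x) {
  kn <- basis$knots
  K <- basis$n
  x <- pmin(pmax(x, kn[1]), kn[K])
  idx <- findInterval(x, kn, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), K - 1L)
  u <- (x - kn[idx]) / (kn[idx + 1L] - kn[idx])
  n <- length(x)
  M <- matrix(0, n, K)
  M[cbind(seq_len(n), idx)] <- 1 - u
  M[cbind(seq_len(n), idx + 1L)] <- M[cbind(seq_len(n), idx + 1L)] + u
  M
}

#' Interpolate a tent-basis weight vector
#'
#' Piecewise-linear interpolation of \code{(knots, weights)} at \code{x},
#' clamped outside the knot range.
#'
#' @param basis a \code{tent_basis}.
#' @param weights one value per knot.
#' @param x evaluation points.
#' @return numeric vector.
#' @export
tent_interp <- function(basis, weights, x) {
  tent_interp_cpp(basis$knots, weights, as.numeric(x), FALSE)$value
}

# Derivative (slope of the active segment) of the interpolant at points x;
# zero outside the knot range (clamped).
tent_interp_deriv <- function(basis, weights, x) {
  tent_interp_cpp(basis$knots, weights, as.numeric(x), TRUE)$deriv
}

#' Hexagonal-pyramid basis for 2-D nonlinearities
#'
#' Piecewise-planar basis on a rectangular grid: each grid square is split
#' into two triangles along the anti-diagonal, and the basis function at a
#' vertex is the hexagonal pyramid that is 1 at that vertex, 0 at all other
#' vertices, and planar on each adjacent triangle. Weights on this basis give
#' the continuous piecewise-planar surface interpolating the weights at the
#' vertices; at most three bases are nonzero at any point (the enclosing
#' triangle's corners). Points outside the grid are clamped to its boundary.
#'
#' @param grid_x,grid_y strictly increasing numeric grids, length >= 3 each.
#' @return An object of class \code{"pyramid_basis"}.
#' @export
pyramid_basis_2d <- function(grid_x, grid_y) {
  grid_x <- as.numeric(grid_x); grid_y <- as.numeric(grid_y)
  if (length(grid_x) < 3 || any(diff(grid_x) <= 0) ||
      length(grid_y) < 3 || any(diff(grid_y) <= 0))
    stop_invalid("grids must be strictly increasing with >= 3 points")
  structure(list(grid_x = grid_x, grid_y = grid_y,
                 nx = length(grid_x), ny = length(grid_y)),
            class = "pyramid_basis")
}

#' Evaluate a 2-D pyramid basis
#'
#' @param basis a \code{pyramid_basis}.
#' @param x,y numeric vectors of evaluation points (recycled to equal length).
#' @param sparse return a \code{Matrix::sparseMatrix} (default) or dense.
#' @return matrix \code{n} x \code{nx*ny} (vertex (i,j) in column
#'   \code{(j-1)*nx + i}); rows sum to 1. Attribute \code{"clamped"} flags
#'   points outside the grid.
#' @export
pyramid_eval <- function(basis, x, y, sparse = TRUE) {
  gx <- basis$grid_x; gy <- basis$grid_y
  nx <- basis$nx; ny <- basis$ny
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  clamped <- x < gx[1] | x > gx[nx] | y < gy[1] | y > gy[ny]
  x <- pmin(pmax(x, gx[1]), gx[nx])
  y <- pmin(pmax(y, gy[1]), gy[ny])
  i <- pmin(pmax(findInterval(x, gx, rightmost.closed = TRUE), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(y, gy, rightmost.closed = TRUE), 1L), ny - 1L)
  u <- (x - gx[i]) / (gx[i + 1L] - gx[i])
  v <- (y - gy[j]) / (gy[j + 1L] - gy[j])
  # lower triangle u + v <= 1: corners (i,j), (i+1,j), (i,j+1)
  # upper triangle:             corners (i+1,j+1), (i+1,j), (i,j+1)
  lower <- (u + v) <= 1
  vid <- function(ii, jj) (jj - 1L) * nx + ii
  rows <- rep(seq_len(n), 3L)
  cols <- numeric(3L * n); vals <- numeric(3L * n)
  c1 <- ifelse(lower, vid(i, j), vid(i + 1L, j + 1L))
  w1 <- ifelse(lower, 1 - u - v, u + v - 1)
  c2 <- vid(i + 1L, j); w2 <- ifelse(lower, u, 1 - v)
  c3 <- vid(i, j + 1L); w3 <- ifelse(lower, v, 1 - u)
  cols <- c(c1, c2, c3); vals <- c(w1, w2, w3)
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(n, nx * ny))
  if (!sparse) M <- as.matrix(M)
  attr(M, "clamped") <- clamped
  M
}

#' Interpolate a pyramid-basis weight matrix
#'
#' Piecewise-planar interpolation of the vertex weights at \code{(x, y)},
#' clamped to the grid boundary.
#'
#' @param basis a \code{pyramid_basis}.
#' @param weights matrix \code{nx} x \code{ny} of vertex values.
#' @param x,y evaluation points.
#' @return numeric vector.
#' @export
pyramid_interp <- function(basis, weights, x, y) {
  as.numeric(pyramid_eval(basis, x, y) %*% as.numeric(weights))
}
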