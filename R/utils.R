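# Internal numerical helpers shared across fitting routines.

#' @useDynLib divsenc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm rpois sd var fft convolve quantile runif
NULL

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded generators do not perturb the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Causal FFT convolution: out[t] = sum_{tau=0}^{L-1} k[tau+1] * x[t - tau],
# zero-padded before t = 1.
causal_conv <- function(x, k) {
  n <- length(x)
  L <- length(k)
  m <- stats::nextn(n + L - 1, 2)
  xf <- stats::fft(c(x, rep(0, m - n)))
  kf <- stats::fft(c(k, rep(0, m - L)))
  out <- Re(stats::fft(xf * kf, inverse = TRUE)) / m
  out[seq_len(n)]
}

# Quadratic program min 0.5 b' A b - d' b subject to box constraints,
# solved with projected quasi-Newton (L-BFGS-B). A small ridge keeps A
# positive definite when tent bins are empty.
qp_box <- function(A, d, lower = -Inf, upper = Inf, init = NULL,
                   ridge = 1e-9) {
  p <- length(d)
  A <- A + diag(ridge * (mean(diag(A)) + 1), p)
  if (is.null(init)) init <- rep(0, p)
  init <- pmin(pmax(init, lower), upper)
  fn <- function(b) 0.5 * sum(b * (A %*% b)) - sum(d * b)
  gr <- function(b) as.numeric(A %*% b) - d
  res <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  res$par
}

# Nonnegative least squares via Cholesky reduction of the normal equations,
# then Lawson-Hanson on the reduced p x p system (pracma::lsqnonneg).
nnls_normal <- function(A, d, ridge = 1e-9) {
  p <- length(d)
  A <- A + diag(ridge * (mean(diag(A)) + 1), p)
  R <- chol(A)
  rhs <- backsolve(R, d, transpose = TRUE)
  pracma::lsqnonneg(R, rhs)$x
}

#' Softplus spiking nonlinearity
#'
#' Overflow-safe \eqn{\log(1 + e^g)}, the fixed output nonlinearity of the
#' spiking models.
#'
#' @param g numeric.
#' @return numeric.
#' @export
softplus <- function(g) ifelse(g > 30, g, log1p(exp(pmin(g, 30))))
softplus_deriv <- function(g) 1 / (1 + exp(-pmin(pmax(g, -700), 700)))

#' Cosine similarity between kernels
#'
#' By default sign-canonicalized (absolute value), since kernels are
#' defined up to sign with the compensating sign absorbed by the
#' nonlinearity domain.
#'
#' @param a,b numeric vectors.
#' @param signed keep the sign (default FALSE).
#' @return scalar in [0, 1] (or [-1, 1] if signed).
#' @export
cosine_sim <- function(a, b, signed = FALSE) {
  cs <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (signed) cs else abs(cs)
}

#' Lag of the absolute peak of a kernel
#'
#' @param kernel numeric kernel sampled at \code{dt}.
#' @param dt bin width in ms.
#' @return peak lag in ms (0-based).
#' @export
peak_lag_ms <- function(kernel, dt) {
  (which.max(abs(kernel)) - 1) * dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
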