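# 1-D nonparametric nonlinearities on tent bases, with the constraint
# classes used by the cascade models: unconstrained (LN), monotone
# increasing (excitatory), suppressive-unit (gain in [0,1], value 1 at zero
# input), and nonpositive (additive suppression).

#' Piecewise-linear nonlinearity
#'
#' @param basis a \code{\link{tent_basis}}.
#' @param weights numeric, one value per knot (the function values at the
#'   knots).
#' @param constraint one of \code{"none"}, \code{"monotone_increasing"},
#'   \code{"suppressive_unit"} (values in [0,1], value 1 at x = 0),
#'   \code{"nonpositive"}.
#' @return object of class \code{"nonlinearity"}.
#' @export
nonlinearity <- function(basis, weights, constraint = "none") {
  weights <- as.numeric(weights)
  if (length(weights) != basis$n)
    stop_invalid("one weight per knot required")
  constraint <- match.arg(constraint,
                          c("none", "monotone_increasing",
                            "suppressive_unit", "nonpositive"))
  structure(list(basis = basis, weights = weights, constraint = constraint),
            class = "nonlinearity")
}

#' Evaluate a nonlinearity
#'
#' Piecewise-linear interpolation of the knot weights, clamped (constant)
#' outside the knot range.
#'
#' @param nl a \code{nonlinearity}.
#' @param x numeric vector.
#' @return numeric vector \code{f(x)}.
#' @export
nl_eval <- function(nl, x) tent_interp(nl$basis, nl$weights, x)

nl_deriv <- function(nl, x) tent_interp_deriv(nl$basis, nl$weights, x)

# Rescale the knot axis by 1/alpha: f_new(x) = f_old(alpha * x). Exact for
# piecewise-linear functions (knots move, weights unchanged); used when a
# filter is renormalized so model predictions are unchanged.
nl_rescale_x <- function(nl, alpha) {
  kn <- nl$basis$knots * (1 / alpha)
  if (alpha < 0) { kn <- rev(kn); nl$weights <- rev(nl$weights) }
  nl$basis <- tent_basis(kn)
  nl
}

check_constraint <- function(nl, tol = 1e-7) {
  w <- nl$weights
  switch(nl$constraint,
    none = TRUE,
    monotone_increasing = all(diff(w) >= -tol),
    suppressive_unit = all(w >= -tol) && all(w <= 1 + tol) &&
      abs(nl_eval(nl, 0) - 1) < 1e-6,
    nonpositive = all(w <= tol))
}

# Default knot grid over the observed generator-signal distribution.
default_knots <- function(g, n_knots = 21, n_sd = 3) {
  m <- mean(g); s <- stats::sd(g)
  if (s == 0) stop_invalid("degenerate (constant) generator signal")
  seq(m - n_sd * s, m + n_sd * s, length.out = n_knots)
}

#' @export
print.nonlinearity <- function(x, ...) {
  cat(sprintf("Nonlinearity: %d knots on [%.3g, %.3g], constraint = %s\n",
              x$basis$n, x$basis$knots[1], x$basis$knots[x$basis$n],
              x$constraint))
  invisible(x)
}
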