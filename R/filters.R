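# Temporal filters on the orthonormal basis, and their application to
# stimuli (causal convolution of the mean-subtracted stimulus).

#' Temporal filter
#'
#' A linear filter represented as coefficients on a \code{\link{temporal_basis}},
#' one coefficient column per stimulus channel. Under the unit-norm
#' convention (used by all fitted models) the concatenated kernel has L2 norm
#' 1 and all gain lives in the downstream nonlinearity, which resolves the
#' scale degeneracy between filter amplitude and nonlinearity domain.
#'
#' @param coeffs numeric vector (1 channel) or matrix \code{n_funcs} x
#'   \code{n_channels}.
#' @param basis a \code{temporal_basis}.
#' @param normalize rescale coefficients so the kernel has unit L2 norm.
#' @return object of class \code{"temporal_filter"}.
#' @export
temporal_filter <- function(coeffs, basis, normalize = FALSE) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != basis$n_funcs)
    stop_invalid("coefficient rows must match basis size")
  f <- structure(list(coeffs = coeffs, basis = basis,
                      n_channels = ncol(coeffs), normalized = normalize),
                 class = "temporal_filter")
  if (normalize) f <- normalize_filter(f)
  f
}

#' Expand a temporal filter to its discrete kernel
#'
#' @param filter a \code{temporal_filter}.
#' @return matrix \code{t_max/dt} x \code{n_channels}; \code{kernel = basis
#'   matrix \%*\% coeffs} exactly.
#' @export
filter_kernel <- function(filter) {
  filter$basis$matrix %*% filter$coeffs
}

normalize_filter <- function(filter) {
  # basis columns are orthonormal, so the kernel norm equals the coeff norm
  nrm <- sqrt(sum(filter$coeffs^2))
  if (nrm == 0) stop_invalid("cannot normalize a zero filter")
  filter$coeffs <- filter$coeffs / nrm
  filter$normalized <- TRUE
  filter
}

#' Apply a temporal filter to a stimulus
#'
#' Computes the generator signal \eqn{g(t) = \sum_{\tau \ge 0} k(\tau)
#' s(t-\tau)}, summed over channels, by causal convolution. The stimulus is
#' expressed as deviation from its mean level before filtering (standard
#' practice for contrast stimuli). The first \code{t_max/dt} bins are
#' burn-in, flagged via \code{attr(, "burn_in")}.
#'
#' @param filter a \code{temporal_filter}.
#' @param stim a \code{stimulus} (or plain numeric vector/matrix, assumed
#'   zero-mean).
#' @return numeric vector of generator-signal values with attribute
#'   \code{"burn_in"} (number of leading bins affected by the zero-padded
#'   history).
#' @export
apply_filter <- function(filter, stim) {
  if (inherits(stim, "stimulus")) {
    vals <- sweep(stim$values, 2, stim$mean_level)
  } else {
    vals <- as.matrix(stim)
  }
  if (ncol(vals) != filter$n_channels)
    stop_invalid("stimulus channels do not match filter channels")
  kern <- filter_kernel(filter)
  g <- numeric(nrow(vals))
  for (ch in seq_len(ncol(vals)))
    g <- g + causal_conv(vals[, ch], kern[, ch])
  attr(g, "burn_in") <- nrow(kern)
  g
}

# Generator design matrix: column (ch, j) holds the basis function j of
# channel ch convolved with the stimulus, so g = G %*% c(coeffs).
generator_design <- function(basis, stim) {
  vals <- sweep(stim$values, 2, stim$mean_level)
  nch <- ncol(vals)
  G <- matrix(0, nrow(vals), basis$n_funcs * nch)
  for (ch in seq_len(nch))
    for (j in seq_len(basis$n_funcs))
      G[, (ch - 1) * basis$n_funcs + j] <-
        causal_conv(vals[, ch], basis$matrix[, j])
  G
}

#' Center fraction of a two-channel filter
#'
#' Norm of the center (spot) component divided by the norm of the full
#' filter; used to compare the spatial footprint of excitatory and
#' suppressive terms in spot/annulus fits.
#'
#' @param filter a two-channel \code{temporal_filter}.
#' @return scalar in [0, 1].
#' @export
center_fraction <- function(filter) {
  if (filter$n_channels != 2)
    stop_invalid("center_fraction requires a two-channel filter")
  k <- filter_kernel(filter)
  sqrt(sum(k[, 1]^2)) / sqrt(sum(k^2))
}
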