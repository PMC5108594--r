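# Response-weighted covariance analysis: the cross-correlation between
# stimulus and response (analogous to the spike-triggered average) and the
# response-weighted covariance with the prior (unweighted) stimulus
# covariance subtracted, followed by eigendecomposition. One code path
# serves currents (continuous weights) and spikes (binned counts).

#' Response-weighted stimulus moments and covariance difference
#'
#' Builds the lagged stimulus matrix \eqn{s_t(\tau), \tau = 0..n_{lags}-1},
#' computes the response-weighted mean kernel (centered cross-correlation,
#' proportional to the spike-triggered average minus the prior mean for
#' count weights) and the response-weighted covariance minus the prior
#' covariance, then diagonalizes the difference. When the weights have a
#' usable nonzero mean (counts, rectified currents) the weighted moments
#' are normalized by the total weight, which makes the count path exactly
#' the classical spike-triggered covariance; for zero-mean weights the
#' second moment is computed with centered weights at \code{1/T} scaling
#' (the covariance difference directly, as both terms then coincide in
#' expectation for linear responses).
#'
#' @param stim a \code{stimulus} (channel 1 used), or numeric vector.
#' @param response numeric response (current trace or binned spike counts),
#'   one value per stimulus bin.
#' @param n_lags number of lags (default 200; at 1-ms resolution this
#'   covers 200 ms).
#' @param n_surrogates if > 0, eigenvalue significance is assessed against
#'   this many response-shuffled surrogates (circular shifts); an
#'   eigenvalue is significant outside the [1st, 99th] percentile band.
#' @return object of class \code{"covariance_result"}: \code{mean_kernel},
#'   \code{covdiff} (symmetric), \code{eigenvalues} (sorted by decreasing
#'   magnitude), \code{eigenvectors} (unit-norm columns, sign-canonicalized
#'   so the largest-magnitude element is positive), and optionally
#'   \code{significant}, \code{surrogate_band}.
#' @export
response_weighted_moments <- function(stim, response, n_lags = 200,
                                      n_surrogates = 0) {
  s <- if (inherits(stim, "stimulus"))
    stim$values[, 1] - stim$mean_level else as.numeric(stim)
  w_full <- as.numeric(response)
  if (length(w_full) != length(s))
    stop_invalid("response length must match stimulus")
  S <- stats::embed(s, n_lags)          # row t: s(t), s(t-1), ...
  w <- w_full[n_lags:length(s)]
  if (all(w == 0)) stop_invalid("degenerate weighting: response is all zero")
  res <- rw_moments(S, w)
  ev <- eigen(res$covdiff, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  out <- list(mean_kernel = res$mean_kernel, covdiff = res$covdiff,
              eigenvalues = vals, eigenvectors = vecs, n_lags = n_lags)
  if (n_surrogates > 0) {
    n <- length(w)
    sur <- sapply(seq_len(n_surrogates), function(i) {
      ws <- w[((seq_len(n) - 1 + sample.int(n, 1)) %% n) + 1]
      eigen(rw_moments(S, ws)$covdiff, symmetric = TRUE,
            only.values = TRUE)$values
    })
    band <- stats::quantile(sur, c(0.01, 0.99))
    out$surrogate_band <- band
    out$significant <- vals < band[1] | vals > band[2]
  }
  structure(out, class = "covariance_result")
}

rw_moments <- function(S, w) {
  T_ <- length(w)
  wbar <- mean(w)
  prior_mean <- colMeans(S)
  Sc <- sweep(S, 2, prior_mean)
  mean_kernel <- as.numeric(crossprod(Sc, w - wbar)) / T_
  if (abs(sum(w)) > 1e-8 * (sum(abs(w)) + 1e-300)) {
    sw <- sum(w)
    mu_w <- as.numeric(crossprod(S, w)) / sw
    Sw <- sweep(S, 2, mu_w)
    Cw <- crossprod(Sw * w, Sw) / sw
    Cp <- crossprod(Sc) / T_
    covdiff <- Cw - Cp
  } else {
    wc <- w - wbar
    covdiff <- crossprod(Sc * wc, Sc) / T_
  }
  covdiff <- (covdiff + t(covdiff)) / 2
  list(mean_kernel = mean_kernel, covdiff = covdiff)
}

#' Projection of filters onto a filter subspace
#'
#' Norm of each unit-normalized filter's orthogonal projection onto the
#' span of a set of basis filters: 1 when the filter lies in the span, 0
#' when orthogonal to it.
#'
#' @param filters list of numeric kernels (or a matrix, one per column).
#' @param basis_filters list/matrix of linearly independent kernels
#'   spanning the reference subspace.
#' @return numeric vector of projection norms in [0, 1].
#' @export
subspace_projection <- function(filters, basis_filters) {
  F_ <- if (is.list(filters)) do.call(cbind, filters) else
    as.matrix(filters)
  B <- if (is.list(basis_filters)) do.call(cbind, basis_filters) else
    as.matrix(basis_filters)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) stop_invalid("basis filters are linearly dependent")
  Q <- qr.Q(qrB)
  apply(F_, 2, function(f) {
    f <- f / sqrt(sum(f^2))
    sqrt(sum(as.numeric(crossprod(Q, f))^2))
  })
}

#' @export
print.covariance_result <- function(x, ...) {
  cat(sprintf("Response-weighted covariance: %d lags\n", x$n_lags))
  cat("  leading eigenvalues (|.| sorted):",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "\n")
  invisible(x)
}
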