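# Deterministic model predictions on a stimulus, plus generic goodness of
# fit on held-out repeat windows.

#' Predict the continuous current response of a fitted model
#'
#' Dispatches on the model class (LN, DivS, AddS, 2-D, LNK). The returned
#' series carries a \code{"burn_in"} attribute flagging the leading
#' filter-length bins.
#'
#' @param model a fitted current model.
#' @param stim a \code{stimulus} with matching channel count.
#' @return numeric vector, one prediction per stimulus bin.
#' @export
predict_current <- function(model, stim) {
  UseMethod("predict_current")
}

#' @export
predict_current.ln_model <- function(model, stim) {
  g <- apply_filter(model$filter, stim)
  out <- nl_eval(model$nonlinearity, g) + model$offset
  attr(out, "burn_in") <- attr(g, "burn_in")
  out
}

#' @export
predict_current.divs_model <- function(model, stim) {
  ge <- apply_filter(model$exc$filter, stim)
  gs <- apply_filter(model$sup$filter, stim)
  out <- nl_eval(model$exc$nonlinearity, ge) *
    nl_eval(model$sup$nonlinearity, gs) + model$offset
  attr(out, "burn_in") <- attr(ge, "burn_in")
  out
}

#' @export
predict_current.adds_model <- function(model, stim) {
  ge <- apply_filter(model$exc$filter, stim)
  gs <- apply_filter(model$sup$filter, stim)
  out <- nl_eval(model$exc$nonlinearity, ge) +
    nl_eval(model$sup$nonlinearity, gs) + model$offset
  attr(out, "burn_in") <- attr(ge, "burn_in")
  out
}

#' @export
predict_current.model2d <- function(model, stim) {
  ge <- apply_filter(model$filters$exc, stim)
  gs <- apply_filter(model$filters$sup, stim)
  out <- pyramid_interp(model$basis, model$weights, ge, gs)
  attr(out, "burn_in") <- attr(ge, "burn_in")
  out
}

#' Held-out R-squared on repeat windows
#'
#' Fraction of variance of the response explained by the model prediction
#' over the held-out repeat windows (trial-averaged when several repeats are
#' present).
#'
#' @param model a fitted current model.
#' @param stim the \code{stimulus}.
#' @param response a \code{trial_set} or numeric trace.
#' @param label restrict to repeat windows with this contrast label
#'   (default: all).
#' @return R-squared (1 - MSE / variance), can be negative for models worse
#'   than the mean.
#' @export
heldout_r2 <- function(model, stim, response, label = NULL) {
  pred <- predict_current(model, stim)
  obs <- extract_repeats(stim, response, label)
  prd <- extract_repeats(stim, trial_set(pred, stim$dt), label)
  m_obs <- rowMeans(obs)
  m_prd <- rowMeans(prd)   # identical across repeats of the same stimulus
  1 - mean((m_prd - m_obs)^2) / stats::var(m_obs)
}

#' Training R-squared over a mask
#'
#' @param model fitted model.
#' @param stim stimulus.
#' @param response trace or \code{trial_set}.
#' @param mask logical vector (default: unique segments minus burn-in).
#' @return R-squared on the masked samples.
#' @export
masked_r2 <- function(model, stim, response, mask = NULL) {
  y <- response_trace(response)
  pred <- predict_current(model, stim)
  if (is.null(mask))
    mask <- training_mask(stim, burn_in_bins = attr(pred, "burn_in") %||% 0)
  1 - mean((pred[mask] - y[mask])^2) / stats::var(y[mask])
}

#' @export
print.divs_model <- function(x, ...) {
  ke <- filter_kernel(x$exc$filter); ks <- filter_kernel(x$sup$filter)
  dt <- x$exc$filter$basis$dt
  cat("Divisive suppression (DivS) model\n")
  cat(sprintf("  exc filter peak %g ms; sup filter peak %g ms; offset %.4g\n",
              peak_lag_ms(ke[, 1], dt), peak_lag_ms(ks[, 1], dt), x$offset))
  cat(sprintf("  final training MSE %.5g (%d outer iterations)\n",
              utils::tail(x$mse_log, 1), length(x$mse_log)))
  invisible(x)
}

#' @export
print.ln_model <- function(x, ...) {
  cat("LN model\n")
  cat(sprintf("  final training MSE %.5g (%d outer iterations)\n",
              utils::tail(x$mse_log, 1), length(x$mse_log)))
  invisible(x)
}
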