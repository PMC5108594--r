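# Shared fitting configuration and the trial container for continuous
# (synaptic-current) responses.

#' Fitting configuration
#'
#' @param dt working bin width in ms (default 1; all evaluation uses 1-ms
#'   bins).
#' @param n_basis number of temporal basis functions (default 12).
#' @param t_max filter duration in ms (default 200).
#' @param n_knots knots per 1-D nonlinearity (default 21, spanning mean
#'   +/- 3 SD of the generator signal).
#' @param grid_n vertices per axis of the 2-D nonlinearity grid (default 15).
#' @param n_random_inits random restarts in addition to the deterministic
#'   (cross-correlation / LN-initialized) start (default 2).
#' @param max_outer_iters maximum block-coordinate outer iterations
#'   (default 100).
#' @param rel_tol relative MSE / LL change declaring convergence
#'   (default 1e-6).
#' @param filter_maxit quasi-Newton iterations per filter block update
#'   (default 30).
#' @param train_stride fit continuous-current models on every
#'   \code{train_stride}-th training sample (default 2; the 30-Hz
#'   band-limited stimulus is heavily oversampled at 1 ms, so thinning the
#'   fitting samples loses essentially no information while halving cost).
#'   Evaluation always uses every 1-ms bin.
#' @param seed RNG seed for random restarts.
#' @return list of class \code{"fit_config"}.
#' @export
fit_config <- function(dt = 1, n_basis = 12, t_max = 200, n_knots = 21,
                       grid_n = 15, n_random_inits = 2,
                       max_outer_iters = 100, rel_tol = 1e-6,
                       filter_maxit = 30, train_stride = 2, seed = 1) {
  stopifnot(n_basis >= 1, n_knots >= 3, grid_n >= 3,
            max_outer_iters >= 1, rel_tol > 0, train_stride >= 1)
  structure(list(dt = dt, n_basis = n_basis, t_max = t_max,
                 n_knots = n_knots, grid_n = grid_n,
                 n_random_inits = n_random_inits,
                 max_outer_iters = max_outer_iters, rel_tol = rel_tol,
                 filter_maxit = filter_maxit,
                 train_stride = as.integer(train_stride), seed = seed),
            class = "fit_config")
}

#' Trial container for continuous current responses
#'
#' Holds the continuous recorded trace aligned to a stimulus. In the
#' contrast-switching protocol the unique segment of each cycle is seen once
#' (used for fitting) while the repeated segment recurs every cycle; the
#' response in each repeat window is one cross-validation trial.
#'
#' @param trace numeric vector, one sample per stimulus bin.
#' @param dt bin width in ms.
#' @return object of class \code{"trial_set"}.
#' @export
trial_set <- function(trace, dt = 1) {
  structure(list(trace = as.numeric(trace), dt = dt,
                 n_time = length(trace)), class = "trial_set")
}

#' Extract repeat-window trials
#'
#' @param stim the \code{stimulus} (provides repeat windows).
#' @param trials a \code{trial_set} (or numeric trace).
#' @param label contrast label of the windows to extract ("HC"/"LC"), or
#'   NULL for all.
#' @param trim_ms leading portion of each window to drop (default 200,
#'   one filter length): responses there carry over from the distinct
#'   unique segments preceding each repeat, so they differ across cycles
#'   even without noise.
#' @return numeric matrix, window bins x number of repeats.
#' @export
extract_repeats <- function(stim, trials, label = NULL, trim_ms = 200) {
  trace <- if (inherits(trials, "trial_set")) trials$trace else
    as.numeric(trials)
  rw <- stim$repeat_windows
  if (!is.null(label)) rw <- rw[rw$label == label, , drop = FALSE]
  if (nrow(rw) == 0) stop_invalid("no repeat windows with that label")
  cols <- lapply(seq_len(nrow(rw)), function(i) {
    i0 <- round((rw$start[i] + trim_ms) / stim$dt) + 1
    i1 <- round(rw$end[i] / stim$dt)
    trace[i0:i1]
  })
  len <- min(lengths(cols))
  sapply(cols, function(v) v[seq_len(len)])
}

response_trace <- function(response) {
  if (inherits(response, "trial_set")) response$trace else
    as.numeric(response)
}
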