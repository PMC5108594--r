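# MSE fitting of continuous synaptic-current models by block-coordinate
# descent: LN, DivS (multiplicative suppression), AddS (additive control)
# and the nonparametric 2-D nonlinearity model.
#
# Shared conventions: temporal filters live on the orthonormal basis and are
# renormalized to unit L2 after every filter update, with the scale folded
# exactly into the knot axis of the downstream nonlinearity (piecewise-linear
# functions rescale exactly, so predictions are unchanged). Models are fit on
# the unique stimulus segments (repeat windows held out) after discarding
# the filter-length burn-in.

# ---- shared internals ------------------------------------------------------

fit_prepare <- function(stim, response, cfg) {
  y <- response_trace(response)
  if (length(y) != stim$n_time)
    stop_invalid("response length does not match stimulus")
  basis <- temporal_basis(cfg$n_basis, cfg$t_max, cfg$dt)
  mask <- training_mask(stim, burn_in_bins = nrow(basis$matrix))
  mask <- mask & is.finite(y)
  if ((cfg$train_stride %||% 1L) > 1L)
    mask <- mask & (seq_along(mask) %% cfg$train_stride == 0L)
  if (stats::sd(stim$values[, 1]) == 0)
    stop_invalid("degenerate (constant) stimulus: singular design")
  G <- generator_design(basis, stim)
  list(y = y, basis = basis, mask = mask, G = G,
       nch = stim$n_channels)
}

# Ridge-stabilized linear filter estimate (response-weighted
# cross-correlation corrected by the stimulus covariance in basis space);
# the deterministic initialization for every model.
linear_filter_init <- function(G, y, mask, ridge = 1e-6) {
  Gm <- G[mask, , drop = FALSE]
  A <- crossprod(Gm) / sum(mask)
  b <- crossprod(Gm, y[mask] - mean(y[mask])) / sum(mask)
  a <- solve(A + ridge * mean(diag(A)) * diag(ncol(G)), b)
  as.numeric(a / sqrt(sum(a^2)))
}

random_filter_init <- function(n) {
  a <- stats::rnorm(n)
  a / sqrt(sum(a^2))
}

# Quasi-Newton update of one filter-coefficient block, minimizing the
# masked MSE with everything else held fixed. `resid_fun(g)` returns the
# residual (pred - y) and `weight_fun(g)` the pointwise d pred / d g.
# The generator signal and residual are memoized across the paired
# objective/gradient calls optim makes at the same point.
filter_block_update <- function(a, Gm, ym, resid_fun, weight_fun, maxit) {
  cache <- new.env(parent = emptyenv())
  state <- function(a) {
    if (is.null(cache$a) || !identical(cache$a, a)) {
      cache$a <- a
      cache$g <- as.numeric(Gm %*% a)
      cache$r <- resid_fun(cache$g)
    }
    cache
  }
  fn <- function(a) mean(state(a)$r^2)
  gr <- function(a) {
    st <- state(a)
    as.numeric(crossprod(Gm, 2 * st$r * weight_fun(st$g))) / length(st$g)
  }
  res <- stats::optim(a, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  res$par
}

mse_of <- function(pred, y, mask) mean((pred[mask] - y[mask])^2)

# cumulative-increment map: fe weights = Lmat %*% d with d >= 0 (d_1 = 0
# anchors fe at the leftmost knot), enforcing monotone increase.
increment_map <- function(K) {
  L <- matrix(0, K, K)
  L[lower.tri(L, diag = TRUE)] <- 1
  L[, 1] <- 0  # leftmost value fixed at 0
  L
}

monotone_weights_from <- function(w) {
  # project arbitrary knot values to the increment parameterization
  d <- c(0, pmax(diff(w), 0))
  cumsum(d)
}

# ---- LN model --------------------------------------------------------------

#' Fit the linear-nonlinear (LN) model of synaptic currents
#'
#' \eqn{c(t) = f[k \cdot s(t)] + c_0}: one temporal filter on the orthonormal
#' basis followed by an unconstrained piecewise-linear nonlinearity, fit by
#' alternating least-squares nonlinearity updates and quasi-Newton filter
#' updates until the training MSE converges. The constant offset is absorbed
#' into the nonlinearity (tent bases span constants).
#'
#' @param stim a \code{stimulus}.
#' @param response a \code{trial_set} or numeric trace at \code{cfg$dt}.
#' @param cfg a \code{\link{fit_config}}.
#' @return object of class \code{"ln_model"} with elements \code{filter},
#'   \code{nonlinearity}, \code{offset}, \code{mse_log}.
#' @export
fit_ln <- function(stim, response, cfg = fit_config()) {
  pp <- fit_prepare(stim, response, cfg)
  y <- pp$y; mask <- pp$mask; G <- pp$G
  Gm <- G[mask, , drop = FALSE]; ym <- y[mask]
  a <- linear_filter_init(G, y, mask)
  g <- as.numeric(Gm %*% a)
  nl <- nonlinearity(tent_basis(default_knots(g, cfg$n_knots)),
                     rep(0, cfg$n_knots), "none")
  mse_log <- numeric(0)
  best <- NULL
  for (it in seq_len(cfg$max_outer_iters)) {
    # nonlinearity block: unconstrained least squares at the current g
    Tm <- tent_eval(nl$basis, g)
    A <- crossprod(Tm); b <- crossprod(Tm, ym)
    nl$weights <- as.numeric(qp_box(A, as.numeric(b)))
    mse <- mse_of_vec(nl, g, ym)
    # filter block
    a_new <- filter_block_update(a, Gm, ym,
      resid_fun = function(gg) nl_eval(nl, gg) - ym,
      weight_fun = function(gg) nl_deriv(nl, gg),
      maxit = cfg$filter_maxit)
    alpha <- sqrt(sum(a_new^2))
    a_new <- a_new / alpha
    nl_new <- nl_rescale_x(nl, alpha)
    g_new <- as.numeric(Gm %*% a_new)
    mse_new <- mse_of_vec(nl_new, g_new, ym)
    a <- a_new; nl <- nl_new; g <- g_new
    if (is.null(best) || mse_new <= best$mse)
      best <- list(a = a, nl = nl, mse = mse_new)
    mse_log <- c(mse_log, best$mse)
    if (length(mse_log) > 2 &&
        mse_log[length(mse_log) - 2] - mse_log[length(mse_log)] <
          cfg$rel_tol * mse_log[1]) break
  }
  filt <- temporal_filter(matrix(best$a, ncol = pp$nch), pp$basis,
                          normalize = TRUE)
  structure(list(filter = filt, nonlinearity = best$nl, offset = 0,
                 mse_log = mse_log, cfg = cfg, kind = "ln"),
            class = "ln_model")
}

mse_of_vec <- function(nl, g, ym) mean((nl_eval(nl, g) - ym)^2)

# ---- DivS / AddS -----------------------------------------------------------

#' Fit the divisive suppression (DivS) model of synaptic currents
#'
#' \eqn{c(t) = f_e[k_e \cdot s(t)] \times f_s[k_s \cdot s(t)] + c_0}: an
#' excitatory LN unit (monotone-increasing nonlinearity, anchored at 0 at
#' its leftmost knot) multiplied by a suppressive LN unit whose gain is
#' bounded in [0, 1] with \eqn{f_s(0) = 1}, so suppression can only divide
#' the excitatory drive. Fit by block-coordinate descent (nonlinearity
#' blocks are constrained least squares; filter blocks are quasi-Newton),
#' best-of-restarts: one deterministic start initialized from the LN
#' solution with \eqn{f_s \equiv 1} (so DivS can never do worse than LN on
#' training data) plus \code{cfg$n_random_inits} seeded random suppressive
#' filters.
#'
#' @inheritParams fit_ln
#' @return object of class \code{"divs_model"} with elements \code{exc},
#'   \code{sup} (each \code{list(filter, nonlinearity)}), \code{offset},
#'   \code{mse_log}.
#' @export
fit_divs <- function(stim, response, cfg = fit_config()) {
  fit_divs_adds(stim, response, cfg, combine = "multiplicative")
}

#' Fit the additive suppression (AddS) control model
#'
#' As \code{\link{fit_divs}} but the suppressive term adds instead of
#' multiplies: \eqn{c(t) = f_e[k_e \cdot s(t)] + f_s[k_s \cdot s(t)] + c_0}
#' with \eqn{f_s \le 0} and \eqn{f_s(0) = 0}.
#'
#' @inheritParams fit_ln
#' @return object of class \code{"adds_model"}.
#' @export
fit_adds <- function(stim, response, cfg = fit_config()) {
  fit_divs_adds(stim, response, cfg, combine = "additive")
}

fit_divs_adds <- function(stim, response, cfg, combine) {
  pp <- fit_prepare(stim, response, cfg)
  y <- pp$y; mask <- pp$mask; G <- pp$G
  Gm <- G[mask, , drop = FALSE]; ym <- y[mask]
  a_lin <- linear_filter_init(G, y, mask)
  inits <- list(list(ae = a_lin, as = delay_init(a_lin, pp$basis, 10)))
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_random_inits))
      inits[[length(inits) + 1]] <-
        list(ae = a_lin, as = random_filter_init(length(a_lin)))
  })
  fits <- lapply(inits, function(ini)
    divs_descent(ini$ae, ini$as, Gm, ym, cfg, combine))
  best <- fits[[which.min(vapply(fits, function(f) f$mse, 0))]]
  exc_f <- temporal_filter(matrix(best$ae, ncol = pp$nch), pp$basis, TRUE)
  sup_f <- temporal_filter(matrix(best$as, ncol = pp$nch), pp$basis, TRUE)
  structure(list(exc = list(filter = exc_f, nonlinearity = best$fe),
                 sup = list(filter = sup_f, nonlinearity = best$fs),
                 offset = best$c0, mse_log = best$mse_log, cfg = cfg,
                 kind = if (combine == "multiplicative") "divs" else "adds"),
            class = if (combine == "multiplicative") "divs_model"
                    else "adds_model")
}

# initialize the suppressive filter as the excitatory one delayed by
# delay_ms (projected back onto the basis, which is an orthonormal map)
delay_init <- function(a, basis, delay_ms) {
  k <- as.numeric(basis$matrix %*% a)
  nd <- round(delay_ms / basis$dt)
  kd <- c(rep(0, nd), k[seq_len(length(k) - nd)])
  ad <- as.numeric(crossprod(basis$matrix, kd))
  ad / sqrt(sum(ad^2))
}

divs_descent <- function(ae, as_, Gm, ym, cfg, combine) {
  mult <- combine == "multiplicative"
  ge <- as.numeric(Gm %*% ae); gs <- as.numeric(Gm %*% as_)
  fe <- nonlinearity(tent_basis(default_knots(ge, cfg$n_knots)),
                     rep(0, cfg$n_knots), "monotone_increasing")
  kn_s <- default_knots(gs, cfg$n_knots)
  kn_s <- range_include_zero(kn_s)
  fs <- nonlinearity(tent_basis(kn_s),
                     rep(if (mult) 1 else 0, cfg$n_knots),
                     if (mult) "suppressive_unit" else "nonpositive")
  c0 <- 0
  Le <- increment_map(cfg$n_knots)
  mse_log <- numeric(0)
  best <- NULL
  state_mse <- function(fe, fs, c0, ge, gs) {
    pred <- if (mult) nl_eval(fe, ge) * nl_eval(fs, gs) + c0
            else nl_eval(fe, ge) + nl_eval(fs, gs) + c0
    mean((pred - ym)^2)
  }
  for (it in seq_len(cfg$max_outer_iters)) {
    fsv <- nl_eval(fs, gs)
    # excitatory nonlinearity: constrained LS over increments (>= 0) + c0
    Te <- tent_eval(fe$basis, ge)
    Xe <- if (mult) (Te * fsv) %*% Le[, -1] else Te %*% Le[, -1]
    X <- cbind(Xe, 1)
    A <- crossprod(X); b <- as.numeric(crossprod(X, ym))
    sol <- qp_box(A, b, lower = c(rep(0, ncol(Xe)), -Inf),
                  init = c(pmax(diff(fe$weights), 0), c0))
    fe$weights <- as.numeric(Le[, -1] %*% sol[seq_len(ncol(Xe))])
    c0 <- sol[length(sol)]
    fev <- nl_eval(fe, ge)
    # suppressive nonlinearity: box-constrained LS
    Ts <- tent_eval(fs$basis, gs)
    if (mult) {
      Xs <- Ts * fev
      A <- crossprod(Xs); b <- as.numeric(crossprod(Xs, ym - c0))
      w <- qp_box(A, b, lower = 0, upper = 1, init = fs$weights)
      v0 <- tent_interp(fs$basis, w, 0)
      if (v0 > 1e-3) {           # renormalize so fs(0) = 1, gain into fe
        w <- pmin(w / v0, 1)
        fe$weights <- fe$weights * v0
      }
      fs$weights <- w
    } else {
      Xs <- Ts
      A <- crossprod(Xs); b <- as.numeric(crossprod(Xs, ym - fev - c0))
      w <- qp_box(A, b, upper = 0, init = fs$weights)
      v0 <- tent_interp(fs$basis, w, 0)
      w <- pmin(w - v0, 0)       # anchor fs(0) = 0, shift into c0
      c0 <- c0 + v0
      fs$weights <- w
    }
    # filter blocks
    fsv <- nl_eval(fs, gs)
    ae <- filter_block_update(ae, Gm, ym,
      resid_fun = if (mult)
          function(g) nl_eval(fe, g) * fsv + c0 - ym
        else function(g) nl_eval(fe, g) + fsv + c0 - ym,
      weight_fun = if (mult)
          function(g) nl_deriv(fe, g) * fsv
        else function(g) nl_deriv(fe, g),
      maxit = cfg$filter_maxit)
    alpha <- sqrt(sum(ae^2)); ae <- ae / alpha
    fe <- nl_rescale_x(fe, alpha)
    ge <- as.numeric(Gm %*% ae)
    fev <- nl_eval(fe, ge)
    as_ <- filter_block_update(as_, Gm, ym,
      resid_fun = if (mult)
          function(g) fev * nl_eval(fs, g) + c0 - ym
        else function(g) fev + nl_eval(fs, g) + c0 - ym,
      weight_fun = if (mult)
          function(g) fev * nl_deriv(fs, g)
        else function(g) nl_deriv(fs, g),
      maxit = cfg$filter_maxit)
    alpha <- sqrt(sum(as_^2)); as_ <- as_ / alpha
    fs <- nl_rescale_x(fs, alpha)
    gs <- as.numeric(Gm %*% as_)
    mse <- state_mse(fe, fs, c0, ge, gs)
    if (is.null(best) || mse <= best$mse)
      best <- list(ae = ae, as_ = as_, fe = fe, fs = fs, c0 = c0, mse = mse)
    # log the best-so-far (returned-model) MSE; block updates are descent
    # steps up to the suppressive renormalization, which can blip upward
    mse_log <- c(mse_log, best$mse)
    if (length(mse_log) > 2 &&
        mse_log[length(mse_log) - 2] - mse_log[length(mse_log)] <
          cfg$rel_tol * mse_log[1]) break
  }
  list(ae = best$ae, as = best$as_, fe = best$fe, fs = best$fs,
       c0 = best$c0, mse = best$mse, mse_log = mse_log)
}

# shift the grid so it spans zero with a knot exactly at 0: the
# suppressive renormalization f_s(0) = 1 then lands on a knot and
# survives the [0, 1] clipping exactly
range_include_zero <- function(knots) {
  if (knots[1] > 0) knots <- knots - knots[1]
  if (knots[length(knots)] < 0) knots <- knots - knots[length(knots)]
  knots - knots[which.min(abs(knots))]
}
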