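# Point-process spiking models: Poisson likelihood with a fixed softplus
# spiking nonlinearity, spike-history (refractory) terms on a log-spaced
# bump basis, a linear-stimulus GLM (LN / LN+RP), and the spiking DivS
# extension in which the upstream subunit is a multiplicative pair of LN
# units.

#' Spike train container
#'
#' @param trials list of numeric vectors of spike times (ms), strictly
#'   increasing within each trial, in \code{[0, duration)}.
#' @param duration recording duration in ms.
#' @param dt_bin bin width used for fitting/evaluation (default 1 ms).
#' @return object of class \code{"spike_train_set"}.
#' @export
spike_train_set <- function(trials, duration, dt_bin = 1) {
  trials <- lapply(trials, as.numeric)
  for (tr in trials) {
    if (length(tr) && (any(tr < 0) || any(tr >= duration)))
      stop_invalid("spike times must lie in [0, duration)")
    if (any(diff(tr) <= 0)) stop_invalid("spike times must be increasing")
  }
  structure(list(trials = trials, duration = duration, dt_bin = dt_bin,
                 n_trials = length(trials)), class = "spike_train_set")
}

#' Bin spike times into counts
#'
#' @param spikes a \code{spike_train_set} (or numeric vector of times).
#' @param duration duration in ms (default from the set).
#' @param dt_bin bin width in ms.
#' @return integer matrix bins x trials (vector input gives one column).
#' @export
bin_spikes <- function(spikes, duration = NULL, dt_bin = NULL) {
  if (inherits(spikes, "spike_train_set")) {
    duration <- duration %||% spikes$duration
    dt_bin <- dt_bin %||% spikes$dt_bin
    trials <- spikes$trials
  } else trials <- list(as.numeric(spikes))
  n <- round(duration / dt_bin)
  sapply(trials, function(tt) {
    tabulate(pmin(floor(tt / dt_bin) + 1L, n), nbins = n)
  })
}

#' Poisson log-likelihood of binned spikes
#'
#' \eqn{LL = \sum_t [r_{obs}(t) \log r(t) - r(t)]} in nats, dropping the
#' data-only factorial term; \eqn{0 \log 0 = 0}; a zero rate with a nonzero
#' count gives \code{-Inf}.
#'
#' @param rate predicted rate per bin (spikes/bin), nonnegative.
#' @param counts observed counts per bin.
#' @return scalar log-likelihood (nats).
#' @export
poisson_ll <- function(rate, counts) {
  if (length(rate) != length(counts)) stop_invalid("length mismatch")
  pos <- counts > 0
  if (any(rate[pos] == 0)) return(-Inf)
  sum(counts[pos] * log(rate[pos])) - sum(rate)
}

#' Log-spaced bump basis for spike-history filters
#'
#' Raised-cosine bumps, equally spaced on a logarithmic lag axis, covering
#' 1 to \code{t_max_ms}; captures millisecond-scale absolute refractoriness
#' and slower (>15 ms) relative refractoriness with few coefficients. Lag 0
#' (the self-bin) is excluded.
#'
#' @param n_funcs number of bumps (default 8).
#' @param t_max_ms maximal lag (default 100).
#' @param dt bin width in ms.
#' @return list with \code{matrix} (lags x n_funcs; row 1 = lag 1 bin),
#'   \code{lags_ms}.
#' @export
history_basis <- function(n_funcs = 8, t_max_ms = 100, dt = 1) {
  lags <- seq(dt, t_max_ms, by = dt)
  phi <- function(t) log(t + 1)
  ctr <- seq(phi(dt), phi(t_max_ms), length.out = n_funcs)
  width <- 2 * diff(ctr[1:2])
  M <- sapply(ctr, function(c0) {
    d <- (phi(lags) - c0) / width
    ifelse(abs(d) < 0.5, 0.5 * (1 + cos(2 * pi * d)), 0)
  })
  list(matrix = matrix(M, nrow = length(lags)), lags_ms = lags,
       n_funcs = n_funcs)
}

history_design <- function(counts, hb) {
  sapply(seq_len(hb$n_funcs), function(j)
    history_conv_cpp(as.integer(counts), hb$matrix[, j]))
}

# rate per bin for a parameter state on precomputed designs
spk_rate <- function(g) pmax(softplus(g), 1e-12)

spk_ll_grad <- function(g, y) {
  # d LL / d g with rate = softplus(g)
  F <- spk_rate(g)
  Fp <- softplus_deriv(g)
  y * Fp / F - Fp
}

#' Fit a Poisson GLM spiking model (LN or LN+RP)
#'
#' Maximizes the Poisson log-likelihood of an inhomogeneous Poisson model
#' \eqn{r(t) = F_{spk}[k_{lin} \cdot s(t) + h_{spk} \cdot R(t) - \theta]}
#' with \eqn{F_{spk}[g] = \log(1 + e^g)} over the stimulus filter,
#' spike-history coefficients and threshold, by quasi-Newton ascent (the
#' problem is concave, so a single start suffices). The history term is
#' built from the observed spikes.
#'
#' @param stim a \code{stimulus}.
#' @param spikes a \code{spike_train_set} (trial 1 used for fitting).
#' @param cfg a \code{\link{fit_config}}.
#' @param with_history include the spike-history (refractory) term
#'   (default TRUE; FALSE gives the plain LN spiking model).
#' @return object of class \code{"spiking_model"}.
#' @export
fit_glm <- function(stim, spikes, cfg = fit_config(), with_history = TRUE) {
  pd <- spk_prepare(stim, spikes, cfg, with_history)
  nG <- ncol(pd$G); nH <- if (with_history) ncol(pd$H) else 0L
  pack_g <- function(th) {
    g <- as.numeric(pd$G %*% th[seq_len(nG)])
    if (nH) g <- g + as.numeric(pd$H %*% th[nG + seq_len(nH)])
    g - th[nG + nH + 1]
  }
  negll <- function(th) -poisson_ll(spk_rate(pack_g(th)[pd$mask]),
                                    pd$y[pd$mask])
  grad <- function(th) {
    g <- pack_g(th)
    dg <- numeric(length(g))
    dg[pd$mask] <- spk_ll_grad(g[pd$mask], pd$y[pd$mask])
    gr <- as.numeric(crossprod(pd$G, dg))
    if (nH) gr <- c(gr, as.numeric(crossprod(pd$H, dg)))
    -c(gr, -sum(dg))
  }
  th0 <- c(rep(0, nG + nH), -log(expm1(mean(pd$y[pd$mask]) + 1e-9)))
  res <- stats::optim(th0, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  th <- res$par
  filt <- temporal_filter(matrix(th[seq_len(nG)], ncol = pd$nch), pd$basis)
  hist <- if (with_history)
    spk_history(pd$hb, th[nG + seq_len(nH)]) else NULL
  structure(list(subunits = list(list(kind = "linear", filter = filt)),
                 history = hist, theta = th[nG + nH + 1],
                 ll_log = c(-res$value), cfg = cfg, kind = "glm",
                 train_ll = -res$value),
            class = "spiking_model")
}

spk_history <- function(hb, coeffs) {
  list(basis = hb, coeffs = coeffs,
       kernel = as.numeric(hb$matrix %*% coeffs))
}

spk_prepare <- function(stim, spikes, cfg, with_history) {
  basis <- temporal_basis(cfg$n_basis, cfg$t_max, cfg$dt)
  y <- bin_spikes(spikes, duration = stim$n_time * stim$dt,
                  dt_bin = cfg$dt)[, 1]
  if (sum(y) == 0) stop_invalid("no spikes in training data: degenerate fit")
  G <- generator_design(basis, stim)
  mask <- training_mask(stim, burn_in_bins = nrow(basis$matrix))
  hb <- history_basis(dt = cfg$dt)
  H <- if (with_history) history_design(y, hb) else NULL
  val_mask <- window_mask(stim, stim$repeat_windows)
  val_mask[seq_len(min(length(val_mask), nrow(basis$matrix)))] <- FALSE
  list(y = y, G = G, H = H, hb = hb, mask = mask, val_mask = val_mask,
       basis = basis, nch = stim$n_channels)
}

#' Fit the spiking DivS model
#'
#' Nonlinear-input point-process model whose upstream subunit is a DivS
#' pair: \eqn{r(t) = F_{spk}[f_e(k_e \cdot s) f_s(k_s \cdot s) + h_{spk}
#' \cdot R(t) - \theta]} with the same excitatory/suppressive constraints
#' as the current-based DivS model. Filters and nonlinearities are
#' alternately estimated (each nonlinearity/history/threshold block is a
#' concave constrained subproblem; filter blocks are quasi-Newton).
#' Initialized from the LN+RP (GLM) solution with \eqn{f_s \equiv 1}, so
#' the training likelihood can only improve on the GLM's.
#'
#' @inheritParams fit_glm
#' @return object of class \code{"spiking_model"} with a DivS subunit.
#' @export
fit_divs_spike <- function(stim, spikes, cfg = fit_config()) {
  pd <- spk_prepare(stim, spikes, cfg, TRUE)
  glm0 <- fit_glm(stim, spikes, cfg, with_history = TRUE)
  a0 <- as.numeric(glm0$subunits[[1]]$filter$coeffs)
  ae_glm <- a0 / sqrt(sum(a0^2))
  # Filter-pair starts come from the spike-triggered covariance analysis:
  # the top-2 eigenvectors of the covariance difference span the
  # excitatory/suppressive filter subspace, but the rotation within that
  # plane is not identified by covariance alone. Candidate pairs are
  # rotations (ae, as) of the eigenvector frame on a coarse angle grid
  # (the suppressive sign is immaterial under a symmetric f_s); each is
  # probed by one block pass and scored by simulated-PSTH likelihood on
  # the held-out repeats, then the winner is refined by the full damped
  # descent. Falls back to the GLM filter plus a delayed copy when the
  # covariance analysis is unavailable.
  cand <- list(list(ae = ae_glm, as_ = delay_init(ae_glm, pd$basis, 10)))
  stc <- tryCatch(
    response_weighted_moments(stim, pd$y, n_lags = nrow(pd$basis$matrix)),
    error = function(e) NULL)
  if (!is.null(stc)) {
    v1 <- as.numeric(crossprod(pd$basis$matrix, stc$eigenvectors[, 1]))
    v2 <- as.numeric(crossprod(pd$basis$matrix, stc$eigenvectors[, 2]))
    v1 <- v1 / sqrt(sum(v1^2))
    v2 <- v2 - v1 * sum(v1 * v2)
    v2 <- v2 / sqrt(sum(v2^2))
    for (phi in seq(0, 2 * pi, length.out = 9)[-9])
      cand[[length(cand) + 1]] <-
        list(ae = cos(phi) * v1 + sin(phi) * v2,
             as_ = -sin(phi) * v1 + cos(phi) * v2)
  }
  probe_cfg <- cfg
  probe_cfg$max_outer_iters <- 1L
  probes <- vapply(cand, function(cc)
    divs_spike_descent(cc$ae, cc$as_, glm0$history$coeffs, glm0$theta,
                       pd, probe_cfg, with_history = TRUE)$score, 0)
  best <- cand[[which.max(probes)]]
  fit <- divs_spike_descent(best$ae, best$as_, glm0$history$coeffs,
                            glm0$theta, pd, cfg, with_history = TRUE)
  build_divs_spiking(fit, pd, cfg, "divs_spike")
}

build_divs_spiking <- function(fit, pd, cfg, kind) {
  exc_f <- temporal_filter(matrix(fit$ae, ncol = pd$nch), pd$basis, TRUE)
  sup_f <- temporal_filter(matrix(fit$as, ncol = pd$nch), pd$basis, TRUE)
  hist <- if (!is.null(fit$h)) spk_history(pd$hb, fit$h) else NULL
  structure(list(subunits = list(list(kind = "divs",
                   exc = list(filter = exc_f, nonlinearity = fit$fe),
                   sup = list(filter = sup_f, nonlinearity = fit$fs))),
                 history = hist, theta = fit$theta, ll_log = fit$ll_log,
                 cfg = cfg, kind = kind, train_ll = fit$ll),
            class = "spiking_model")
}

# Block-coordinate ascent for the DivS subunit. When the stimulus has
# repeat windows they form a validation split and the returned state is
# the one with the best validation likelihood across outer iterations
# (early stopping): the subunit decomposition is flexible enough to
# overfit single recordings at ~5 spikes/s, and the protocol's own
# held-out segments are the standard guard.
divs_spike_descent <- function(ae, as_, h, theta, pd, cfg, with_history,
                               fe = NULL, fs = NULL, trace = FALSE) {
  trace_states <- if (trace) list() else NULL
  Gm <- pd$G[pd$mask, , drop = FALSE]
  Hm <- if (with_history) pd$H[pd$mask, , drop = FALSE] else NULL
  ym <- pd$y[pd$mask]
  has_val <- any(pd$val_mask)
  yv <- pd$y[pd$val_mask]
  # validation scores a model by how well the PSTH of spike trains
  # simulated with the model's own history (the cross-validation rule for
  # history models: observed spikes must not feed the prediction)
  # predicts the held-out repeat-window spikes
  val_score <- function(ae, as_, fe, fs, h, theta) {
    if (!has_val) return(NA_real_)
    z <- nl_eval(fe, as.numeric(pd$G %*% ae)) *
      nl_eval(fs, as.numeric(pd$G %*% as_))
    hk <- if (with_history) as.numeric(pd$hb$matrix %*% h) else numeric(0)
    counts <- with_seed(12345,
      simulate_spikes_cpp(z, hk, theta, 12L, 1e-12))
    psth <- pmax(rowMeans(counts), 1e-4)
    poisson_ll(psth[pd$val_mask], yv)
  }
  # angle cap (radians) on each filter block update: block-coordinate
  # steps on the weakly identified subunit are damped so a single outer
  # iteration cannot swing a filter into a different configuration
  cap_step <- function(old, new, cap = 0.26) {
    new <- new / sqrt(sum(new^2))
    cosang <- max(-1, min(1, sum(old * new)))
    ang <- acos(cosang)
    if (ang <= cap) return(new)
    # spherical interpolation toward the proposal
    t <- cap / ang
    v <- (sin((1 - t) * ang) * old + sin(t * ang) * new) / sin(ang)
    v / sqrt(sum(v^2))
  }
  ge <- as.numeric(Gm %*% ae); gs <- as.numeric(Gm %*% as_)
  if (is.null(fe))
    fe <- nonlinearity(tent_basis(default_knots(ge, cfg$n_knots)),
                       rep(0, cfg$n_knots), "monotone_increasing")
  if (is.null(fs))
    fs <- nonlinearity(tent_basis(range_include_zero(
                         default_knots(gs, cfg$n_knots))),
                       rep(1, cfg$n_knots), "suppressive_unit")
  Le <- increment_map(fe$basis$n)
  hterm <- if (with_history) as.numeric(Hm %*% h) else 0
  ll_of <- function(zeta) poisson_ll(spk_rate(zeta + hterm - theta), ym)
  ll_log <- numeric(0)
  best <- NULL
  for (it in seq_len(cfg$max_outer_iters)) {
    fsv <- nl_eval(fs, gs)
    # excitatory nonlinearity block, jointly with the threshold (the
    # anchored fe cannot absorb offsets, so theta must move with it);
    # concave in (increments, theta)
    Te <- tent_eval(fe$basis, ge)
    Xe <- (Te * fsv) %*% Le[, -1]
    p0 <- c(pmax(diff(fe$weights), 0), theta)
    np <- length(p0)
    sol <- stats::optim(p0,
      fn = function(p) -poisson_ll(
        spk_rate(as.numeric(Xe %*% p[-np]) + hterm - p[np]), ym),
      gr = function(p) {
        g <- as.numeric(Xe %*% p[-np]) + hterm - p[np]
        dg <- spk_ll_grad(g, ym)
        -c(as.numeric(crossprod(Xe, dg)), -sum(dg))
      },
      method = "L-BFGS-B", lower = c(rep(0, np - 1), -Inf),
      control = list(maxit = 60, factr = 1e5))$par
    fe$weights <- as.numeric(Le[, -1] %*% sol[-np])
    theta <- sol[np]
    fev <- nl_eval(fe, ge)
    # suppressive nonlinearity block (concave, box-constrained)
    Ts <- tent_eval(fs$basis, gs)
    Xs <- Ts * fev
    w <- stats::optim(fs$weights,
      fn = function(w) -ll_of(as.numeric(Xs %*% w)),
      gr = function(w) {
        g <- as.numeric(Xs %*% w) + hterm - theta
        -as.numeric(crossprod(Xs, spk_ll_grad(g, ym)))
      },
      method = "L-BFGS-B", lower = 0, upper = 1,
      control = list(maxit = 60, factr = 1e5))$par
    v0 <- tent_interp(fs$basis, w, 0)
    if (v0 > 1e-3) { w <- pmin(w / v0, 1); fe$weights <- fe$weights * v0 }
    fs$weights <- w
    fsv <- nl_eval(fs, gs)
    zeta <- fev * fsv
    # history + threshold block (concave, unconstrained)
    if (with_history) {
      ht0 <- c(h, theta)
      ht <- stats::optim(ht0,
        fn = function(p) -poisson_ll(
          spk_rate(zeta + as.numeric(Hm %*% p[-length(p)]) - p[length(p)]),
          ym),
        gr = function(p) {
          g <- zeta + as.numeric(Hm %*% p[-length(p)]) - p[length(p)]
          dg <- spk_ll_grad(g, ym)
          -c(as.numeric(crossprod(Hm, dg)), -sum(dg))
        },
        method = "BFGS", control = list(maxit = 100, reltol = 1e-10))$par
      h <- ht[-length(ht)]; theta <- ht[length(ht)]
      hterm <- as.numeric(Hm %*% h)
    } else {
      theta <- stats::optim(theta,
        fn = function(p) -poisson_ll(spk_rate(zeta - p), ym),
        gr = function(p) sum(spk_ll_grad(zeta - p, ym)),
        method = "BFGS", control = list(maxit = 50))$par
    }
    # filter blocks
    fsv <- nl_eval(fs, gs)
    ae_prop <- spk_filter_block(ae, Gm, ym, hterm, theta, cfg,
      val_fun = function(g) nl_eval(fe, g) * fsv,
      der_fun = function(g) nl_deriv(fe, g) * fsv)
    alpha <- sqrt(sum(ae_prop^2))
    ae <- cap_step(ae, ae_prop)
    fe <- nl_rescale_x(fe, alpha)
    ge <- as.numeric(Gm %*% ae)
    fev <- nl_eval(fe, ge)
    as_prop <- spk_filter_block(as_, Gm, ym, hterm, theta, cfg,
      val_fun = function(g) fev * nl_eval(fs, g),
      der_fun = function(g) fev * nl_deriv(fs, g))
    alpha <- sqrt(sum(as_prop^2))
    as_ <- cap_step(as_, as_prop)
    fs <- nl_rescale_x(fs, alpha)
    gs <- as.numeric(Gm %*% as_)
    ll <- poisson_ll(spk_rate(nl_eval(fe, ge) * nl_eval(fs, gs) +
                              hterm - theta), ym)
    # the full fit guards against kernel drift with validation-based
    # selection; the history-free refit optimizes training likelihood
    # directly (it starts at the full model's subunit)
    score <- if (has_val && with_history)
      val_score(ae, as_, fe, fs, h, theta) else ll
    if (trace)
      trace_states[[it]] <- list(ae = ae, as_ = as_, ll = ll,
                                 score = score)
    if (is.null(best) || score >= best$score)
      best <- list(ae = ae, as = as_, fe = fe, fs = fs, h = if (with_history)
        h else NULL, theta = theta, ll = ll, score = score)
    ll_log <- c(ll_log, best$ll)
    if (length(ll_log) > 2 &&
        ll_log[length(ll_log)] - ll_log[length(ll_log) - 2] <
          cfg$rel_tol * abs(ll_log[1])) break
  }
  best$ll_log <- ll_log
  if (trace) best$trace <- trace_states
  best
}

spk_filter_block <- function(a, Gm, ym, hterm, theta, cfg, val_fun, der_fun) {
  cache <- new.env(parent = emptyenv())
  state <- function(a) {
    if (is.null(cache$a) || !identical(cache$a, a)) {
      cache$a <- a
      cache$g <- as.numeric(Gm %*% a)
      cache$z <- val_fun(cache$g) + hterm - theta
    }
    cache
  }
  stats::optim(a,
    fn = function(a) -poisson_ll(spk_rate(state(a)$z), ym),
    gr = function(a) {
      st <- state(a)
      dg <- spk_ll_grad(st$z, ym) * der_fun(st$g)
      -as.numeric(crossprod(Gm, dg))
    },
    method = "BFGS",
    control = list(maxit = cfg$filter_maxit, reltol = 1e-9))$par
}

#' Refit a spiking model without its spike-history term
#'
#' Removes the refractory term and re-optimizes the remaining parameters
#' starting from the full model's solution (the DivS-RP construction: same
#' stimulus processing family, no spike-history).
#'
#' @param model a fitted \code{spiking_model} with a history term.
#' @inheritParams fit_glm
#' @return a \code{spiking_model} with \code{history = NULL}.
#' @export
refit_without_history <- function(model, stim, spikes, cfg = model$cfg) {
  if (is.null(model$history)) stop_invalid("model has no history term")
  pd <- spk_prepare(stim, spikes, cfg, FALSE)
  su <- model$subunits[[1]]
  if (su$kind == "linear") {
    return(fit_glm(stim, spikes, cfg, with_history = FALSE))
  }
  fit <- divs_spike_descent(as.numeric(su$exc$filter$coeffs),
                            as.numeric(su$sup$filter$coeffs),
                            NULL, model$theta, pd, cfg,
                            with_history = FALSE,
                            fe = su$exc$nonlinearity,
                            fs = su$sup$nonlinearity)
  build_divs_spiking(fit, pd, cfg, "divs_rp")
}

# deterministic stimulus-driven part of g (excluding history and theta)
spiking_drive <- function(model, stim) {
  z <- 0
  for (su in model$subunits) {
    if (su$kind == "linear") {
      z <- z + apply_filter(su$filter, stim)
    } else {
      ge <- apply_filter(su$exc$filter, stim)
      gs <- apply_filter(su$sup$filter, stim)
      z <- z + nl_eval(su$exc$nonlinearity, ge) *
        nl_eval(su$sup$nonlinearity, gs)
    }
  }
  as.numeric(z)
}

#' Predicted firing rate using observed spike history
#'
#' @param model a \code{spiking_model}.
#' @param stim the stimulus.
#' @param spikes observed spikes supplying the history term (required when
#'   the model has one).
#' @return rate per bin (spikes/bin).
#' @export
predict_rate <- function(model, stim, spikes = NULL) {
  g <- spiking_drive(model, stim) - model$theta
  if (!is.null(model$history)) {
    if (is.null(spikes))
      stop_invalid("observed spikes required for the history term")
    y <- bin_spikes(spikes, duration = stim$n_time * stim$dt,
                    dt_bin = stim$dt)[, 1]
    g <- g + as.numeric(history_conv_cpp(as.integer(y),
                                         model$history$kernel))
  }
  spk_rate(g)
}

#' Log-likelihood of a spiking model on data
#'
#' Poisson log-likelihood per bin using the observed spike train for the
#' history term; restricted to \code{mask} when given.
#'
#' @param model a \code{spiking_model}.
#' @param stim the stimulus.
#' @param spikes a \code{spike_train_set} (trial 1 evaluated).
#' @param mask logical vector of bins to include (default: all after
#'   burn-in).
#' @return list with \code{ll} (nats) and \code{ll_per_spike}.
#' @export
model_ll <- function(model, stim, spikes, mask = NULL) {
  y <- bin_spikes(spikes, duration = stim$n_time * stim$dt,
                  dt_bin = stim$dt)[, 1]
  r <- predict_rate(model, stim, spikes)
  if (is.null(mask)) {
    mask <- rep(TRUE, length(y))
    mask[seq_len(min(length(y), 200))] <- FALSE
  }
  ll <- poisson_ll(r[mask], y[mask])
  list(ll = ll, ll_per_spike = ll / max(1, sum(y[mask])))
}

#' Simulate spike trains from a spiking model
#'
#' Per 1-ms bin, draws a Poisson count from the instantaneous rate computed
#' causally from the simulated train's own history. Deterministic given the
#' seed.
#'
#' @param model a \code{spiking_model}.
#' @param stim the stimulus to simulate on.
#' @param n_repeats number of independent repeats (default 500).
#' @param seed RNG seed.
#' @return list with \code{spikes} (a \code{spike_train_set}),
#'   \code{counts} (bins x repeats), \code{psth} (mean spikes/bin),
#'   \code{dt}.
#' @export
simulate_spikes <- function(model, stim, n_repeats = 500, seed = 1) {
  gstim <- spiking_drive(model, stim)
  hkern <- if (!is.null(model$history)) model$history$kernel else numeric(0)
  counts <- with_seed(seed,
    simulate_spikes_cpp(gstim, hkern, model$theta, n_repeats, 1e-12))
  dt <- stim$dt
  trials <- lapply(seq_len(n_repeats), function(r) {
    idx <- which(counts[, r] > 0)
    cnt <- counts[idx, r]
    # multiple events in one bin are spread evenly within the bin so spike
    # times stay strictly increasing
    unlist(lapply(seq_along(idx), function(i)
      (idx[i] - 1) * dt + (seq_len(cnt[i]) - 0.5) * dt / cnt[i]),
      use.names = FALSE) %||% numeric(0)
  })
  list(spikes = spike_train_set(trials, duration = stim$n_time * dt,
                                dt_bin = dt),
       counts = counts, psth = rowMeans(counts), dt = dt)
}

#' @export
print.spiking_model <- function(x, ...) {
  cat(sprintf("Spiking model (%s): %d subunit(s), %s spike-history, theta = %.3f\n",
              x$kind, length(x$subunits),
              if (is.null(x$history)) "no" else "with", x$theta))
  cat(sprintf("  training LL %.2f nats\n", x$train_ll))
  invisible(x)
}
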