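# Linear-Nonlinear-Kinetic (LNK) model: an LN front end drives the R -> A
# transition of a three-state kinetic chain (resting R, active A,
# inactivated I); the output current is proportional to active-state
# occupancy. Emulates synaptic vesicle depletion (depression). The slow
# fourth state of the original formulation is omitted.

#' Construct an LNK model
#'
#' The stimulus is filtered (\code{filter}), passed through a monotone
#' nonnegative input nonlinearity with maximum 1 (\code{input_nl}), and
#' scaled by \code{u_max} to give the R-to-A transition rate
#' \eqn{u(t) = u_{max} f[k \cdot s(t)]} in 1/s. A-to-I (\code{k_ai}) and
#' I-to-R (\code{k_ir}) rates are constant. Output:
#' \eqn{c(t) = gain \cdot A(t) + offset}.
#'
#' Fixing the input nonlinearity's maximum at 1 resolves the degeneracy
#' under joint rescaling of the drive and the rate constants.
#'
#' @param filter a \code{temporal_filter} (1 or 2 channels).
#' @param input_nl a monotone \code{nonlinearity} with values in [0, 1].
#' @param u_max maximal R-to-A rate (1/s).
#' @param k_ai A-to-I rate (1/s).
#' @param k_ir I-to-R recovery rate (1/s).
#' @param gain,offset output scaling.
#' @return object of class \code{"lnk_model"}.
#' @export
lnk_model <- function(filter, input_nl, u_max, k_ai, k_ir,
                      gain = 1, offset = 0) {
  if (u_max < 0 || k_ai < 0 || k_ir < 0)
    stop_invalid("rates must be nonnegative")
  structure(list(filter = filter, input_nl = input_nl, u_max = u_max,
                 k_ai = k_ai, k_ir = k_ir, gain = gain, offset = offset,
                 kind = "lnk"),
            class = "lnk_model")
}

#' Simulate an LNK model
#'
#' Propagates the three-state kinetics under the stimulus-driven input rate
#' with a trapezoidal discretization of the master equation, which
#' conserves \eqn{R + A + I = 1} exactly and has the continuous-time steady
#' state as its exact fixed point. Occupancies start from the steady state
#' of the initial drive.
#'
#' @param model an \code{lnk_model}.
#' @param stim a \code{stimulus}.
#' @param dt integration step in ms (default: the stimulus dt).
#' @return list with \code{current} (numeric, \code{gain * A + offset}),
#'   \code{states} (matrix time x 3, columns R/A/I), \code{drive} (u(t),
#'   1/s).
#' @export
simulate_lnk <- function(model, stim, dt = stim$dt) {
  g <- apply_filter(model$filter, stim)
  u <- model$u_max * pmax(nl_eval(model$input_nl, g), 0)
  check_lnk_stability(max(u), model$k_ai, model$k_ir, dt)
  init <- lnk_steady_state(u[1], model$k_ai, model$k_ir)
  states <- lnk_propagate_cpp(u, model$k_ai, model$k_ir, dt / 1000, init)
  colnames(states) <- c("R", "A", "I")
  current <- model$gain * states[, "A"] + model$offset
  attr(current, "burn_in") <- attr(g, "burn_in")
  list(current = current, states = states, drive = u)
}

check_lnk_stability <- function(u_max, k_ai, k_ir, dt) {
  p <- max(u_max, k_ai, k_ir) * dt / 1000
  if (p >= 0.2)
    stop_invalid(sprintf(
      "step size too coarse: per-bin transition probability %.2f >= 0.2", p))
}

#' Steady-state occupancies of the three-state chain
#'
#' Closed form for constant drive \eqn{u}: flows balance around the cycle
#' R -> A -> I -> R.
#'
#' @param u R-to-A rate (1/s).
#' @param k_ai,k_ir the constant rates (1/s).
#' @return named vector (R, A, I) summing to 1.
#' @export
lnk_steady_state <- function(u, k_ai, k_ir) {
  z <- u * k_ir + u * k_ai + k_ai * k_ir
  if (z == 0) return(c(R = 1, A = 0, I = 0))
  c(R = k_ai * k_ir / z, A = u * k_ir / z, I = u * k_ai / z)
}

#' @export
predict_current.lnk_model <- function(model, stim) {
  simulate_lnk(model, stim)$current
}

#' Fit an LNK model by constrained optimization
#'
#' Minimizes the MSE between the simulated output and the observed current
#' over filter coefficients, input-nonlinearity shape (monotone via
#' log-increments, maximum fixed at 1), and log rate constants; output gain
#' and offset are profiled out by linear regression at every objective
#' evaluation. Multi-start quasi-Newton with numerical gradients.
#'
#' @inheritParams fit_ln
#' @param n_nl_knots knots of the input nonlinearity (default 9).
#' @param n_starts random restarts around the deterministic start
#'   (default 2).
#' @param maxit quasi-Newton iteration cap per optimization stage.
#' @return an \code{lnk_model} with attributes \code{mse_log} (best
#'   objective per start) and \code{train_mse}.
#' @export
fit_lnk <- function(stim, response, cfg = fit_config(), n_nl_knots = 9,
                    n_starts = 2, maxit = 200) {
  pp <- fit_prepare(stim, response, cfg)
  y <- pp$y; mask <- pp$mask; G <- pp$G
  a0 <- linear_filter_init(G, y, mask)
  # kinetics carry state across time, so the simulation always runs on the
  # full continuous timeline; only the residuals are masked
  g0 <- as.numeric(G %*% a0)
  knots <- default_knots(g0[mask], n_nl_knots)
  Knl <- n_nl_knots
  dt <- stim$dt
  na <- length(a0)
  unpack <- function(th) {
    a <- th[seq_len(na)]
    a <- a / sqrt(sum(a^2))
    d <- exp(th[na + seq_len(Knl - 1)])
    w <- cumsum(c(0, d)); w <- w / w[Knl]
    list(a = a, w = w,
         u_max = exp(th[na + Knl]),
         k_ai = exp(th[na + Knl + 1]),
         k_ir = exp(th[na + Knl + 2]))
  }
  tb <- tent_basis(knots)
  ym <- y[mask]
  sim_mse <- function(u, k_ai, k_ir) {
    st <- lnk_propagate_cpp(u, k_ai, k_ir, dt / 1000,
                            lnk_steady_state(u[1], k_ai, k_ir))
    fit <- stats::lm.fit(cbind(1, st[mask, 2]), ym)
    mean(fit$residuals^2)
  }
  objective <- function(th) {
    p <- unpack(th)
    g <- as.numeric(G %*% p$a)
    sim_mse(p$u_max * tent_interp(tb, p$w, g), p$k_ai, p$k_ir)
  }
  # filter-fixed objective reuses the precomputed generator signal, which
  # makes the first (nonlinearity + rates) stage cheap
  obj_fixed_g <- function(v, gsig) {
    d <- exp(v[seq_len(Knl - 1)])
    w <- cumsum(c(0, d)); w <- w / w[Knl]
    sim_mse(exp(v[Knl]) * tent_interp(tb, w, gsig),
            exp(v[Knl + 1]), exp(v[Knl + 2]))
  }
  ramp0 <- log(pmax(diff(pmax(knots, 0)) + 1e-4, 1e-4))
  rate_max <- 0.18 * 1000 / dt      # keep inside the stability region
  lower <- c(rep(-Inf, na), rep(-12, Knl - 1), rep(log(0.5), 3))
  upper <- c(rep(Inf, na), rep(5, Knl - 1), rep(log(rate_max), 3))
  starts <- list(c(log(50), log(30), log(20)))
  with_seed(cfg$seed, {
    for (i in seq_len(n_starts))
      starts[[i + 1]] <- starts[[1]] + stats::rnorm(3, 0, 0.7)
  })
  stage1 <- lapply(starts, function(r0) {
    v0 <- c(ramp0, r0)
    res <- stats::optim(v0, obj_fixed_g, gsig = g0, method = "L-BFGS-B",
                        lower = lower[na + seq_len(Knl + 2)],
                        upper = upper[na + seq_len(Knl + 2)],
                        control = list(maxit = maxit, factr = 1e7))
    res
  })
  best1 <- stage1[[which.min(vapply(stage1, function(f) f$value, 0))]]
  th <- c(a0, best1$par)
  res2 <- stats::optim(th, objective, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = maxit, factr = 1e7))
  vals <- c(vapply(stage1, function(f) f$value, 0), res2$value)
  bestf <- list(th = res2$par, value = res2$value)
  p <- unpack(bestf$th)
  g <- as.numeric(G %*% p$a)
  u <- p$u_max * tent_interp(tb, p$w, g)
  st <- lnk_propagate_cpp(u, p$k_ai, p$k_ir, dt / 1000,
                          lnk_steady_state(u[1], p$k_ai, p$k_ir))
  co <- stats::lm.fit(cbind(1, st[mask, 2]), ym)$coefficients
  filt <- temporal_filter(matrix(p$a, ncol = pp$nch), pp$basis, TRUE)
  nl <- nonlinearity(tb, p$w, "monotone_increasing")
  out <- lnk_model(filt, nl, p$u_max, p$k_ai, p$k_ir,
                   gain = co[2], offset = co[1])
  attr(out, "train_mse") <- bestf$value
  attr(out, "mse_log") <- sort(vals, decreasing = TRUE)
  out
}

#' Simulate extended two-channel LNK variants
#'
#' Spot/annulus extension in which center and surround drives are each
#' rectified before entering the kinetics. The \code{shared_depression}
#' variant feeds the weighted sum of rectified channel drives into a single
#' kinetic stage; \code{independent_depression} runs one kinetic stage per
#' channel (same rate constants) and sums the weighted outputs.
#'
#' @param variant \code{"shared_depression"} or
#'   \code{"independent_depression"}.
#' @param components list, one per channel, each
#'   \code{list(filter = <single-channel temporal_filter>, weight = w,
#'   rectifier = function)} (rectifier defaults to \code{max(0, x)}; drive
#'   in 1/s).
#' @param k_ai,k_ir kinetic rates (1/s).
#' @param stim two-channel \code{stimulus}.
#' @param gain,offset output scaling of each active-state occupancy.
#' @param dt integration step in ms.
#' @return list with \code{current} and \code{states} (list of stage
#'   trajectories).
#' @export
extended_lnk_simulate <- function(variant = c("shared_depression",
                                              "independent_depression"),
                                  components, k_ai, k_ir, stim,
                                  gain = 1, offset = 0, dt = stim$dt) {
  variant <- match.arg(variant)
  if (stim$n_channels < length(components))
    stop_invalid("stimulus must provide one channel per component")
  drives <- lapply(seq_along(components), function(i) {
    cmp <- components[[i]]
    if (is.null(cmp$weight) || cmp$weight < 0)
      stop_invalid("component weights must be nonnegative")
    ch_stim <- stimulus(stim$values[, i, drop = FALSE], stim$dt,
                        stim$mean_level)
    g <- apply_filter(cmp$filter, ch_stim)
    rect <- cmp$rectifier %||% function(x) pmax(x, 0)
    cmp$weight * rect(g)
  })
  if (variant == "shared_depression") {
    u <- Reduce(`+`, drives)
    check_lnk_stability(max(u), k_ai, k_ir, dt)
    st <- lnk_propagate_cpp(u, k_ai, k_ir, dt / 1000,
                            lnk_steady_state(u[1], k_ai, k_ir))
    colnames(st) <- c("R", "A", "I")
    list(current = gain * st[, "A"] + offset, states = list(st))
  } else {
    sts <- lapply(drives, function(u) {
      check_lnk_stability(max(u), k_ai, k_ir, dt)
      st <- lnk_propagate_cpp(u, k_ai, k_ir, dt / 1000,
                              lnk_steady_state(u[1], k_ai, k_ir))
      colnames(st) <- c("R", "A", "I")
      st
    })
    cur <- offset + gain * Reduce(`+`, lapply(sts, function(s) s[, "A"]))
    list(current = cur, states = sts)
  }
}
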