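# Ground-truth generators and the parameter-recovery harness. Canonical
# parameter shapes emulate the qualitative structure of ON-Alpha ganglion
# cell inputs -- a sharp biphasic excitatory kernel, a U-shaped (ON-OFF)
# suppressive gain delayed by ~10 ms, millisecond-scale absolute plus
# slower relative refractoriness -- but the values are generator choices,
# not fits to recorded data.

# canonical scale of the generator signal under the high-contrast protocol
# (SD of a unit-norm kernel's output; see vignette)
.sigma_hc <- 1.2

gamma_kernel <- function(t, n, tau) (t / tau)^n * exp(n * (1 - t / tau))

canonical_kernels <- function(basis, delay_ms = 10) {
  tt <- basis$times
  k <- gamma_kernel(tt, 6, 45) - 0.55 * gamma_kernel(tt, 6, 80)
  k <- k / sqrt(sum(k^2))
  nd <- round(delay_ms / basis$dt)
  ks <- c(rep(0, nd), k[seq_len(length(k) - nd)])
  ks <- ks / sqrt(sum(ks^2))
  ae <- as.numeric(crossprod(basis$matrix, k))
  as_ <- as.numeric(crossprod(basis$matrix, ks))
  list(ae = ae / sqrt(sum(ae^2)), as = as_ / sqrt(sum(as_^2)))
}

canonical_fe <- function(gain = 1, slope = 1.5, n_knots = 41,
                         span = 5 * .sigma_hc) {
  kn <- seq(-span, span, length.out = n_knots)
  w <- gain * softplus(slope * kn)
  w <- w - w[1]                        # anchored at the leftmost knot
  nonlinearity(tent_basis(kn), w, "monotone_increasing")
}

canonical_fs <- function(width = 0.8, n_knots = 41, span = 5 * .sigma_hc) {
  kn <- seq(-span, span, length.out = n_knots)
  kn <- kn - kn[which.min(abs(kn))]    # a knot exactly at 0 so fs(0) = 1
  w <- 1 / (1 + (kn / width)^2)
  nonlinearity(tent_basis(kn), w, "suppressive_unit")
}

canonical_history_kernel <- function(t_max_ms = 100) {
  lags <- seq_len(t_max_ms)
  h <- -2.5 * exp(-(lags - 2) / 15)
  h[lags <= 2] <- -8                   # absolute refractory period
  h
}

#' Construct a canonical ground-truth model
#'
#' Deterministic given \code{seed}; all DivS/monotonicity constraints hold
#' by construction. Parameter shapes (sharp biphasic kernel peaking at
#' ~41 ms, suppressive kernel delayed 10 ms, U-shaped suppressive gain,
#' 2-ms absolute plus ~15-ms relative refractoriness) are chosen to emulate
#' reported qualitative structure; see the methods vignette.
#'
#' @param kind one of \code{"ln"}, \code{"divs"}, \code{"adds"},
#'   \code{"lnk"}, \code{"glm"}, \code{"divs_spike"}.
#' @param overrides named list replacing canonical parameters
#'   (\code{delay_ms}, \code{fe_gain}, \code{fs_width}, \code{u_max},
#'   \code{k_ai}, \code{k_ir}, \code{theta}, \code{spk_gain},
#'   \code{n_basis}, \code{t_max}, \code{dt}).
#' @param seed RNG seed (reserved; canonical construction is
#'   deterministic).
#' @return a fitted-model-classed object usable with
#'   \code{\link{predict_current}} / \code{\link{simulate_spikes}}.
#' @export
make_ground_truth <- function(kind = c("ln", "divs", "adds", "lnk", "glm",
                                       "divs_spike"),
                              overrides = list(), seed = 1) {
  kind <- match.arg(kind)
  par <- utils::modifyList(list(
    n_basis = 12, t_max = 200, dt = 1, delay_ms = 10,
    fe_gain = 1, fe_slope = 1.5, fs_width = 0.8,
    u_max = 80, k_ai = 50, k_ir = 15, lnk_gain = 3, lnk_offset = 0,
    spk_gain = 0.5, theta = 6, hist_scale = 1), overrides)
  basis <- temporal_basis(par$n_basis, par$t_max, par$dt)
  kk <- canonical_kernels(basis, par$delay_ms)
  fE <- temporal_filter(kk$ae, basis, TRUE)
  fS <- temporal_filter(kk$as, basis, TRUE)
  fe <- canonical_fe(par$fe_gain, par$fe_slope)
  fs <- canonical_fs(par$fs_width)
  model <- switch(kind,
    ln = structure(list(filter = fE, nonlinearity = fe, offset = 0,
                        mse_log = numeric(0), kind = "ln"),
                   class = "ln_model"),
    divs = structure(list(exc = list(filter = fE, nonlinearity = fe),
                          sup = list(filter = fS, nonlinearity = fs),
                          offset = 0, mse_log = numeric(0), kind = "divs"),
                     class = "divs_model"),
    adds = {
      kn <- fs$basis$knots
      fsa <- nonlinearity(fs$basis,
                          -par$fe_gain * 0.5 * (1 - fs$weights),
                          "nonpositive")
      structure(list(exc = list(filter = fE, nonlinearity = fe),
                     sup = list(filter = fS, nonlinearity = fsa),
                     offset = 0, mse_log = numeric(0), kind = "adds"),
                class = "adds_model")
    },
    lnk = {
      kn <- seq(-5 * .sigma_hc, 5 * .sigma_hc, length.out = 41)
      w <- pmin(pmax(kn / (2 * .sigma_hc), 0), 1)   # saturating rectifier
      inl <- nonlinearity(tent_basis(kn), w, "monotone_increasing")
      lnk_model(fE, inl, par$u_max, par$k_ai, par$k_ir,
                gain = par$lnk_gain, offset = par$lnk_offset)
    },
    glm = {
      hk <- par$hist_scale * canonical_history_kernel()
      structure(list(subunits = list(list(kind = "linear",
                       filter = temporal_filter(par$spk_gain * 4 * kk$ae,
                                                basis))),
                     history = list(basis = NULL, coeffs = NULL,
                                    kernel = hk),
                     theta = par$theta, ll_log = numeric(0), kind = "glm",
                     train_ll = NA_real_),
                class = "spiking_model")
    },
    divs_spike = {
      fes <- fe
      fes$weights <- par$spk_gain * 3 * fes$weights
      hk <- par$hist_scale * canonical_history_kernel()
      structure(list(subunits = list(list(kind = "divs",
                       exc = list(filter = fE, nonlinearity = fes),
                       sup = list(filter = fS, nonlinearity = fs))),
                     history = list(basis = NULL, coeffs = NULL,
                                    kernel = hk),
                     theta = par$theta, ll_log = numeric(0),
                     kind = "divs_spike", train_ll = NA_real_),
                class = "spiking_model")
    })
  attr(model, "ground_truth") <- par
  model
}

#' Generate a synthetic recording from a ground-truth model
#'
#' Continuous models produce a single continuous current trace: the model
#' prediction plus iid Gaussian noise whose variance is set so that
#' Var(signal)/Var(noise) on the repeat windows equals \code{snr}. Spiking
#' models produce \code{n_trials} independent spike trains over the full
#' stimulus (trial 1 is the fitting trial; repeat-window spikes of all
#' trials serve validation).
#'
#' @param model a ground-truth (or fitted) model.
#' @param stim a \code{stimulus}; default: the high/low contrast-switching
#'   protocol with \code{n_cycles} cycles per contrast.
#' @param n_trials repeats for validation (currents: trials arise from the
#'   repeat windows of the protocol itself; spikes: independent trains).
#' @param snr signal-to-noise variance ratio on repeat windows (currents;
#'   Inf for noiseless).
#' @param seed RNG seed.
#' @param n_cycles protocol cycles per contrast for the default stimulus.
#' @return object of class \code{"recording"}: list with \code{stim},
#'   \code{currents} (a \code{trial_set} or NULL), \code{spikes} (a
#'   \code{spike_train_set} or NULL), \code{signal} (noiseless trace or
#'   PSTH), \code{meta}.
#' @export
generate_recording <- function(model, stim = NULL, n_trials = 10, snr = 10,
                               seed = 1, n_cycles = 4) {
  if (is.null(stim))
    stim <- contrast_switching_stimulus(n_cycles = n_cycles, seed = seed)
  spiking <- inherits(model, "spiking_model")
  if (spiking) {
    sim <- simulate_spikes(model, stim, n_repeats = n_trials, seed = seed)
    rec <- list(stim = stim, currents = NULL, spikes = sim$spikes,
                signal = sim$psth,
                meta = list(seed = seed, kind = model$kind,
                            n_trials = n_trials))
  } else {
    sig <- as.numeric(predict_current(model, stim))
    rep_mask <- window_mask(stim, stim$repeat_windows)
    noise_sd <- if (is.finite(snr))
      stats::sd(sig[rep_mask]) / sqrt(snr) else 0
    trace <- sig + with_seed(seed, stats::rnorm(length(sig), 0, noise_sd))
    rec <- list(stim = stim, currents = trial_set(trace, stim$dt),
                spikes = NULL, signal = sig,
                meta = list(seed = seed, snr = snr, noise_sd = noise_sd,
                            kind = model$kind, n_trials = n_trials))
  }
  structure(rec, class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Synthetic recording (%s ground truth): %s\n",
              x$meta$kind,
              if (is.null(x$spikes)) "continuous current" else
                sprintf("%d spike trains", x$spikes$n_trials)))
  print(x$stim)
  invisible(x)
}

model_kernels <- function(model) {
  if (inherits(model, c("divs_model", "adds_model")))
    return(list(exc = filter_kernel(model$exc$filter)[, 1],
                sup = filter_kernel(model$sup$filter)[, 1]))
  if (inherits(model, "ln_model"))
    return(list(exc = filter_kernel(model$filter)[, 1]))
  if (inherits(model, "lnk_model"))
    return(list(exc = filter_kernel(model$filter)[, 1]))
  if (inherits(model, "spiking_model")) {
    su <- model$subunits[[1]]
    if (su$kind == "linear")
      return(list(exc = filter_kernel(su$filter)[, 1]))
    return(list(exc = filter_kernel(su$exc$filter)[, 1],
                sup = filter_kernel(su$sup$filter)[, 1]))
  }
  stop_invalid("unsupported model kind")
}

#' Parameter-recovery report
#'
#' Compares a fitted model against the generating ground truth: kernel
#' cosine similarities (after sign canonicalization), peak-lag errors, the
#' excitatory-to-suppressive delay error where both models have a
#' suppressive filter, and rate-constant relative errors for LNK models.
#'
#' @param true_model,fitted_model models of the same (or nested) kind.
#' @param dt kernel sampling in ms.
#' @return list with per-kernel \code{cosine}, \code{peak_lag_error_ms},
#'   and (when applicable) \code{delay_error_ms}, \code{rate_rel_error}.
#' @export
recovery_report <- function(true_model, fitted_model, dt = 1) {
  kt <- model_kernels(true_model)
  kf <- model_kernels(fitted_model)
  common <- intersect(names(kt), names(kf))
  if (length(common) == 0) stop_invalid("incompatible model kinds")
  cosine <- sapply(common, function(nm) cosine_sim(kt[[nm]], kf[[nm]]))
  peak_err <- sapply(common, function(nm)
    peak_lag_ms(kf[[nm]], dt) - peak_lag_ms(kt[[nm]], dt))
  out <- list(cosine = cosine, peak_lag_error_ms = peak_err)
  if (all(c("exc", "sup") %in% common)) {
    d_true <- peak_lag_ms(kt$sup, dt) - peak_lag_ms(kt$exc, dt)
    d_fit <- peak_lag_ms(kf$sup, dt) - peak_lag_ms(kf$exc, dt)
    out$delay_true_ms <- d_true
    out$delay_fit_ms <- d_fit
    out$delay_error_ms <- d_fit - d_true
  }
  if (inherits(true_model, "lnk_model") &&
      inherits(fitted_model, "lnk_model")) {
    out$rate_rel_error <- c(
      k_ai = abs(fitted_model$k_ai - true_model$k_ai) / true_model$k_ai,
      k_ir = abs(fitted_model$k_ir - true_model$k_ir) / true_model$k_ir)
  }
  out
}
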