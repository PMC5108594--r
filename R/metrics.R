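# Model-evaluation statistics: noise-corrected predictive power, trial
# coherence with its noise-corrected upper bound, contrast-adaptation LN
# analysis, and sliding-window block statistics.

#' Noise-corrected predictive power
#'
#' Fraction of the explainable (signal) variance of the trial-averaged
#' response captured by a prediction. Signal variance is estimated from the
#' trial mean with the within-trial noise contribution subtracted:
#' \eqn{\hat{V}_{sig} = Var(\bar{y}) - \hat{\sigma}^2_{noise} / n}, where
#' \eqn{\hat{\sigma}^2_{noise}} is the across-trial variance averaged over
#' time. The captured fraction is the squared correlation between the
#' prediction and the trial mean, rescaled from total to signal variance:
#' \eqn{PP = \rho^2(pred, \bar{y}) \cdot Var(\bar{y}) / \hat{V}_{sig}}. An
#' ideal prediction (the true signal) scores 1 regardless of trial noise;
#' an unrelated prediction scores ~0.
#'
#' @param pred numeric prediction over the repeat window.
#' @param trials numeric matrix, window bins x trials (>= 2 trials), e.g.
#'   from \code{\link{extract_repeats}}, or a PSTH matrix for spikes.
#' @return predictive power (fraction; multiply by 100 for percent).
#' @export
predictive_power <- function(pred, trials) {
  trials <- as.matrix(trials)
  n <- ncol(trials)
  if (n < 2) stop_invalid("need >= 2 trials to estimate noise")
  if (length(pred) != nrow(trials)) stop_invalid("length mismatch")
  m <- rowMeans(trials)
  noise_var <- mean(apply(trials, 1, stats::var))
  v_sig <- stats::var(m) - noise_var / n
  if (v_sig <= 0) return(NA_real_)
  stats::cor(pred, m)^2 * stats::var(m) / v_sig
}

# Welch cross- and auto-spectra with Hann-tapered segments, 50% overlap.
welch_spectra <- function(x, y, dt_ms, seg_s = 1) {
  n <- length(x)
  seg <- round(seg_s * 1000 / dt_ms)
  seg <- min(seg, n)
  step <- max(1, floor(seg / 2))
  starts <- seq(1, n - seg + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
  nf <- floor(seg / 2) + 1
  Sxx <- Syy <- numeric(nf); Sxy <- complex(nf)
  for (s0 in starts) {
    xs <- (x[s0:(s0 + seg - 1)] - mean(x[s0:(s0 + seg - 1)])) * win
    ys <- (y[s0:(s0 + seg - 1)] - mean(y[s0:(s0 + seg - 1)])) * win
    Xf <- stats::fft(xs)[seq_len(nf)]
    Yf <- stats::fft(ys)[seq_len(nf)]
    Sxx <- Sxx + Mod(Xf)^2
    Syy <- Syy + Mod(Yf)^2
    Sxy <- Sxy + Xf * Conj(Yf)
  }
  freq_hz <- (seq_len(nf) - 1) / (seg * dt_ms / 1000)
  list(freq_hz = freq_hz, Sxx = Sxx / length(starts),
       Syy = Syy / length(starts), Sxy = Sxy / length(starts),
       n_segments = length(starts))
}

#' Trial coherence of a model prediction
#'
#' Magnitude-squared coherence \eqn{\gamma^2(\omega)} between a prediction
#' and each single-trial response, averaged across trials (Welch estimator,
#' Hann-tapered segments with 50\% overlap). The noise-corrected upper
#' bound replaces the prediction by the leave-one-out trial average (the
#' ideal stimulus-locked predictor), so it reflects the response
#' consistency attainable by any model at each frequency.
#'
#' @param pred numeric prediction over the repeat window.
#' @param trials matrix, window bins x trials (>= 2).
#' @param dt_ms bin width in ms.
#' @param seg_s Welch segment length in seconds (default 1).
#' @return object of class \code{"coherence_result"}: \code{freq_hz},
#'   \code{omega} (rad/s), \code{gamma2}, \code{noise_bound},
#'   \code{n_segments}.
#' @export
coherence <- function(pred, trials, dt_ms = 1, seg_s = 1) {
  trials <- as.matrix(trials)
  if (ncol(trials) < 2) stop_invalid("need >= 2 trials")
  if (length(pred) != nrow(trials)) stop_invalid("misaligned lengths")
  g2 <- function(x, y) {
    w <- welch_spectra(x, y, dt_ms, seg_s)
    Mod(w$Sxy)^2 / pmax(w$Sxx * w$Syy, 1e-300)
  }
  per_trial <- sapply(seq_len(ncol(trials)), function(i)
    g2(pred, trials[, i]))
  loo <- sapply(seq_len(ncol(trials)), function(i)
    g2(rowMeans(trials[, -i, drop = FALSE]), trials[, i]))
  w0 <- welch_spectra(pred, trials[, 1], dt_ms, seg_s)
  structure(list(freq_hz = w0$freq_hz, omega = 2 * pi * w0$freq_hz,
                 gamma2 = rowMeans(per_trial),
                 noise_bound = rowMeans(loo),
                 n_segments = w0$n_segments),
            class = "coherence_result")
}

#' Sliding-window response statistics
#'
#' Mean and SD of the response over a sliding window, per trial then
#' averaged across trials; used to screen for slow drift or slow
#' adaptation across the recording.
#'
#' @param resp numeric vector/matrix (bins x trials) or \code{trial_set}.
#' @param window_s window length in seconds (default 1).
#' @param dt_ms bin width in ms.
#' @return data.frame with \code{time_s} (window center), \code{mean},
#'   \code{sd}.
#' @export
block_stats <- function(resp, window_s = 1, dt_ms = 1) {
  M <- if (inherits(resp, "trial_set")) matrix(resp$trace, ncol = 1) else
    as.matrix(resp)
  wlen <- round(window_s * 1000 / dt_ms)
  if (wlen >= nrow(M)) stop_invalid("window longer than the trace")
  kern <- rep(1 / wlen, wlen)
  roll <- function(v) stats::filter(v, kern, sides = 2)
  mu <- rowMeans(sapply(seq_len(ncol(M)), function(j) roll(M[, j])))
  m2 <- rowMeans(sapply(seq_len(ncol(M)), function(j) roll(M[, j]^2)))
  keep <- !is.na(mu)
  sdv <- sqrt(pmax(m2 - mu^2, 0) * wlen / (wlen - 1))
  data.frame(time_s = ((seq_len(nrow(M)) - 1) * dt_ms / 1000)[keep],
             mean = mu[keep], sd = sdv[keep])
}

# ---- contrast adaptation LN analysis --------------------------------------

# Whitened reverse-correlation filter from the blocks of one contrast:
# periodogram-averaged cross spectrum divided by the ridge-stabilized auto
# spectrum, zeroed above the stimulus band edge, causal part kept.
revcor_filter <- function(s, y, blocks, dt_ms, n_lags, cutoff_hz = 30,
                          ridge_frac = 1e-3) {
  nb <- nrow(blocks)
  Sxx <- NULL; Sxy <- NULL; nfft <- NULL
  for (i in seq_len(nb)) {
    i0 <- round(blocks$start[i] / dt_ms) + 1
    i1 <- round(blocks$end[i] / dt_ms)
    xs <- s[i0:i1] - mean(s[i0:i1])
    ys <- y[i0:i1] - mean(y[i0:i1])
    if (is.null(nfft)) nfft <- length(xs)
    if (length(xs) < nfft) next
    Xf <- stats::fft(xs[seq_len(nfft)])
    Yf <- stats::fft(ys[seq_len(nfft)])
    Sxx <- if (is.null(Sxx)) Mod(Xf)^2 else Sxx + Mod(Xf)^2
    Sxy <- if (is.null(Sxy)) Conj(Xf) * Yf else Sxy + Conj(Xf) * Yf
  }
  K <- Sxy / (Sxx + ridge_frac * mean(Sxx))
  freqs <- c(seq(0, floor(nfft / 2)),
             seq(-(ceiling(nfft / 2) - 1), -1)) / (nfft * dt_ms / 1000)
  K[abs(freqs) > cutoff_hz] <- 0
  k <- Re(stats::fft(K, inverse = TRUE)) / nfft
  k[seq_len(n_lags)]
}

#' Contrast-adaptation LN analysis
#'
#' Performs a separate LN analysis at each contrast: the filter by
#' whitened reverse correlation (spectral division, stabilized by a ridge
#' and restricted to the stimulus band), the nonlinearity nonparametrically
#' from the filter output. The two nonlinearities are then aligned by
#' jointly estimating an x-axis scale and a y-axis offset minimizing their
#' mean squared deviation; the scale is folded into the low-contrast
#' filter, so any gain change is attributed entirely to the linear filter.
#' Contrast gain is the ratio of filter SDs (LC/HC) after alignment; > 1
#' means reduced gain at high contrast (adaptation).
#'
#' @param stim a \code{stimulus} with both contrast labels in its schedule.
#' @param resp numeric response trace (current or firing rate per bin).
#' @param n_lags filter length in bins (default 200).
#' @param n_knots knots of the nonparametric nonlinearities.
#' @return object of class \code{"adaptation_result"}: per-contrast
#'   \code{filters} (after alignment) and \code{nonlinearities},
#'   \code{x_scale}, \code{y_offset}, \code{contrast_gain},
#'   \code{biphasic_index}.
#' @export
contrast_ln_analysis <- function(stim, resp, n_lags = 200, n_knots = 21) {
  resp <- as.numeric(resp)
  sched <- stim$schedule
  if (!all(c("HC", "LC") %in% sched$label))
    stop_invalid("both contrast labels required in the schedule")
  s <- stim$values[, 1] - stim$mean_level
  dt <- stim$dt
  per_contrast <- lapply(c(HC = "HC", LC = "LC"), function(lab) {
    blocks <- sched[sched$label == lab, , drop = FALSE]
    k <- revcor_filter(s, resp, blocks, dt, n_lags)
    g <- causal_conv(s, k)
    mask <- window_mask(stim, blocks)
    mask[seq_len(min(n_lags, length(mask)))] <- FALSE
    gm <- g[mask]; ym <- resp[mask]
    tb <- tent_basis(default_knots(gm, n_knots))
    Tm <- tent_eval(tb, gm)
    w <- qp_box(crossprod(Tm), as.numeric(crossprod(Tm, ym)))
    list(k = k, nl = nonlinearity(tb, w), g_sd = stats::sd(gm))
  })
  hc <- per_contrast$HC; lc <- per_contrast$LC
  # alignment: minimize over (alpha, beta) the deviation between
  # f_lc(x / alpha) + beta and f_hc(x) on the HC generator range
  grid <- seq(hc$nl$basis$knots[1], hc$nl$basis$knots[n_knots],
              length.out = 201)
  fh <- nl_eval(hc$nl, grid)
  obj <- function(la) {
    fl <- nl_eval(lc$nl, grid / exp(la))
    beta <- mean(fh - fl)
    mean((fl + beta - fh)^2)
  }
  opt <- stats::optimize(obj, c(-2.5, 2.5))
  alpha <- exp(opt$minimum)
  beta <- mean(fh - nl_eval(lc$nl, grid / alpha))
  k_lc_aligned <- alpha * lc$k
  bip <- function(k) abs(min(k) / max(k))
  structure(list(
    filters = list(HC = hc$k, LC = k_lc_aligned),
    nonlinearities = list(HC = hc$nl, LC = lc$nl),
    x_scale = alpha, y_offset = beta,
    contrast_gain = stats::sd(k_lc_aligned) / stats::sd(hc$k),
    biphasic_index = c(HC = bip(hc$k), LC = bip(k_lc_aligned)),
    dt = dt), class = "adaptation_result")
}

#' Biphasic index of a temporal filter
#'
#' Ratio of the most negative to the most positive filter amplitude,
#' \eqn{|min(k)/max(k)|}.
#'
#' @param k numeric kernel.
#' @return scalar index.
#' @export
biphasic_index <- function(k) abs(min(k) / max(k))

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "Contrast adaptation LN analysis: gain (LC/HC) = %.3f, x-scale = %.3f\n",
    x$contrast_gain, x$x_scale))
  cat(sprintf("  biphasic index HC %.3f, LC %.3f\n",
              x$biphasic_index["HC"], x$biphasic_index["LC"]))
  invisible(x)
}
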