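# Stimulus generators reproducing the temporal-contrast protocols: a
# low-pass (30 Hz) Gaussian flickering spot whose contrast (SD/mean) switches
# between 0.3 (high) and 0.1 (low) every cycle, and a two-channel
# spot/annulus stimulus with independent 60-Hz Gaussian modulation.

#' Stimulus container
#'
#' @param values numeric matrix, time x channels (channel 1 = spot/center,
#'   channel 2 = annulus/surround when present).
#' @param dt bin width in ms.
#' @param mean_level mean luminance (normalized units).
#' @param schedule data.frame with \code{start}, \code{end} (ms, half-open
#'   \code{[start, end)}) and \code{label} ("HC"/"LC") tiling the duration.
#' @param repeat_windows data.frame with \code{start}, \code{end}, \code{label}
#'   for the repeated (cross-validation) segment of each cycle.
#' @return object of class \code{"stimulus"}.
#' @export
stimulus <- function(values, dt, mean_level = 1,
                     schedule = NULL, repeat_windows = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop_invalid("stimulus values must be finite")
  n <- nrow(values)
  if (is.null(schedule))
    schedule <- data.frame(start = 0, end = n * dt, label = "HC")
  if (is.null(repeat_windows))
    repeat_windows <- data.frame(start = numeric(0), end = numeric(0),
                                 label = character(0))
  structure(list(values = values, dt = dt, mean_level = mean_level,
                 n_time = n, n_channels = ncol(values),
                 schedule = schedule, repeat_windows = repeat_windows),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus: %.1f s, %d channel(s), dt = %g ms, mean = %g\n",
              x$n_time * x$dt / 1000, x$n_channels, x$dt, x$mean_level))
  if (nrow(x$schedule) > 1)
    cat(sprintf("  %d contrast blocks (%s)\n", nrow(x$schedule),
                paste(unique(x$schedule$label), collapse = "/")))
  invisible(x)
}

#' Band-limited Gaussian noise
#'
#' Unit-SD, zero-mean Gaussian noise sharply band-limited below
#' \code{cutoff_hz} by Fourier-domain masking (exactly band-limited).
#'
#' @param n samples.
#' @param dt bin width (ms).
#' @param cutoff_hz cutoff frequency.
#' @return numeric vector.
#' @export
bandlimited_noise <- function(n, dt, cutoff_hz) {
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  freqs <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) /
    (n * dt / 1000)
  zf[abs(freqs) > cutoff_hz] <- 0
  z <- Re(stats::fft(zf, inverse = TRUE)) / n
  (z - mean(z)) / stats::sd(z)
}

#' Contrast-switching flickering-spot stimulus
#'
#' Low-pass Gaussian noise (sharp spectral cutoff, default 30 Hz) whose SD
#' alternates between \code{hc_frac} and \code{lc_frac} times the mean every
#' cycle. Each cycle consists of a unique segment (fresh noise, used for
#' fitting) followed by a repeated segment that is identical across cycles of
#' the same contrast (used for cross-validation). The repeated waveform shape
#' is shared between contrasts and scaled to each contrast's SD, so only
#' contrast differs between HC and LC repeats. Each segment is rescaled to
#' its exact target sample SD and mean.
#'
#' @param n_cycles cycles per contrast (default 10; total duration
#'   \code{2 * n_cycles * cycle_s} seconds).
#' @param cycle_s cycle length in seconds (default 10).
#' @param unique_s unique (non-repeated) portion per cycle in seconds
#'   (default 7).
#' @param dt bin width in ms (default 1).
#' @param mean_level mean luminance (default 1).
#' @param hc_frac,lc_frac contrast (SD/mean) at high and low contrast
#'   (defaults 0.3, 0.1).
#' @param cutoff_hz low-pass cutoff (default 30).
#' @param seed integer RNG seed.
#' @param first_contrast which contrast starts the alternation ("HC").
#' @return a \code{stimulus} with alternating HC/LC blocks.
#' @export
contrast_switching_stimulus <- function(n_cycles = 10, cycle_s = 10,
                                        unique_s = 7, dt = 1,
                                        mean_level = 1, hc_frac = 0.3,
                                        lc_frac = 0.1, cutoff_hz = 30,
                                        seed = 1, first_contrast = "HC") {
  if (unique_s >= cycle_s) stop_invalid("unique_s must be < cycle_s")
  if (hc_frac <= 0 || hc_frac >= 1 || lc_frac <= 0 || lc_frac >= 1)
    stop_invalid("contrast fractions must lie in (0, 1)")
  if (cutoff_hz >= 1000 / (2 * dt))
    stop_invalid("dt too coarse for the requested cutoff (Nyquist violation)")
  n_cyc_bins <- round(cycle_s * 1000 / dt)
  n_uni_bins <- round(unique_s * 1000 / dt)
  n_rep_bins <- n_cyc_bins - n_uni_bins
  with_seed(seed, {
    rep_wave <- bandlimited_noise(n_rep_bins, dt, cutoff_hz)
    labels <- rep(if (first_contrast == "HC") c("HC", "LC") else c("LC", "HC"),
                  n_cycles)
    vals <- vector("list", length(labels))
    sched <- repw <- vector("list", length(labels))
    t0 <- 0
    for (b in seq_along(labels)) {
      frac <- if (labels[b] == "HC") hc_frac else lc_frac
      uni <- bandlimited_noise(n_uni_bins, dt, cutoff_hz)
      vals[[b]] <- mean_level + frac * mean_level * c(uni, rep_wave)
      sched[[b]] <- data.frame(start = t0, end = t0 + n_cyc_bins * dt,
                               label = labels[b])
      repw[[b]] <- data.frame(start = t0 + n_uni_bins * dt,
                              end = t0 + n_cyc_bins * dt, label = labels[b])
      t0 <- t0 + n_cyc_bins * dt
    }
    stimulus(matrix(unlist(vals), ncol = 1), dt = dt,
             mean_level = mean_level,
             schedule = do.call(rbind, sched),
             repeat_windows = do.call(rbind, repw))
  })
}

#' Spot/annulus two-channel stimulus
#'
#' Center (spot) and surround (annulus) channels independently modulated by
#' Gaussian noise updated at \code{update_hz} and held constant within each
#' frame (sample-and-hold).
#'
#' @param duration_s total duration in seconds.
#' @param dt bin width in ms (default 1).
#' @param update_hz frame rate of the Gaussian modulation (default 60).
#' @param mean_level mean luminance (default 1).
#' @param contrast_frac SD/mean of each channel (default 0.3).
#' @param seed integer RNG seed.
#' @return a two-channel \code{stimulus}.
#' @export
spot_annulus_stimulus <- function(duration_s, dt = 1, update_hz = 60,
                                  mean_level = 1, contrast_frac = 0.3,
                                  seed = 1) {
  if (update_hz >= 1000 / dt)
    stop_invalid("dt too coarse for the requested update rate")
  n <- round(duration_s * 1000 / dt)
  frame_of <- floor((seq_len(n) - 1) * dt * update_hz / 1000) + 1L
  n_frames <- max(frame_of)
  with_seed(seed, {
    ch <- sapply(1:2, function(k) {
      z <- stats::rnorm(n_frames)
      z <- (z - mean(z)) / stats::sd(z)
      mean_level + contrast_frac * mean_level * z[frame_of]
    })
    stimulus(ch, dt = dt, mean_level = mean_level)
  })
}

#' Bin mask for a set of time windows
#'
#' Logical mask over stimulus bins for half-open windows \code{[start,
#' end)} in ms (rows of a schedule or repeat-window table).
#'
#' @param stim a \code{stimulus}.
#' @param windows data.frame with \code{start}, \code{end} (ms).
#' @return logical vector.
#' @export
window_mask <- function(stim, windows) {
  n <- stim$n_time
  mask <- rep(FALSE, n)
  tms <- (seq_len(n) - 1) * stim$dt
  for (i in seq_len(nrow(windows)))
    mask <- mask | (tms >= windows$start[i] & tms < windows$end[i])
  mask
}

#' Training mask (unique segments)
#'
#' Bins outside every repeat window, optionally dropping a leading
#' burn-in.
#'
#' @param stim a \code{stimulus}.
#' @param burn_in_bins leading bins to exclude.
#' @return logical vector.
#' @export
training_mask <- function(stim, burn_in_bins = 0) {
  mask <- !window_mask(stim, stim$repeat_windows)
  if (burn_in_bins > 0) mask[seq_len(min(burn_in_bins, length(mask)))] <- FALSE
  mask
}
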