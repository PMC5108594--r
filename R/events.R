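# Spike-event analysis: segmentation of the PSTH into firing events
# separated by >= 8 ms of silence, recursive splitting of temporally
# bimodal events via a two-component Gaussian mixture, and per-event
# precision (first-spike jitter, event time scale) and reliability (count
# Fano factor) statistics.

# Deterministic 1-D two-component Gaussian mixture EM, initialized at the
# 25th/75th percentile spike times.
gmm2_em <- function(x, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  s2 <- rep(stats::var(x) + 1e-6, 2)
  pi_ <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi_[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- pi_[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2 + 1e-300
    r1 <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-6 || n2 < 1e-6) break
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s2 <- c(sum(r1 * (x - mu[1])^2) / n1,
            sum((1 - r1) * (x - mu[2])^2) / n2) + 1e-6
    pi_ <- c(n1, n2) / n
  }
  list(mu = mu, sd = sqrt(s2), pi = pi_)
}

# Recursive event splitting: split when the mixture means differ by more
# than split_factor times the sum of component SDs; boundary at the
# midpoint of the means.
split_event <- function(times, split_factor = 2, depth = 0, max_depth = 3,
                        sd_floor = 1) {
  if (length(times) < 4 || depth >= max_depth ||
      stats::sd(times) < 1e-9) return(list(times))
  gm <- gmm2_em(times)
  # component SDs are floored at the PSTH bin width so that perfectly
  # stereotyped spike times do not split without limit
  if (abs(diff(gm$mu)) > split_factor * sum(pmax(gm$sd, sd_floor))) {
    cut <- mean(gm$mu)
    left <- times[times < cut]; right <- times[times >= cut]
    if (length(left) == 0 || length(right) == 0) return(list(times))
    return(c(split_event(left, split_factor, depth + 1, max_depth, sd_floor),
             split_event(right, split_factor, depth + 1, max_depth,
                         sd_floor)))
  }
  list(times)
}

#' Spike-event analysis
#'
#' Segments the pooled high-contrast response into firing events: periods
#' of firing in the 1-ms PSTH separated by silences of at least
#' \code{silence_ms}; events whose pooled spike times are bimodal (mixture
#' means more than \code{split_factor} times the summed component SDs
#' apart) are split recursively at the midpoint of the component means.
#' Event boundaries are the midpoints between neighboring event centers.
#' Events with spikes on at most \code{min_trial_frac} of trials are
#' flagged excluded (spontaneous firing). Per event: the SD across trials
#' of the first spike time (first-spike jitter), the SD of all spike times
#' (event time scale), and the Fano factor of the per-trial spike counts.
#' When a low-contrast spike set is supplied its spikes are scored inside
#' the high-contrast event windows.
#'
#' @param spikes a \code{spike_train_set} (high contrast).
#' @param spikes_lc optional \code{spike_train_set} at low contrast.
#' @param silence_ms minimal silence separating events (default 8).
#' @param min_trial_frac exclusion threshold on the fraction of trials
#'   with at least one spike (default 0.5).
#' @param split_factor mixture-splitting criterion (default 2).
#' @param max_depth recursion cap for splitting (default 3).
#' @return object of class \code{"event_table"}: data.frame(s) with one
#'   row per event (\code{start}, \code{end}, \code{center},
#'   \code{n_trials_active}, \code{first_spike_sd}, \code{all_spike_sd},
#'   \code{fano}, \code{excluded}, \code{reason}); the low-contrast table
#'   (same windows) in \code{attr(, "lc")} when requested.
#' @export
event_analysis <- function(spikes, spikes_lc = NULL, silence_ms = 8,
                           min_trial_frac = 0.5, split_factor = 2,
                           max_depth = 3) {
  if (spikes$n_trials == 0 || all(lengths(spikes$trials) == 0)) {
    out <- empty_event_table()
    return(structure(out, class = c("event_table", "data.frame")))
  }
  dtb <- spikes$dt_bin
  counts <- rowSums(bin_spikes(spikes))
  # maximal runs of activity separated by >= silence_ms of zero counts
  active <- counts > 0
  idx <- which(active)
  gaps <- which(diff(idx) > silence_ms / dtb)
  seg_start <- idx[c(1, gaps + 1)]
  seg_end <- idx[c(gaps, length(idx))]
  pooled <- sort(unlist(spikes$trials))
  events <- list()
  for (k in seq_along(seg_start)) {
    t0 <- (seg_start[k] - 1) * dtb; t1 <- seg_end[k] * dtb
    tt <- pooled[pooled >= t0 & pooled < t1]
    if (length(tt) == 0) next
    events <- c(events, split_event(tt, split_factor,
                                    max_depth = max_depth,
                                    sd_floor = spikes$dt_bin))
  }
  centers <- vapply(events, mean, 0)
  ord <- order(centers)
  events <- events[ord]; centers <- centers[ord]
  bounds <- c(0, (utils::head(centers, -1) + utils::tail(centers, -1)) / 2,
              spikes$duration)
  tab <- score_events(spikes, bounds, centers, min_trial_frac)
  out <- structure(tab, class = c("event_table", "data.frame"))
  if (!is.null(spikes_lc)) {
    lc <- score_events(spikes_lc, bounds, centers, min_trial_frac)
    attr(out, "lc") <- structure(lc, class = c("event_table", "data.frame"))
  }
  out
}

score_events <- function(spikes, bounds, centers, min_trial_frac) {
  nev <- length(centers)
  ntr <- spikes$n_trials
  res <- lapply(seq_len(nev), function(k) {
    w0 <- bounds[k]; w1 <- bounds[k + 1]
    per_trial <- lapply(spikes$trials, function(tt) tt[tt >= w0 & tt < w1])
    cnt <- lengths(per_trial)
    active <- sum(cnt > 0)
    first <- vapply(per_trial[cnt > 0], min, 0)
    allsp <- unlist(per_trial)
    excluded <- active <= min_trial_frac * ntr
    data.frame(
      event = k, start = w0, end = w1, center = centers[k],
      n_trials_active = active,
      first_spike_sd = if (length(first) > 1) stats::sd(first) else NA_real_,
      all_spike_sd = if (length(allsp) > 1) stats::sd(allsp) else NA_real_,
      fano = if (mean(cnt) > 0) stats::var(cnt) / mean(cnt) else NA_real_,
      excluded = excluded,
      reason = if (excluded) sprintf("spikes on %d/%d trials", active, ntr)
               else "")
  })
  do.call(rbind, res)
}

empty_event_table <- function() {
  data.frame(event = integer(0), start = numeric(0), end = numeric(0),
             center = numeric(0), n_trials_active = integer(0),
             first_spike_sd = numeric(0), all_spike_sd = numeric(0),
             fano = numeric(0), excluded = logical(0),
             reason = character(0))
}

#' Summary statistics of an event table
#'
#' Medians of the precision/reliability statistics over non-excluded
#' events.
#'
#' @param tab an \code{event_table}.
#' @return named vector: \code{n_events}, \code{first_spike_sd},
#'   \code{all_spike_sd}, \code{fano}.
#' @export
event_summary <- function(tab) {
  keep <- !tab$excluded
  c(n_events = sum(keep),
    first_spike_sd = stats::median(tab$first_spike_sd[keep], na.rm = TRUE),
    all_spike_sd = stats::median(tab$all_spike_sd[keep], na.rm = TRUE),
    fano = stats::median(tab$fano[keep], na.rm = TRUE))
}
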