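# Spike-event segmentation and precision/reliability statistics.

test_that("bursts separated by >= 8 ms of silence form separate events", {
  # two 5-ms bursts, 20 ms apart, identical on 10 trials
  trials <- lapply(1:10, function(i) c(10, 12, 14, 34, 36, 38))
  sp <- spike_train_set(trials, duration = 100)
  tab <- event_analysis(sp)
  expect_equal(sum(!tab$excluded), 2)
  # every spike falls in exactly one window, windows ordered and disjoint
  expect_true(all(diff(tab$start) > 0))
  expect_true(all(tab$end[-nrow(tab)] <= tab$start[-1] + 1e-9))
})

test_that("a short unimodal firing episode stays one event", {
  trials <- lapply(1:10, function(i) c(10, 11, 12, 13, 14))
  tab <- event_analysis(spike_train_set(trials, 60))
  expect_equal(nrow(tab), 1)
})

test_that("deterministic counts give zero Fano and identical first spikes give zero jitter", {
  trials <- lapply(1:8, function(i) c(20, 25))
  tab <- event_analysis(spike_train_set(trials, 60))
  keep <- !tab$excluded
  expect_true(all(tab$fano[keep] == 0))
  expect_true(all(tab$first_spike_sd[keep] == 0))
})

test_that("bimodal events split when means differ by > 2 x summed SDs", {
  # one continuous firing span, but spike times cluster 40 ms apart with
  # ~5 ms component SDs (40 > 2 * (5 + 5))
  set.seed(71)
  trials <- lapply(1:20, function(i) {
    a <- sort(pmin(pmax(rnorm(8, 30, 5), 12), 48))
    b <- sort(pmin(pmax(rnorm(8, 70, 5), 52), 88))
    c(a, b)
  })
  sp <- spike_train_set(trials, 120)
  # bridge the silence so run-length segmentation alone cannot split
  tab <- event_analysis(sp, silence_ms = 60)
  expect_gte(sum(!tab$excluded), 2)
  centers <- tab$center[!tab$excluded]
  expect_true(any(centers < 50) && any(centers > 50))
})

test_that("events on too few trials are excluded with a reason", {
  trials <- c(lapply(1:2, function(i) c(10, 30)),
              lapply(1:8, function(i) c(10)))
  tab <- event_analysis(spike_train_set(trials, 60))
  expect_true(any(tab$excluded))
  expect_match(tab$reason[tab$excluded][1], "trials")
})

test_that("low-contrast spikes are scored inside high-contrast windows", {
  hc <- spike_train_set(lapply(1:10, function(i) c(10, 12, 40, 42)), 80)
  lc <- spike_train_set(lapply(1:10, function(i) c(10.5, 40.5, 42.5)), 80)
  tab <- event_analysis(hc, spikes_lc = lc)
  lct <- attr(tab, "lc")
  expect_equal(nrow(lct), nrow(tab))
  expect_equal(lct$start, tab$start)
  expect_true(any(lct$n_trials_active > 0))
})

test_that("empty spike sets give an empty table", {
  sp <- spike_train_set(list(numeric(0), numeric(0)), 50)
  tab <- event_analysis(sp)
  expect_equal(nrow(tab), 0)
})
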