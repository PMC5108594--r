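# Stimulus generators: contrast-switching low-pass noise and the
# spot/annulus frozen-frame protocol.

test_that("contrast-switching stimulus has 3:1 SD ratio and is band-limited", {
  st <- contrast_switching_stimulus(n_cycles = 7, seed = 2)  # 70 s/contrast
  hc <- window_mask(st, st$schedule[st$schedule$label == "HC", ])
  lc <- window_mask(st, st$schedule[st$schedule$label == "LC", ])
  ratio <- sd(st$values[hc, 1]) / sd(st$values[lc, 1])
  expect_equal(ratio, 3.0, tolerance = 0.05)
  # block SDs match the requested contrast fractions
  expect_equal(sd(st$values[hc, 1]), 0.3 * st$mean_level, tolerance = 0.05)
  expect_equal(sd(st$values[lc, 1]), 0.1 * st$mean_level, tolerance = 0.05)
  # spectral content above the 30 Hz cutoff
  x <- st$values[hc, 1] - mean(st$values[hc, 1])
  pg <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) / (length(x) * st$dt / 1000)
  half <- freqs <= 500
  frac_above <- sum(pg[half & freqs > 30.5]) / sum(pg[half])
  expect_lt(frac_above, 0.01)
})

test_that("same seed gives bit-identical stimuli; different seeds decorrelate", {
  a <- contrast_switching_stimulus(n_cycles = 2, seed = 9)
  b <- contrast_switching_stimulus(n_cycles = 2, seed = 9)
  expect_identical(a$values, b$values)
  c <- contrast_switching_stimulus(n_cycles = 3, seed = 10)
  d <- contrast_switching_stimulus(n_cycles = 3, seed = 11)
  um <- training_mask(c)
  expect_lt(abs(cor(c$values[um, 1], d$values[um, 1])), 0.05)
})

test_that("repeat windows are exact copies within each contrast", {
  st <- contrast_switching_stimulus(n_cycles = 3, seed = 5)
  for (lab in c("HC", "LC")) {
    reps <- extract_repeats(st, trial_set(st$values[, 1], st$dt), lab)
    expect_true(all(reps == reps[, 1]))
  }
})

test_that("schedule tiles the duration without overlap", {
  st <- contrast_switching_stimulus(n_cycles = 2, seed = 1)
  sch <- st$schedule
  expect_equal(sch$start[-1], sch$end[-nrow(sch)])
  expect_equal(sch$start[1], 0)
  expect_equal(sch$end[nrow(sch)], st$n_time * st$dt)
})

test_that("Nyquist violations are rejected", {
  expect_error(contrast_switching_stimulus(n_cycles = 1, dt = 20,
                                           cutoff_hz = 30), "Nyquist")
  expect_error(contrast_switching_stimulus(n_cycles = 1, hc_frac = 1.5),
               "fractions")
})

test_that("spot/annulus channels are independent sample-and-hold sequences", {
  st <- spot_annulus_stimulus(duration_s = 100, seed = 3)
  expect_equal(st$n_channels, 2)
  expect_lt(abs(cor(st$values[, 1], st$values[, 2])), 0.05)
  # sample-and-hold: values constant within each ~16.7 ms frame
  frame_of <- floor((seq_len(st$n_time) - 1) * st$dt * 60 / 1000)
  within_var <- tapply(st$values[, 1], frame_of, var)
  expect_true(all(within_var[!is.na(within_var)] == 0))
  # frame length: number of changes matches the 60 Hz update rate
  n_frames <- length(unique(frame_of))
  expect_equal(st$n_time / n_frames, 1000 / 60 / st$dt, tolerance = 0.01)
})
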