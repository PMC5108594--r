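# Shared fixtures, computed lazily once per test run. Heavy model fits are
# memoized here so unit, property and acceptance tests can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]]))
    assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# small fitting configuration used across the suite
quick_cfg <- function(max_outer_iters = 60, ...) {
  fit_config(max_outer_iters = max_outer_iters, n_random_inits = 1, ...)
}

# canonical DivS ground truth and a ~80 s SNR-10 recording (the standard
# protocol: 4 cycles per contrast, HC/LC alternating)
fix_divs_truth <- function() fixture("divs_truth", make_ground_truth("divs"))

fix_divs_recording <- function() fixture("divs_recording", {
  generate_recording(fix_divs_truth(), n_trials = 10, snr = 10, seed = 11,
                     n_cycles = 4)
})

fix_divs_fit <- function() fixture("divs_fit", {
  rec <- fix_divs_recording()
  fit_divs(rec$stim, rec$currents, quick_cfg())
})

fix_ln_fit_on_divs <- function() fixture("ln_fit_on_divs", {
  rec <- fix_divs_recording()
  fit_ln(rec$stim, rec$currents, quick_cfg())
})

fix_adds_fit_on_divs <- function() fixture("adds_fit_on_divs", {
  rec <- fix_divs_recording()
  fit_adds(rec$stim, rec$currents, quick_cfg(max_outer_iters = 40))
})

# spiking DivS ground truth, a 200 s recording and its fits
fix_spk_truth <- function() fixture("spk_truth", make_ground_truth("divs_spike"))

fix_spk_recording <- function() fixture("spk_recording", {
  stim <- contrast_switching_stimulus(n_cycles = 10, lc_frac = 0.299,
                                      seed = 31)  # ~200 s, HC-level drive
  generate_recording(fix_spk_truth(), stim = stim, n_trials = 8, seed = 31)
})

fix_glm_fit <- function() fixture("glm_fit", {
  rec <- fix_spk_recording()
  fit_glm(rec$stim, rec$spikes, quick_cfg())
})

# GLM ground truth fitted to its own data (parameter recovery)
fix_glm_recording <- function() fixture("glm_recording", {
  stim <- contrast_switching_stimulus(n_cycles = 10, lc_frac = 0.299,
                                      seed = 32)
  generate_recording(make_ground_truth("glm"), stim = stim, n_trials = 1,
                     seed = 32)
})

fix_glm_fit_own <- function() fixture("glm_fit_own", {
  rec <- fix_glm_recording()
  fit_glm(rec$stim, rec$spikes, quick_cfg())
})

fix_glm_nohist_fit <- function() fixture("glm_nohist_fit", {
  rec <- fix_spk_recording()
  fit_glm(rec$stim, rec$spikes, quick_cfg(), with_history = FALSE)
})

fix_divs_spike_fit <- function() fixture("divs_spike_fit", {
  rec <- fix_spk_recording()
  fit_divs_spike(rec$stim, rec$spikes, quick_cfg(max_outer_iters = 10))
})
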