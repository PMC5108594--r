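---
title: "Divisive suppression models of retinal ganglion cell responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive suppression models of retinal ganglion cell responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Retinal ganglion cells fire with millisecond precision and adapt their gain
to stimulus contrast, yet the classical linear-nonlinear (LN) cascade — a
temporal receptive field followed by a static nonlinearity — captures
neither property. `divsenc` implements a family of nonlinear encoding
models built around *divisive suppression*: the hypothesis that the
excitatory drive to a ganglion cell is multiplied by a delayed, ON-OFF
suppressive gain bounded between zero and one. The package fits these
models to trial-structured recordings of synaptic currents or spike
trains driven by temporally modulated spot (and spot/annulus) stimuli,
and provides the statistics used to evaluate them: noise-corrected
predictive power, frequency-resolved coherence, contrast-adaptation LN
analysis, and spike-event precision measures.

Because recorded data are not distributed with the package, a first-class
synthetic module generates ground-truth models and recordings under the
same stimulus protocols, so every fitting routine is exercised by
parameter recovery rather than by reproducing archived fits.

## Models

All temporal filters are parameterized by coefficients on an orthonormal
family of time-warped sinusoids
$\zeta_n(t) = \sin[\pi n (2t/t_F - (t/t_F)^2)]$ over $t_F = 200$ ms,
orthonormalized by ordered Gram–Schmidt at the working resolution (1 ms).
The warping concentrates resolution at short lags where retinal filters
have structure; every function vanishes at $t = 0$ and $t = t_F$, so
kernels are causal and smooth. Twelve basis functions are the default —
enough to represent structure down to roughly 8 ms across the 200 ms
window; the number is configurable (`fit_config(n_basis = )`).

1-D nonlinearities are piecewise-linear functions on tent (hat) bases, by
default 21 knots spanning the mean ± 3 SD of the generator signal
observed at initialization. Evaluation outside the knot range clamps to
the boundary value, since the weights are only constrained in range.

* **LN**: $c(t) = f[k \cdot s(t)]$, unconstrained $f$ (the constant
  offset lives inside $f$, since tent bases span constants).
* **DivS**: $c(t) = f_e[k_e \cdot s(t)] \times f_s[k_s \cdot s(t)] + c_0$
  with $f_e$ monotonically increasing and $f_s \in [0, 1]$, $f_s(0) = 1$,
  so the second pathway can only *divide* the excitatory drive.
* **AddS**: the additive control, $f_e[\cdot] + f_s[\cdot] + c_0$ with
  $f_s \le 0$ and $f_s(0) = 0$ — the natural additive analogue of the
  DivS constraints.
* **2-D**: $c(t) = F[k_e \cdot s, k_s \cdot s]$ with $F$ a nonparametric
  piecewise-planar surface on a grid of hexagonal-pyramid bases
  (15 × 15 vertices by default), constrained monotone along the
  excitatory axis. This removes the degeneracy under linear remixing of
  the two filters. `separability_r2()` measures how much of the fitted
  surface is explained by the separable DivS product, weighted by the
  empirical density of generator signals.
* **LNK**: an LN front end drives the resting-to-active transition of a
  three-state kinetic chain (resting R, active A, inactivated I);
  A-to-I and I-to-R rates are constant and the output is proportional to
  active-state occupancy — first-order kinetics emulating vesicle
  depletion. The slow fourth state of the original formulation is
  omitted. Only R→A is stimulus-driven.
* **Spiking models**: inhomogeneous Poisson processes with the fixed
  softplus output $F_{spk}[g] = \log(1 + e^g)$ at 1-ms bins. The GLM
  (LN+RP) uses a linear stimulus filter, a spike-history term on eight
  log-spaced raised-cosine bumps covering 1–100 ms, and a threshold.
  The spiking DivS model replaces the linear drive by a DivS subunit
  with the same constraints as for currents. DivS−RP removes the
  history term and refits the remaining parameters.

## Fitting

Continuous models minimize MSE; spiking models maximize the Poisson
log-likelihood $\sum_t [r_{obs} \log r - r]$. Both use block-coordinate
descent: each nonlinearity (and history/threshold) block is a convex —
for nonlinearities, constrained least-squares or concave-likelihood —
subproblem, solved by projected quasi-Newton (monotonicity is enforced by
nonnegative increments between knots; the suppressive gain by a [0, 1]
box plus renormalization of $f_s(0)$ to 1, with the scale absorbed into
$f_e$); filter blocks are quasi-Newton steps on the nonconvex MSE/LL.
Several numerical conventions matter:

* **Scale degeneracies.** Filters are renormalized to unit L2 norm after
  every update, with the scale folded exactly into the knot axis of the
  downstream nonlinearity (piecewise-linear functions rescale exactly,
  so the model's predictions are unchanged and the logged objective
  cannot jump). All gain lives in the nonlinearities; $f_e$ is anchored
  at 0 at its leftmost knot, resolving the offset degeneracy with $c_0$.
* **Initialization.** The deterministic start uses the ridge-stabilized
  response-weighted cross-correlation (the covariance module's mean
  kernel in basis space); the suppressive filter starts from a 10-ms
  delayed copy plus seeded random restarts
  (`fit_config(n_random_inits = )`). DivS always includes a start at the
  LN solution with $f_s \equiv 1$, so its training error can never
  exceed the LN model's.
* **Convergence.** Outer iterations stop when the best-so-far objective
  improves by less than `rel_tol` (default 1e-6) over two iterations, up
  to `max_outer_iters` (default 100). The fit log records the
  best-so-far objective, which is non-increasing by construction; the
  suppressive renormalization can transiently perturb the raw objective,
  and the returned model is always the best visited state.
* **Training samples.** Models are fit on the unique 7-s segments of
  each cycle (repeat windows held out for validation) after discarding
  one filter length of burn-in. Because the 30-Hz band-limited stimulus
  is heavily oversampled at 1 ms, continuous-current fits use every
  second training sample by default (`train_stride = 2`); evaluation
  always uses every 1-ms bin. The first 200 ms of each repeat window are
  trimmed during evaluation, because responses there carry over from the
  distinct unique segments preceding each repeat.
* **LNK integration.** The three-state master equation is integrated
  with the trapezoidal (Padé 1,1) discretization, which conserves
  total occupancy exactly and has the continuous-time stationary
  distribution as its exact fixed point — the property the steady-state
  oracle test checks to 1e-6, which simple per-rate exponential
  transition probabilities would not satisfy at 1-ms steps. A step-size
  guard rejects simulations whose per-bin transition probabilities reach
  0.2. LNK fitting profiles the output gain and offset out by linear
  regression inside the objective, parameterizes the input nonlinearity
  by log-increments with its maximum fixed at 1 (resolving the
  drive/rate rescaling degeneracy), and optimizes the rest by
  multi-start quasi-Newton with numerical gradients.
* **Spiking DivS estimation.** The multiplicative subunit is weakly
  identified from single recordings at ~5 spikes/s: unconstrained
  maximum likelihood visibly overfits (training likelihood improves
  while the recovered kernels drift). Two guards are built in. The
  suppressive filter is initialized both from a 10-ms delayed copy of
  the excitatory filter and from the leading spike-triggered covariance
  axes orthogonal to it, with a short probe run selecting the start by
  likelihood on the held-out repeat windows; and the returned state is
  the iterate with the best repeat-window likelihood (early stopping on
  the protocol's own validation split). The excitatory-nonlinearity
  block updates the threshold jointly, because the anchored
  \eqn{f_e} cannot absorb offsets; filter block steps are angle-capped
  so one outer iteration cannot swing a filter into a different
  configuration. The history-free refit (DivS−RP) starts from the full
  model's subunit and selects its result by training likelihood.
* **2-D surface.** Monotonicity along the excitatory axis is imposed by
  writing each grid column as a free base value plus nonnegative
  increments; the constrained least-squares problem is solved on the
  normal equations. Filters can be held fixed at the DivS solution or
  refined jointly (the default), which is the mode used throughout the
  tests.

## The synthetic ground truth

`make_ground_truth()` builds canonical models whose parameter *shapes*
emulate reported qualitative structure of ON-Alpha ganglion cell inputs,
while the *values* are generator choices:

* a sharp biphasic excitatory kernel (difference of sixth-order gamma
  kernels, peak at ~41 ms, biphasic index ~0.5);
* a suppressive kernel equal to the excitatory one delayed by 10 ms —
  the magnitude of delay reported for divisive suppression;
* a U-shaped (ON-OFF) suppressive gain $f_s(x) = 1/(1 + (x/0.8)^2)$;
* LNK rates ($u_{max} = 80$, $k_{AI} = 50$, $k_{IR} = 15$ s$^{-1}$)
  chosen so depression is engaged at high contrast (active-state
  occupancy swings over most of its range) while the chain stays well
  inside the integrator's stability region;
* spike-history structure with a 2-ms absolute refractory period (−8 on
  the log-rate scale) and a ~15-ms relative refractory tail, and a
  threshold giving ~5 spikes/s under the high-contrast protocol.

Nonlinearity knot grids span ±5 times the canonical generator-signal SD
under the high-contrast protocol (≈1.2 for a unit-norm kernel driven at
contrast 0.3 through the 30-Hz band; the band-limited stimulus is
temporally correlated, which is why this exceeds the raw stimulus SD).

The stimulus generator reproduces the experimental protocols: Gaussian
noise sharply truncated above 30 Hz in the Fourier domain (exactly
band-limited, which sidesteps any assumption about the pre-filter
generation rate), rescaled per block to SD = 0.3 (high contrast) or 0.1
(low contrast) times the mean, alternating every 10-s cycle, with the
last 3 s of each cycle frozen and repeated across cycles of the same
contrast. The repeated waveform shape is shared between contrasts and
scaled to each contrast's SD, mirroring the contrast-scaling logic of
the protocol; whether the original repeated segments were shared across
contrasts is not documented, and this choice makes the contrast
comparison a pure gain comparison. The spot/annulus protocol draws
independent Gaussian values per channel at a 60-Hz update rate with
sample-and-hold interpolation.

What the generator does *not* emulate: photoreceptor adaptation and
slow drift, cell-to-cell variability of kernels and nonlinearities,
non-Poisson spiking noise, and recording artifacts. Passing recovery
tests therefore demonstrates estimator correctness under the model
class and protocol, not robustness to every feature of real data.

## Evaluation statistics

* **Predictive power** — the fraction of *explainable* variance
  captured: $\rho^2(\hat{c}, \bar{y}) \cdot Var(\bar{y}) / \hat{V}_{sig}$
  with $\hat{V}_{sig} = Var(\bar{y}) - \hat\sigma^2_{noise}/n$ estimated
  from between- versus within-trial variance. The exact noise-correction
  estimator is a package choice (the correlation-ratio form), documented
  here because the literature contains several variants; an ideal
  prediction scores 1 regardless of trial count.
* **Coherence** — per-trial magnitude-squared coherence between
  prediction and response, Welch-estimated with 1-s Hann windows at 50%
  overlap and averaged over trials; the noise-corrected bound replaces
  the prediction by the leave-one-out trial mean. Estimates lie in
  [0, 1] by construction.
* **Contrast adaptation** — per-contrast LN analysis with the filter
  from whitened reverse correlation (spectral division stabilized by a
  1e-3 ridge and restricted to the 30-Hz stimulus band), nonlinearities
  aligned by a joint x-scale/y-offset, the scale folded into the
  low-contrast filter; contrast gain is the LC/HC ratio of filter SDs.
* **Event analysis** — events are silences ≥ 8 ms in the pooled 1-ms
  PSTH (raw binning, no smoothing), recursively split when a
  two-component Gaussian mixture (deterministic EM, initialized at the
  25th/75th percentile spike times, recursion depth ≤ 3) finds means
  more than twice the summed component SDs apart; component SDs are
  floored at the bin width so perfectly stereotyped trains do not split
  without limit. Boundaries are midpoints between event centers; events
  with spikes on ≤ 50% of trials are excluded; low-contrast responses
  are scored inside the high-contrast windows. First-spike statistics
  use only trials containing a spike in the window.
* **Covariance analysis** — one code path serves spike-triggered and
  current-weighted moments. With usable nonzero-mean weights the
  weighted moments are normalized by total weight (exactly classical
  STC for counts); for zero-mean weights the covariance difference is
  computed with centered weights at $1/T$ scaling. Eigenvalue
  significance, when requested, uses circularly-shifted response
  surrogates (the original analyses identified significant eigenvalues
  by inspection, so the surrogate band is a package choice).

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data
at desk scale: current-model recovery uses ~80 s of the switching
protocol at SNR 10 (4 cycles per contrast, versus 10 in the full
protocol), spiking fits use ~200–300 s at ~5 spikes/s, and the
LNK-to-DivS analysis uses ~70 s of high-contrast stimulation per seed —
sizes chosen so each fit completes in about a minute while leaving
recovery accuracy comfortably inside the acceptance bands. All
randomness flows through explicit integer seeds; the same seed
reproduces stimuli, recordings and fits bit-for-bit.

## Known limitations

* The suppressive-delay summary uses the lag of the absolute kernel
  peak; for kernels with flat peaks this is ill-conditioned, and the
  recovery harness therefore uses sharp-peaked canonical kernels.
* The 2-D model's joint filter refinement can stall in shallow regions
  of the nonconvex objective; the DivS-initialized default has been
  reliable in recovery tests, but multi-start is available.
* LNK rate constants are only weakly identified from short recordings
  when depression is weak; recovery to ±20% needs depression clearly
  engaged (as in the canonical ground truth).
* Spiking models use Poisson emission per 1-ms bin; bursting beyond one
  spike per bin is represented by counts, and within-bin spike times are
  spread evenly when trains are exported.
* The extended spot/annulus LNK variants are simulation-only, as their
  parameters are not tractably identifiable from data of this kind.
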