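---
title: "Depth profiling and trial-aligned sequence statistics for deep two-photon calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth profiling and trial-aligned sequence statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(deepcalseq)
```

## The problem

Two-photon calcium imaging of deep brain areas (≳ 900 µm below the cortical
surface) is limited by scattering and refractive-index mismatch.  One
strategy is to *underfill* the back aperture of a high-NA objective with a
narrowed laser beam: the effective excitation NA drops (shorter light path,
less aberration) while the full aperture still collects emitted
fluorescence.  `deepcalseq` implements, with seeded synthetic data in place
of raw recordings, the quantitative analysis that accompanies this
approach:

1. **Optics** — closed-form effective NA, a cranial-window clipping bound,
   and laser pulse energy.
2. **Image-quality depth profiling** — per-plane signal from the brightest
   pixel fraction and circular-Hough soma counting, as functions of depth.
3. **Trace statistics for periodic-reward conditioning** — ΔF/F
   detrending, lick-gated trial alignment, ridge-to-background sequence
   statistics against circular-shift nulls, split-half peak-time
   stability, cross-area permutation tests, and behavioural metrics.

## Optics

For an objective of numerical aperture $\mathrm{NA}_{\mathrm{obj}}$ with
back-aperture diameter $\phi_{BA}$ illuminated by a beam of $1/e^2$ width
$\phi_{\mathrm{Beam}}$,

$$\mathrm{NA}_{\mathrm{eff}} \;=\; \mathrm{NA}_{\mathrm{obj}} \cdot
\frac{\min(\phi_{\mathrm{Beam}}, \phi_{BA})}{\phi_{BA}},$$

the plain diameter ratio with no Gaussian-truncation correction; overfilled
beams are clamped rather than rejected.  A focus at depth $d$ below a
window of clear radius $r$ in immersion medium of index $n$ is unclipped
when $\mathrm{NA}_{\mathrm{eff}} < n \sin(\arctan(r/d))$.  Pulse energy is
average power over repetition rate.  All three are reported at full
precision; rounding (2 d.p. for NA, 1 d.p. for nJ, half *up* — base R
`round()` is half-even) happens only in the reporting layer.

```{r}
optics_report(optical_config())
```

## Image-quality metrics

`bright_signal()` is the mean of the brightest 0.1% of pixels in a plane —
a signal measure robust to the sparse spatial coverage of labelled somata.
`detect_circles()` is a circular Hough transform over integer radii 6–12 px
(≈ somatic radii at ~1 µm/px): image gradients vote one radius inward
along the gradient direction, each radius slice is box-smoothed, and peaks
above `sensitivity` × the global accumulator maximum are accepted greedily
with a minimum centre separation of `r_min`.  Design notes:

* The reference implementation in the original analysis was a black-box
  toolbox routine; this contract (gradient voting, integer radii,
  relative threshold, NMS) is fixed so behaviour is testable.
* No per-radius normalisation is applied: vote mass grows with the
  perimeter, but angular discretisation spreads it over an area that grows
  proportionally, so peak heights are naturally comparable across radii
  (verified on planted discs).
* The threshold is *relative to the plane's own maximum*, so detection is
  contrast-based: on noise-free attenuated volumes recall stays flat with
  depth, and it is noise, not attenuation alone, that makes deep-plane
  detection fail — the qualitative shape of the depth-count profiles.
* The default `sensitivity = 0.5` was tuned on synthetic disc fixtures
  (20 planted discs: recall 1.0, 0 false positives) — the upstream
  parameter is unpublished.

`profile_fwhm()` measures the full width at half maximum of a bead or soma
intensity profile with the baseline at the profile *minimum* (in vivo
profiles carry background) and linear interpolation at the two crossings.
`roi_intensity_ratio()` is the treated/contralateral mean-intensity ratio
used for immunoreactivity comparisons.

## Trace conditioning

Raw 30 Hz traces are three-frame averaged to a 10 Hz working rate
(`block_average()`), then detrended (`percentile_detrend()`): the baseline
$F_0(t)$ is the 8th percentile of the raw trace in a ±30 s window around
$t$ (truncated at the session edges — reflection would fabricate data),
and $\Delta F/F = (F - F_0)/F_0$.  Percentiles interpolate linearly
between order statistics (the `stats::quantile()` type-7 convention),
fixed so oracle tests can assert exact equality; the sliding window is
implemented in C++ with the same arithmetic bit for bit.

`align_trials()` keeps deliveries with at least one lick within 2 s and
extracts −10 s to +10 s of ΔF/F per neuron, giving a neurons × trials ×
frames tensor on a bin-centre time axis symmetric about 0 (−9.95 … +9.95 s
at 10 Hz); time 0 maps to the first frame whose centre is at or after the
delivery.  Deliveries whose window leaves the recording are dropped with a
warning.  Peak times come from trial-averaged traces with ties broken
toward the earliest frame; min–max normalisation (used for raster
displays, a choice — the original normalisation is unpublished) never
moves the argmax.

## Sequence statistics

For each neuron the **ridge** ΔF/F is the mean over a 12-frame (1.2 s)
window containing the trial-averaged peak — 6 frames before through 5
after, shifted to the nearest fully in-range window at the edges
(deterministic and length-preserving) — and the **background** is the mean
of all other frames; their ratio measures how concentrated activity is at
the preferred time.  Neurons with non-positive background are excluded
from ratio distributions and flagged.

The null model (`circular_shuffle()`) rotates each neuron's trace in each
trial by an independent uniform whole-frame offset before averaging —
whether the original analysis shifted neurons jointly per trial is
unpublished; independent shifts are the default here and a common-shift
variant would be a one-line change in the shift matrix.  The shuffled peak
is recomputed from the shuffled average, not inherited.
`sequence_test()` compares original and shuffled ratio distributions
across neurons with a two-tailed Wilcoxon rank-sum test.

### Calibration of the circular-shift null

The circular-shift construction tests the hypothesis that trial content
has no consistent phase relative to the delivery *and is statistically
invariant to circular rotation of the 20 s cycle*.  Two departures from
this null matter in practice, and both are visible in simulation:

* If transients live on *linear* session time, the tiling trial windows
  are not circularly exchangeable: a transient's tail that leaves one
  window enters the next window's start, while a rotated trial wraps it
  within the same window.  This edge asymmetry makes the test
  anticonservative (≈ 9–19% rejections at α = 0.05 depending on how much
  mass crosses window edges).
* Under exact cyclostationarity the test is slightly *conservative*
  (≈ 2–4%): original and shuffled averages share each trial's sub-frame
  bump phase, which positively correlates the two ratio samples that the
  rank-sum treats as independent.

The synthetic generator therefore confines each transient to its own 20 s
delivery cycle (wrapping at the cycle boundary), so that "untuned"
corresponds exactly to the null-hypothesis class of the statistic.  The
residual coupling introduced by the ±30 s detrending window (the baseline
sees neighbouring cycles) keeps measured type-I error slightly above the
nominal 5% — a genuine, documented property of the method rather than a
bug.  A green calibration test therefore establishes calibration under
the cyclostationary null with realistic detrending, not robustness to
arbitrary non-stationary backgrounds.

`peak_time_histogram()` bins peak times into left-closed 0.5 s bins over
[−10, 10); `peak_fraction_in_interval()` summarises peak composition
(e.g. the fraction peaking in the 5 s after delivery);
`window_ridge_analysis()` repeats the sequence test within 5 s pre-reward
windows, either two disjoint windows or a 1 s-stride sliding version
(unpublished upstream; both are provided, disjoint by default).

## Stability statistics

`split_half_peak_correlation()` randomly halves the trials (sizes
differing by at most one when odd), subsamples 50 neurons (the fixed panel
that removes population-size differences between areas), trial-averages
each half, and correlates the two sets of peak times; 1000 repetitions
give a resampling distribution whose 2.5–97.5 percentile range is the 95%
CI, and `ci_low > 0` is the verdict that peak timing is reproducible
across trials.  Peak times are taken on unnormalised averages
(normalisation cannot move the argmax).

`area_stability_permutation()` compares two areas' mean split-half
correlations.  Within each permutation the reassigned areas are evaluated
from a *single* fresh split with their full memberships — the quoted
procedure mentions no subsampling inside the permutation loop, so none is
applied (a `subsample` argument exposes the alternative).  The observed
per-area means use `n_obs_reps` (default 1000) splits from identically
seeded streams, so identical inputs give an observed difference of
exactly zero.  The tail probability is Bonferroni-scaled by the number of
area pairings (default 3).  Both areas must share the trial count — the
original analysis pooled sessions of differing lengths, which cannot be
reproduced without the raw recordings.

## The synthetic world

`simulate_session()` states the recording conditions the analysis assumes;
these defaults are fixed and are not adjusted per experiment:

| parameter | default | rationale |
|---|---|---|
| neurons, trials | 100, 30 | typical field sizes (~65–80 active neurons/field) and a 10-min block of 20 s trials |
| frame rate | 30 Hz → 10 Hz | resonant scanning with three-frame averaging |
| calcium kernel | 0.1 s rise, 1.0 s decay | red-GECI-like kinetics; unpublished upstream, documented default |
| tuned fractions | 30% pre-reward; remainder 5:2 early/late post-reward | the observed peak-time composition (≈50% within 5 s post-reward, ≈30% pre-reward), planted by exact counts so the composition is not a sampling variable |
| tuning width / jitter | 1 s / 0.5 s | transient-scale bumps with sub-second trial reliability |
| baseline, drift, noise | 100 a.u.; 10% sinusoid (300 s) + 5% linear; σ = 2 a.u. | slow drift sized to exercise the ±30 s detrend; ~2% noise |
| licking | lognormal latency, median 230 ms; 1% misses; ~7 Hz bursts | matches reported reaction times (~220–270 ms) and response rates (~99%) |

Each neuron's response template (Gaussian bump convolved with the calcium
kernel) is peak-aligned so that the planted preferred time *is* the peak
of the noiseless response; without this the kernel's causal lag (~0.3 s)
would bias every recovered peak.  Transients are confined to their
delivery cycle as discussed above.  All randomness flows from one seed
through named sub-streams (tuning, jitter, noise, behaviour, drift), so
outputs are bit-identical under a fixed seed.

What the generator does **not** emulate: motion artifacts, neuropil
contamination, overlapping sources, bursty multi-event trials,
non-Gaussian noise, session-to-session drift.  Green end-to-end tests
therefore establish internal consistency of the statistics on a clean
world, not robustness to extraction artefacts.

`simulate_volume()` renders non-overlapping spherical somata (radii
6–12 px) with depth attenuation $e^{-d/\ell}$ on a constant background
plus Gaussian noise; `simulate_disc_plane()` is the 2-D variant used to
validate the detector.

## Numerical choices

* Percentile convention: linear interpolation (type 7), exact-match
  tested against `stats::quantile()`.
* Window truncation (never reflection) at session edges.
* Peak ties break toward the earliest frame; `max.col(ties = "first")`.
* Ridge window at trace edges shifts to the nearest fully in-range
  position rather than shrinking, keeping the frame count constant.
* Brightest-fraction count `k = max(1, floor(fraction × n))`; ties at the
  k-th value resolved by taking exactly k sorted values.
* Degenerate cases: constant averaged traces have undefined peaks (`NA`),
  non-positive backgrounds yield `NA` ratios, and both are flagged rather
  than silently dropped.
* Sub-seeds are derived arithmetically from the user seed (< 2³¹), one
  stream per stochastic component.

## Limitations

* The cross-area permutation requires equal trial counts; pooling across
  sessions of different lengths is out of scope.
* The circular-shift null is mildly miscalibrated for non-cyclostationary
  backgrounds (see above); interpret borderline p-values accordingly.
* TIFF I/O is not provided in this environment; stacks are in-memory
  arrays (`image_stack()`), and all tabular interchange is CSV/JSON.
* The Hough detector targets bright filled discs; rings, vessels and
  dendrites are out of scope.

## A complete run

```{r, eval = FALSE}
sim <- simulate_session(session_params(rng_seed = 1))
dff <- sim$traces |> block_average() |> percentile_detrend()
tensor <- align_trials(dff, sim$events)
st <- sequence_test(tensor, rng_seed = 1)
glance(st)
autoplot(trial_average(tensor, normalize = TRUE))
```

or, file-based and manifest-tracked:

```{r, eval = FALSE}
run_workflow(list(workflow = "conditioning", rng_seed = 1), "results/run1")
```
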