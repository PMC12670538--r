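---
title: "Methods: permutation-band inference, learning stages, and 4 Hz synchronization in T-maze electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-band inference, learning stages, and 4 Hz synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striosync)
```

## The scientific setting

`striosync` analyzes chronic multi-region extracellular recordings from
rats learning a T-maze visual discrimination. In the task, a rat enters a
wide central "judgment zone", sees monitors lit white (Stim 1, left arm
rewarded) or black (Stim 2, right arm rewarded), and commits to an arm;
its head position, spike-sorted units from the posterior striatum (pStr),
visual thalamus (dLGN) and visual cortex (VC), and the three regions'
local field potentials (LFPs, 1250 Hz) are recorded throughout. The
analyses the package implements address four linked questions:

1. **Behavior.** How does performance evolve (success rate, reaction
   time), where does the left/right trajectory bifurcation — the
   *judgment point* — occur, and how can sessions be partitioned into
   early/middle/late learning stages in an unsupervised way?
2. **Units.** Which units are regular-spiking (RS, putative medium spiny
   neurons) versus fast-spiking (FS, putative interneurons); how do their
   occupancy-normalized rate maps over the judgment zone depend on the
   stimulus and on position (spatial information in bits/spike); and how
   do population averages change across stages?
3. **LFP.** How strong are the two prominent low-frequency rhythms — the
   4 Hz band (2–5 Hz) and theta (6–10 Hz) — within and between regions
   (Morlet wavelet power and wavelet coherence), and how does band
   amplitude relate to running speed (Kendall's tau)?
4. **Phase locking.** Are unit spikes entrained by the band-limited
   oscillations (Rayleigh test on Hilbert phases), with what preferred
   phase, and how does the locked fraction evolve across stages
   (Clopper–Pearson intervals, Kolmogorov–Smirnov contrasts of log Z)?

Real recordings are not required: a synthetic-session generator with
fully known ground truth exercises every estimator end to end.

## The core inferential engine: permutation bands for curve families

Almost every comparison in the pipeline reduces to: *do two families of
curves on a common position grid differ, and where?* Left- versus
right-choice lateral trajectories define the judgment point; Stim 1
versus Stim 2 per-trial rate curves define stimulus selectivity; early
versus late unit populations define the learning contrast.

`band_permutation_test()` implements the label-permutation test:

* The observed statistic per grid position is the difference of condition
  means.
* Condition labels are permuted over trials (5000 permutations by
  default; the observed labeling is always a member of the null set, so
  Monte-Carlo p-values are `(1 + b)/(1 + n_perm)`).
* The **pointwise band** at level $\alpha$ is the per-position pair of
  empirical order statistics at ranks $\lfloor m\alpha/2 \rfloor$ from
  either end of the null sample, with ties broken toward the wider band.
* The **global band** corrects for multiplicity over positions: the band
  rank $k$ is lowered (widening the band) until the fraction of null
  datasets exceeding the band *anywhere* is at most $\alpha$. Because the
  null sample is discrete, the exact 5% level is generally not
  attainable; the largest achievable level $\le \alpha$ is used and
  reported as `global_alpha_achieved` rather than pretending the nominal
  level was met.

Two numerical points deserve emphasis. First, the familywise exceedance
of the rank-$k$ band is computed via per-column *depths* (the rank
distance of each null value from its column's nearest extreme); a dataset
exceeds the band at rank $k$ iff its minimal depth over positions is
$\le k$, which makes the scan over $k$ exact and cheap. Second, the
discreteness has a practical floor: with $m$ null samples and roughly
$P_{\mathrm{eff}}$ effectively independent positions, even the widest
nontrivial band (the null extremes) has familywise level about
$2P_{\mathrm{eff}}/m$. With 50 bins of *independent* noise and
$m = 1000$ that floor is ~10% and the global band degenerates to "never
significant" (type-I error 0, maximally conservative). Real trajectory
and rate curves are smooth, so $P_{\mathrm{eff}}$ is small and the 5%
level is attainable; tests that need the global band therefore use
realistic smooth curves and permutation counts of 1000 or more.

`first_divergence()` turns the global significance mask into a judgment
point: the earliest position whose significant run lasts at least
`k_run = 3` contiguous bins (the run-length guard suppresses isolated
single-bin exceedances; the source analyses do not state a value, so it
is exposed as configuration).

For families with at most a few hundred thousand label assignments,
`exhaustive_null()` enumerates the complete null set; the test suite
verifies the Monte-Carlo engine against it exactly on every family with
up to 9 trials (e.g. the 4-vs-4 constant-separation case has two-sided
pointwise p exactly $2/70 \approx 0.0286$).

## Behavior

Reaction time is the latency from judgment-zone entry to reward-port
arrival; running speed is the per-step travel distance over time,
smoothed with a Gaussian kernel of 2 samples. Normalized distance maps
the judgment zone to $[0,1]$ over 50 half-open bins (the last closed).

Learning stages are found by Ward-linkage hierarchical clustering
(Euclidean distance) of session *sets* — disjoint consecutive triplets by
default, sliding windows by option — on two features: success rate and
reaction time. Two design choices are deliberately explicit:

* **Feature standardization** (on by default): a proportion and a time in
  seconds are incommensurate; z-scoring prevents the larger-variance
  feature from dominating the metric. The flag is exposed because the
  choice is substantive.
* **Stage labels are assigned behaviorally**, not from dendrogram order:
  the cluster with the slowest mean reaction time is `early`, the fastest
  `late`. Dendrogram leaf order is arbitrary and would make labels
  seed-dependent.

Reaction-time distributions symmetrize as learning progresses;
`sample_skewness()` (moment skewness $g_1 = m_3/m_2^{3/2}$) and
`dagostino_skew_test()` (the D'Agostino 1970 normalizing transformation,
verified in the tests against an independent implementation) quantify
this.

## Unit characterization

Spike width is the contiguous time around the waveform trough during
which the voltage stays more than one third of the trough-to-peak
amplitude below the pre-trough baseline. The two threshold crossings are
located by linear sub-sample interpolation, which makes the measure exact
on piecewise-linear waveforms (a symmetric triangular trough of 0.6 ms
yields exactly 0.4 ms by similar triangles) and invariant to amplitude
scaling. Classification is rule-based with exposed boundaries
(defaults: width 0.55 ms, rate 2 Hz, long-ISI proportion 0.05): narrow
and fast is FS; broad and rarely pausing — a striatal signature, so the
rule applies only to pStr units — is TAN, pooled into FS by default
(TAN counts are too small to analyze separately); everything else is RS.
The boundaries are free parameters calibrated on the synthetic
population, since printed boundaries are not available.

Rate maps divide in-zone spike counts by occupancy time per
normalized-distance bin, per stimulus condition; the identity
`rate × occupancy = count` holds exactly per bin, and zero-occupancy bins
are flagged rather than imputed. Spikes are assigned to the animal's bin
at spike time via the nearest tracking sample. Spatial information uses
the occupancy-weighted per-spike (Skaggs-type) form
$I = \sum_i p_i (\lambda_i/\bar\lambda)\log_2(\lambda_i/\bar\lambda)$ —
the standard quantity carrying the printed unit bits/spike; it is zero
iff the rate is constant over occupied bins and invariant under uniform
rate rescaling. A unit is *stimulus selective* when any position of its
Stim 1 vs Stim 2 per-trial rate-curve comparison is significant under the
**globally corrected** band (the familywise-safe mask; the pointwise mask
is also returned, since the family of maps a reader might want differs by
use).

## LFP spectral analysis

Band-limited signals come from zero-phase (forward–backward) order-3
Butterworth filters at 2–5 Hz and 6–10 Hz, with instantaneous phase and
envelope from the analytic signal. The phase convention is
cosine-referenced — 0° at the oscillation peak, 180° at the trough — and
every preferred-phase number in the package inherits it.

Wavelet power uses the Morlet continuous transform with
center-frequency parameter $\omega_0 = 6$ in the Torrence–Compo
normalization, under which white-noise expected power is flat across
scales (verified in the tests to within 20%). Cells inside the
edge cone of influence (e-folding distance $\sqrt 2\,s$ at scale $s$) are
masked from all band means.

Wavelet magnitude-squared coherence smooths the cross- and auto-spectra
with a Gaussian over time (SD = 8 wavelet scales) and a 5-point boxcar
over adjacent scales (grid spacing 0.5 Hz). The smoothing width is the
key accuracy knob: a magnitude-squared coherence estimator's bias at true
coherence $c$ is roughly $(1-c)^2/\nu$ for $\nu$ effective independent
samples, so narrow smoothing inflates low coherences badly. The defaults
were chosen so the no-coherence floor sits near 0.05 on ten-minute
traces — comfortably inside the ±0.1 recovery tolerance the tests
enforce at targets 0 and 0.6 — at the cost of temporal resolution
(≈2 s at 4 Hz); both knobs are exposed. Analyses at these frequencies
decimate the 1250 Hz traces tenfold first (anti-aliased), which changes
nothing below 10 Hz and makes the transform cheap. Coherence estimates
are clipped to $[0,1]$, and symmetric in the two traces by construction.

Position alignment averages any per-sample quantity into
normalized-distance bins weighting each tracking sample equally (i.e. by
occupancy time), which makes profiles invariant to running speed.
Amplitude–speed association uses Kendall's tau-b on both series
block-averaged to a common 10 Hz.

## Spike–LFP phase locking

Spike phases are nearest-sample lookups on the Hilbert phase, restricted
by default to judgment-zone traversals (the decision context of the
synchronization analyses); a whole-session option exists because the
sampling epoch is a substantive choice. The Rayleigh statistic is
$Z = R^2/n$ with $R$ the resultant length of the unit phase vectors, with
the standard approximation
$p = \exp\{\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\}$; units with fewer
than 50 in-epoch spikes are reported but flagged unreliable (no minimum
is printed in the source analyses; 50 is this package's default and is
recorded in outputs). Population summaries report the locked fraction
per stage with exact Clopper–Pearson 95% intervals, pairwise
Kolmogorov–Smirnov contrasts of the variance-stabilized $\log Z$, and
preferred-phase histograms normalized per unit to maximum 1.

A subtle validity point, checked by simulation in the acceptance tests:
spike phases sampled from a *stochastic* narrowband oscillation are
uniform only asymptotically, so the Rayleigh test's false-positive rate
on oscillation-independent (homogeneous Poisson) spikes is verified
empirically to stay at the nominal 5% under the study conditions.

## The synthetic-session generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses assume.

* **Behavior.** About 29 sessions of 60 trials; per-session success
  probability rising sigmoidally 0.5 → 0.95 and mean zone-traversal time
  falling 2.8 → 1.2 s (reaction times then span roughly 4.5 → 1.9 s,
  matching the scale of the task's learning curves). Trial-to-trial
  traversal durations are log-normal with CV 0.18, the printed
  across-traversal variability (17.7%). The judgment zone is 100 maze
  units; left/right trajectories coincide up to the programmed
  bifurcation (default 0.5 normalized distance) and diverge linearly to
  ±25 units afterwards. Lateral tracking noise (SD 1.5 units) is
  temporally smoothed (120 ms kernel) because camera-tracked head
  position is low-pass, not white — this also matters statistically:
  white positional noise would make adjacent distance bins independent
  and push the global band's discreteness floor above 5%.
* **LFP.** Each region is a sum of narrowband processes — white noise
  band-passed to 2–5 Hz and 6–10 Hz (order-3 Butterworth, zero phase) so
  that phase and coherence estimates are nondegenerate, unlike pure
  sinusoids — plus broadband white noise. The 2–5 Hz component mixes a
  shared source with a private one; mixing weights are solved in closed
  form so each pair's asymptotic in-band coherence equals its target,
  with a correction for the white-noise power falling inside the band.
  Infeasible target patterns (e.g. two strongly coherent pairs with the
  third forced to zero, or a target of exactly 1.0 with nonzero noise)
  are rejected with an explanatory error — a coherence of 1.0 is only
  realizable with zero private and noise power. Theta amplitude is
  modulated by running speed (gain 0.02 per unit speed), giving the
  positive theta–speed and near-zero 4 Hz–speed Kendall correlations the
  analyses expect.
* **Spikes.** Each unit is an inhomogeneous point process simulated by
  thinning (exact for time-varying intensity):
  $\lambda(t) = r_0\,\mathrm{tuning}(d(t))\,\mathrm{stimgain}\,
  e^{\kappa\cos(\varphi(t)-\varphi_0)}/I_0(\kappa)$, with Gaussian
  position tuning and stimulus gain active inside the zone and the von
  Mises factor normalized so mean rate is preserved under uniform phase.
  Default RS rates are below 2 Hz and FS rates 6–15 Hz, the realistic
  striatal ranges (this matters for the long-ISI TAN rule, which would
  misfire on implausibly fast "RS" units). Mean waveforms are synthesized
  with class-dependent trough widths (≈0.9 ms RS, ≈0.25 ms FS) so the
  width classifier recovers the class. An intensity ceiling (500 Hz)
  rejects mis-set gains.

What the generator does **not** emulate: 1/f background spectra and
nonstationary artifacts of real LFP (its noise floor is a free parameter,
not a claim about the recordings), electrode drift, spike-sorting errors,
bursting/refractory ISI structure, and behavioral idiosyncrasies such as
mid-zone pauses. Green tests therefore demonstrate estimator correctness
under the stated generative assumptions, not robustness to everything
real data can do.

## Session store and pipeline

The session container holds trials, tracking, units (spike times + mean
waveform) and per-region LFP on a single session clock. It is persisted
as a plain-text directory (YAML metadata, CSV arrays written with 17
significant digits, so a write/read round trip is bit-exact); the schema
validator reports every failing field at once. `run_pipeline()` executes
behavior → stages → units → lfp → phase with dependency checks before any
computation, stamps every CSV with the configuration hash and seed, and
is deterministic: identical inputs, config and seed give hash-identical
report bundles. A seed is mandatory in batch mode.

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use sizes chosen to make
each property measurable with comfortable statistical margins while
keeping a full run convenient on a laptop: 500 null datasets at 1000
permutations for familywise calibration; 100 forty-trial sessions for
judgment-point recovery; 300–500 synthetic units for Rayleigh
calibration; ten-minute traces for coherence recovery and eight synthetic
subjects for the stage contrast; 60 units for classification recovery.
These are the package's own choices of simulation scale.

## Known limitations

* The wavelet-coherence defaults trade temporal resolution for low bias;
  analyses needing sharp event-locked coherence should narrow the
  smoothing and accept the higher floor (and interpret low-coherence
  values accordingly).
* The global band's achievable level is discrete in `n_perm`; with few
  permutations or many independent positions it degenerates to a
  maximally conservative (never-significant) band — the achieved level is
  always reported so this is visible.
* `stage_comparison()` reproduces an ANOVA-gated rank-test reporting
  scheme without any further multiple-testing correction, by design.
* The TAN rule is a heuristic on pause structure; genuinely bursty RS
  units with pathologically regular firing would be pooled into FS.
* Phase conventions matter: all preferred phases are cosine-referenced
  (0° = peak). Comparing against sine-referenced numbers requires a 90°
  shift.
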