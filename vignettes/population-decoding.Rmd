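---
title: "Population decoding and state-dependent geometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding and state-dependent geometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popshift)
```

## The problem

In a Go/No-Go click-rate discrimination task, an animal licks a water spout
through *reference* click trains and must stop licking after a *target*
click train. Each trial follows a fixed timeline: 0.4 s of silence, a
1.25 s neutral broadband noise (TORC), a 0.75 s click train, and a 0.8 s
post-stimulus silence containing the behavioral response window. The same
stimuli are presented passively (no behavioral contingency) and during task
engagement, while populations of cortical units are recorded.

`popshift` implements the population-level analysis chain for such data:
single-unit phase-locking metrics, linear stimulus reconstruction,
prototype-based population decoding of reference vs target with
pseudo-population cross-validation, the projection geometry that separates
baseline shifts from evoked-pattern changes between behavioral states, and
a motor-confound control that removes lick-responsive units. Because
recordings of this kind are rarely deposited, the package also ships a
synthetic-session generator that plants each of these structures with known
ground truth, so the full pipeline is testable end to end.

## Data model

Event tables (spikes, stimulus clicks, licks) are seconds relative to trial
onset; `session_data()` validates them against an `epoch_template()`
(contiguous, non-overlapping epochs; clicks confined to the click-train
epoch). `bin_spikes()` produces a units x trials x bins tensor of rates in
spikes/s. Bins are half-open `[start, start + width)` and a spike exactly
on a boundary belongs to the later bin; this makes binning deterministic
and conserves spike counts exactly when `step = width`. Decoding uses
100 ms non-overlapping bins; reconstruction uses 10 ms bins on a finer step
lattice (overlapping bins are supported for that reason).

## Single-unit metrics

*Vector strength* is the resultant length of spike phases relative to the
click period, `VS = |Σ exp(iθ_j)|/n` with
`θ_j = 2π((t_j − onset) mod P)/P`: 1 for perfect locking, ~0 for uniform
phases. Significance uses the large-sample Rayleigh approximation
`p = exp(−n·VS²)` with the conventional `p < 0.001` criterion, and
`vs_table()` applies the 1 spikes/s within-epoch inclusion floor. An empty
spike train yields an explicitly undefined result rather than `VS = 0`,
because "no evidence of locking" and "evidence of no locking" must not be
conflated downstream.

The *modulation index* `MI = (X₁ − X₂)/(X₁ + X₂)` compares any
non-negative quantity between two conditions. The package fixes the
argument order as (engaged, passive) everywhere, so positive values always
mean "larger when engaged"; the index is flagged undefined when both
inputs are zero. The behavioral *discrimination ratio* is
`DR = HR × (1 − FA)`; the click-task training criterion corresponds to
`DR(0.8, 0.2) = 0.64`.

## Linear stimulus reconstruction

The reconstruction stage assumes a linear mapping from lagged population
rates to a stimulus signal,

S(t) = Σᵢ Σ_δ gᵢ(δ) · rᵢ(t + δ),  δ = 0…τ,

estimated by least squares over training trials through the normal
equations `G = (Σₖ Sₖ Rₖᵀ)(Σₖ Rₖ Rₖᵀ)⁻¹`, where `Rₖ` stacks each unit's
(τ+1) lag rows. Before inversion, the autocorrelation matrix is
eigendecomposed and truncated: at most `rank_cap` components are kept
(default 70, the empirical cap for this recording scale), and components
below `1e-10` of the leading eigenvalue are always dropped — the numerical
floor the cap alone does not provide. Degenerate designs therefore resolve
to the minimum-norm (pseudo-inverse) solution, which the tests verify
against an independent Moore–Penrose oracle.

Choices this method family leaves open, fixed here:

* **Lag span τ**: 100 ms by default (configurable). Click-evoked cortical
  latencies fall well inside this span.
* **Target signal**: the stimulus waveform is represented as a boxcar of
  `kernel_width` (10 ms default) after each event, matching the response
  binning resolution; clicks and licks use the same representation.
* **No intercept**: the linear model has none, so signals are
  reconstructed about zero.
* **Evaluation**: strictly leave-one-trial-out (`loo_reconstruction_mse()`),
  one filter per (state, stimulus) cell per session, scored by MSE, with
  units below a 2 spikes/s spontaneous-rate floor excluded. The
  engaged-vs-passive error change is summarized as MI(engaged, passive),
  so degraded encoding when engaged appears as positive MI.

## Population decoding

Pseudo-population vectors pair trials of different units at random
(`pseudo_population()`, `assemble_pseudo_population()`), which destroys
noise correlations by construction — a feature of the method, not a bug:
the decoder measures the information available in the mean population
geometry. Per resample, 15 trials per class per unit train the prototype
decoder

w = c_T − c_R,  b = −((c_R + c_T)·w)/2,  y(x) = w·x + b,

and all remaining trials, subsampled to the largest balanced size
available to every unit, are tested. The decision tie `y(x) = 0` is
resolved to "reference" for determinism; under continuous noise it has
measure zero. Cross-validation redraws train *and* test sets 400 times by
default; spread is reported both as 1 standard deviation (error bars) and
a 95% percentile interval (significance statements), and p-values derived
from the resamples are floored at `1/400 = 0.0025`.

Chance is calibrated by label shuffling within each unit (class counts
preserved): 100 permutations, each cross-validated 100 times. The
empirical p-value uses the add-one form `(1 + #{null ≥ obs})/(1 + n_perm)`
— a raw exceedance count can report an impossible `p = 0`, so the
corrected form is reported alongside the count. Temporal generalization
trains on the window-averaged rates of one epoch and tests at every bin;
`decode_transfer()` applies correct-trial decoders to error-trial
pseudo-vectors.

## Projection geometry

`project_on_axis()` projects trial-averaged class activity, per bin, onto
each stored cross-validation decoding vector. Axes are unit-normalized
first — raw decoding vectors carry arbitrary units, and normalization
makes distances comparable across windows and states. The
spontaneous baseline is each unit's mean rate over the pre-stimulus
silence (0–0.4 s), per state; in the default mode this baseline is
subtracted before projection so the spontaneous point sits at 0 by
construction. Distances from baseline are window means (the bins whose
start lies in the window), the asymmetry index is `d(Targ) − d(Ref)`, and
the target-enhancement index is
`(d(Targ_eng) − d(Targ_pass)) − (d(Ref_eng) − d(Ref_pass))`.

`cross_state_projection()` attributes an engaged asymmetry to one of two
mechanisms by evaluating three evoked/baseline combinations on a fixed
(engaged) axis: if evoked patterns are state-invariant and only the
spontaneous pattern shifts, projecting *passive* evoked activity against
the *engaged* baseline reproduces the engaged picture (case 1 ≈ case 3);
if instead the evoked patterns change over a fixed baseline, case 1 stays
near the passive value. The uniform-weight control replaces the decoder
axis with the normalized all-ones vector: an asymmetry that survives it is
a global rate change, one that vanishes is carried by a specific
population direction. Latency to half-maximum is measured on the
trial-averaged projected trace after a 3-bin boxcar (configurable; there
is no standard smoothing convention), with linear interpolation between
bins.

## Lick-responsive unit removal

Lick features reuse the reconstruction machinery with single-unit designs:
each unit's lagged filter maps its own activity to the lick event signal,
and reconstruction values are sampled at lick times and at an equal number
of random non-lick times (≥ 100 ms from any lick; both the margin and the
count matching are package choices).
Reconstruction here is leave-one-trial-out like the click analysis: fitting
and sampling on the same trials lets the filters overfit, which inflates
the randomized control's accuracy to ~0.58 and masks weak lick units.

Decodability of lick vs non-lick vectors is evaluated per session with the
prototype decoder (split-half resampling) and compared against controls
in which each session's licks are reconstructed from a *different*
session's activity (a circular shift of the session's own trials when only
one session exists). Units are then removed one per step, highest mean
absolute classifier weight first, until the add-one p-value exceeds 0.4. Each step re-evaluates with a reduced resample count
and the retained set gets a final full evaluation. One caveat the
synthetic tests expose: with dense (7 Hz) licking, control times often
coincide with real licks, so the null partially contains a weak lick
unit's own signal; a single high-baseline lick unit in a large session can
therefore remain below the detection floor while every unit that *is*
removed is a true lick unit.

## The synthetic generator

`generate_cohort()` plants, in inhomogeneous-Poisson spike trains at 1 ms
resolution (rectified at zero so planted means stay interpretable):

* log-normal spontaneous rates (meanlog log 4, sdlog 0.5 — a few spikes/s,
  typical of cortical units);
* an engaged baseline shift of magnitude Δ = 6 spikes/s along a unit-norm
  direction `u`, applied in the silent epochs;
* click-epoch evoked patterns: common gain 4 spikes/s plus a class
  contrast of amplitude 20 along a unit-norm direction `v` (reference −,
  target +), temporally shaped by a von Mises kernel at the trial's click
  rate (κ = 5 passive, 2 engaged: locking degrades with engagement);
* a persistent silence code along `v₂ ⟂ v` on target trials only:
  15 spikes/s when engaged and correct, 3 spikes/s passive — and 3 on
  engaged *error* trials, so errors lose the silence code while the sound
  response stays intact;
* a 10% fraction of lick units receiving a Gaussian kernel (amplitude
  10 spikes/s, σ = 20 ms) around each lick; licking is Poisson at 7 Hz,
  gated by the avoidance contingency (stop 0.4 s after target onset on
  correct trials, not on errors; an appetitive mode reverses the rule).

Two modeling choices matter enough to call out. First, the engaged
baseline shift lives in the silent epochs only: during sound the absolute
evoked pattern is state-invariant (stimulus drive clamps the population),
which is precisely the configuration under which the cross-state analysis
must find case 1 ≈ case 3. With `mechanism = "evoked_change"` the
generator instead keeps the baseline fixed and changes the engaged evoked
patterns (reference contrast removed, target boosted), the alternative the
analysis must distinguish. Second, the von Mises kernel is renormalized to
mean 1 within 100 ms blocks: a raw periodic kernel spanning a non-integer
number of cycles rescales the planted class contrast by a state- and
rate-dependent factor, which corrupts the planted geometry; blockwise
normalization makes the planted patterns appear exactly as bin-level rates
while the kernel only shapes spike timing within blocks. Disable it
(`kernel_norm_block = NULL`) when the raw periodic rate profile itself is
wanted, e.g. when checking vector strength against the closed form
I₁(κ)/I₀(κ).

Amplitudes were fixed once from design calculations: with ~60 units,
100 ms bins and these rates, single-bin Poisson noise projects at
σ ≈ 8–9 spikes/s on the decoding axis, so a class separation of 40 gives
sound-window accuracy ≈ Φ(40/18) ≈ 0.99, the silence code gives ≈ 0.88
engaged vs ≈ 0.59 passive, and the baseline shift contributes an engaged
asymmetry increment of ≈ 2Δ·|u·v̂| ≈ 6.5 in projection units, large
against its ≈ 1 estimation noise.

What the generator does **not** emulate: noise correlations (irrelevant to
pseudo-population decoding by construction), spike-history structure
(refractoriness, bursting, adaptation), laminar or cell-type diversity,
acoustic TORC statistics, slow drifts within sessions, and behavioral
variability beyond Poisson licking with fixed latencies. Passing the
planted-recovery tests therefore shows that the analyses recover the
population-geometry structures they target under Poisson variability at
realistic rates — not that real recordings contain those structures.

## Seeds, determinism, problem sizes

All randomness flows from named substreams derived from one master seed
(baselines, trial order, licks, spikes per session; directions per
cohort), so one component can be varied while holding others fixed, and
identical (config, seed) pairs give byte-identical sessions. The test
suite runs the default cohort (3 sessions x 20 units, 40
trials/state/class) for end-to-end checks, 20–30 resamples where only a
mean is needed and the full 400 where the resample floor itself is under
test; null calibration uses reduced permutation counts (15–20). These
sizes are the package's choices for routine verification; every analysis
accepts the full-scale parameters as arguments.

## Known limitations

* The prototype decoder is deliberately the simplest linear classifier —
  its weights are directly interpretable as a population direction; no
  regularized or max-margin alternative is provided.
* Distances and indices inherit a positive bias from projecting onto
  noisy, normalized axes; comparisons are therefore always made between
  conditions evaluated the same way, never against an absolute zero.
* The per-bin accuracy time course treats bins independently; no
  correction for temporal autocorrelation across bins is attempted beyond
  Bonferroni over the tested windows.
* GPFA-style trajectory visualization is out of scope.
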