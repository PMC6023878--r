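# popshift

Population-level analysis of trial-aligned spike recordings from Go/No-Go
auditory discrimination tasks, where an animal licks through *reference*
click trains and must stop after a *target* click train, and the same
stimuli are also presented passively. The scientific question the toolkit
serves: how does task engagement reorganize the population code in sensory
cortex — does the stimulus representation itself change, or does the
spontaneous baseline shift so that behaviorally meaningful stimuli stand
out along the decoding axis?

It is written for electrophysiologists and computational neuroscientists
with trial-structured spike/event tables (unit, trial, time), and for
anyone who wants a fully testable reference implementation of this family
of population analyses.

## What it computes

* **Single-unit metrics** — vector strength `VS = |Σ e^{iθ_j}|/n` of
  click phase locking with Rayleigh significance `p = e^{−n·VS²}`;
  modulation index `MI = (X₁−X₂)/(X₁+X₂)` (argument order fixed as
  engaged, passive); behavioral discrimination ratio `DR = HR·(1−FA)`.
* **Linear stimulus reconstruction** — optimal-prior lagged filters
  `S(t) = Σᵢ Σ_δ gᵢ(δ) rᵢ(t+δ)` fit by least squares with an
  SVD-truncated autocorrelation (component cap 70), evaluated strictly
  leave-one-trial-out.
* **Population decoding** — per-bin prototype classifier
  `w_t = c_{T,t} − c_{R,t}`, `y(x) = w_t·x + b_t`, on balanced
  pseudo-population resamples (15 training trials per class per unit, 400
  cross-validation resamples, label-shuffle null of 100 × 100), plus
  temporal generalization and correct→error transfer.
* **Projection geometry** — population activity projected on the
  (unit-normalized) decoding axes after spontaneous-baseline subtraction;
  asymmetry index `d(Targ) − d(Ref)`, target-enhancement index, and the
  three-way cross-state projection that separates a baseline-shift from
  an evoked-change mechanism.
* **Lick-control** — per-unit lick reconstruction features, lick/no-lick
  decodability against a mismatched-session randomized control, and
  iterative removal of the highest-weight units until decodability is at
  chance (p > 0.4).
* **Synthetic sessions** — `generate_cohort()` plants all of the above
  (baseline shift, class directions, silence code absent on errors, lick
  units, controllable phase locking) in Poisson spike trains with known
  ground truth.

## Worked example

```r
library(popshift)

# a small synthetic cohort: 2 sessions x 15 units, 20 trials/state/class
cfg <- generator_config(n_sessions = 2, n_units = 15, n_trials = 20)
report <- run_full_analysis(cfg, seed = 1,
                            n_resamples = 50, n_perm = 20, n_cv = 20)
print(report)
```

```
analysis_report (config 7601da60, seed 1)
  decoding passive  sound    acc 0.996 (null p = 0.04762)
  decoding passive  silence  acc 0.474 (null p = 0.5714)
  decoding engaged  sound    acc 1.000 (null p = 0.04762)
  decoding engaged  silence  acc 0.860 (null p = 0.04762)
  asymmetry passive  sound -5.97 silence -1.69
  asymmetry engaged  sound -3.75 silence 0.81
  elapsed: 13.1 s
```

Reading the output: the reference/target contrast is decodable during the
sound in both states (≈ 1.0, far above the shuffle null), while the
persistent *silence-window* code is decodable only in the engaged state
(0.86 vs 0.47 passive) — the planted state-dependent structure. The
asymmetry lines give `d(Targ) − d(Ref)` along each state's sound-window
decoding axis: the engaged value exceeds the passive one because the
planted engaged baseline shifts toward the reference-evoked pattern,
pulling the reference projection toward baseline. Null p-values are
add-one corrected, so their floor here is 1/21 ≈ 0.048.

Single values:

```r
discrimination_ratio(0.8, 0.2)$dr
#> [1] 0.64                      # the task's training criterion
v <- vector_strength(c(0.01, 0.052, 0.088, 0.131), period = 0.04)
c(v$r, v$rayleigh_p)
#> VS r = 0.973, n = 4, Rayleigh p = 0.0226
```

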