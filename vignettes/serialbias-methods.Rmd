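---
title: "Methods: bias curves, resampling inference, and the synthetic observer"
author: "serialbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias curves, resampling inference, and the synthetic observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialbias)
```

## The problem

When observers reproduce the orientation of the last Gabor in a short
sequence, their single-trial errors carry the fingerprints of three
distinct history processes:

* **adaptation** — a repulsive shift away from recently exposed
  orientations, attributed to early, retinotopically local sensory
  neurons;
* **representational momentum (RM)** — a forward displacement along the
  implied trajectory when the sequence rotates coherently, i.e. a further
  shift *away* from the previous orientation;
* **serial dependence (SD)** — an attractive pull toward the orientation
  *reported* on the previous trial, a decision-level effect.

The package implements the full analysis chain that separates these
components: blocked Rotational/Random sequence designs, circular error
computation and filtering, a derivative-of-Gaussian (DoG) bias-curve fit,
stratified bootstrap and permutation inference on its amplitude, a
model-free index, and a regression dominance analysis — together with a
synthetic observer so that every stage can be validated by parameter
recovery rather than by trusting the code.

## Conventions

Orientations live on a 180°-periodic circle. All differences are signed
acute angles in (−90°, 90°], computed by `acute_diff(a, b)`; the
orthogonal tie resolves to +90°. The history variable is always

> Δ = previous − present orientation,

and the adjustment error is reported − actual orientation. An error with
the *same* sign as Δ is attraction toward the previous orientation
(positive convention); opposite signs mean repulsion. In this convention
SD is positive, adaptation negative, and RM — a forward displacement —
also registers as negative. (The RM literature uses the inverted sign.)

## The design generator

`design_spec()` encodes the three designs: E1/E2 run 4 blocks × 72
six-stimulus trials with Δ ∈ ±{20°, 40°, 60°}; E3 runs 4 blocks × 80
trials of 4–12 stimuli with Δ ∈ ±{20°, 40°}. First orientations sit on the
20° grid {0°, …, 160°}. Rotational sequences step by −Δ per stimulus
(`make_rotational_trial()`); Random sequences are derived from rotational
prototypes by shuffling all but the final two stimuli
(`make_random_trial()`), so the final-pair Δ — the quantity the analyses
condition on — and the per-Δ trial counts are preserved across conditions.
Permutations that are still a constant rotation are rejected and redrawn
(up to 100 times); the rejection rule is ours, chosen as the weakest
condition that removes the temporal structure.

Within each Rotational/Random block pair the Δ multiset is allocated in
exactly equal numbers (12 per Δ value in E1/E2), and each Random trial is
derived one-to-one from a rotational prototype with the same Δ and the
same early-termination status. The designed per-Δ allocation is therefore
identical across conditions by construction; the *analysed* counts differ
only by the rotation-break controls, which exist in the Rotational
condition alone.

Control trials: 20% of trials terminate early (after 1 to n−1 stimuli)
and 16% of Rotational trials replace the last orientation with a random
grid orientation (rotation-break controls). Since 0.2 × 288 = 57.6 is not
an integer, exact global percentages are unattainable; counts follow
cumulative (largest-remainder) rounding across block pairs, giving 58
early controls (230/288 = 79.86% full-length, i.e. 80% at printed
precision) and 23 rotation-break trials (15.97% of 144). We preferred the
closest session-level realisation over per-block nearest rounding (which
would give 80.6%).

For E3, `make_exp3_random_trial()` additionally replaces every shuffled
non-target stimulus lying more than 40° from the target with an
orientation 20° or 40° from the target *on the same side as the trial's
rotation step*. This stacks same-side adaptors in the Random condition —
the designed asymmetry that lets momentum be dissociated from adaptation.
The replacement side is our reading of the design goal ("more adaptors
toward the target direction"); the resulting Random sequences contain at
least as many within-±40° adaptors as their rotational sources, which is
the property the analysis needs and the property the tests check.

E2 adds per-stimulus locations drawn uniformly from a disc of radius 3°
around fixation. Locations are metadata only — they never enter the
analysis mathematics ("within ±3°" is ambiguous between a disc and a
square; we chose the disc).

## The synthetic observer

`simulate_response()` generates a report as

report = target + DoG(Δ_stim; a_adapt, w_adapt) + DoG(Δ_rep; a_sd, w_sd)
− sign(Δ_rot) · rm_shift + ε,  wrapped to [0°, 180°),

where Δ_stim is the acute difference between the penultimate stimulus and
the target, Δ_rep the difference between the previous trial's *report*
and the target (SD follows decisions, not stimuli), the momentum term
applies only on non-control Rotational trials, and ε is wrapped Gaussian
noise. With probability `lapse_rate` the report is uniform. Reaction
times are lognormal with median ≈ 1.6 s.

Defaults are the study-regime magnitudes: a_adapt = −2.16° peaking at
24°, a_sd = +1.24° peaking at 28.3°, rm_shift = 3°, noise 9°, lapse 2%.
These are the conditions under which the recovery tests run; they were
fixed once, from the published effect sizes, and are not tuned.

Choices worth knowing:

* the two DoG biases are **additive**; how adaptation and SD really
  interact in humans is unknown, and additivity is the simplest model
  that lets each analysis isolate its own component;
* momentum is a **constant** shift, not velocity-scaled — the designs use
  one rotation step per trial, so velocity dependence is unidentifiable
  here anyway;
* noise is wrapped Gaussian rather than von Mises; at σ ≤ 15° on a 180°
  circle the difference is negligible and degrees stay degrees;
* adaptation acts on the immediately preceding stimulus by default;
  `adapt_scope = "all"` sums DoG contributions (unit weights) over every
  stimulus in the sequence, for adaptor-stacking simulations;
* the previous-report memory resets at block boundaries, matching the
  blocked analysis;
* what the observer does **not** emulate: attention fluctuations, spatial
  effects of the E2 locations on precision, trial-to-trial variability in
  bias strength. Passing recovery tests therefore shows the *pipeline* is
  correct under the stated generative model, not that real data obey it.

`simulate_dataset()` chains responses sequentially within blocks so that
the SD term operates on the actual noisy, lapsing reports — exactly what
the analysis will face.

## Preprocessing

`preprocess_trials()` applies, in order:

1. raw errors and Δ_stim (`compute_errors()`);
2. outlier flags (`flag_outliers()`): |error − participant mean| > 3 SD
   (one pass, raw errors, per participant), RT < 0.5 s or > 10 s —
   strict inequalities in all three rules, so a 500 ms RT survives;
3. participant exclusion (`exclude_participants()`): raw error SD > 30°
   (a uniform guesser has SD 180/√12 ≈ 52° and is caught);
4. the previous-report predictor Δ_rep, computed on raw within-block
   adjacency *before* control rows are dropped — a report made on a
   control trial is still the observer's most recent decision — but set
   to `NA` when the preceding trial was an outlier
   (`chain_prev_report = TRUE` instead walks back to the last retained
   report);
5. removal of control trials, outliers, and the trial immediately after
   an outlier (within block; the first trial of a block never inherits
   one);
6. mean correction of the retained errors per participant × condition.

Mean correction is applied after filtering, on retained trials, and per
participant × condition; the per-group means are then zero to machine
precision, so constant response offsets cannot masquerade as bias.
Whether correction preceded or followed outlier flagging in the original
analysis is unstated; flagging on raw errors is invariant to constant
offsets per participant, so the order only matters through the
condition-specific component, which is small.

Preprocessing is idempotent by definition: a `clean_trials` object is
returned unchanged. Re-estimating the 3-SD threshold on already-filtered
data would be a different (iterated) rule, which the original procedure
does not use.

## The DoG model and its fit

The bias curve is

error(Δ) = Δ · α · w · c · exp(−(wΔ)²),  c = √2 / e^(−0.5) ≈ 2.3316.

The constant makes α the peak value exactly, attained at
Δ* = 1/(√2 w); `peak_metrics()` returns the peak bias, its location, and
the percentage 100·|α|/Δ*. The curve is odd, so it cannot absorb constant
offsets — which is why mean correction matters.

`fit_dog()` minimises the trial-level sum of squared residuals (the
resampling scheme selects *trials*, so the cost must be trial-level, not
per-Δ means) over α ∈ [−30°, 30°] and w ∈ [0.005, 0.20]/°. The bounds are
ours: published amplitudes top out near 5.3° and peak locations near
23°–28°, and the w window puts the peak between ~3.5° and ~141°, so the
bounds bracket everything plausible without constraining the optimum.
Δ = 0 observations are excluded (the model is identically zero there;
they only inflate the cost), and fewer than 20 usable pairs is an error.

Two deterministic strategies give the same optimum:

* `"multistart"` — L-BFGS-B with the analytic gradient from a fixed 5 × 5
  grid of starts over the bounds;
* `"profile"` — for fixed w the model is linear in α, so the conditional
  optimum is closed-form (clipped to the bounds); a 41-point log grid in
  w plus 1-D refinement of the best bracket finds the global optimum at a
  fraction of the cost. This is the default inside resampling loops.

The tests require the multi-start optimum to match a dense 201 × 201 grid
search within 10⁻⁶ on random small datasets, and the two strategies to
agree with each other.

## Resampling inference

`stratified_bootstrap_alpha()` implements the grand-subject scheme:
each iteration pools ⌊0.8 · n_p⌋ trials sampled *without replacement*
from every participant p, refits, and records α (defaults 5000 × 80%;
tests and scripts use fewer iterations — see problem sizes below). The
p value is one-sided: the proportion of bootstrap amplitudes on the side
of zero opposite the full-data point estimate. Note that this is
subsampling rather than a classical bootstrap, and an 80% subsample
spreads about √((1−f)/f) ≈ half as much as the sampling error of the full
fit; the one-sided p is therefore **anti-conservative under the null**
(empirically ~35–40% of null runs fall below 0.05). It is decisive for
the large published effects, which is what it is used for; the calibrated
between-condition comparison is the permutation test, and a two-sided
variant is also reported.

`permutation_test_alpha()` shuffles condition labels trial-wise *within
participant* (respecting the stratification; the shuffling scope is our
choice), refits per label, and compares |α₁ − α₂| with the surrogate
distribution, two-sided. Under the null observer its type-I rate is ≤ 7%
at nominal 5% in the acceptance suite.

`model_free_index()` is the fit-free control analysis: mean error at
Δ ∈ {+20°, +40°} minus mean error at Δ ∈ {−20°, −40°}, per participant.
Read literally, the verbal rule ("subtract the positive-Δ average from
the negative-Δ average") would make repulsion positive — contradicting
the sign of every published statistic (repulsive effects print negative
t values). We orient the index attraction-positive so that signs agree
with the model-based convention; `orientation = "literal"` restores the
verbal reading. `group_tests()` supplies the one-sample and paired t
tests with Cohen's d = mean/SD of the (difference) scores, i.e.
d = t/√n.

`dominance_analysis()` restricts to trials with both |Δ_stim| and
|Δ_rep| in 20°–40° (where the DoG is near-linear), codes each predictor
by its sign (±1), and fits error ~ b₀ + b₁·sign(Δ_stim) + b₂·sign(Δ_rep)
by OLS inside the same stratified resampling scheme, recording b₁ − b₂.
Because a repulsive stimulus effect makes b₁ negative while an attractive
report effect makes b₂ positive, the raw difference is negative whenever
either effect exists; the result object therefore also records
|b₁| − |b₂|, which is the magnitude-dominance reading, along with both
coefficients. Collinear resamples are redrawn.

`control_checks()` runs on the raw table: paired t tests of
per-participant mean |error| on (i) five-stimulus early-termination
trials versus full-length trials and (ii) rotation-break versus complete
Rotational trials.

## Problem sizes

The default iteration counts follow the study (5000 bootstrap, 10,000
permutations). The shipped tests and analysis scripts run the same code
at sizes we chose for a desk-scale validation: 100 recovery replicates of
14 × 288 trials, 200 null replicates at 500 permutations on 6 × 72-trial
sessions, bootstrap checks at 300–1000 iterations, dominance at 150–500.
At these sizes the statistical assertions in the test suite are stable
under their fixed seeds.

## Limitations

* The observer is additive and stationary; it cannot reveal
  misspecification of the DoG family on real data, only verify the
  estimation chain.
* The one-sided subsample-bootstrap p is anti-conservative under the
  null, as discussed; treat it as a summary of resample stability, not a
  calibrated test.
* The E3 replacement rule reproduces the designed adaptor asymmetry but
  the original replacement procedure is under-specified; exact adaptor
  proportions may differ.
* Whether the original Random condition reused the exact orientation
  multisets of Rotational trials or only matched Δ counts is unknown; we
  preserve the multiset per trial, which implies the count match.
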