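# serialbias

Analysis pipeline for single-trial orientation adjustment errors in
sequential psychophysics designs, for researchers studying history biases
in perception. When observers reproduce the orientation of the last Gabor
in a short sequence, their errors mix three history effects: repulsive
**adaptation** away from preceding stimuli, forward displacement along an
implied rotation (**representational momentum**), and attractive **serial
dependence** toward the previously *reported* orientation. This package
implements the full chain that separates them — the blocked
Rotational/Random sequence designs, circular error preprocessing, the
derivative-of-Gaussian (DoG) bias-curve model, stratified bootstrap and
permutation inference, a model-free index, and a regression dominance
analysis — plus a synthetic observer that makes every stage verifiable by
parameter recovery.

## The model

With Δ the signed acute difference *previous − present* orientation (in
(−90°, 90°]), the bias curve is

```
error(Δ) = Δ · α · w · c · exp(−(wΔ)²),   c = √2 / e^(−0.5)
```

so that α (degrees) is exactly the peak bias, attained at Δ = 1/(√2·w).
Errors sharing the sign of Δ indicate attraction toward the previous
orientation (α > 0, serial dependence); opposite signs indicate repulsion
(α < 0, adaptation and momentum). The amplitude is estimated by
constrained trial-level least squares; group inference resamples 80% of
each participant's trials into a grand-subject dataset (5000 iterations
by default), and conditions are compared by shuffling labels within
participant (10,000 permutations by default).

## Worked example

Simulate the first experiment at the study-regime parameters (adaptation
−2.16° peaking at 24°, serial dependence +1.24° peaking at 28.3°,
momentum 3°, noise 9°), clean it, and fit the bias curves:

```r
library(serialbias)
obs   <- observer_params()   # study-regime defaults
tab   <- simulate_dataset("E1", n_participants = 14, params = obs, seed = 1)
clean <- preprocess_trials(tab)
nrow(tab); nrow(clean)
#> 4032 trials, 2829 after cleaning

rand <- clean[clean$condition == "Random", ]
fit_dog(rand$delta_prev_stim, rand$error)
#> DoG fit (multistart, n = 1575)
#>   alpha = -2.399 deg   w = 0.03344 /deg   sse = 130110.66
#>   peak bias -2.399 deg at Delta = 21.1 deg (11.3%)

stratified_bootstrap_alpha(clean, "prev_report", n_iter = 1000, seed = 2)
#> Stratified bootstrap (1000 x 80%) of DoG alpha [prev_report]
#>   point +1.219, boot mean +1.230 [0.850, 1.593], p = 0

idx <- model_free_index(clean, "prev_stim", condition = "Rotational")
group_tests(idx$index)
#> t(13) = -15.359, p = 1.031e-09, Cohen's d = -4.10 (mean -8.579, n = 14)
```

The Random-condition amplitude of −2.4° is the repulsive adaptation left
after random sequences; the positive previous-report amplitude (+1.2°,
with no bootstrap mass across zero) is serial dependence toward the last
decision; and the strongly negative Rotational model-free t shows the
extra forward displacement that coherent rotation adds.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow — `01_simulate.R` through `05_recovery.R` — writing their tables
under `results/`.

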