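# vocometrics

Noise-vocoded speech intelligibility: psychometrics and group
discrimination for degraded-speech listening studies.

## What this is for

Noise-vocoding degrades speech in a graded way: the signal is split into
`n` frequency channels and each channel's fine structure is replaced by
white noise carrying that channel's slow amplitude envelope. The number
of channels a listener needs to identify 50% of spoken digits — the
**intelligibility threshold** — probes central (cortical) speech
processing rather than the ear, and elevated thresholds are a candidate
behavioural marker in dementia syndromes. This package is for researchers
running or simulating such studies: it implements the vocoder, the
spoken-three-digit-number experimental design (100 items: 4 clear + 4 at
each channel count 24…1), digit-level scoring, psychometric-function
fitting, nonparametric group statistics, and ROC analysis of how well the
threshold separates patient groups from controls. A synthetic listener
and cohort simulator generates everything a real study would collect, so
the whole chain can be exercised and validated end-to-end.

## The model

Per-digit performance at `x = log2(channels)` is a Weibull sigmoid scaled
between a guess floor γ and a lapse ceiling 1 − λ:

    p(x) = γ + (1 − γ − λ) · [1 − exp(−(x/α)^β)]

Per-level counts (k of n = 12 digits) are binomial, or beta-binomial with
overdispersion η (latent variance η²·p(1−p); η = 0 is the exact binomial
limit). Fits are bounded maximum likelihood (grid initialization,
multi-start L-BFGS-B, Nelder–Mead polish). Reported per listener:

* **threshold** — channels at absolute 50% correct, `2^x*` with
  `x* = α(−log(1−q))^{1/β}`, `q = (0.5−γ)/(1−γ−λ)`;
* **slope** — analytic `dp/dx` at `x*` (proportion per log2 channel);
* **γ, λ, η** as above.

Groups are compared with tie-corrected Kruskal–Wallis tests plus the rank
effect size `η²_H = (H − k + 1)/(n − k)`, Dunn's pairwise z tests,
Spearman correlations and a 97.5%-quantile outlier rule; discrimination
from controls uses empirical (Mann–Whitney + DeLong CI) and binormal AUC.

## Worked example

Simulate one control-like listener on the standard design, fit their
psychometric function, and compare two small groups:

```r
library(vocometrics)

design <- build_stimulus_list(seed = 1)          # 100 items, levels clear, 24..1
truth  <- listener_params(threshold = 3.14, slope = 1.08, gamma = 0.04)
trials <- simulate_listener(truth, design, seed = 2)

pd  <- aggregate_trials(trials)                  # 24 levels x 12 digits
fit <- fit_psychometric(pd)
fit
#> <psychometric_fit: threshold 3.212 channels, slope 1.187, gamma 0.077,
#>  lam 0.000, eta 0.000, nll 4.75>

kruskal_wallis(list(Controls = c(3.1, 3.2, 3.0, 3.3),
                    AD       = c(4.1, 4.9, 3.9, 5.2)))
#> Kruskal-Wallis: H(1) = 5.33, p = 0.02092, eta2_H = 0.722 (n = 8)

empirical_auc(cases = c(4.1, 4.9, 3.9, 5.2), controls = c(3.1, 3.2, 3.0, 3.3))
#> ROC (empirical): AUC = 1.000, 95% CI (1.000, 1.000) [delong]
```

The fitted threshold (3.21 channels) recovers the generating value (3.14)
to within the noise of 12 digits per level; the toy group comparison
shows the reporting conventions (tie-corrected H, rank effect size, AUC
oriented so higher thresholds mark cases).

The `analysis/` scripts run the full study narrative on synthetic data —
`01_build_stimuli.R` (design + vocoder characterization),
`02_run_study.R` (74-listener five-group cohort: simulate, fit, group
stats, ROC), `03_outlier_sensitivity.R`, `04_roc_comparison.R` — writing
their tables under `results/`. `run_pipeline(pipeline_config(...))` does
the same end-to-end from R, byte-reproducibly from one seed.

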