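---
title: "Noise-vocoded speech intelligibility: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-vocoded speech intelligibility: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Understanding degraded speech is a demanding "central" auditory task: the
listener must reconstruct a message from a signal whose spectral detail has
been stripped away, relying on cortical machinery well beyond the cochlea.
Noise-vocoding is the standard laboratory tool for producing such
degradation in a graded, parametric way. The speech band is divided into
`n` contiguous frequency channels; each channel's fine structure is
replaced by white noise modulated with that channel's slow amplitude
envelope. With many channels the result is readily intelligible; with one
or two it is an unintelligible rhythmic noise. The number of channels a
listener needs to reach 50% correct — the **intelligibility threshold** —
is therefore a compact, interpretable measure of central speech
processing, and an elevated threshold is a candidate marker of cortical
disease (healthy adults typically need only 3–4 channels for spoken
digits).

`vocometrics` implements the complete analysis chain for such experiments:
the vocoder itself, a synthetic-listener and cohort simulator, digit-level
scoring, psychometric-function fitting, nonparametric group statistics,
and ROC analysis of diagnostic discrimination. The target design is a
spoken three-digit-number task: 100 items, 4 clear plus 4 at each channel
count from 24 down to 1, presented in decreasing-intelligibility order,
scored by digits correct (12 digit-datapoints per level).

## The vocoder

`vocode()` follows the classic noise-vocoder recipe:

1. **Filterbank** (`make_filterbank()`): `n_channels` contiguous bands
   spanning 100–6400 Hz with edges equally spaced in log frequency,
   `edge_k = f_lo (f_hi/f_lo)^{k/N}`. Log spacing mirrors cochlear
   frequency resolution and is the conventional choice; both limits and
   the spacing rule are configurable, not claims about any particular
   laboratory's filters.
2. **Filters**: 4th-order Butterworth band-passes applied
   forward–backward (`signal::filtfilt`). Zero-phase filtering keeps the
   channel envelope aligned with its carrier; the price is that the
   effective magnitude response is the squared design response, which is
   why the in-band flatness check sums squared magnitudes.
3. **Envelope** (`extract_envelope()`): half-wave rectification followed
   by a 4th-order low-pass at 30 Hz (zero-phase), clamped non-negative.
   30 Hz keeps syllabic and phonemic modulation and discards periodicity.
   A Hilbert-magnitude extractor is available behind `env_method =
   "hilbert"`; on the AM-tracking tests the two agree.
4. **Carrier**: fresh white Gaussian noise per channel, multiplied by the
   envelope and then re-filtered into the band. The second filtering pass
   bounds the spectral splatter that modulation re-introduces.
5. **Normalization**: the summed output is RMS-matched to the input. If
   that would push the peak above full scale the whole signal is rescaled
   (never clipped) and the result flagged via the `renormalized`
   attribute; RMS equality is then intentionally sacrificed for safety.

Clear speech is represented by the unprocessed signal, not by a
large-`n` vocode: the task axis "number of channels" simply does not apply
to it, and the fitting code treats it accordingly.

All randomness is consumed inside `withr::with_seed()`, so `vocode()` is a
pure function of `(signal, config)` and never perturbs the caller's RNG
state.

## The psychometric model

Performance is modelled on `x = log2(channels)` — the perceptual effect of
adding channels is roughly logarithmic (2 → 4 channels matters far more
than 20 → 24) — with a Weibull sigmoid scaled between a guess floor and a
lapse ceiling:

$$p(x) = \gamma + (1 - \gamma - \lambda)\left[1 - e^{-(x/\alpha)^\beta}\right].$$

* `gamma` (guess rate): correct responses at the performance floor. For
  open-set digit report a listener reduced to guessing single digits would
  sit near 0.1 per digit; the fit bound of 0.25 leaves that regime free.
* `lambda` (lapse rate): errors that persist at ceiling, unrelated to the
  stimulus.
* `alpha`, `beta`: Weibull scale and shape on the log2 axis.

Two quantities are reported from the fitted curve. The **threshold** is
the *absolute* 50%-correct point — not the midpoint of the asymptote range
— converted back to channels: solving `p(x*) = 0.5` gives the closed form
`x* = alpha * (-log(1 - q))^{1/beta}` with
`q = (0.5 - gamma)/(1 - gamma - lambda)`. Because the scaled Weibull has
an exact inverse there is no need for iterative root finding; the
implementation uses the closed form (machine precision rather than a
bisection tolerance), and `threshold_50()` distinguishes an *undefined*
threshold (`1 - lambda <= 0.5`: a condition signalled with class
`undefined_threshold`) from numeric failure. The **slope** is the analytic
derivative of `p` at `x*`, in proportion correct per log2 channel; typical
human values on this task are around 0.8–1.1 on that scale.

### Overdispersion

Per-level counts are often more variable than a binomial allows — the
three digits of one trial share a single acoustic token, attention drifts,
and so on. The likelihood therefore uses a beta-binomial whose latent
per-level probability has mean `p(x)` and variance
`eta^2 p(1-p)`, i.e. shape parameters `a = p·nu`, `b = (1-p)·nu` with
`nu = 1/eta^2 - 1`. This parameterization makes `eta = 0` the *exact*
binomial limit (verified to `1e-4` in the tests at `eta = 1e-4`), and
`eta` reads directly as the fraction of maximal extra variance. Other
packages parameterize overdispersion differently, so numerical equality
of `eta` values across implementations is not claimed — only the shared
binomial limit and ordering.

### Fitting

`fit_psychometric()` is a bounded maximum-likelihood fit: a coarse
log-spaced grid over `(alpha, beta)` with nuisance parameters at mild
defaults, the best three grid points carried into L-BFGS-B over all five
parameters, then a bound-projected Nelder–Mead polish. The polish exists
because L-BFGS-B's finite-difference line search can abort spuriously on
the flat region near the `eta = 0` boundary even when it has found the
optimum; the derivative-free step both refines the solution and provides
a trustworthy convergence signal. Bounds are
`alpha ∈ (0.01, log2 48]`, `beta ∈ (0.1, 20]`,
`gamma, lambda ∈ [0, 0.25]`, `eta ∈ [0, 0.95]`. The procedure is
deterministic given data and options; non-convergence is flagged, never
silent, and all-zero or all-perfect data yield a flagged boundary fit. A
full MLE was chosen over a Bayesian integration because everything
downstream consumes point estimates of five parameters; priors and
credible intervals are out of scope.

Point estimation of five parameters from 24 levels × 12 Bernoulli
outcomes is noisy at the individual level — that is a property of the
design, not the optimizer — which is why recovery claims below are about
medians and cohort means.

## The synthetic listener and cohort

`simulate_listener()` is the generative mirror of the fitted model: digit
outcomes are Bernoulli draws of a trial-level probability, which equals
`p(x)` when `eta = 0` and is otherwise drawn from the matching Beta
distribution *per trial*, shared by the trial's three digit slots. Drawing
at trial level (rather than digit level) is what produces genuinely
extra-binomial per-level counts, because the three digits of a trial are
then positively correlated — the modelling rationale being that they share
one acoustic token. Whether human within-trial digit errors are correlated
in exactly this way is unknown; it is a modelling choice, and the
dispersion tests characterize its consequences (binomial dispersion at
`eta = 0`, significant overdispersion at `eta = 0.3`). Clear trials use
`p = 1 - lambda` and are excluded from fitting.

`simulate_cohort()` draws each listener's true parameters from per-group
truncated normal distributions. The default `dementia_cohort_spec()`
encodes a five-group study — 25 healthy older controls, 19 typical
Alzheimer's disease, 8 logopenic-, 10 non-fluent- and 12 semantic-variant
primary progressive aphasia (74 listeners) — with group threshold means
from ~3.1 channels (controls, SD 0.27) to ~5.4 channels (lvPPA, SD 2.13),
matching published behavioural profiles for this population. Truncation
bounds: threshold > 1.05 channels (the log2 axis degenerates at exactly
1), slope ≥ 0.05, rates in [0, 0.25], `eta ∈ [0, 0.95]`. Truncation is
consequential and deliberate: the control threshold SD sits near the
1-channel floor, so an untruncated normal would occasionally produce
physically meaningless listeners. With SD = 0 the draw degenerates to the
(clamped) mean, which the tests use as a determinism check.

Listeners are specified on the reporting scale `(threshold, slope)` and
converted to `(alpha, beta)` by the closed-form inversion in
`weibull_from_threshold_slope()`, so generative truth and fitted estimates
live on the same scale. All seeds derive hierarchically from one run seed
(`derive_seed()`), so any listener or stage can be reproduced in
isolation.

What the generator does **not** emulate: real speech acoustics (the
stand-in utterances are digit-indexed harmonic complexes, useful for
testing the DSP chain, not for human listening), digit confusion
structure (wrong responses are uniform over the nine other digits),
serial-position effects, fatigue or practice across the session, and any
correlation between psychometric parameters within a listener. Passing
tests therefore validate the statistical machinery under a known
generative model — they do not certify behaviour on human data with
different noise structure.

## Scoring conventions

Scoring is positional: target "587" vs response "585" scores 2. Two
conventions are explicit because the task description leaves them open:
partial responses are **left-aligned** to the hundreds position (a
two-digit response is read as hundreds + tens), and transpositions are
scored strictly by position ("578" for "587" scores 1). Both are
documented in `score_trial()`; the left-alignment choice is configurable
in effect by pre-padding responses upstream if a study records alignment
explicitly. Non-digit characters are rejected as transcription errors
rather than silently scored 0.

## Group statistics

Groups are compared with tie-corrected Kruskal–Wallis tests (the
parameter distributions are far from normal — bounded rates piled at
zero, skewed thresholds), with the rank eta-squared effect size
`eta2_H = (H - k + 1)/(n - k)`. This estimator is centred at zero under
the null, so small-sample values can be slightly negative; they are
reported as computed rather than clamped. Dunn's tests provide pairwise
contrasts on the joint ranks, with the tie-corrected pooled variance; raw
(unadjusted) z and p are reported by default, with Holm adjustment behind
an option, matching the common reporting style for this design.
Spearman correlation is computed as Pearson-on-average-ranks with a t
approximation, which handles ties. The outlier rule flags values strictly
above the 97.5% empirical quantile under the linear-interpolation
(type 7) convention; the quantile convention is stated because different
software defaults differ and the flagged set can change with it.

## ROC analysis

Diagnostic discrimination of patients from controls on the fitted
threshold is quantified two ways. The **empirical** AUC
(Mann–Whitney, ties one-half; DeLong 95% CI; computed via pROC) is the
default: control thresholds are tightly clustered while patient
thresholds are skewed, so a normality assumption is visibly doubtful. The
**binormal** AUC, `Phi((mu_case - mu_control)/sqrt(s1^2 + s2^2))` with a
percentile-bootstrap CI, is provided because parametric estimates are
common in the clinical literature and because on a truncated-normal
generative model it is the natural closed-form oracle for the empirical
estimator. The two are property-tested for their distinguishing
invariances: the empirical AUC is invariant under any strictly monotone
transform of the marker, the binormal only under affine maps.

## Numerical choices and degenerate inputs

* Likelihood evaluation clamps `p` into `(1e-9, 1 - 1e-9)` so boundary
  parameters cannot produce infinite masses.
* `kruskal_wallis()` defines the all-tied case as `H = 0, p = 1`; Dunn's
  z under zero pooled variance, Spearman's rho under constant input, the
  DeLong CI when both groups are single-valued, and the binormal AUC under
  zero variance all signal typed warning conditions (`undefined_*`)
  rather than returning misleading numbers or crashing.
* The vocoder rejects configurations whose upper band limit reaches the
  signal's Nyquist frequency, and refuses silent outputs rather than
  dividing by zero during RMS matching.
* CSV/JSON outputs are written deterministically; the pipeline's two-run
  byte-identity is part of the test suite, and every output file carries
  the MD5 hash of the generating configuration.

## Problem sizes

The simulation studies are sized to characterize the estimators while
keeping a full run of the suite and scripts comfortable on a laptop:
threshold recovery uses 20 cohorts of 25 control listeners on the
standard design (500 fits) for the cohort-mean check, 100 replicates per
condition for the high-precision (10× trials) bias check and the
per-listener recovery medians, and 500 simulated cohorts for the
svPPA-vs-controls AUC distribution. These sizes give Monte-Carlo standard
errors comfortably below the decision tolerances used in the tests
(±0.25 channels on the cohort-mean threshold; ±0.05 on mean AUC).

## Known limitations

* The vocoder's exact band limits, filter family/order and envelope
  cutoff are laboratory-specific in practice; the defaults here are
  standard but generic, and conclusions that hinge on precise filter
  shapes should treat them as tunable.
* The MLE reports point estimates only; uncertainty on individual
  thresholds is visible indirectly (likelihood-distance test) but not
  propagated into the group statistics.
* The beta-binomial overdispersion parameterization is one of several in
  use; `eta` values are comparable within this package, not across
  packages.
* The synthetic cohort draws parameters independently within listener;
  real psychometric parameters are likely correlated (e.g. threshold with
  lapse), which would alter group-statistic power but not the estimators
  themselves.
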