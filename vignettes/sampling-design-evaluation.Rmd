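---
title: "Evaluating coastal sampling designs for habitat distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating coastal sampling designs for habitat distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Mapping littoral habitats at 10 m resolution over hundreds of kilometers of
coast is expensive. If a presence/absence habitat distribution model (HDM)
fitted on a *fraction* of the coast predicts the rest well, surveys can be
much cheaper — but how should that fraction be laid out? `littoralHDM`
implements a replicable version of this experiment. The coast is an ordered
1-D chain of survey points carrying environmental predictors (mean
sea-surface temperature, mean and minimum wave height, slope class 1–5,
geology, substrate type) and binary habitat layers. Three designs compete:

* **aggregated** — one contiguous stretch of coast (cheap logistics, biased
  environmental coverage); four pinned placements start at 0%, 25%, 50% and
  75% of the chain;
* **interspaced** — at least five equal stretches spaced regularly along the
  whole coast;
* **random** — uniformly sampled points, replicated ten times: the
  performance ceiling ("null models") that any practical design is compared
  against.

Each design is run at sampling fractions 10–50%. Sample sizes are the
nearest integer to `fraction * n` (halves away from zero); at the reference
size of 16,098 points these are 1,610 / 3,220 / 4,829 / 6,439 / 8,049. (The
20% figure is sometimes quoted as 3,219, which is the truncation rather
than the nearest integer; the other published sizes are all nearest-integer
roundings, so the package rounds.)

## The model

Occurrence of a habitat is modeled with a binomial GLM with logit link:

$$\operatorname{logit} P(y_i = 1) = \beta_0 + x_i^\top \beta$$

with main effects only. Categorical predictors are treatment-coded against
the most frequent level of the training data (this keeps rare-level fits
stable on small training stretches). Fitting is iteratively reweighted least
squares with a `1e-8` ridge on the normal equations and a stop rule of
deviance change `< 1e-8` or 50 iterations; quasi-separation — common when a
rare habitat is fitted on a short stretch — is flagged
(`separation_flag`, any standardized coefficient beyond ±15) rather than
treated as failure. Model fit is summarized by explained deviance,

$$D^2 = \frac{\text{null deviance} - \text{residual deviance}}
            {\text{null deviance}} \times 100,$$

and predictor subsets are chosen by exhaustive AIC search over the six
candidate terms (categorical blocks enter or leave whole, so 64 fits; AIC =
deviance + 2·coefficients, which for 0/1 data is the usual binomial AIC).
Ties go to fewer terms, then lexicographic order. By default selection runs
once on the *complete* dataset and the selected terms are refitted on each
training sample; per-sample re-selection is available
(`selection_mode = "per_sample"`), since either protocol is defensible and
they answer slightly different questions.

## Validation

Predictions on the held-out coast are scored with three statistics:

* **AUC**, computed by the rank (Mann–Whitney) formulation, ties counting
  one half. Bands follow the usual reading: > 0.9 highly accurate, 0.7–0.9
  useful, below 0.7 poor, ≤ 0.5 no discriminative power.
* **Sensitivity and specificity** at a habitat-specific threshold that
  maximizes their sum. Candidate cut-offs are the midpoints between
  consecutive distinct predicted probabilities plus the two boundary
  midpoints; presence is predicted when `prob >= threshold`; ties on the
  objective resolve to the smallest threshold, which favours sensitivity
  (detecting presences is the harder task for uncommon habitats). The
  threshold is chosen on the test predictions by default
  (`threshold_on = "train"` switches sides).

Degenerate training samples (response all 0 or all 1 — routine for rare
habitats inside one aggregated block) are recorded with
`status = "degenerate"` and their training prevalence, not dropped
silently.

## What the synthetic generator emulates

Real survey data of this kind cannot be redistributed with a package, so
every claim is exercised on synthetic coastlines built by
`simulate_coastline()`:

* **Geometry** — `n` points (default 16,098) at 10 m spacing on a gently
  curving southward chain; the chain order is the spatial order.
* **SST** — a linear north→south warming gradient spanning 16.8–18.7 °C
  plus AR(1) noise (marginal SD 0.2 °C), clipped to the range.
* **Wave heights** — AR(1) processes rescaled into 0.02–0.9 m (mean) and
  0.01–0.07 m (minimum), with `wh_min <= wh_avg` enforced pointwise. AR(1)
  was chosen as the simplest process with a single spatial-scale knob; the
  default lag-1 correlation 0.995 makes fields vary on the kilometer scale.
* **Categoricals** — first-order Markov chains with geometric run lengths,
  expected run 200 points (~2 km), echoing alongshore geological patchiness.
* **Habitats** — Bernoulli draws from the same logistic family the pipeline
  fits: `plogis(intercept + X beta + pattern offset)`. Distribution
  patterns that predictors alone cannot carry are injected as a logit
  offset of ±`pattern_strength` (default 2) inside/outside a zone split at
  the chain midpoint (`localized_north` / `localized_south`); the midpoint
  is a deliberate simplification — the contrast between northern and
  southern distributions matters, not the exact boundary.
  `rare_scattered` instead shrinks `beta` by 0.25 so the few presences
  spread along the coast. The intercept is calibrated by bisection so the
  mean occurrence probability is within 0.002 of the target prevalence.
* **Default layers** — six, mirroring the prevalence spectrum of the
  motivating survey: 47.9% and 34.9% northern-localized, 7.2%
  northern-localized, 3.3% southern-localized, 0.7% rare-scattered, 28.4%
  widespread. (3.3% is the count-derived frequency 528/16,098; a sometimes
  quoted 2.8% is inconsistent with the count.)

Because the habitat layers are generated by the very model family being
fitted, passing tests show that the *pipeline* is correct and that design
effects (aggregation bias, prevalence limits) behave as expected — they do
not show that a logistic main-effects model is adequate for real littoral
habitats, nor do they reproduce real spatial autocorrelation in the
*residual* habitat structure, observation error, or the irregular geometry
of a real coast. Published per-habitat metric values from field data are
therefore not reproduction targets; the qualitative design ranking is.

## The experimental grid

`run_grid()` runs, per habitat, 19 deterministic scenarios — interspaced at
10–50%, aggregated case 1 at 10–50%, aggregated cases 2–4 at 20–40% — plus
10 random-null replicates at each of the five fractions (seeds are a fixed
ladder from `null_base_seed`). The published experiment totals 19 scenarios
per habitat without itemizing them; this enumeration matches that count and
the published design figure, and the grid is an ordinary data.frame
argument, so it can be re-pinned without code changes. The aggregated
placements were "arbitrarily chosen" in the original GIS workflow;
quarter-position starts make them reproducible here.

`replicate_design_comparison()` distills the headline comparison: on
replicate synthetic worlds carrying a northern-localized habitat at
prevalence 0.35, it scores interspaced 20%, the southern aggregated block
(case 4) at 20%, interspaced 50%, and the 20% null mean. With 20 worlds of
16,098 points (the default, and the size used by `scripts/acceptance.R`)
the interspaced design tracks the null ceiling within 0.05 AUC, beats the
spatially biased aggregated placement by a wide margin, and gains little
from more coast — the design ranking the experiment exists to demonstrate.

## Numerical choices and edge cases

* Probabilities are clipped to `(1e-12, 1 - 1e-12)`; thresholds therefore
  stay inside (0, 1) for model output.
* `order_chain()` rebuilds along-shore order greedily from the northernmost
  point when a table arrives shuffled; duplicate coordinates tie-break by
  original row order with a warning. Construction warns when an inter-point
  gap exceeds 5× the median spacing.
* Rows with missing predictors are dropped with a logged count.
* Aliased design columns are dropped with a warning; all-constant responses
  raise a classed error (`hdm_degenerate_error`) that the orchestrator
  converts to a status.
* Problem sizes in the test suite: unit tests run on worlds of 300–5,000
  points; the end-to-end checks use the full 16,098-point scale with 20
  replicate worlds, which completes in about a minute of compute per
  experiment.

## Known limitations

* The coast is strictly 1-D; no 2-D seascape, no geodesy (coordinates are
  projected meters).
* Main effects only — no interactions, GAM smoothers, or spatial random
  effects; that matches the modeling protocol under evaluation, not the
  state of the art in SDMs.
* Only AUC, sensitivity and specificity are reported (no TSS, kappa, or
  calibration diagnostics).
* The interspaced stretch count is fixed at its minimum (5) by default;
  whether more, shorter stretches help is left to the user via `k`.
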