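# littoralHDM

Evaluating how the spatial layout of a coastal survey affects the predictive
accuracy of littoral habitat distribution models.

## The problem

Exhaustive cartographies of rocky-shore habitats — presence/absence recorded
at thousands of points along a coastline, together with environmental
predictors — are expensive to produce. A habitat distribution model (HDM)
fitted on a fraction of the coast could predict the rest, but the answer
depends strongly on *how* that fraction is laid out. `littoralHDM` is for
coastal ecologists and survey planners who want to compare sampling designs
before committing field effort:

* **aggregated** — one contiguous stretch of coast (four reproducible
  placements: blocks starting at 0%, 25%, 50%, 75% of the chain);
* **interspaced** — ≥ 5 equal stretches spaced regularly along the whole
  coast;
* **random** — uniformly sampled points replicated 10×, the "null model"
  performance ceiling;

each at sampling fractions from 10% to 50%.

## The model

Each habitat is modeled as a binomial GLM with logit link over mean
sea-surface temperature, mean and minimum wave height, slope class, geology
and substrate type, with exhaustive AIC subset selection over the six
candidate terms (categorical blocks enter whole). Fit is summarized by
explained deviance

D² = (null deviance − residual deviance) / null deviance × 100,

and predictions on the held-out coast are scored with AUC (rank
formulation), plus sensitivity and specificity at the habitat-specific
threshold maximizing their sum (presence predicted when
prob ≥ threshold). AUC > 0.9 is read as highly accurate, 0.7–0.9 useful,
≤ 0.5 no predictive power.

Because real survey databases of this kind are not redistributable, the
package includes a synthetic coastline generator
(`simulate_coastline()`): spatially autocorrelated AR(1) environmental
fields on a 16,098-point, 10 m-spaced chain, Markov-segment categorical
predictors, and Bernoulli habitat layers drawn from the logistic family
itself, with intercepts calibrated to hit target prevalences (defaults
mirror a real prevalence spectrum: 47.9%, 34.9%, 7.2%, 3.3%, 0.7%, 28.4%).

## Worked example

```r
library(littoralHDM)

coast <- simulate_coastline(coast_config(n = 16098, seed = 7))
coast
#> <coastline> 16098 points, 6 habitat layer(s): Riv, Lby, Tro, Neo, Hph, Cme
#>   index           x          y  sst_avg    wh_avg     wh_min slope_class ...
#> 1     0 0.000000000   0.000000 17.25745 0.4517127 0.02577986           5 ...

# one scenario: interspaced design, 20% of the coast as training data
res <- run_scenario(coast, "Riv",
                    list(strategy = "interspaced", fraction = 0.2, k = 5))
res[c("strategy", "fraction", "n_train", "F_train", "D2", "AUC",
      "threshold", "sensitivity", "specificity", "status")]
#>      strategy fraction n_train F_train   D2   AUC threshold sensitivity specificity status
#> 1 interspaced      0.2    3220   0.566 51.5 0.869     0.529       0.747        0.85     ok

# the random-null ceiling at the same fraction
null_replicates(coast, "Riv", 0.2, n_reps = 10, base_seed = 1000)
#> <null_summary> 10 replicates (0 degenerate)
#>        metric       mean          sd
#> 1          D2 43.0466642 1.763976329
#> 2         AUC  0.9027253 0.001738508
#> 3 sensitivity  0.8362602 0.008348737
#> 4 specificity  0.8566132 0.006073399
```

Reading this: training on five regularly spaced stretches covering 20% of
the coast (3,220 points, training prevalence 0.566), the selected logistic
model explains 51.5% of the null deviance and ranks held-out
presences/absences with AUC 0.869 ("useful", close to the 0.90 random-null
ceiling); at the threshold 0.529 that maximizes sensitivity + specificity
it correctly detects 74.7% of presences and 85.0% of absences.

The full experiment — 6 habitats × 19 scenarios plus 50 null fits per
habitat — is one call:

```r
out <- run_grid(coast, out_dir = "results")   # results.csv, null_summary.csv
```

and `replicate_design_comparison()` repeats the headline design comparison
over independently generated worlds. Real data can be ingested with
`read_coastline()` (CSV or XLSX, with column-name mapping), and
per-point prediction maps are produced by `binary_map()` and exported with
`write_geojson()`.

## Package layout

* `R/coastio.R` — coastline data model, CSV/XLSX reader, chain ordering,
  results/GeoJSON writers
* `R/synthetic.R` — synthetic environment and habitat generator with
  prevalence calibration
* `R/sampling.R` — aggregated / interspaced / random splits and the
  scenario grids
* `R/fit.R` — design matrices, IRLS logistic fitting, AIC subset
  selection, prediction
* `R/eval.R` — AUC, optimal threshold, confusion statistics, accuracy
  bands, null replicates
* `R/scenarios.R` — per-scenario runner, full-grid orchestrator, binary
  maps, replicated design comparison
* `vignettes/sampling-design-evaluation.Rmd` — the methods vignette
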