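# shrimpselect

Codend size selectivity for North Sea brown shrimp (*Crangon crangon*)
from paired-gear trawl experiments.

The brown shrimp beam-trawl fishery uses codends with very small meshes,
and only shrimp above the 50 mm minimum landing size (mls) are marketable,
so the retention of undersized shrimp is the central gear-design question.
`shrimpselect` implements the standard analysis chain for answering it:

1. **Per-haul estimation** (`fit_haul`): the logistic selection curve
   `r(l) = exp(ln 9 (l − L50)/SR) / (1 + exp(ln 9 (l − L50)/SR))`,
   with `L50` the length at 50% retention and `SR = L75 − L25`, is fitted
   by maximum likelihood to test/control length-frequency counts together
   with the split parameter `SP` (probability of entering the test codend)
   and the subsampling factors `qt`, `qc`. Covariance from the observed
   information; deviance/DOF/p-value diagnostics and deviance residuals.
2. **Fryer meta-analysis** (`fit_fryer_model`, `select_best_model`):
   haul-level estimates `θ_i = (L50, SR, SP)_i ~ N(X_i β, R_i + D)` with
   known within-haul covariances `R_i` and between-haul covariance `D`;
   fixed-effect candidate terms {intercept, m, m², w, m×w, s, p} per
   equation; exhaustive structure enumeration (2^21 = 2,097,152 candidates
   for the full model) ranked by AICc, per mesh orientation (T0/T45/T90).
3. **Prediction framework** (`retention_isolines`, `indicator_table`):
   lengths at given retention levels
   `L_r = L50 + SR/ln 9 · ln(0.01r/(1 − 0.01r))` over a mesh-size grid,
   and exploitation indicators `nR`, `nP`, `nPa`, `nPb` for a population
   length structure.
4. **Synthetic experiments** (`generate_experiment`): paired-gear trials
   with known ground truth (population, covariates, between-haul
   deviations, entry split, retention, subsampling) for end-to-end
   validation.

Reference models for diamond (T0), square (T45) and T90 codends, as
published from a large sea-trial data set, ship with the package
(`reference_codend_models()`) and drive the prediction framework out of
the box.

## Worked example

Simulate a small diamond-mesh experiment at known truth, fit every haul,
select the meta-analysis structure by AICc, and predict:

```r
library(shrimpselect)

tr <- synthetic_truth(design = data.frame(mesh_size = c(20, 24, 28, 32),
                                          n_hauls = c(5, 5, 5, 5)),
                      D = c(6, 1.5, 0.005))
ex   <- generate_experiment(tr, seed = 42)
fits <- lapply(ex$hauls, fit_haul)
tab  <- haul_fit_table(fits)
head(tab[, c("haul_id", "mesh_size_mm", "L50", "SR", "SP", "sd_L50", "p_value")], 3)
#>   haul_id mesh_size_mm    L50     SR    SP sd_L50 p_value
#> 1    H001           20 35.164 10.800 0.488  1.095   0.334
#> 2    H002           20 36.253  9.863 0.477  1.156   0.279
#> 3    H003           20 37.561  7.561 0.494  0.817   0.559

sel <- select_best_model(tab, enumerate_structures(
  fe_structure(L50 = c("m", "m2"), SR = c("m", "w"), SP = "intercept"),
  forced = c("L50:m", "SR:m", "SP:intercept")), D_type = "diagonal")
sel$ranking[1:3, c("rank", "structure", "k", "AICc")]
#>   rank                       structure k     AICc
#> 1    1   L50{m+m2} SR{m} SP{intercept} 7 135.7806
#> 2    2      L50{m} SR{m} SP{intercept} 6 139.7140
#> 3    3 L50{m+m2} SR{m+w} SP{intercept} 8 141.4743
```

The AICc winner is the structure the data were generated from
(`L50 ~ m + m²`, `SR ~ m`, `SP ~ intercept`), with coefficients close to
the generating values 2.05, −0.01, 0.37, 0.49:

```r
sel$best
#> Fryer meta-analysis fit (T0 codends, n = 20 hauls, D: diagonal)
#>                value     se ci_lower ci_upper
#> L50:m         2.1462 0.1017   1.9469   2.3455
#> L50:m2       -0.0126 0.0037  -0.0198  -0.0054
#> SR:m          0.3726 0.0128   0.3476   0.3977
#> SP:intercept  0.4818 0.0159   0.4506   0.5130
#> D diagonal: 2.373, 0.857, 0.005
```

Prediction and exploitation indicators for a gamma-shaped population
(mode 48 mm):

```r
predict(sel$best, data.frame(m = 26))[, c("L50_mean", "SR_mean")]
#>   L50_mean SR_mean
#> 1   47.287   9.689

nPop <- generate_population(seed = 1)
indicator_table(list(T0 = sel$best), mesh_sizes = c(21, 25, 29), nPop = nPop)
#>   mesh_size mesh_type L50_mean SR_mean    nR    nP   nPa   nPb
#> 1        21        T0    39.52    7.83 33.54 77.51 99.11 54.13
#> 2        25        T0    45.78    9.32 22.29 62.67 93.71 29.09
#> 3        29        T0    51.65   10.81 13.74 48.63 80.71 13.91
```

Here widening the mesh from 21 to 29 mm cuts the retention of undersized
shrimp (`nPb`) from 54% to 14% while retention of marketable sizes
(`nPa`) drops from 99% to 81% — the bycatch/yield trade-off the framework
is built to quantify. `run_pipeline()` sequences all stages from a single
YAML or list configuration and writes schema-commented CSVs.

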