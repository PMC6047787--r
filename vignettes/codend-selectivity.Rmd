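---
title: "Codend size selectivity for brown shrimp: models, estimation and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codend size selectivity for brown shrimp: models, estimation and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrimpselect)
```

## The problem

Brown shrimp (*Crangon crangon*) are fished in the North Sea with beam
trawls whose codends use very small meshes (roughly 20–22 mm), and only
shrimp longer than the 50 mm minimum landing size (mls) are marketable.
Whether a shrimp of length $l$ escapes through the codend meshes or is
retained is the codend's *size selection*; quantifying it as a function of
mesh size and mesh orientation (standard diamond T0, square T45, or T90) is
what lets managers predict the bycatch of undersized shrimp for any codend
design.

`shrimpselect` implements the full analysis chain for paired-gear
selectivity experiments: per-haul maximum-likelihood estimation of a
logistic selection curve, a Fryer-type random-effects meta-analysis across
hauls with exhaustive AICc subset selection of the fixed-effect structure,
and a prediction layer that turns a fitted (or packaged reference) model
into retention isolines and exploitation indicators. A synthetic experiment
generator with known ground truth makes every stage testable without
access to sea-trial data.

## Per-haul model

Retention of a shrimp of length $l$ follows the logistic selection curve

$$r(l) = \frac{\exp(\ln 9\,(l - L50)/SR)}{1 + \exp(\ln 9\,(l - L50)/SR)},$$

parameterised by $L50$, the length at 50% retention, and the selection
range $SR = L_{75\%} - L_{25\%}$ (the $\ln 9$ scaling makes these
definitions exact). In a paired-gear trial a test codend fishes alongside a
small-mesh control codend assumed non-selective; a shrimp enters the test
side with length-independent probability $SP$ (the split parameter). The
expected share of length class $l$ found in the test codend is then

$$\phi(l) = \frac{SP\,r(l)}{(1 - SP) + SP\,r(l)},$$

and, because only fractions $q_t$ and $q_c$ of each codend's catch are
length-measured, the log-likelihood of the measured counts $nt_l, nc_l$ is

$$\sum_l nt_l \ln\frac{q_t\phi_l}{q_t\phi_l + q_c(1-\phi_l)}
      + nc_l \ln\frac{q_c(1-\phi_l)}{q_t\phi_l + q_c(1-\phi_l)}.$$

Only the ratio $q_t/q_c$ matters, and classes with no measured shrimp
contribute nothing. Lengths are recorded rounded down to the half
millimetre, so the 0.5 mm class label *is* the recorded length and is used
directly as $l$ in the likelihood. `fit_haul()` maximises this
log-likelihood in transformed coordinates ($L50$ free, $\log SR$,
$\mathrm{logit}\,SP$) from a small multi-start grid (convergence tolerance
$10^{-8}$ on the objective), which avoids boundary failures without box
constraints. The covariance of the estimates is the inverse of the
numerically differenced observed information on the natural scale — the
meta-analysis consumes it on that scale. When the information matrix is not
positive definite the haul is flagged `valid = FALSE` and excluded
downstream rather than raising an error; this mirrors how field analyses
drop the occasional haul whose covariance cannot be estimated.

Goodness of fit is assessed by the deviance against its degrees of freedom
(classes with measured shrimp minus the three parameters) and the
corresponding chi-square p-value. A p-value below 0.05 with no systematic
pattern in the deviance residuals is conventionally read as overdispersion
and the haul retained; `assess_haul_fit()` therefore returns the per-class
residuals for inspection instead of automating that judgement.

```{r}
tr <- synthetic_truth(design = data.frame(mesh_size = 22, n_hauls = 1),
                      D = c(0, 0, 0))
ex <- generate_experiment(tr, seed = 1)
fit_haul(ex$hauls[[1]])
```

## Meta-analysis across hauls

Haul-level estimates $\theta_i = (L50_i, SR_i, SP_i)$ vary for two reasons:
finite per-haul samples (*within-haul* variation, the covariance $R_i$ from
the haul fit) and uncontrolled differences in fishing conditions
(*between-haul* variation, a covariance $D$). The Fryer model combines both
with fixed effects of the haul covariates:

$$\theta_i \sim N(X_i\beta,\; R_i + D),$$

where each row block of $X_i$ builds one of the three mean equations from
candidate terms {intercept, $m$, $m^2$, $w$, $m\times w$, $s$, $p$} — mesh
size (mm), its square, catch weight (kg), their interaction, sea state
(0–9) and trawl side (0/1). Mesh orientations are analysed separately,
never pooled, because their between-haul variability need not be
comparable. `fit_fryer_model()` maximises the multivariate-normal
likelihood directly over $D$ (log-Cholesky parameterised, so always
positive semi-definite; a diagonal-$D$ option is provided), profiling the
coefficients out by generalised least squares at each candidate $D$.
Coefficient standard errors come from the inverse GLS information at the
optimum. Estimability requires more than one observation per parameter;
since each haul contributes a 3-vector, the check is
$3 n_\text{hauls} > n_\beta + n_D$.

With 7 candidate terms in each of 3 equations, independently toggling every
term yields $2^{21} = 2{,}097{,}152$ candidate structures.
`enumerate_structures()` represents the enumeration as a deterministic
bit-pattern stream decoded lazily by `structure_at()`, so the full set is
cheap to enumerate; `select_best_model()` fits candidates and ranks them by
AICc,

$$\mathrm{AICc} = -2\log L + 2k + \frac{2k(k+1)}{n - k - 1},$$

with $k$ counting fixed-effect coefficients plus free $D$ parameters and
$n$ the number of hauls (the correction is undefined at $n \le k + 1$;
such models are assigned $+\infty$ so they can never win). Ties break by
fewer parameters, then enumeration order, making the ranking deterministic
regardless of input order. In practice exhaustive runs should restrict the
toggled set (the `forced` argument pins terms): the default pipeline
configuration toggles at most a few hundred candidates, which is the scale
a desk analysis needs.

Predictions at a covariate point report two tiers of 95% limits:
estimation-only, $\hat\mu \pm 1.96\sqrt{x'\Sigma_\beta x}$, and total,
$\hat\mu \pm 1.96\sqrt{x'\Sigma_\beta x + D_{jj}}$, the latter describing
where individual hauls are expected to fall. The variance and the
between-haul variance are summed *before* the square root — both are
variances in mm², and only their root gives limits in mm.

## Packaged reference models

`reference_codend_models()` ships the selected models for T0, T45 and T90
codends from a large North Sea paired-gear data set, exactly as published:
for diamond mesh $L50 = \alpha_1 m + \alpha_2 m^2$, $SR = \beta_1 m$,
$SP = \gamma_0$, with between-haul variances
$(D_{L50}, D_{SR}, D_{SP}) = (26.14, 6.38, 0.01)$, and analogous
structures for the other two orientations. Published tables report
coefficient standard errors but not their correlations, so the coefficient
covariance of these fixture models is diagonal: mean predictions are exact,
estimation-tier limits are approximate (in our checks the missing negative
$m$/$m^2$ correlation makes them conservative by a factor of several for
diamond mesh), and total-tier limits are dominated by $D$ anyway. One
published value is internally inconsistent (the square-mesh $SR$ mesh-size
coefficient prints as 0.02 with CI 0.014–0.017); the printed value is used
and the CI midpoint is kept alongside as an attribute without asserting
which drove the published predictions.

```{r}
mod <- reference_codend_models("T0")
predict(mod, data.frame(m = 21.7))[, c("L50_mean", "SR_mean", "SP_mean")]
```

## Prediction framework

Inverting the selection curve gives the length at any retention level $r$
(percent),

$$L_r = L50 + \frac{SR}{\ln 9}\,\ln\frac{0.01r}{1 - 0.01r},$$

so `retention_isolines()` tabulates $L_r$ for $r = 5, 10, \dots, 95\%$
over a mesh-size grid (lengths beyond the outermost levels are read as
fully released/retained). Applying a predicted curve to a population
length structure `nPop` gives the deterministic expected catch
`nCatch`$_l = r(l)\,$`nPop`$_l$; retention is evaluated at the class
midpoint (lower bound + 0.25 mm) by default, configurable to the lower
bound — at 0.5 mm resolution the choice moves indicators by well under a
percentage point, and the midpoint minimises discretisation bias. From
`nPop` and `nCatch` the usability indicators follow: `nR` (undersized
share of the catch), `nP` (overall retention), and `nPa`/`nPb` (retention
above/below mls). They satisfy the conservation identity
$nP \sum nPop = nPa \sum_{l \ge mls} nPop_l + nPb \sum_{l < mls} nPop_l$
by construction. The deterministic expectation (no Bernoulli thinning) is
used because the indicators summarise a mean exploitation pattern, not a
single realised trip.

```{r}
nPop <- generate_population(seed = 1)
indicator_table(reference_codend_models(), mesh_sizes = c(21, 25, 29),
                nPop = nPop)[, c(1, 2, 5:8)]
```

Catch-weight-dependent predictions (square and T90 models) default to
$w = 35$ kg, near the mean test-codend catches of the trials the reference
models came from; sea state and side never entered the selected structures.

## Synthetic experiments

`generate_experiment()` draws, for every haul: covariates (catch weight
from a normal with mean 35 kg and SD 25 kg truncated at zero — the
observed cruise-level means ranged from about 9 to 82 kg; sea state
uniform on 0–4; side Bernoulli(½); $q_t \in [0.03, 0.47]$ and
$q_c \in [0.02, 0.26]$, the observed ranges), a haul-level parameter
vector from the mean equations plus a $N(0, D)$ deviation (SR floored at
0.5 mm, SP clamped into (0.02, 0.98), events logged in the truth record),
and then the catch process itself: lengths multinomial from a gamma-shaped
population (mode 48 mm over 10–100 mm in 0.5 mm classes — a typical
Wadden Sea size structure), a Bernoulli(SP) split into test and control,
logistic retention on the test side, full retention in the control, and
independent binomial subsampling at $q_t$, $q_c$. The default design
mirrors the diamond-mesh arm of the emulated trials (13 codends of
19–36.4 mm mesh, 5–12 hauls each, 89 hauls) with 20,000 shrimp entering
the gear pair per haul, which yields roughly a thousand measured shrimp
per codend per haul — the scale of the real trials, where about 1 kg per
codend was measured. All randomness descends from one master seed through
per-haul substreams, so identical seeds reproduce experiments exactly.

What the generator deliberately does not emulate: length-dependent entry
(contact/behaviour effects), correlation of catch weight with the
simulated counts (weight enters only as a covariate), within-haul
overdispersion beyond binomial noise, and non-selective control codend
violations. Passing tests therefore demonstrate correctness of the
estimation chain under the stated model, not robustness to those
real-data departures.

## Numerical choices

* Haul fits: Nelder–Mead from each start, polished by BFGS; starts place
  $L50$ at the 25/50/75% quantiles of the raised length distribution and
  $SP$ at the raised test share of the largest-length quintile.
* Covariance validity requires all eigenvalues of the observed information
  to be strictly positive; anything else flags the haul invalid.
* $D$ optimisation bounds the log-standard-deviations in $[-8, 8]$; a
  component reaching the lower bound warns of a boundary collapse (the
  PSD projection is implicit in the Cholesky form).
* Degenerate inputs error early with named conditions: all-zero counts,
  one empty codend, fewer than four informative classes, mixed mesh types,
  rank-deficient designs (naming the collinear terms).
* Problem sizes in the test suite (hauls per experiment, replicate counts,
  restricted enumerations) are chosen as the smallest sizes at which the
  checked property is statistically decidable, so the whole suite runs at
  desk scale.

## Known limitations

* The Fryer weighting $1/(R_i + D)$ uses each haul's estimated within-haul
  covariance, and that covariance depends on the haul's own realised
  parameters (the standard error of $SR$ scales with $SR$ itself). When
  between-haul variation is as large as the packaged reference values
  (CV of $SR$ around 25%), hauls with smaller realised $SR$ are
  systematically up-weighted and the $SR$ slope is biased low by a few
  percent — our simulations put 95% CI coverage for that coefficient near
  80% rather than 95%, while $L50$, $SP$ and $D$ recovery stay calibrated.
  This is a property of inverse-variance meta-analysis with
  parameter-dependent within-unit precision, inherited by any
  implementation of the method; it is documented here rather than patched,
  because the weighting *is* the method.
* Wald intervals for the fixed effects condition on the estimated $D$;
  the extra uncertainty from estimating $D$ is not propagated, which
  contributes mild undercoverage with few hauls.
* Only the logistic selection curve is implemented (no Richards or
  dual-logistic alternatives), and only paired-gear (not covered-codend)
  designs.
* The subsampling factors are taken as given; whether they were derived
  from weight or count ratios is the caller's concern.
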