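---
title: "Methods: linking on-farm, market and dietary diversity by system GMM"
author: "divtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking on-farm, market and dietary diversity by system GMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtriad)
```

## The scientific problem

Rural households in low-income settings feed themselves through two
complementary channels: the portfolio of plant species they grow or collect
(on-farm diversity, OFD) and the variety of foods they purchase in local
markets (market diversity, MD). Both plausibly shape the dietary diversity
(DD) of the women who run household food provisioning — but DD, MD and OFD
are jointly chosen, so a regression of DD on OFD and MD is confounded by
unobserved household-level factors (taste for variety, unmeasured resources,
shocks) that move all three. `divtriad` implements the full chain needed to
study this triangle: indicator construction from raw survey tables, a
three-equation simultaneous system estimated by instrumental-variable GMM,
specification diagnostics, and a synthetic survey generator that reproduces
the statistical structure the model assumes.

## Indicators

* **WDD (women's dietary diversity score, 0–10).** A 24-hour quantitative
  recall is aggregated into the ten standard MDD-W food groups; a group
  scores 1 when at least 15 g of it was consumed. The 15 g boundary is
  inclusive, because that is how an "at least" threshold reads; the
  per-group indicators also feed the descriptive food-group tables.
* **MDD-W.** Binary: 1 when WDD ≥ 5.
* **MD.** The number of distinct *purchased* food items a mother consumed
  over a 7-day recall. Distinctness is by item name as recorded, so
  different preparations of one species count separately when the survey
  records them separately. A food obtained under several sources counts
  once per source and once overall, so the per-source counts in the source
  profile are each interpretable on their own (and can sum to more than the
  overall count).
* **OFD.** The number of distinct species a household grew or collected in
  the season, pooling all use categories. Zero is meaningful (landless and
  non-growing households) and such households are retained in estimation;
  descriptive species means exclude them, mirroring how such tables are
  conventionally reported.
* **SES index.** The first factor of a one-factor analysis
  (`stats::factanal`, regression scores) of the six standardized asset
  counts — bicycles, motorcycles, motor vehicles, radios, TVs, cellphones —
  pooled over both survey rounds. The score is oriented to correlate
  positively with total asset ownership. When the factor solution is
  degenerate (Heywood case, non-convergence) or there are fewer households
  than asset types, the first principal component is used instead, with a
  warning. Scores are invariant to positively rescaling any asset column
  because columns are standardized first.

## The three-equation system

For mother/household $i$:

$$DD_i = \exp(x_i'\omega + \delta\,OFD_i + \zeta\,MD_i) + e_i$$
$$MD_i = x_i'\lambda + z_i'\beta + u_i$$
$$OFD_i = \exp(x_i'\theta + z_i'\gamma) + v_i$$

$x_i$ collects the exogenous covariates (market-shed dummies with the rural
shed as reference, travel time and its square, gender-specific income-source
variables with the two low agriculture-importance ratings pooled as
reference, mother's age, education, ethnicity, family size, three village
climate variables, and a dry-season dummy). $z_i$ holds the excluded
instruments: landholdings, landholdings squared, and the SES index.
Landholding size shifts OFD through plot heterogeneity but is excluded from
the DD mean once agricultural income importance is controlled; wealth shifts
purchasing (MD) but not current consumption decisions directly. DD and OFD
are counts, hence the exponential (Poisson-type) means; MD is left linear.

The DD equation contains the two endogenous regressors and **excludes** $z$;
the MD and OFD equations are just-identified (their regressors equal their
instruments $(x, z)$). With three instruments and two endogenous regressors
the system has one overidentifying restriction.

## Estimation

The moment vector stacks, per equation, residual × instrument row. Each
equation's moments depend only on its own parameters, so the Jacobian is
block diagonal; the equations are tied together through the joint weighting
matrix, which exploits cross-equation error correlation (the full-information
property that makes the estimator asymptotically equivalent to an efficient
full-information IV estimator).

Numerical choices, in the order they matter:

* **Step 1** minimizes the moment norm under a 2SLS-type block weight
  $(Z_k'Z_k/n)^{-1}$, from equation-wise starting values (least squares;
  Poisson-type IRLS ignoring endogeneity for the exponential links). The
  2SLS-type weight — rather than the identity — makes the first step, and
  with it the whole two-step estimator and the J statistic, exactly
  invariant to nonsingular re-combinations of the instrument set.
* **Step 2** re-minimizes under $W = \hat S^{-1}$, where $\hat S$ is the
  cluster-aggregated outer product of moments at the step-1 estimates
  (households cluster; a village-level option exists). `weighting =
  "iterated"` repeats the weight update until the estimates stabilize; true
  continuous updating was deliberately not implemented because the
  continuously updated objective is numerically fragile with exponential
  links at these sample sizes, and the iterated fixed point bounds the same
  drift (a property test checks the two-step and iterated solutions agree
  closely).
* **Optimizer.** Gauss–Newton on the weighted moment norm with the analytic
  Jacobian (finite differences are fragile under exponential links),
  step-halving line search, convergence at gradient norm $<10^{-8}$, at
  most 500 iterations.
* **Conditioning.** Design columns are internally centered (when an
  explicit constant column can absorb the shift — never otherwise, since
  centering without a constant changes the moment span) and scaled to unit
  root-mean-square; estimates and covariance are mapped back exactly.
  Near-constant covariates such as village climate otherwise make the
  weighting matrix badly conditioned and slow the optimizer by an order of
  magnitude.
* **Overflow guard.** Inside the optimizer, linear indices are clipped at
  ±30 before exponentiation; a solution sitting on the clip boundary is
  flagged non-converged.
* **Inference.** Cluster-robust sandwich covariance
  $A^{-1} B A^{-1}/n$ with $A = G'WG$, $B = G'W\hat S_{\text{final}}WG$;
  two-tailed normal p-values with significance stars at 0.05/0.01/0.001.
  With singleton clusters this reduces exactly to the
  heteroskedasticity-robust covariance.
* **J statistic.** $J = n\,\bar g'W\bar g$ at the optimum; in a
  just-identified system the optimizer drives it to numerical zero.

## Diagnostics

* **Durbin–Wu–Hausman (control-function form).** Each endogenous regressor
  is regressed on $(x, z)$, the first-stage residuals are appended to the DD
  equation, and their coefficients are jointly tested with a cluster-robust
  Wald statistic. The classic estimator-contrast form is fragile with
  exponential links, which is why the variable-addition form is used. The
  default first stage is **linear for both endogenous regressors**: a linear
  projection residual is exactly orthogonal to the exogenous set in sample,
  which keeps the test correctly sized even when a first-stage mean model is
  misspecified. An exponential-mean first stage for the OFD count is
  available (`first_stage = "exponential"`), but simulation in this
  package's test suite shows it over-rejects when the SES instrument carries
  the estimation noise of a fitted factor score, so it is not the default.
* **Sargan–Hansen.** The step-2 J with $\chi^2$ reference on the
  overidentification degree; the p-value reported is computed from the very
  J the estimator reports (single source of truth). Not applicable for
  just-identified systems.
* **Weak instruments.** Linear first stages (the first-stage F statistic is
  defined for linear projections, also for the count regressor), with a
  cluster-robust F on the excluded instruments and the partial R². The
  common F > 10 rule of thumb is the reading aid; no critical-value tables
  are shipped. One caveat the test suite documents: a robust Wald on an
  extremely heavy-tailed column (landholdings squared under a wide
  log-normal) is liberal in finite samples — a property of the statistic,
  not of the implementation, which matches an independent reference
  implementation to machine precision.

## The synthetic survey generator

`synth_generate()` emulates the structure the analysis assumes; its defaults
are the study conditions the package is validated under:

* 9/11/13 villages in urban/semi-urban/rural market-sheds, ~15 households
  per village and season; two seasons with a panel-overlap fraction of
  302/652. `synth_config_study()` pins the exact shape (33 villages,
  652 households, 472 + 482 = 954 mother-season rows, 302 households in
  both).
* Village-level travel time (truncated normal, mean 31 min) and climate.
  Both spreads are deliberately narrow: the villages sit in three adjacent
  districts of one agro-ecological zone, and the quadratic travel responses
  carry point estimates that would otherwise imply implausibly large
  outcome gradients across villages.
* A landless point mass (default 25%) and log-normal landholdings.
* Asset counts driven by a latent wealth factor $w$ through log-linear
  Poisson loadings. The structural MD and OFD equations use $w$ itself; the
  estimation pipeline by default re-estimates the SES score from the
  generated assets, deliberately mimicking the generated-regressor situation
  of real data (`use_true_wealth = TRUE` switches to the clean oracle).
* A shared household shock $\eta \sim N(0, \sigma_\eta^2)$ entering all
  three equations with loadings $\kappa$ (exponential-link loadings are
  mean-centered so the structural residuals stay mean zero given the
  exogenous variables). The shock is shared across a household's two season
  rows, which is exactly what makes household-clustered standard errors
  necessary.
* Structural slope coefficients default to the estimated system's values;
  equation intercepts are calibrated at generation time so the mean
  outcomes land at their survey levels (mean DD ≈ 4.5, MD ≈ 17.9,
  OFD ≈ 5).
* **The score draw.** The 0–10 DD score is drawn, by default, as ten group
  indicators with common success probability $\exp(\text{index})/10$ — a
  binomial count whose mean is exactly the exponential index wherever that
  mean is below 10. This mirrors the survey instrument (a sum of ten
  indicators), reproduces the underdispersion characteristic of an observed
  group-count score, and avoids the truncation a Poisson draw capped at 10
  suffers at a mean of 4.5, where cap saturation of several percent
  attenuates all score-equation slopes. A `dd_family = "poisson"` option
  retains the capped-Poisson variant for studying exactly that tension; the
  generator warns when the mean exceeds the bound on more than 20% of rows.
* In survey mode the generator additionally realizes item-level food
  records, gram recalls and species inventories whose recomputed indicators
  reproduce the generated counts exactly (a round-trip identity the test
  suite asserts).

What the generator does **not** emulate: real Benin food and species lists
(names are synthetic placeholders; a small illustrative food-group lookup
ships in `extdata`), GIS-based travel-time band construction, sampling
weights, item-level gram distributions beyond the threshold structure, and
any spatial market network. Passing tests therefore demonstrate that the
statistical machinery recovers the structure the model assumes — not that
the model is true of any particular real data set.

## Validation experiments and problem sizes

The test suite runs, among others: parameter recovery over 200 synthetic
surveys of ~5,000 mother-seasons each (bias and coverage of $\delta$ and
$\zeta$, against a naive uninstrumented fit); exogenous-data equivalence
with single-equation least-squares/Poisson oracles at n = 2,000; empirical
size of the endogeneity test over 500 replicates at n = 1,000 and of the
overidentification test over 500 replicates at n = 4,000 (the larger size
because the 66-moment clustered J approaches its asymptotic reference
slowly from the conservative side); and endogeneity-test power under
`synth_config_endogenous()`, a named scenario with large shock loadings and
reinforced instrument relevance — reinforced because a control-function test
can only see endogeneity through the variation its instruments explain, and
the score equation's bounded outcome caps how much shock loading it can
carry. These sizes are the package's choices for routine validation; all
experiments are plain R functions and scale up freely.

## Known limitations

* The estimator conditions on an uncapped exponential mean for a bounded
  score; the generator quantifies (and by default avoids) the resulting
  attenuation, but real 0–10 scores with means near the bound would need a
  bounded-mean specification.
* The MDD-W variant (`variant = "mddw_outcome"`) applies the same
  exponential-mean moment structure to a binary outcome; it is a robustness
  variant, not a recommended binary-outcome model.
* Two-step GMM inference ignores the sampling noise of the estimated SES
  factor score (as applied work typically does); the generator's default
  reproduces this situation so its consequences are visible in the
  validation experiments rather than hidden.
* With few clusters (e.g. village-level clustering: 33 clusters against 65
  parameters) the sandwich covariance is fragile; the fit warns.
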