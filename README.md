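# divtriad

Rural households in low-income settings obtain dietary variety through two
channels at once: the portfolio of plant species they grow or collect
(**on-farm diversity**, OFD) and the variety of foods they purchase in local
markets (**market diversity**, MD). Whether either channel actually improves
the **dietary diversity** (DD) of the women who manage household food
provisioning is confounded by the fact that production, purchasing and
consumption are decided jointly. `divtriad` implements the complete analysis
chain for this question on two-season household-survey data:

* **Indicators** — the ten-group women's dietary diversity score from a
  24-hour recall (a group counts at ≥ 15 g), the binary MDD-W indicator
  (WDD ≥ 5), distinct purchased-food counts from a 7-day recall, distinct
  species counts per household, and an asset-based socioeconomic index
  (first factor of six asset counts).
* **A three-equation simultaneous system** estimated by two-step GMM with
  instrumental variables and household-clustered sandwich inference:

  DD_i = exp(x_i'ω + δ·OFD_i + ζ·MD_i) + e_i
  MD_i = x_i'λ + z_i'β + u_i
  OFD_i = exp(x_i'θ + z_i'γ) + v_i

  with excluded instruments z = (landholdings, landholdings², SES index).
  DD and OFD are counts and get exponential (Poisson-type) means; the system
  has one overidentifying restriction.
* **Diagnostics** — Durbin–Wu–Hausman endogeneity test (control-function
  form), Sargan–Hansen overidentification test, and first-stage
  weak-instrument F statistics with partial R².
* **A synthetic household-survey generator** reproducing the statistical
  structure the model assumes (villages in three market-sheds, partial panel
  overlap, landless point mass, latent-wealth-driven assets, and a shared
  household shock that makes OFD and MD endogenous), so the whole pipeline
  is testable without any data download.

See the methods vignette (`vignettes/diversity-triad-methods.Rmd`) for the
model, the estimator's numerical choices and the generator's design.

## Worked example

```r
library(divtriad)

sim <- emulate_study_shape(seed = 1, mode = "survey")  # 33 villages, 2 seasons
ind <- compute_indicators(sim$bundle)                  # WDD/MDD-W/MD/OFD/SES
des <- build_design(sim$bundle$household, ind, model_spec())
fit <- fit_gmm_system(des)
fit
#> System GMM fit (two_step weighting): 954 obs, 652 clusters
#>   65 parameters, 66 moments (overidentification dof 1)
#>   J = 0.1908, converged: TRUE (10 iterations)
```

The coefficient table is arranged with one column pair per outcome equation
(stars at 0.05/0.01/0.001 from two-tailed normal p-values):

```r
ct <- coef_table(fit, digits = 3)
ct[ct$variable %in% c("OFD", "MD", "landholdings", "SES", "season_dry"), ]
#>        variable dd_estimate dd_stars md_estimate md_stars ofd_estimate ofd_stars
#> 19   season_dry       0.345      ***      -1.287      ***       -0.520       ***
#> 20          OFD       0.077      ***          NA                    NA
#> 21           MD       0.022                   NA                    NA
#> 22 landholdings          NA                0.081                 0.144       ***
#> 24          SES          NA                1.122      ***       -0.062        **
```

Reading it: each unit of on-farm diversity multiplies the expected dietary
diversity score by exp(0.077) ≈ 1.08 in this synthetic draw (the generator's
true values are δ = 0.036, ζ = 0.023; at n = 954 a single draw carries
standard errors of a few hundredths). Landholdings shift OFD and wealth
shifts MD — the instrument relevance pattern the identification relies on.

```r
diagnose(des, fit)
#> Specification diagnostics
#>   Durbin-Wu-Hausman: chi2(2) = 3.374, p = 0.1851 (small p: endogeneity)
#>   Sargan-Hansen: J = 0.191, chi2(1), p = 0.6623 (small p: invalid instruments)
#>   First-stage F on excluded instruments:
#>     OFD          F(3, 651) = 23.86, p = 1.17e-14, partial R2 = 0.078
#>     MD           F(3, 651) = 12.12, p = 9.987e-08, partial R2 = 0.041
```

`run_pipeline()` performs the whole chain in one call and writes indicator,
descriptive, coefficient and diagnostics artifacts; a thin command-line
wrapper with `simulate` / `indicators` / `estimate` / `diagnose` / `report` /
`run-all` subcommands ships in `inst/cli/divtriad.R`.

Real data come in as four UTF-8 CSV tables (household, 7-day food items,
24-hour recall grams per food group, species inventory) via
`read_survey_bundle()`; column contracts are documented in the function
reference.

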