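# vitdpk

Population pharmacokinetics of oral cholecalciferol (vitamin D3) and its
metabolites 25-hydroxyvitamin D3 (25D3), 1,25-dihydroxyvitamin D3 and
24,25-dihydroxyvitamin D3, for the chronic kidney disease (CKD) setting.

Vitamin D deficiency is nearly universal in CKD, and dosing guidance is
extrapolated from the general population. `vitdpk` implements, as reusable
and tested R code, the modelling workflow behind a single-dose (5000 I.U.)
parent-plus-three-metabolites population PK analysis in vitamin-D-deficient
CKD patients, and the dose-regimen simulations such a model supports. It is
aimed at pharmacometricians who want to reuse, stress-test or extend the
model: simulate virtual studies, re-estimate parameters under censoring,
screen covariates, and project repletion times for candidate regimens.

## The model

A linear compartmental cascade in molar units (nmol, nmol/L, h):

* cholecalciferol: first-order oral absorption (ka) into a two-compartment
  model (Vc/F, Vp/F, Q/F, CL/F) with zero-order endogenous production
  k_endog;
* 25D3: one compartment (V_m1, CL_m1), formed from a fraction fm1 = 1 of
  parent elimination;
* 1,25D3 and 24,25D3: one compartment each, formed from fractions
  fm2 = 0.017 and 1 − fm2 of 25D3 elimination.

so dx/dt = A x + b is solved exactly (matrix exponential / closed-form
spectral cascade) for any dosing schedule. Inter-individual variability is
log-normal on C0, Vc/F and CL/F (P_i = TVP·exp(η)); residual error is
proportional per analyte; concentrations below the assay limit enter the
likelihood by Beal's M3 method, log Φ((LLOQ − f)/(σf)), or are dropped
(M1). Estimation maximizes the Laplace-approximated marginal likelihood;
diagnostics include CWRES-based goodness of fit and a visual predictive
check; `simulate_regimen()` runs the 6-month daily-dosing projections.

## Worked example

```r
library(vitdpk)

model <- population_model()          # final-model estimates + IIV + error
ds <- generate_study(study_design(), model, seed = 1)  # 29-subject study
ds
#> PK dataset: 29 subjects, 1276 observations (30 BLQ), 29 dose events

# re-estimate the 25D3 submodel from this study, everything else fixed
fit <- fit_population(
  ds, population_model(fixed = setdiff(names(structural_params()),
                                       c("C0_m1", "V_m1", "CL_m1"))),
  estimate_omega = FALSE)
fit
#> Population fit (M3): OFV 2163.181, AIC 2177.181, 7 estimated, converged: FALSE
#>   optimizer: false convergence (8)
#>             estimate    CV%
#> C0_m1        41.3100   4.39
#> V_m1         70.7000  86.20
#> CL_m1         0.0218   6.24
#> sigma_VITD3   0.1438   4.66
#> sigma_D25     0.6981   6.00
#> sigma_D125    0.1680   3.96
#> sigma_D2425   0.1697   4.00
#> eta-shrinkage: C0=0.23, Vc_F=0.23, CL_F=0.08

# six months of 5000 I.U./day: mean 25D3 curve over 20 x 29 subjects
sim <- simulate_regimen(regimen_scenario(5000, seed = 1), model)
sim
#> Regimen: 5000 I.U./day x 180 days (20 replicates x 29 subjects)
#>   max mean 25D3: 220.8 ng/mL (sd 0.07)
#>   time to 30 ng/mL: 187 h
```

The fitted `C0_m1` (baseline 25D3, nmol/L) comes back within a few percent
of the generating value 43.5, `V_m1` — a slow-turnover volume observed for
only 14 days — carries the wide CV this design implies, and the "false
convergence" note is the optimizer reporting the flat likelihood valley
that goes with it. The regimen summary says a CKD patient population on
5000 I.U./day is predicted to average ~221 ng/mL of 25D3 after six months
(far above the 30-60 ng/mL target window; the lower dose arms land inside
it), crossing 30 ng/mL after about a week.

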