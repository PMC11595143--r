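---
title: "Population pharmacokinetics of cholecalciferol and its metabolites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of cholecalciferol and its metabolites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdpk)
```

## The model

`vitdpk` implements a population pharmacokinetic model of oral
cholecalciferol (vitamin D3, "VitD3") and its three sequential metabolites
in patients with chronic kidney disease and vitamin D deficiency:
25-hydroxyvitamin D3 (25D3, the major circulating form), the active hormone
1,25-dihydroxyvitamin D3 (1,25D3), and the catabolic product
24,25-dihydroxyvitamin D3 (24,25D3).

The structural model is linear and compartmental:

* VitD3: first-order oral absorption (rate constant $k_a$) from a depot
  into a two-compartment disposition model (apparent central volume
  $V_c/F$, peripheral volume $V_p/F$, intercompartmental clearance $Q/F$,
  apparent clearance $CL/F$), plus a zero-order endogenous production
  $k_{endog}$ (diet and skin synthesis) into the central compartment.
* 25D3: one compartment ($V_{m1}$, $CL_{m1}$) fed by a fraction
  $f_{m1}$ of parent elimination. $f_{m1}$ is fixed at 1: the parent is
  administered alone, so the metabolite scale parameters are only
  identified relative to an assumed conversion fraction.
* 1,25D3 and 24,25D3: one compartment each ($V_{m2}, CL_{m2}$ and
  $V_{m3}, CL_{m3}$), fed by fractions $f_{m2} = 0.017$ and $1 - f_{m2}$
  of 25D3 elimination. Only the terminal metabolites eliminate drug from
  the system.

Writing the six compartment amounts (depot, parent central, parent
peripheral, 25D3, 1,25D3, 24,25D3) as $x$, the system is
$\dot x = A x + b$ with a constant matrix $A$ and input
$b = (0, k_{endog}, 0, 0, 0, 0)^T$. `build_rate_matrix()` exposes $A$ and
$b$; `simulate_profile()` returns concentrations.

All internal computation is molar (nmol, nmol/L, hours). Mass units
(ng/mL) and international units are converted at the boundary only
(`ngml_to_nmoll()`, `iu_to_nmol()`, with 40 I.U. = 1 microgram of
cholecalciferol). The canonical parameter values are stored in molar
units; the package deliberately never re-derives them from mass-unit
figures, because published mass/molar pairs for these analytes are easy to
get wrong (the package's canonical set reflects the molar values). An
alternative preset (`params_preset("early-fixed")`) preserves an earlier
fixed-parameter choice ($k_a$ 0.323 h$^{-1}$, $V_p/F$ 2333 L, $Q/F$ 0.185
L/h) for sensitivity analyses; it is not the default.

### Baselines are initial conditions

Each compound starts at its baseline concentration ($C_0$, $C_{0,m1}$,
$C_{0,m2}$, $C_{0,m3}$) times its volume; the parent peripheral
compartment starts in distribution equilibrium with the central one
($C_0 \cdot V_p/F$), the only choice with no transient at $t = 0^-$. No
hidden inputs are added to hold the metabolites at their baselines:
$k_{endog}$ stays fixed at 0.55 nmol/h even though $CL/F \cdot C_0 =
1.372$ nmol/h, so in the absence of dosing the profiles relax from the
baselines toward the equilibria $k_{endog}/(CL/F)$ for the parent and
$f_{m1} k_{endog}/CL_{m1}$ etc. for the metabolites. This choice — rather
than re-balancing $k_{endog}$ to freeze the baselines — is what reproduces
the magnitudes of the published dosing simulations, and it treats the
measured baselines as data-derived initial states rather than enforced
steady states; the mismatch between the fixed $k_{endog}$ and the
baselines is a declared modelling compromise inherited from the original
analysis.

### Exact solution

Because the system is linear and time-invariant between dose events, the
solver is exact: deviations from equilibrium are propagated by the matrix
exponential, with each oral dose deposited instantaneously into the depot
(dose-first when a dose and an observation coincide). The implementation
exploits the block-triangular structure — eigenvalues are $-k_a$, the
classic two-compartment $\alpha$ and $\beta$, and the three metabolite
elimination rate constants, all real — so the propagator reduces to a
closed-form exponential-sum cascade. Near an eigenvalue coincidence
(which makes the cascade denominators degenerate) the code falls back to a
numerically computed matrix exponential. Exactness removes integrator
tolerances from the scientific results; an adaptive ODE integration
(deSolve) serves as an independent oracle in the test suite, with
agreement required to 1e-8 relative error on randomized parameter sets.

## Stochastic components

Inter-individual variability (IIV) is log-normal,
$P_i = TVP\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$, on the parent
baseline $C_0$, $V_c/F$ and $CL/F$ — the random-effect set of the final
model. The study the package models does not report the $\omega^2$
estimates, so the default $\omega^2 = 0.09$ (30% CV) on each is a declared
simulation assumption of a typical pharmacokinetic magnitude, carried in
the model configuration, not presented as a literature value.

Residual error is proportional per analyte, $y = f \cdot (1 +
\sigma \varepsilon)$, with $\sigma$ = 0.125, 0.657, 0.172, 0.166 for
VitD3, 25D3, 1,25D3, 24,25D3 (additive and combined forms are available
for model comparison). Noise is Gaussian on the concentration scale,
consistent with the censored-likelihood treatment below; simulated values
below the assay lower limit of quantification (LLOQ: 0.1, 1.0, 0.01, 0.1
ng/mL respectively), including the occasional negative draw under the
large 25D3 error, become below-limit (BLQ) records with the value
withheld.

### Censored observations: M1 and M3

Quantified records contribute a Gaussian log-density with prediction-
scaled standard deviation $\sigma f$. BLQ records are handled by either of
the two classical methods: M1 discards them; M3 keeps them with the
censored-likelihood contribution $\log \Phi\!\big((LLOQ - f)/(\sigma
f)\big)$ — the probability the model assigns to the unquantifiable region.
The plain CDF (no additional truncation at zero) is used, the standard
formulation of the M3 method. A floor of $10^{-10}$ nmol/L on predictions
inside the likelihood guards the proportional variance; it is far below
any physical concentration.

## Estimation

`fit_population()` maximizes the marginal likelihood: for each subject the
conditional likelihood is integrated over the random effects by a Laplace
approximation around the posterior mode of $\eta$ (inner quasi-Newton
search, finite-difference curvature). The outer optimization works on an
unconstrained scale — log for positive parameters and variances, logit for
fractions — with `stats::nlminb`. The objective function value is
OFV $= -2 \log L$; AIC adds 2 per estimated parameter. Standard errors
(reported as CV%) come from the inverse Hessian of the negative marginal
log-likelihood on the transformed scale, delta-method back-transformed;
the condition number of the estimate correlation matrix and per-$\eta$
shrinkage $1 - \mathrm{sd}(EBE)/\omega$ (flagged above 0.40) accompany
every fit. The fixed/estimated split of the final model holds $k_a$,
$k_{endog}$, $V_p/F$, $Q/F$, $f_{m1}$ and $f_{m2}$ fixed.

The Laplace scheme replaces the proprietary expectation-maximization
engine used in the original analysis; equivalence is asserted behaviorally
— the test suite requires agreement with brute-force three-dimensional
quadrature of the marginal (mode-centered trapezoidal product grid) to 1%,
including subjects with censored records — not bit-compatibility.

### Covariate screening

Covariate effects are single-coefficient relationships: a power form
centered at the covariate median for continuous covariates,
$P_i = TVP (x_i/x_{ref})^\beta$, and a proportional shift for indicator
covariates. `covariate_screen()` performs stepwise forward addition
(accept the largest OFV drop if it exceeds 3.841, the df-1 chi-square
5% point) followed by backward elimination (delete unless removal raises
the OFV by at least 6.635, the 1% point), refitting the full free
parameter set at every step and returning the complete decision trail.
The chi-square thresholds assume one degree of freedom per candidate; the
screen rejects multi-parameter forms by construction.

## Diagnostics

`gof()` returns the standard goodness-of-fit quantities: population
predictions (PRED, at $\eta = 0$), individual predictions (IPRED, at the
empirical Bayes estimates), and conditional weighted residuals (CWRES)
from a first-order conditional linearization of the subject model around
the EBE — residuals whitened by $G \Omega G^T + \Sigma$ with $G$ the
finite-difference sensitivity of the predictions to $\eta$. BLQ rows carry
predictions but no residual. On data simulated at the truth, CWRES are
standard-normal-like (the suite checks mean, variance and the ~95% share
inside $\pm 2$).

`vpc()` simulates replicates of the observed design (default 200),
applies residual error and the per-record LLOQ censoring, and compares
the 5th/50th/95th percentiles of the quantified simulated concentrations
with the observed ones per analyte and nominal time bin (the design is a
fixed grid, so no automatic binning is used). Simulated values below the
LLOQ are excluded from percentiles — mirroring what can be computed on
the observed side — and the censored fraction per bin is reported
separately, since the percentile treatment of BLQ records admits several
conventions. Band limits are across-replicate quantiles of each
percentile statistic.

## Dosing-regimen simulation

`simulate_regimen()` reproduces the repletion simulations: daily oral
dosing (600 to 10,000 I.U./day) for 6 months on an hourly grid (4320
points), 20 replicates of 29 virtual subjects each (the study size; the
original report states only the replicate count), IIV drawn fresh per
subject, residual error excluded from the mean curves (it is mean-zero and
would only add noise). The summary is the mean 25D3 curve in ng/mL, its
maximum (which, for these regimens, the test suite verifies is the
end-of-treatment value — the curves are still rising at 6 months), the
across-replicate spread, and the first hourly grid time at which the mean
curve reaches the 30 ng/mL repletion target (74.88 nmol/L). Doses are
administered at 24-hour intervals starting at $t = 0$.

An instructive analytic limit — instantaneous absorption and conversion,
so 25D3 sees a constant-rate input $\text{dose}/24 + k_{endog}$ — gives
$C_{ss} = (\text{dose rate} + k_{endog})/CL_{m1}$ and an exponential
approach with rate $CL_{m1}/V_{m1}$. The full model lands within a few
percent of this limit at the end of treatment, and the five end-of-
treatment means match the published 38.1, 54.1, 95.3, 218.5 and 424.03
ng/mL within a few percent.

The published time to reach 30 ng/mL under 5000 I.U./day is 144 h; the
analytic limit above gives 142 h. The full compartmental model, however,
crosses at about 186 h: oral absorption ($1/k_a = 18.5$ h) and parent
distribution delay the metabolite input, and because the mean curve is
still about 11% below target at 144 h, a small concentration gap
translates into a large crossing-time gap. We report the model's crossing
time as computed; reproducing the printed 144 h would require either the
instantaneous-absorption limit or a different fixed parent disposition
(the `"early-fixed"` preset crosses at about 164 h), and the published
crossing times for the other dose arms are mutually inconsistent with any
single convention we could construct. The end-of-treatment
concentrations, which are insensitive to the early-time delay, are the
robust quantities.

## Synthetic studies and what passing tests mean

`generate_study()` draws studies with the design of the modelled trial
(29 subjects, one 5000 I.U. dose, sampling at 0-336 h, four analytes,
assay LLOQs) from any `population_model()`: random effects, exact
profiles, proportional noise, LLOQ censoring, with the true $\eta$ and
individual parameters attached for recovery experiments.
`generate_covariates()` emulates the cohort table (weight median 92 kg,
range 70.7-135.3; eGFR 37, 11-97; 59% female; genotype frequencies at the
vitamin-D loci) with two-piece uniform distributions anchored at the
reported median and bounded by the reported range — only those summaries
are honoured.

The generator emulates the statistical structure the analysis assumes —
log-normal IIV, proportional Gaussian error, deterministic kinetics — and
none of the things real data add: assay drift, between-visit variation,
seasonal endogenous input, enterohepatic recirculation, binding-protein
kinetics, dropout. Passing recovery and calibration tests therefore
demonstrates internal consistency of the estimator with the declared
model, not robustness to those violations.

One structural property of the design matters for interpretation: with a
single dose and 14 days of sampling, the terminal metabolite pairs
$(V_{m2}, CL_{m2})$ and $(V_{m3}, CL_{m3})$ are only weakly identified —
profiles over 336 h constrain mostly their ratios, and the original
analysis itself reports >100% CV on those volumes. In
simulation-estimation experiments at $n = 100$ subjects this appears as a
slow, flat likelihood valley: baseline parameters recover to within a few
percent, while the metabolite clearances scatter by 15-35% (about one
standard error, as the chi-square distance between the truth and the
optimum confirms), with a finite-sample drift toward higher clearances
and lower $V_{m1}$ that shrinks with $n$. The recovery experiments in
the test suite use three studies of 100 subjects with a fixed
optimization protocol (`nlminb` with an explicit finite-difference
gradient, relative tolerance $10^{-7}$, a 50-iteration budget) and a
$\pm 15$% perturbed start; the IIV variances are
held at their known simulation values there, since the original estimated
set does not report them.

Problem sizes throughout the suite (subjects per study, replicate counts,
quadrature grids) are chosen as the smallest that make each property
statistically decisive; the regimen simulations always use the full
protocol (4320 points, 20 replicates).

## Pipeline and reproducibility

`run_pipeline()` chains `generate`, `fit` (optionally both BLQ methods for
OFV comparison), `gof`, `vpc` and `simulate` from one configuration with a
single top-level seed; every artifact directory carries a manifest with
the configuration hash, seed and package version, and identical
configurations reproduce identical artifacts. Datasets are NONMEM-style
CSV (ID, TIME, AMT, EVID, DVID, DV, BLQ, LLOQ), always stored in nmol/L
with full double precision; ng/mL is accepted on input and converted
immediately, avoiding the unit ambiguities that plague this literature.
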