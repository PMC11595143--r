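Package: vitdpk
Title: Population Pharmacokinetics of Cholecalciferol and Its Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic modelling of oral
    cholecalciferol (vitamin D3) and its sequential metabolites
    25-hydroxyvitamin D3, 1,25-dihydroxyvitamin D3 and
    24,25-dihydroxyvitamin D3, with an emphasis on chronic kidney disease
    study designs. Implements a linear parent-metabolite compartmental
    model solved exactly by matrix exponentials, log-normal
    inter-individual variability, proportional residual error, censored
    (below-quantification-limit) likelihood via the M1 and M3 methods,
    Laplace-approximated marginal-likelihood estimation with stepwise
    covariate screening, goodness-of-fit and visual-predictive-check
    diagnostics, a synthetic-study generator, and multi-dose regimen
    simulation for 25-hydroxyvitamin D3 target attainment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2
Config/testthat/edition: 3
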