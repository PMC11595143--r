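# Shared fixtures: everything is generated in code at test time.

# a model with no random effects / no residual noise, for exactness checks
noiseless_model <- function(sigma = 0) {
  population_model(
    omega2 = stats::setNames(numeric(0), character(0)),
    sigma = c(VITD3 = sigma, D25 = sigma, D125 = sigma, D2425 = sigma))
}

# random positive parameter set in physiologically plausible ranges
random_params <- function() {
  structural_params(
    ka = stats::runif(1, 0.02, 0.5),
    k_endog = stats::runif(1, 0.1, 2),
    Vc_F = stats::runif(1, 5, 60),
    CL_F = stats::runif(1, 0.3, 4),
    Vp_F = stats::runif(1, 10, 200),
    Q_F = stats::runif(1, 0.05, 2),
    C0 = stats::runif(1, 0.2, 3),
    fm1 = stats::runif(1, 0.5, 1),
    C0_m1 = stats::runif(1, 10, 80),
    V_m1 = stats::runif(1, 20, 150),
    CL_m1 = stats::runif(1, 0.005, 0.1),
    fm2 = stats::runif(1, 0.005, 0.1),
    C0_m2 = stats::runif(1, 0.05, 0.5),
    V_m2 = stats::runif(1, 30, 150),
    CL_m2 = stats::runif(1, 0.02, 0.3),
    C0_m3 = stats::runif(1, 0.5, 5),
    V_m3 = stats::runif(1, 40, 200),
    CL_m3 = stats::runif(1, 0.1, 1))
}

# small observation-only dataset builder for likelihood unit tests
tiny_dataset <- function(conc, times, analyte = "D25", blq = NULL,
                         lloq = NA_real_, id = 1L, dose_iu = 5000) {
  n <- length(conc)
  blq <- blq %||% rep(0L, n)
  obs <- data.frame(ID = id, TIME = times, AMT = 0, EVID = 0L,
                    DVID = analyte, DV = conc, BLQ = blq, LLOQ = lloq)
  dose <- data.frame(ID = id, TIME = 0, AMT = dose_iu, EVID = 1L,
                     DVID = NA_character_, DV = NA_real_, BLQ = 0L,
                     LLOQ = NA_real_)
  as_pk_dataset(rbind(dose, obs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

TAB2_TIMES <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 48, 168, 336)
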