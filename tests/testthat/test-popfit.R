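test_that("with vanishing IIV the marginal collapses to the conditional", {
  ds <- generate_study(study_design(n_subjects = 1L), population_model(),
                       seed = 17L)
  sub <- vitdpk:::split_subjects(ds)[[1L]]
  m0 <- population_model(omega2 = stats::setNames(numeric(0), character(0)))
  cond <- marginal_loglik_subject(sub, m0)
  expect_length(cond$eta, 0L)
  # manual conditional at eta = 0
  pred <- vitdpk:::subject_pred(sub, m0$params)
  manual <- sum(obs_loglik(sub$conc, sub$blq, sub$lloq,
                           pmax(pred, 1e-10),
                           sigma = m0$sigma[sub$analyte]))
  expect_equal(cond$loglik, manual, tolerance = 1e-10)
  m_tiny <- population_model(omega2 = c(C0 = 1e-12, Vc_F = 1e-12,
                                        CL_F = 1e-12))
  near <- marginal_loglik_subject(sub, m_tiny)
  expect_equal(near$loglik, manual, tolerance = 1e-4)
})

test_that("Laplace agrees with brute-force quadrature on a toy study", {
  ds <- generate_study(study_design(n_subjects = 2L,
                                    sample_times = c(0, 4, 24, 168),
                                    analytes = c("VITD3", "D25")),
                       population_model(), seed = 23L)
  model <- population_model()
  for (sub in vitdpk:::split_subjects(ds)) {
    lap <- marginal_loglik_subject(sub, model)$loglik
    quad <- quadrature_marginal(sub, model)
    expect_equal(lap, quad, tolerance = 0.01)
  }
})

test_that("evaluating with everything fixed is a fixed point of fitting", {
  ds <- generate_study(study_design(n_subjects = 4L), population_model(),
                       seed = 29L)
  model <- population_model(fixed = vitdpk:::PARAM_NAMES)
  fit <- fit_population(ds, model, estimate_sigma = FALSE,
                        estimate_omega = FALSE)
  expect_equal(fit$n_estimated, 0L)
  expect_true(fit$converged)
  expect_equal(fit$ofv, ofv_population(ds, model), tolerance = 1e-12)
  expect_equal(fit$aic, fit$ofv)
})

test_that("AIC adds two per estimated parameter", {
  ds <- generate_study(study_design(n_subjects = 4L, analytes = "D25"),
                       population_model(), seed = 31L)
  model <- population_model(
    fixed = setdiff(vitdpk:::PARAM_NAMES, "C0_m1"),
    omega2 = stats::setNames(numeric(0), character(0)))
  fit <- fit_population(ds, model, estimate_sigma = TRUE,
                        estimate_omega = FALSE)
  expect_equal(fit$n_estimated, 2L)  # C0_m1 and sigma_D25
  expect_equal(fit$aic, fit$ofv + 4)
  expect_true(all(c("C0_m1", "sigma_D25") %in% names(fit$estimates)))
  # the one-dimensional refit actually moved toward the data
  expect_lt(abs(fit$estimates[["C0_m1"]] / 43.5 - 1), 0.2)
})

test_that("OFV differences are invariant to a change of concentration scale", {
  ds <- generate_study(study_design(n_subjects = 4L), population_model(),
                       seed = 37L)
  scale_c <- 3.7
  rescale_data <- function(d, cc) {
    d$DV <- d$DV * cc
    d$LLOQ <- d$LLOQ * cc
    as_pk_dataset(as.data.frame(d))
  }
  rescale_model <- function(m, cc) {
    p <- m$params
    for (nm in c("Vc_F", "Vp_F", "V_m1", "V_m2", "V_m3",
                 "CL_F", "Q_F", "CL_m1", "CL_m2", "CL_m3")) {
      p[[nm]] <- p[[nm]] / cc
    }
    for (nm in c("C0", "C0_m1", "C0_m2", "C0_m3")) p[[nm]] <- p[[nm]] * cc
    population_model(params = p, omega2 = m$omega2, sigma = m$sigma,
                     fixed = m$fixed)
  }
  m_a <- population_model()
  m_b <- rescale_model(population_model(), 1)  # identity check
  expect_equal(ofv_population(ds, m_b), ofv_population(ds, m_a))
  perturb <- function(m) {
    m$params$CL_m1 <- m$params$CL_m1 * 1.4
    m
  }
  d1 <- ofv_population(ds, perturb(m_a)) - ofv_population(ds, m_a)
  ds2 <- rescale_data(ds, scale_c)
  m_s <- rescale_model(m_a, scale_c)
  d2 <- ofv_population(ds2, perturb(m_s)) - ofv_population(ds2, m_s)
  expect_equal(d1, d2, tolerance = 1e-5)
})

test_that("per-observation OFV at truth is stable across seeds", {
  model <- population_model()
  vals <- vapply(c(41L, 42L, 43L), function(s) {
    ds <- generate_study(study_design(n_subjects = 30L), model, seed = s)
    ofv_population(ds, model) / sum(ds$EVID == 0L)
  }, 0)
  expect_lt(max(vals) - min(vals), 0.12 * abs(mean(vals)))
})

test_that("shrinkage is bounded and low for rich designs at truth", {
  model <- population_model()
  ds <- generate_study(study_design(n_subjects = 25L), model, seed = 47L)
  fit <- fit_population(ds, population_model(fixed = vitdpk:::PARAM_NAMES),
                        estimate_sigma = FALSE, estimate_omega = FALSE)
  shr <- eta_shrinkage(fit)
  expect_setequal(shr$parameter, c("C0", "Vc_F", "CL_F"))
  expect_true(all(shr$shrinkage >= 0 & shr$shrinkage <= 1))
  # 11 samples x 4 analytes per subject identify the parent clearance eta
  expect_lt(shr$shrinkage[shr$parameter == "CL_F"], 0.40)
  expect_false(shr$flag_removal[shr$parameter == "CL_F"])
  # shrinkage formula consistency with the stored EBEs (clamped to [0, 1])
  expect_equal(shr$shrinkage[shr$parameter == "CL_F"],
               max(0, 1 - sd(fit$ebe[, "CL_F"]) / sqrt(0.09)),
               tolerance = 1e-10)
})

test_that("the fit report serializes the estimate table", {
  ds <- generate_study(study_design(n_subjects = 3L, analytes = "D25"),
                       population_model(), seed = 53L)
  model <- population_model(
    fixed = setdiff(vitdpk:::PARAM_NAMES, "C0_m1"),
    omega2 = stats::setNames(numeric(0), character(0)))
  fit <- fit_population(ds, model, estimate_omega = FALSE)
  path <- tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$ofv, fit$ofv, tolerance = 1e-12)
  expect_equal(rep$aic, fit$aic, tolerance = 1e-12)
  expect_setequal(rep$parameters$parameter, names(fit$estimates))
  expect_equal(rep$fixed$ka, 0.054)
})
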