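test_that("log-normal IIV multiplies the targeted parameters only", {
  pop <- structural_params()
  expect_equal(apply_iiv(pop, c(C0 = 0, Vc_F = 0, CL_F = 0)), pop)
  ind <- apply_iiv(pop, c(CL_F = log(2)))
  expect_equal(ind$CL_F, 2 * pop$CL_F)
  same <- setdiff(names(pop), "CL_F")
  expect_equal(ind[same], pop[same])
  expect_error(apply_iiv(pop, c(zz = 1)), "not parameters")
  expect_error(apply_iiv(pop, c(fm2 = 0.1)), "fraction")
})

test_that("sampled IIV gives a log-normal with the typical value as median", {
  set.seed(11)
  cl <- vapply(rnorm(20000, 0, 0.3),
               function(e) apply_iiv(structural_params(), c(CL_F = e))$CL_F,
               0)
  expect_equal(median(cl), 1.4, tolerance = 0.02)
  expect_gt(mean(cl), median(cl))  # right-skew
  expect_equal(sd(log(cl)), 0.3, tolerance = 0.02)
})

test_that("residual sd follows the declared error form", {
  expect_equal(residual_sd(0, 0.5, form = "proportional"), 0)
  expect_equal(residual_sd(10, 0.657, form = "proportional"), 6.57)
  expect_equal(residual_sd(c(1, 100), 0, sigma_add = 1,
                           form = "combined"), c(1, 1))
  expect_equal(residual_sd(7, 0.3, sigma_add = 2, form = "additive"), 2)
  expect_equal(residual_sd(10, 0.3, sigma_add = 4, form = "combined"),
               sqrt(16 + 9))
})

test_that("observation likelihood handles quantified and censored records", {
  # BLQ with prediction exactly at the limit: half the mass is censored
  ll <- obs_loglik(NA, blq = TRUE, lloq = 2.5, pred = 2.5, sigma = 0.657)
  expect_equal(as.numeric(ll), log(0.5), tolerance = 1e-12)
  # Gaussian at its mode
  ll <- obs_loglik(10, blq = FALSE, lloq = NA, pred = 10, sigma = 0.657)
  expect_equal(as.numeric(ll), -log(sqrt(2 * pi) * 6.57), tolerance = 1e-12)
  expect_equal(as.numeric(ll), -2.8014, tolerance = 1e-4)
  # prediction far above the limit: the model is contradicted
  ll <- obs_loglik(NA, blq = TRUE, lloq = 0.26, pred = 50, sigma = 0.125)
  expect_lt(as.numeric(ll), -30)
  ll2 <- obs_loglik(NA, blq = TRUE, lloq = 0.26, pred = 500, sigma = 0.125)
  expect_lt(as.numeric(ll2), as.numeric(ll))
  expect_error(obs_loglik(1, FALSE, NA, pred = -1, sigma = 0.1),
               "positive")
  expect_error(obs_loglik(NA, TRUE, NA, pred = 1, sigma = 0.1),
               "lloq")
})

test_that("M1 simply drops the censored records", {
  conc <- c(5, NA, 7, NA)
  blq <- c(FALSE, TRUE, FALSE, TRUE)
  lloq <- rep(2.5, 4)
  pred <- c(5.5, 2.0, 6.5, 1.0)
  m3 <- obs_loglik(conc, blq, lloq, pred, sigma = 0.3, method = "M3")
  m1 <- obs_loglik(conc, blq, lloq, pred, sigma = 0.3, method = "M1")
  expect_equal(m1[!blq], m3[!blq])
  expect_equal(as.numeric(m1[blq]), c(0, 0))
  expect_equal(attr(m1, "n_dropped"), 2L)
  expect_equal(attr(m3, "n_dropped"), 0L)
  # no BLQ records: the two methods coincide exactly
  a <- obs_loglik(conc[!blq], FALSE, lloq[!blq], pred[!blq], 0.3,
                  method = "M3")
  b <- obs_loglik(conc[!blq], FALSE, lloq[!blq], pred[!blq], 0.3,
                  method = "M1")
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("the M3 term equals the censored mass of the predictive density", {
  pred <- 3.2
  sigma <- 0.657
  lloq <- 2.496
  dens_mass <- integrate(function(x) dnorm(x, pred, sigma * pred),
                         -Inf, lloq, rel.tol = 1e-12)$value
  ll <- obs_loglik(NA, TRUE, lloq, pred, sigma, method = "M3")
  expect_equal(exp(as.numeric(ll)), dens_mass, tolerance = 1e-9)
})

test_that("standardized residuals are calibrated on simulated data", {
  set.seed(42)
  model <- population_model(
    omega2 = stats::setNames(numeric(0), character(0)),
    sigma = c(VITD3 = 0.1, D25 = 0.1, D125 = 0.1, D2425 = 0.1))
  ds <- generate_study(study_design(n_subjects = 150L), model, seed = 42L)
  obs <- ds[ds$EVID == 0L & ds$BLQ == 0L, ]
  prof <- simulate_profile(model$params,
                           data.frame(time = 0, amount_iu = 5000),
                           TAB2_TIMES)
  pred <- mapply(function(tt, an) prof[[an]][match(tt, prof$time)],
                 obs$TIME, obs$DVID)
  z <- (obs$DV - pred) / (0.1 * pred)
  expect_equal(mean(z), 0, tolerance = 0.03)
  expect_equal(var(z), 1, tolerance = 0.05)
})
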