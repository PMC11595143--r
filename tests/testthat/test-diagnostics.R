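test_that("noise-free data are reproduced exactly in the GOF table", {
  gen_model <- noiseless_model()
  ds <- generate_study(study_design(n_subjects = 3L), gen_model, seed = 73L)
  # evaluation model: same structure, token sigma so the OFV is defined
  eval_model <- population_model(
    omega2 = stats::setNames(numeric(0), character(0)),
    sigma = c(VITD3 = 1e-6, D25 = 1e-6, D125 = 1e-6, D2425 = 1e-6),
    fixed = vitdpk:::PARAM_NAMES)
  fit <- fit_population(ds, eval_model, estimate_sigma = FALSE,
                        estimate_omega = FALSE)
  g <- gof(fit)
  quant <- g[g$BLQ == 0L, ]
  expect_equal(quant$OBS, quant$PRED, tolerance = 1e-10)
  expect_equal(quant$IPRED, quant$PRED, tolerance = 1e-10)
  # BLQ rows still carry predictions but no residual
  expect_true(all(is.na(g$CWRES[g$BLQ == 1L])))
  expect_true(all(is.finite(g$PRED)))
})

test_that("population predictions ignore subject identity", {
  model <- population_model()
  ds <- generate_study(study_design(n_subjects = 4L), model, seed = 79L)
  fit <- fit_population(ds, population_model(fixed = vitdpk:::PARAM_NAMES),
                        estimate_sigma = FALSE, estimate_omega = FALSE)
  g1 <- gof(fit)
  relabel <- as.data.frame(ds)
  relabel$ID <- match(relabel$ID, c(3, 4, 1, 2))  # permute labels
  ds2 <- as_pk_dataset(relabel)
  fit2 <- fit_population(ds2,
                         population_model(fixed = vitdpk:::PARAM_NAMES),
                         estimate_sigma = FALSE, estimate_omega = FALSE)
  g2 <- gof(fit2)
  key <- function(g) g[order(g$analyte, g$time, g$OBS), "PRED"]
  expect_equal(key(g2), key(g1), tolerance = 1e-12)
})

test_that("conditional weighted residuals are calibrated at the truth", {
  model <- population_model()
  ds <- generate_study(study_design(n_subjects = 40L), model, seed = 83L)
  fit <- fit_population(ds, population_model(fixed = vitdpk:::PARAM_NAMES),
                        estimate_sigma = FALSE, estimate_omega = FALSE)
  g <- gof(fit)
  cw <- g$CWRES[g$BLQ == 0L]
  expect_equal(mean(cw), 0, tolerance = 0.08)
  expect_equal(stats::var(cw), 1, tolerance = 0.25)
  expect_gt(mean(abs(cw) <= 2), 0.90)
})

test_that("a single-replicate VPC collapses onto that replicate", {
  ds <- generate_study(study_design(n_subjects = 6L), population_model(),
                       seed = 89L)
  v <- vpc(ds, population_model(), n_rep = 1L, seed = 2L)
  expect_equal(v$p5_lo, v$sim_p5)
  expect_equal(v$p5_hi, v$sim_p5)
  expect_equal(v$p50_lo, v$sim_p50)
  expect_equal(attr(v, "n_replicates"), 1L)
  # percentile ordering within every bin
  expect_true(all(v$sim_p5 <= v$sim_p50 & v$sim_p50 <= v$sim_p95))
})

test_that("VPC is invariant to row order and subject labels", {
  ds <- generate_study(study_design(n_subjects = 8L), population_model(),
                       seed = 97L)
  v1 <- vpc(ds, population_model(), n_rep = 25L, seed = 3L)
  shuffled <- as.data.frame(ds)
  set.seed(1)
  shuffled <- shuffled[sample(nrow(shuffled)), ]
  shuffled$ID <- 9L - shuffled$ID  # relabel
  v2 <- vpc(as_pk_dataset(shuffled), population_model(), n_rep = 25L,
            seed = 3L)
  expect_equal(v2$obs_p50, v1$obs_p50, tolerance = 1e-12)
  expect_equal(v2$sim_p50, v1$sim_p50, tolerance = 1e-12)
})

test_that("VPC bands cover data simulated from the same model", {
  model <- population_model()
  hits <- 0L
  total <- 0L
  for (s in 1:7) {
    ds <- generate_study(study_design(), model, seed = 200L + s)
    v <- vpc(ds, model, n_rep = 100L, seed = 300L + s)
    ok <- (v$obs_p50 >= v$p50_lo & v$obs_p50 <= v$p50_hi)
    hits <- hits + sum(ok)
    total <- total + length(ok)
  }
  expect_gt(hits / total, 0.85)
})

test_that("a deliberately wrong simulation model is flagged by the VPC", {
  truth <- population_model()
  ds <- generate_study(study_design(), truth, seed = 107L)
  wrong_p <- structural_params(C0_m1 = 43.5 / 2)
  wrong <- population_model(params = wrong_p)
  v <- vpc(ds, wrong, n_rep = 70L, seed = 5L)
  d25 <- v[v$analyte == "D25", ]
  # the observed median exits the simulated band in most 25D3 bins
  expect_gt(mean(d25$obs_p50 > d25$p50_hi), 0.8)
})
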