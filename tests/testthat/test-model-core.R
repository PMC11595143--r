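test_that("rate matrix encodes the cascade and conserves internal mass", {
  p <- structural_params()
  sys <- build_rate_matrix(p)
  A <- sys$A
  # depot, central (fm1 = 1) and peripheral columns: pure mass transfer
  expect_equal(unname(colSums(A)[1:3]), c(0, 0, 0), tolerance = 1e-15)
  # every column drains or conserves
  expect_true(all(colSums(A) <= 1e-15))
  expect_equal(A["d25", "d25"], -p$CL_m1 / p$V_m1)
  expect_equal(A["d25", "d25"], -3.4305e-4, tolerance = 1e-4)
  expect_equal(sys$b, c(depot = 0, vitd3_central = 0.55,
                        vitd3_peripheral = 0, d25 = 0, d125 = 0,
                        d2425 = 0))
  # with fm2 = 0 nothing flows into the 1,25D3 compartment
  A0 <- build_rate_matrix(structural_params(fm2 = 0))$A
  expect_equal(unname(A0["d125", ]), c(0, 0, 0, 0, A0["d125", "d125"], 0))
  bad <- unclass(structural_params())
  bad$CL_m1 <- -0.1
  expect_error(build_rate_matrix(bad), "strictly positive")
})

test_that("initial state places baselines in every compartment", {
  p <- structural_params()
  x <- initial_state(p)
  expect_equal(unname(x["depot"]), 0)
  expect_equal(unname(x["vitd3_central"]), 20.874, tolerance = 1e-10)
  expect_equal(unname(x["vitd3_peripheral"]), 0.98 * 50)
  expect_equal(unname(x["d25"]), 43.5 * 58.3, tolerance = 1e-12)
  expect_equal(unname(x["d125"]), 0.20 * 71.5)
  expect_equal(unname(x["d2425"]), 2.2 * 105.2)
  eps <- 1e-9
  near0 <- structural_params(C0 = eps, C0_m1 = eps, C0_m2 = eps,
                             C0_m3 = eps)
  expect_lt(max(initial_state(near0)), 1e-5)
})

test_that("a consistent steady state is a fixed point of the solver", {
  p <- structural_params()
  # re-balance so every baseline equals its influx/clearance ratio
  p <- structural_params(k_endog = p$CL_F * p$C0,
                         C0_m1 = p$fm1 * (p$CL_F * p$C0) / p$CL_m1,
                         C0_m2 = p$fm2 * (p$CL_F * p$C0) / p$CL_m2,
                         C0_m3 = (1 - p$fm2) * (p$CL_F * p$C0) / p$CL_m3)
  prof <- simulate_profile(p, NULL, c(0, 10, 100, 1000, 1e5))
  for (an in ANALYTES) {
    expect_equal(prof[[an]], rep(prof[[an]][1L], 5L), tolerance = 1e-9)
  }
})

test_that("dose-free profiles relax to the closed-form equilibrium", {
  prof <- simulate_profile(structural_params(), NULL, 2e6)
  expect_equal(prof$VITD3, 0.55 / 1.4, tolerance = 1e-3)
  expect_equal(prof$D25, 27.5, tolerance = 1e-3)
  expect_equal(prof$D125, 0.017 * 0.55 / 0.08, tolerance = 1e-3)
  expect_equal(prof$D2425, (1 - 0.017) * 0.55 / 0.40, tolerance = 1e-3)
})

test_that("solver matches the adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- structural_params()
  doses <- data.frame(time = 0, amount_iu = 5000)
  times <- TAB2_TIMES
  a <- simulate_profile(p, doses, times)
  b <- ode_oracle(p, doses, times)
  expect_equal(as.matrix(a[ANALYTES]), as.matrix(b[ANALYTES]),
               tolerance = 1e-8)
})

test_that("superposition holds: dose responses add on top of baseline", {
  p <- structural_params()
  times <- c(1, 12, 48, 200, 500)
  base <- simulate_profile(p, NULL, times)
  d1 <- data.frame(time = 0, amount_iu = 5000)
  d2 <- data.frame(time = 24, amount_iu = 2000)
  both <- rbind(d1, d2)
  f1 <- simulate_profile(p, d1, times)
  f2 <- simulate_profile(p, d2, times)
  f12 <- simulate_profile(p, both, times)
  for (an in ANALYTES) {
    expect_equal(f12[[an]] - base[[an]],
                 (f1[[an]] - base[[an]]) + (f2[[an]] - base[[an]]),
                 tolerance = 1e-8)
  }
})

test_that("mass balance: only terminal metabolite elimination leaves", {
  p <- structural_params()  # fm1 = 1
  doses <- data.frame(time = 0, amount_iu = 5000)
  h <- 1e-3
  for (t0 in c(5, 50, 300)) {
    X <- vitdpk:::simulate_states(p, doses, c(t0 - h, t0, t0 + h))
    dtotal <- (sum(X[, 3L]) - sum(X[, 1L])) / (2 * h)
    expected <- unname(p$k_endog - p$CL_m2 / p$V_m2 * X[5L, 2L] -
      p$CL_m3 / p$V_m3 * X[6L, 2L])
    expect_equal(dtotal, expected, tolerance = 1e-6)
  }
})

test_that("matrix-exponential and ODE integration agree on random sets", {
  skip_if_not_installed("deSolve")
  set.seed(2024)
  times <- c(0.5, 2, 8, 24, 96, 336)
  doses <- data.frame(time = c(0, 24), amount_iu = c(5000, 5000))
  for (r in 1:10) {
    p <- random_params()
    a <- simulate_profile(p, doses, times)
    b <- ode_oracle(p, doses, times)
    expect_equal(as.matrix(a[ANALYTES]), as.matrix(b[ANALYTES]),
                 tolerance = 1e-8)
  }
})

test_that("simulate_profile validates its inputs", {
  p <- structural_params()
  expect_error(simulate_profile(p, NULL, c(2, 1)), "sorted")
  expect_error(simulate_profile(p, NULL, -1), "non-negative")
  expect_error(
    simulate_profile(p, data.frame(time = -5, amount_iu = 100), 1),
    "dose")
  expect_error(
    simulate_profile(p, data.frame(time = 0, amount_iu = 0), 1),
    "positive")
})

test_that("dose monotonicity: more drug, more 25D3 at any later time", {
  p <- structural_params()
  times <- c(24, 240, 2400)
  profs <- lapply(c(600, 2000, 10000), function(dd) {
    doses <- data.frame(time = seq(0, 2160, by = 24), amount_iu = dd)
    simulate_profile(p, doses, times)$D25
  })
  expect_true(all(profs[[2L]] > profs[[1L]]))
  expect_true(all(profs[[3L]] > profs[[2L]]))
})
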