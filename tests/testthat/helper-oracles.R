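# Independent oracles the implementation is checked against. These
# deliberately avoid the package's own solution paths: the ODE oracle
# integrates the system numerically with deSolve, and the quadrature oracle
# integrates the random effects by brute-force summation.

# stiff adaptive ODE integration of the compartmental system with dose
# events added to the depot
ode_oracle <- function(p, doses, times) {
  sys <- build_rate_matrix(p)
  x0 <- as.vector(initial_state(p))
  names(x0) <- rownames(sys$A)
  deriv <- function(t, y, parms) list(as.vector(sys$A %*% y + sys$b))
  eventdat <- NULL
  if (!is.null(doses) && nrow(doses) > 0L) {
    eventdat <- data.frame(var = "depot", time = doses$time,
                           value = iu_to_nmol(doses$amount_iu),
                           method = "add")
  }
  solve_times <- sort(unique(c(0, times,
                               if (!is.null(eventdat)) eventdat$time)))
  out <- deSolve::lsoda(x0, solve_times, deriv, parms = NULL,
                        rtol = 1e-11, atol = 1e-12,
                        events = if (!is.null(eventdat))
                          list(data = eventdat) else NULL)
  amounts <- out[match(times, out[, "time"]), -1L, drop = FALSE]
  vols <- c(p$Vc_F, p$V_m1, p$V_m2, p$V_m3)
  conc <- sweep(amounts[, c("vitd3_central", "d25", "d125", "d2425"),
                        drop = FALSE], 2L, vols, "/")
  colnames(conc) <- ANALYTES
  data.frame(time = times, conc, check.names = FALSE)
}

# brute-force marginal likelihood over the random effects: mode-centered
# trapezoidal product quadrature of the joint density
quadrature_marginal <- function(sub, model, method = "M3", n_grid = 31L,
                                half_width = 7) {
  if (inherits(sub, "vd_dataset")) {
    sub <- vitdpk:::split_subjects(sub)[[1L]]
  }
  om <- model$omega2[model$omega2 > 0]
  d <- length(om)
  sds <- sqrt(as.numeric(om))
  joint <- function(eta) {
    # the mode search is unconstrained; excursions beyond any plausible
    # posterior mass would push the rate matrix toward singularity, so
    # they are cut off with an effectively-zero density
    if (any(abs(eta) > 8 * sds)) return(-1e10)
    eta <- stats::setNames(eta, names(om))
    p_i <- apply_iiv(model$params, eta)
    pred <- tryCatch(vitdpk:::subject_pred(sub, p_i),
                     error = function(e) NULL)
    if (is.null(pred)) return(-1e10)
    ll <- obs_loglik(sub$conc, sub$blq, sub$lloq, pmax(pred, 1e-10),
                     sigma = model$sigma[sub$analyte],
                     sigma_add = model$sigma_add[sub$analyte],
                     form = model$error_model, method = method)
    sum(ll) + sum(stats::dnorm(eta, 0, sds, log = TRUE))
  }
  # locate the mass: mode and local curvature
  opt <- stats::optim(rep(0, d), function(e) -joint(e), method = "BFGS")
  H <- stats::optimHess(opt$par, function(e) -joint(e))
  post_sd <- sqrt(pmax(diag(solve(H)), 1e-12))
  post_sd <- pmin(post_sd, sds)  # never wider than the prior
  grids <- lapply(seq_len(d), function(k) {
    seq(opt$par[k] - half_width * post_sd[k],
        opt$par[k] + half_width * post_sd[k], length.out = n_grid)
  })
  steps <- vapply(grids, function(g) g[2L] - g[1L], 0)
  pts <- as.matrix(expand.grid(grids))
  lv <- apply(pts, 1L, joint)
  # trapezoid weights factorize across dimensions
  w1 <- lapply(seq_len(d), function(k) {
    w <- rep(steps[k], n_grid)
    w[c(1L, n_grid)] <- steps[k] / 2
    w
  })
  logw <- rowSums(log(as.matrix(expand.grid(w1))))
  m <- max(lv)
  m + log(sum(exp(lv - m + logw)))
}

# analytic one-compartment limit of the 25D3 curve under daily dosing:
# instantaneous absorption and conversion, so the d25 compartment sees a
# constant-rate input dose/24 + k_endog
analytic_d25_limit <- function(p, dose_iu, t_h) {
  css <- (iu_to_nmol(dose_iu) / 24 + p$k_endog) / p$CL_m1
  k <- p$CL_m1 / p$V_m1
  css - (css - p$C0_m1) * exp(-k * t_h)
}
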