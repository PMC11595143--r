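# Lean internal evaluation path for the estimation loop.
#
# The public simulate/likelihood functions validate their inputs on every
# call, which is far too costly inside the inner (per-eta) optimization.
# These helpers work on a raw numeric parameter vector in PARAM_NAMES order
# and on a precompiled per-subject record layout; they implement exactly the
# same model (same rate matrix, same matrix-exponential solution, same
# residual/BLQ likelihood) as the public path, which the test suite checks
# by agreement.

as_pv <- function(p) unlist(p[PARAM_NAMES], use.names = FALSE)

pv_as_params <- function(pv) {
  p <- as.list(pv)
  names(p) <- PARAM_NAMES
  structure(p, class = "vd_params")
}

# precompiled subject layout; under M1 the BLQ records are removed here so
# the likelihood loop never sees them
fast_subject <- function(sub, method) {
  keep <- if (method == "M1") !sub$blq else rep(TRUE, length(sub$conc))
  times <- sub$times
  aidx <- match(sub$analyte[keep], ANALYTES)
  list(id = sub$id,
       times = times,
       dose_t = sub$doses$time,
       dose_a = if (nrow(sub$doses) > 0L) iu_to_nmol(sub$doses$amount_iu)
                else numeric(0),
       tidx = sub$time_idx[keep],
       aidx = aidx,
       state_row = c(2L, 4L, 5L, 6L)[aidx],
       conc = sub$conc[keep],
       blq = sub$blq[keep],
       lloq = sub$lloq[keep],
       n_dropped = sum(!keep))
}

# 6 x n_times amounts for the raw parameter vector; exact solution with
# doses deposited into the depot (dose-first at ties).
#
# The system is block-triangular, so its spectral decomposition is closed
# form: eigenvalues are -ka, the two-compartment alpha/beta of the parent
# block, and the three metabolite elimination rates. Deviations from
# equilibrium are carried as exponential sums whose coefficients follow a
# first-order cascade (each metabolite filters its upstream input through
# 1/(lambda + k)). Near an eigenvalue coincidence, where the cascade
# denominators degenerate, the validated matrix-exponential path takes over.
fast_states <- function(pv, dose_t, dose_a, times) {
  ka <- pv[1L]; ke <- pv[2L]; Vc <- pv[3L]; CL <- pv[4L]; Vp <- pv[5L]
  Q <- pv[6L]; C0 <- pv[7L]; fm1 <- pv[8L]; C0m1 <- pv[9L]; Vm1 <- pv[10L]
  CLm1 <- pv[11L]; fm2 <- pv[12L]; C0m2 <- pv[13L]; Vm2 <- pv[14L]
  CLm2 <- pv[15L]; C0m3 <- pv[16L]; Vm3 <- pv[17L]; CLm3 <- pv[18L]
  k20 <- CL / Vc; k23 <- Q / Vc; k32 <- Q / Vp
  k24 <- fm1 * k20
  k4 <- CLm1 / Vm1; k5 <- CLm2 / Vm2; k6 <- CLm3 / Vm3
  # parent-block eigenvalues (both real and negative)
  s <- k20 + k23 + k32
  disc <- sqrt(s * s - 4 * k20 * k32)
  alpha <- (-s - disc) / 2
  beta <- (-s + disc) / 2
  L <- c(-ka, alpha, beta, -k4, -k5, -k6)
  # cascade denominators; bail out to the general path near coincidences
  dens <- c(disc, (-ka - alpha) * (-ka - beta),
            L[1:3] + k4, L[1:4] + k5, L[1:4] + k6)
  if (min(abs(dens)) < 1e-9 * max(abs(L))) {
    return(simulate_states(
      pv_as_params(pv),
      if (length(dose_t) > 0L)
        data.frame(time = dose_t,
                   amount_iu = dose_a * 40 * 384.64 / 1000)
      else NULL, times))
  }
  ceq <- ke / CL
  xeq <- c(0, ceq * Vc, ceq * Vp,
           fm1 * ke / CLm1 * Vm1,
           fm2 * (fm1 * ke) / CLm2 * Vm2,
           (1 - fm2) * (fm1 * ke) / CLm3 * Vm3)
  # coefficient matrix (6 states x 6 exponents) for deviations z = x - xeq
  # from the deviation z0 at the segment start
  coef_matrix <- function(z0) {
    C <- matrix(0, 6L, 6L)
    C[1L, 1L] <- z0[1L]
    # central/peripheral response to the depot forcing ka * z0_1 e^{-ka t}
    Fk <- ka * z0[1L]
    D <- (-ka - alpha) * (-ka - beta)
    z2p <- Fk * (-ka + k32) / D
    z3p <- Fk * k23 / D
    S <- (z0[3L] - z3p) / k23
    Tt <- (z0[2L] - z2p) - k32 * S
    Ca <- (Tt - beta * S) / (alpha - beta)
    Cb <- (alpha * S - Tt) / (alpha - beta)
    C[2L, ] <- c(z2p, Ca * (alpha + k32), Cb * (beta + k32), 0, 0, 0)
    C[3L, ] <- c(z3p, Ca * k23, Cb * k23, 0, 0, 0)
    # d25 filters the central input k24 * z2
    C[4L, 1:3] <- k24 * C[2L, 1:3] / (L[1:3] + k4)
    C[4L, 4L] <- z0[4L] - sum(C[4L, 1:3])
    # terminal metabolites filter the d25 input
    C[5L, 1:4] <- fm2 * k4 * C[4L, 1:4] / (L[1:4] + k5)
    C[5L, 5L] <- z0[5L] - sum(C[5L, 1:4])
    C[6L, 1:4] <- (1 - fm2) * k4 * C[4L, 1:4] / (L[1:4] + k6)
    C[6L, 6L] <- z0[6L] - sum(C[6L, 1:4])
    C
  }
  x <- c(0, C0 * Vc, C0 * Vp, C0m1 * Vm1, C0m2 * Vm2, C0m3 * Vm3)
  nt <- length(times)
  X <- matrix(0, 6L, nt)
  t_cur <- 0
  i_dose <- 1L
  nd <- length(dose_t)
  remaining <- seq_len(nt)
  C <- coef_matrix(x - xeq)
  repeat {
    t_next <- if (i_dose <= nd) dose_t[i_dose] else Inf
    idx <- remaining[times[remaining] < t_next]
    if (length(idx) > 0L) {
      X[, idx] <- C %*% exp(outer(L, times[idx] - t_cur)) + xeq
      remaining <- remaining[!remaining %in% idx]
    }
    if (i_dose > nd) break
    if (t_next > t_cur) {
      x <- as.vector(C %*% exp(L * (t_next - t_cur))) + xeq
      t_cur <- t_next
    }
    x[1L] <- x[1L] + dose_a[i_dose]
    C <- coef_matrix(x - xeq)
    i_dose <- i_dose + 1L
  }
  if (length(remaining) > 0L) {
    X[, remaining] <- C %*% exp(outer(L, times[remaining] - t_cur)) + xeq
  }
  X
}

LOG_2PI <- log(2 * pi)

# conditional log-likelihood of one precompiled subject; sigma4/add4 are the
# residual coefficients in ANALYTES order, m3 switches the BLQ CDF term
fast_cond_ll <- function(fs, pv, sigma4, add4, m3) {
  X <- fast_states(pv, fs$dose_t, fs$dose_a, fs$times)
  vols <- c(pv[3L], pv[10L], pv[14L], pv[17L])
  pred <- X[fs$state_row + 6L * (fs$tidx - 1L)] / vols[fs$aidx]
  pred[pred < 1e-10] <- 1e-10
  sd <- sqrt(add4[fs$aidx]^2 + (sigma4[fs$aidx] * pred)^2)
  ll <- 0
  q <- !fs$blq
  if (any(q)) {
    z <- (fs$conc[q] - pred[q]) / sd[q]
    ll <- sum(-0.5 * (LOG_2PI + z * z) - log(sd[q]))
  }
  if (m3 && any(fs$blq)) {
    ll <- ll + sum(stats::pnorm((fs$lloq[fs$blq] - pred[fs$blq]) /
                                  sd[fs$blq], log.p = TRUE))
  }
  ll
}

# Laplace-approximated marginal log-likelihood for a precompiled subject.
# eta_pos: indices into pv of the random-effect parameters; om: their
# variances. The inner mode search is warm-started by `start`.
fast_laplace <- function(fs, pv, sigma4, add4, m3, eta_pos, om,
                         start = NULL) {
  d <- length(eta_pos)
  if (d == 0L) {
    return(list(loglik = fast_cond_ll(fs, pv, sigma4, add4, m3),
                eta = numeric(0), hessian = NULL, converged = TRUE))
  }
  base <- pv[eta_pos]
  neg_joint <- function(eta) {
    pv[eta_pos] <- base * exp(eta)
    -(fast_cond_ll(fs, pv, sigma4, add4, m3) +
        sum(-0.5 * (LOG_2PI + eta * eta / om) - 0.5 * log(om)))
  }
  opt <- stats::nlminb(start %||% rep(0, d), neg_joint,
                       control = list(rel.tol = 1e-10, iter.max = 200))
  H <- fd_hessian(neg_joint, opt$par, f0 = opt$objective)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  converged <- opt$convergence == 0 && all(ev > 0)
  if (any(ev <= 0)) H <- H + diag(max(0, -min(ev)) + 1e-8, d)
  logdet <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  list(loglik = -opt$objective + 0.5 * d * log(2 * pi) - 0.5 * logdet,
       eta = opt$par, hessian = H, converged = converged)
}

# central-difference diagonal + one-sided cross terms; cheaper than
# optimHess for the 2-3 dimensional inner problems
fd_hessian <- function(fn, x, f0 = fn(x), h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  fp <- numeric(d)
  fm <- numeric(d)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fp[i] <- fn(xp); fm[i] <- fn(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (d > 1L) {
    for (i in seq_len(d - 1L)) {
      for (j in seq((i + 1L), d)) {
        xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
        H[i, j] <- H[j, i] <- (fn(xpp) - fp[i] - fp[j] + f0) / h^2
      }
    }
  }
  (H + t(H)) / 2
}
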