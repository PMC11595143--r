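#' Rate matrix and input vector of the compartmental system
#'
#' The model is a linear, time-invariant ODE system `dx/dt = A x + b` over
#' six amount states ordered as `depot`, `vitd3_central`, `vitd3_peripheral`,
#' `d25`, `d125`, `d2425` (nmol). The parent is eliminated through `CL_F`, a
#' fraction `fm1` of which forms 25D3; 25D3 elimination through `CL_m1`
#' splits into 1,25D3 (`fm2`) and 24,25D3 (`1 - fm2`); both terminal
#' metabolites are cleared out of the system. `b` carries the zero-order
#' endogenous parent production `k_endog` into the central compartment.
#'
#' @param p A [structural_params()] object.
#' @return A list with the 6x6 matrix `A` (1/h) and length-6 vector `b`
#'   (nmol/h), both with state names.
#' @examples
#' sys <- build_rate_matrix(structural_params())
#' colSums(sys$A)  # depot/central/peripheral columns conserve mass
#' @export
build_rate_matrix <- function(p) {
  p <- as_structural_params(p)
  A <- matrix(0, 6L, 6L, dimnames = list(STATE_NAMES, STATE_NAMES))
  A[1L, 1L] <- -p$ka
  A[2L, 1L] <- p$ka
  A[2L, 2L] <- -(p$CL_F + p$Q_F) / p$Vc_F
  A[2L, 3L] <- p$Q_F / p$Vp_F
  A[3L, 2L] <- p$Q_F / p$Vc_F
  A[3L, 3L] <- -p$Q_F / p$Vp_F
  A[4L, 2L] <- p$fm1 * p$CL_F / p$Vc_F
  A[4L, 4L] <- -p$CL_m1 / p$V_m1
  A[5L, 4L] <- p$fm2 * p$CL_m1 / p$V_m1
  A[5L, 5L] <- -p$CL_m2 / p$V_m2
  A[6L, 4L] <- (1 - p$fm2) * p$CL_m1 / p$V_m1
  A[6L, 6L] <- -p$CL_m3 / p$V_m3
  b <- c(0, p$k_endog, 0, 0, 0, 0)
  names(b) <- STATE_NAMES
  list(A = A, b = b)
}

STATE_NAMES <- c("depot", "vitd3_central", "vitd3_peripheral",
                 "d25", "d125", "d2425")

# volumes dividing each observed state, in ANALYTES order
obs_volumes <- function(p) {
  c(VITD3 = p$Vc_F, D25 = p$V_m1, D125 = p$V_m2, D2425 = p$V_m3)
}
OBS_STATE_INDEX <- c(VITD3 = 2L, D25 = 4L, D125 = 5L, D2425 = 6L)

#' Pre-dose initial state
#'
#' Baselines are initial conditions, not enforced steady states: each
#' compartment starts at its baseline concentration times its volume, the
#' parent peripheral compartment at distribution equilibrium with the
#' central one (`C0 * Vp_F`), and the depot empty. No balancing input is
#' added for the metabolites, so in the absence of dosing the profiles relax
#' from these baselines toward the equilibrium set by `k_endog` and the
#' clearances.
#'
#' @param p A [structural_params()] object.
#' @return Named numeric vector of six compartment amounts (nmol) with
#'   attribute `time = 0`.
#' @export
initial_state <- function(p) {
  p <- as_structural_params(p)
  x <- c(0, p$C0 * p$Vc_F, p$C0 * p$Vp_F, p$C0_m1 * p$V_m1,
         p$C0_m2 * p$V_m2, p$C0_m3 * p$V_m3)
  names(x) <- STATE_NAMES
  attr(x, "time") <- 0
  x
}

# ---- exact propagation ----------------------------------------------------
#
# Between dose events the system is linear time-invariant, so the solution
# is x(t0 + h) = xeq + e^{Ah} (x(t0) - xeq) with xeq = -A^{-1} b. A is
# nonsingular for any valid parameter set (all diagonal entries negative,
# block-triangular with a strictly diagonally-dominant-in-determinant 2x2
# parent block). The primary path diagonalizes A (its eigenvalues are real:
# the parent 2x2 block has positive off-diagonal product, the rest is
# triangular); a scaling-and-squaring matrix exponential is the fallback for
# near-defective draws.

pk_propagator <- function(p) {
  sys <- build_rate_matrix(p)
  A <- sys$A
  xeq <- -solve(A, sys$b)
  eg <- eigen(A)
  use_eigen <- all(abs(Im(eg$values)) < 1e-12) &&
    rcond(Re(eg$vectors)) > 1e-10
  if (use_eigen) {
    V <- Re(eg$vectors)
    lam <- Re(eg$values)
    Vi <- solve(V)
    at_times <- function(x0, h) {
      # states at offsets h (vector, >= 0) from x0; 6 x length(h)
      w <- Vi %*% (x0 - xeq)
      X <- V %*% (exp(outer(lam, h)) * as.vector(w))
      X + xeq
    }
  } else {
    at_times <- function(x0, h) {
      d <- x0 - xeq
      X <- vapply(h, function(hh) {
        as.vector(as.matrix(Matrix::expm(A * hh)) %*% d) + xeq
      }, numeric(6L))
      matrix(X, nrow = 6L)
    }
  }
  list(at_times = at_times, xeq = xeq, A = A)
}

#' Simulate concentration-time profiles
#'
#' Exact solution of the compartmental system for an arbitrary oral dosing
#' schedule: the matrix exponential is propagated between dose events and
#' each dose is deposited instantaneously into the depot (converted from
#' I.U. via [iu_to_nmol()]). When an observation time coincides with a dose
#' time the dose is applied first.
#'
#' @param p A [structural_params()] object (or coercible list).
#' @param doses A data.frame with columns `time` (h, >= 0) and `amount_iu`
#'   (> 0), or `NULL` for the dose-free baseline relaxation.
#' @param times Sorted non-negative observation times (h).
#' @return A data.frame with column `time` and one concentration column per
#'   analyte (nmol/L).
#' @examples
#' simulate_profile(structural_params(),
#'                  doses = data.frame(time = 0, amount_iu = 5000),
#'                  times = c(0, 0.5, 1, 2, 4, 8, 12, 24, 48, 168, 336))
#' @export
simulate_profile <- function(p, doses = NULL, times) {
  p <- as_structural_params(p)
  states <- simulate_states(p, doses, times)
  conc <- t(states[OBS_STATE_INDEX, , drop = FALSE] / obs_volumes(p))
  out <- data.frame(time = times, conc)
  names(out) <- c("time", ANALYTES)
  rownames(out) <- NULL
  out
}

# 6 x length(times) amount matrix; shared by simulate_profile and the fitter
simulate_states <- function(p, doses, times, prop = NULL) {
  if (length(times) == 0L) {
    return(matrix(numeric(0), nrow = 6L))
  }
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.null(doses) || nrow(doses) == 0L) {
    dose_t <- numeric(0)
    dose_a <- numeric(0)
  } else {
    if (any(doses$time < 0)) stop("dose before t = 0", call. = FALSE)
    if (any(doses$amount_iu <= 0)) {
      stop("dose amounts must be positive", call. = FALSE)
    }
    ord <- order(doses$time)
    dose_t <- doses$time[ord]
    dose_a <- iu_to_nmol(doses$amount_iu[ord])
  }
  if (is.null(prop)) prop <- pk_propagator(p)
  X <- matrix(NA_real_, 6L, length(times))
  x <- as.vector(initial_state(p))
  t_cur <- 0
  i_dose <- 1L
  remaining <- seq_along(times)
  while (length(remaining) > 0L) {
    t_next_dose <- if (i_dose <= length(dose_t)) dose_t[i_dose] else Inf
    # dose-first tie rule: apply any dose at or before the next obs time
    idx <- remaining[times[remaining] < t_next_dose]
    if (length(idx) > 0L) {
      X[, idx] <- prop$at_times(x, times[idx] - t_cur)
      remaining <- setdiff(remaining, idx)
    }
    if (is.finite(t_next_dose)) {
      x <- as.vector(prop$at_times(x, t_next_dose - t_cur))
      x[1L] <- x[1L] + dose_a[i_dose]
      t_cur <- t_next_dose
      i_dose <- i_dose + 1L
    } else {
      break
    }
  }
  if (length(remaining) > 0L) {
    X[, remaining] <- prop$at_times(x, times[remaining] - t_cur)
  }
  dimnames(X) <- list(STATE_NAMES, NULL)
  X
}

# one-step transition of the affine system over `h` hours:
# x_{k+1} = M x_k + g with M = e^{Ah}, g = (I - M) xeq
pk_step_matrix <- function(p, h = 1) {
  sys <- build_rate_matrix(p)
  A <- sys$A
  xeq <- -solve(A, sys$b)
  eg <- eigen(A)
  M <- if (all(abs(Im(eg$values)) < 1e-12) && rcond(Re(eg$vectors)) > 1e-10) {
    V <- Re(eg$vectors)
    V %*% (exp(Re(eg$values) * h) * solve(V))
  } else {
    as.matrix(Matrix::expm(A * h))
  }
  list(M = M, g = as.vector(xeq - M %*% xeq), xeq = xeq)
}

# fixed-step recursion on an hourly grid with doses every `interval` hours
# starting at t = 0; returns the d25 concentration (nmol/L) at hours
# 0..n_hours. Used by the regimen simulator, where thousands of
# subject-curves make per-event dispatch in simulate_states needlessly slow.
d25_daily_curve <- function(p, dose_iu, n_hours, interval = 24L) {
  st <- pk_step_matrix(p, h = 1)
  M <- st$M
  g <- st$g
  x <- as.vector(initial_state(p))
  d <- iu_to_nmol(dose_iu)
  conc <- numeric(n_hours + 1L)
  conc[1L] <- x[4L] / p$V_m1
  for (k in seq_len(n_hours)) {
    if ((k - 1L) %% interval == 0L && dose_iu > 0) x[1L] <- x[1L] + d
    x <- M %*% x + g
    conc[k + 1L] <- x[4L]
  }
  conc[-1L] <- conc[-1L] / p$V_m1
  conc
}
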