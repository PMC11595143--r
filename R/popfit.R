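# ---- free-parameter bookkeeping -------------------------------------------
#
# The outer optimization works on an unconstrained vector theta: positive
# parameters (structural values, sigma, omega2) on the log scale, fraction
# parameters on the logit scale, covariate coefficients untransformed.

build_theta_info <- function(model, analytes_present,
                             estimate_sigma, estimate_omega) {
  info <- list()
  add <- function(name, kind, target, trans, value) {
    info[[length(info) + 1L]] <<- list(name = name, kind = kind,
                                       target = target, trans = trans,
                                       value = value)
  }
  for (nm in setdiff(PARAM_NAMES, model$fixed)) {
    v <- model$params[[nm]]
    if (nm %in% FRACTION_PARAMS) {
      if (v <= 0 || v >= 1) {
        stop("fraction parameter ", nm,
             " sits on the boundary and cannot be estimated; fix it",
             call. = FALSE)
      }
      add(nm, "struct", nm, "logit", stats::qlogis(v))
    } else {
      add(nm, "struct", nm, "log", log(v))
    }
  }
  if (estimate_sigma) {
    for (an in intersect(ANALYTES, analytes_present)) {
      if (model$error_model %in% c("proportional", "combined")) {
        add(paste0("sigma_", an), "sigma", an, "log", log(model$sigma[[an]]))
      }
      if (model$error_model %in% c("additive", "combined")) {
        add(paste0("sigma_add_", an), "sigma_add", an, "log",
            log(model$sigma_add[[an]]))
      }
    }
  }
  if (estimate_omega) {
    for (nm in names(model$omega2)[model$omega2 > 0]) {
      add(paste0("omega2_", nm), "omega2", nm, "log",
          log(model$omega2[[nm]]))
    }
  }
  for (i in seq_along(model$covariates)) {
    cv <- model$covariates[[i]]
    add(paste0("beta_", cv$covariate, "_", cv$parameter), "coef", i,
        "identity", cv$coef %||% 0)
  }
  info
}

theta_start <- function(info) {
  stats::setNames(vapply(info, `[[`, 0, "value"),
                  vapply(info, `[[`, "", "name"))
}

back_transform <- function(value, trans) {
  switch(trans, log = exp(value), logit = stats::plogis(value),
         identity = value)
}

update_model <- function(model, theta, info) {
  for (i in seq_along(info)) {
    e <- info[[i]]
    v <- back_transform(theta[[i]], e$trans)
    switch(e$kind,
      struct = { model$params[[e$target]] <- v },
      sigma = { model$sigma[[e$target]] <- v },
      sigma_add = { model$sigma_add[[e$target]] <- v },
      omega2 = { model$omega2[[e$target]] <- v },
      coef = { model$covariates[[e$target]]$coef <- v }
    )
  }
  model
}

# ---- subject-level likelihood ---------------------------------------------

# conditional log-likelihood of one subject's records given individual
# parameters (covariate effects already folded in)
subject_cond_loglik <- function(sub, p_i, model, method) {
  pred <- subject_pred(sub, p_i)
  ll <- obs_loglik(sub$conc, sub$blq, sub$lloq, pmax(pred, 1e-10),
                   sigma = model$sigma[sub$analyte],
                   sigma_add = model$sigma_add[sub$analyte],
                   form = model$error_model, method = method)
  sum(ll)
}

# per-subject multiplicative covariate adjustments under the model's
# covariate specs (list mapping parameter -> multiplier scalar)
subject_cov_mult <- function(model, cov_row) {
  out <- list()
  for (sp in model$covariates) {
    x <- cov_row[[sp$covariate]]
    if (is.null(x)) stop("covariate not in table: ", sp$covariate,
                         call. = FALSE)
    m <- covariate_term(x, sp$form, sp$coef %||% 0, sp$ref)
    out[[sp$parameter]] <- (out[[sp$parameter]] %||% 1) * m
  }
  out
}

apply_cov_mult <- function(p, mult) {
  for (nm in names(mult)) p[[nm]] <- p[[nm]] * mult[[nm]]
  p
}

#' Laplace-approximated marginal log-likelihood for one subject
#'
#' Integrates the subject's conditional likelihood over the log-normal
#' random effects, `int L(y | eta) N(eta; 0, Omega) d eta`, by a Laplace
#' expansion around the posterior mode of `eta`: an inner quasi-Newton
#' optimization locates the mode, a finite-difference Hessian `H` of the
#' negative joint log-density supplies the curvature, and the marginal
#' log-likelihood is `l(eta*) + d/2 log(2 pi) - 1/2 log det H`. With all
#' IIV variances zero the marginal reduces exactly to the conditional
#' log-likelihood at `eta = 0`.
#'
#' @param sub One element of the internal per-subject split (or a
#'   `vd_dataset` restricted to a single subject).
#' @param model A [population_model()].
#' @param method BLQ handling, `"M3"` or `"M1"`.
#' @param eta_start Optional warm start for the inner optimization.
#' @param cov_row Optional single-row covariate table for this subject.
#' @return A list: `loglik`, `eta` (posterior mode), `hessian`,
#'   `converged`.
#' @export
marginal_loglik_subject <- function(sub, model, method = c("M3", "M1"),
                                    eta_start = NULL, cov_row = NULL) {
  method <- match.arg(method)
  if (inherits(sub, "vd_dataset")) {
    subs <- split_subjects(sub)
    if (length(subs) != 1L) {
      stop("expected a single-subject dataset", call. = FALSE)
    }
    sub <- subs[[1L]]
  }
  om <- model$omega2[model$omega2 > 0]
  mult <- if (length(model$covariates) > 0L) {
    subject_cov_mult(model, cov_row)
  } else list()
  pv <- as_pv(apply_cov_mult(model$params, mult))
  fs <- fast_subject(sub, method)
  r <- fast_laplace(fs, pv, sigma4 = as.numeric(model$sigma[ANALYTES]),
                    add4 = as.numeric(model$sigma_add[ANALYTES]),
                    m3 = method == "M3",
                    eta_pos = unname(PV_IDX[names(om)]),
                    om = as.numeric(om), start = eta_start)
  r$eta <- stats::setNames(r$eta, names(om))
  r
}

# ---- population fit -------------------------------------------------------

#' Fit the population model by maximum marginal likelihood
#'
#' Maximizes the sum over subjects of the Laplace-approximated marginal
#' log-likelihood ([marginal_loglik_subject()]) over the non-fixed
#' parameters, the residual-error coefficients and (optionally) the IIV
#' variances, all transformed to an unconstrained scale. Reports the
#' objective function value (OFV, `-2 log L`), AIC (`OFV + 2 * n
#' estimated`), relative standard errors (CV%) from the inverse Hessian on
#' the transformed scale (delta-method back-transformed), empirical Bayes
#' estimates (EBEs, the per-subject posterior modes), eta-shrinkage, and the
#' condition number of the estimate correlation matrix.
#'
#' @param dataset A `vd_dataset`.
#' @param model Starting [population_model()]; its `fixed` set defines which
#'   structural parameters stay at their initial values.
#' @param method BLQ handling: `"M3"` (censored likelihood, default) or
#'   `"M1"` (drop BLQ records).
#' @param estimate_sigma,estimate_omega Estimate the residual-error
#'   coefficients / IIV variances alongside the structural parameters.
#' @param covariates Optional covariate table (one row per subject, `ID`
#'   column) when the model declares covariate effects.
#' @param compute_se Compute the Hessian-based CV% and condition number
#'   (adds one finite-difference Hessian of the full objective; skip for
#'   large simulation studies where only point estimates are needed).
#' @param control Passed to [stats::nlminb()] for the outer optimization.
#' @return A `vd_fit` object.
#' @export
fit_population <- function(dataset, model = population_model(),
                           method = c("M3", "M1"),
                           estimate_sigma = TRUE, estimate_omega = TRUE,
                           covariates = NULL, compute_se = TRUE,
                           control = list(rel.tol = 1e-8, iter.max = 150,
                                          eval.max = 600)) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "vd_dataset"))
  subs <- split_subjects(dataset)
  if (length(subs) < 2L && length(model$omega2[model$omega2 > 0]) > 0L) {
    warning("fewer than 2 subjects: IIV variances are weakly identified",
            call. = FALSE)
  }
  analytes_present <- unique(dataset$DVID[dataset$EVID == 0L])
  info <- build_theta_info(model, analytes_present,
                           estimate_sigma, estimate_omega)
  model <- resolve_covariate_refs(model, covariates)
  cov_rows <- covariate_rows(covariates, subs)
  warm <- new.env(parent = emptyenv())
  warm$eta <- vector("list", length(subs))
  n_blq <- sum(dataset$BLQ[dataset$EVID == 0L] == 1L)
  # precompiled layouts and covariate design values for the hot loop
  fss <- lapply(subs, fast_subject, method = method)
  m3 <- method == "M3"
  om_all <- model$omega2[model$omega2 > 0]
  om_names <- names(om_all)
  eta_pos <- unname(PV_IDX[om_names])
  cov_specs <- model$covariates
  cov_x <- lapply(seq_along(subs), function(i) {
    if (length(cov_specs) == 0L) return(NULL)
    vapply(cov_specs, function(sp) cov_rows[[i]][[sp$covariate]], 0)
  })
  cov_pidx <- vapply(cov_specs, function(sp) PV_IDX[[sp$parameter]], 0L)
  cov_form <- vapply(cov_specs, function(sp) sp$form, "")
  cov_ref <- vapply(cov_specs, function(sp) sp$ref %||% NA_real_, 0)
  total_nll <- function(theta) {
    m <- update_model(model, theta, info)
    pv <- as_pv(m$params)
    sigma4 <- as.numeric(m$sigma[ANALYTES])
    add4 <- as.numeric(m$sigma_add[ANALYTES])
    om <- as.numeric(m$omega2[om_names])
    coefs <- vapply(m$covariates, function(sp) sp$coef %||% 0, 0)
    nll <- 0
    for (i in seq_along(fss)) {
      pv_i <- pv
      for (j in seq_along(cov_specs)) {
        mult <- if (cov_form[j] == "power") {
          (cov_x[[i]][j] / cov_ref[j])^coefs[j]
        } else 1 + coefs[j] * cov_x[[i]][j]
        pv_i[cov_pidx[j]] <- pv_i[cov_pidx[j]] * mult
      }
      r <- fast_laplace(fss[[i]], pv_i, sigma4, add4, m3, eta_pos, om,
                        start = warm$eta[[i]])
      if (!is.finite(r$loglik)) return(1e10)
      if (length(r$eta) > 0L) warm$eta[[i]] <- r$eta
      nll <- nll - r$loglik
    }
    nll
  }
  th0 <- theta_start(info)
  if (length(th0) == 0L) {
    ofv <- 2 * total_nll(numeric(0))
    fit <- new_vd_fit(model, info, numeric(0), ofv, subs, method,
                      n_blq_dropped = if (method == "M1") n_blq else 0L,
                      converged = TRUE, cov_rows = cov_rows,
                      vcov = NULL, dataset = dataset)
    return(fit)
  }
  # explicit forward-difference gradient: the Laplace objective carries a
  # small numerical roughness from the inner mode searches, so the step
  # must sit well above it; 1e-3 on the transformed (log/logit) scale
  # keeps truncation error negligible against the estimates' curvature
  grad_h <- 1e-3
  last <- new.env(parent = emptyenv())
  nll_cached <- function(theta) {
    v <- total_nll(theta)
    last$theta <- theta
    last$f <- v
    v
  }
  total_grad <- function(theta) {
    f0 <- if (!is.null(last$theta) && identical(theta, last$theta)) {
      last$f
    } else total_nll(theta)
    g <- numeric(length(theta))
    for (k in seq_along(theta)) {
      tk <- theta
      tk[k] <- tk[k] + grad_h
      g[k] <- (total_nll(tk) - f0) / grad_h
    }
    g
  }
  opt <- stats::nlminb(th0, nll_cached, gradient = total_grad,
                       control = control)
  message_out <- opt$message %||% ""
  model_hat <- update_model(model, opt$par, info)
  vc <- NULL
  if (compute_se) {
    H <- stats::optimHess(opt$par, total_nll)
    H <- (H + t(H)) / 2
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && any(diag(vc) <= 0)) vc <- NULL
    if (!is.null(vc)) dimnames(vc) <- list(names(th0), names(th0))
  }
  fit <- new_vd_fit(model_hat, info, opt$par, ofv = 2 * opt$objective,
                    subs, method,
                    n_blq_dropped = if (method == "M1") n_blq else 0L,
                    converged = opt$convergence == 0, cov_rows = cov_rows,
                    vcov = vc, dataset = dataset)
  fit$optimizer_message <- message_out
  fit
}

# assemble the vd_fit: EBE pass, shrinkage, CV%, condition number
new_vd_fit <- function(model, info, theta, ofv, subs, method,
                       n_blq_dropped, converged, cov_rows, vcov, dataset) {
  om <- model$omega2[model$omega2 > 0]
  ebe <- matrix(NA_real_, length(subs), length(om))
  colnames(ebe) <- names(om)
  ebe_conv <- rep(TRUE, length(subs))
  if (length(om) > 0L) {
    for (i in seq_along(subs)) {
      r <- marginal_loglik_subject(subs[[i]], model, method,
                                   cov_row = cov_rows[[i]])
      ebe[i, ] <- r$eta
      ebe_conv[i] <- r$converged
    }
  }
  shr <- if (length(om) > 0L && nrow(ebe) > 1L) {
    stats::setNames(
      pmin(1, pmax(0, 1 - apply(ebe, 2L, stats::sd) / sqrt(om))),
      names(om))
  } else stats::setNames(numeric(0), character(0))
  cv <- rep(NA_real_, length(info))
  names(cv) <- vapply(info, `[[`, "", "name")
  cond <- NA_real_
  if (!is.null(vcov)) {
    se_t <- sqrt(diag(vcov))
    for (i in seq_along(info)) {
      e <- info[[i]]
      est <- back_transform(theta[[i]], e$trans)
      cv[i] <- switch(e$trans,
        log = 100 * sqrt(exp(se_t[i]^2) - 1),
        logit = 100 * se_t[i] * est * (1 - est) / abs(est),
        identity = if (est != 0) 100 * se_t[i] / abs(est) else NA_real_)
    }
    cr <- stats::cov2cor(vcov)
    ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
    cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  }
  estimates <- stats::setNames(
    vapply(seq_along(info), function(i)
      back_transform(theta[[i]], info[[i]]$trans), 0),
    names(cv))
  structure(list(
    model = model, estimates = estimates, cv_percent = cv,
    ofv = ofv, n_estimated = length(info),
    aic = ofv + 2 * length(info),
    ebe = ebe, ebe_converged = ebe_conv, shrinkage = shr,
    condition_number = cond, converged = converged,
    n_dropped_blq = n_blq_dropped, method = method,
    vcov = vcov, theta = theta, theta_info = info,
    n_obs = sum(vapply(subs, function(s) length(s$conc), 0L)),
    cov_rows = cov_rows, dataset = dataset
  ), class = "vd_fit")
}

#' @export
print.vd_fit <- function(x, ...) {
  cat(sprintf(
    "Population fit (%s): OFV %.3f, AIC %.3f, %d estimated, converged: %s\n",
    x$method, x$ofv, x$aic, x$n_estimated, x$converged))
  if (!is.null(x$optimizer_message) && !x$converged) {
    cat("  optimizer:", x$optimizer_message, "\n")
  }
  if (x$n_dropped_blq > 0L) {
    cat("  BLQ records dropped (M1):", x$n_dropped_blq, "\n")
  }
  if (x$n_estimated > 0L) {
    tab <- data.frame(estimate = signif(x$estimates, 4),
                      `CV%` = signif(x$cv_percent, 3),
                      check.names = FALSE)
    print(tab)
  }
  if (length(x$shrinkage) > 0L) {
    cat("eta-shrinkage:",
        paste(sprintf("%s=%.2f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate-only objective function value
#'
#' The OFV (`-2 log L`) of a model on a dataset without any optimization;
#' identical to what [fit_population()] reports when every parameter is
#' fixed.
#'
#' @inheritParams fit_population
#' @return A single numeric OFV.
#' @export
ofv_population <- function(dataset, model = population_model(),
                           method = c("M3", "M1"), covariates = NULL) {
  method <- match.arg(method)
  subs <- split_subjects(dataset)
  model <- resolve_covariate_refs(model, covariates)
  cov_rows <- covariate_rows(covariates, subs)
  ll <- 0
  for (i in seq_along(subs)) {
    r <- marginal_loglik_subject(subs[[i]], model, method,
                                 cov_row = cov_rows[[i]])
    ll <- ll + r$loglik
  }
  -2 * ll
}

#' Eta-shrinkage
#'
#' `1 - sd(EBE) / omega` per random effect. Values above 0.40 indicate that
#' the individual estimates have collapsed toward the population mean and
#' the corresponding IIV term is a candidate for removal.
#'
#' @param fit A `vd_fit`.
#' @param threshold Flagging threshold (default 0.40).
#' @return A data.frame with columns `parameter`, `shrinkage`,
#'   `flag_removal`.
#' @export
eta_shrinkage <- function(fit, threshold = 0.40) {
  stopifnot(inherits(fit, "vd_fit"))
  data.frame(parameter = names(fit$shrinkage),
             shrinkage = as.numeric(fit$shrinkage),
             flag_removal = as.numeric(fit$shrinkage) > threshold,
             row.names = NULL)
}

#' Serialize a fit report
#'
#' Writes the parameter table (estimate, CV%), OFV/AIC, shrinkage and
#' convergence metadata as JSON.
#'
#' @param fit A `vd_fit`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "vd_fit"))
  report <- list(
    parameters = data.frame(parameter = names(fit$estimates),
                            estimate = as.numeric(fit$estimates),
                            cv_percent = as.numeric(fit$cv_percent)),
    fixed = stats::setNames(
      as.list(unlist(fit$model$params[fit$model$fixed])), fit$model$fixed),
    ofv = fit$ofv, aic = fit$aic, n_estimated = fit$n_estimated,
    n_obs = fit$n_obs, method = fit$method,
    shrinkage = as.list(fit$shrinkage),
    condition_number = fit$condition_number,
    converged = fit$converged, n_dropped_blq = fit$n_dropped_blq)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

covariate_rows <- function(covariates, subs) {
  if (is.null(covariates)) return(vector("list", length(subs)))
  stopifnot(!is.null(covariates$ID))
  lapply(subs, function(s) {
    row <- covariates[covariates$ID == s$id, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("covariate table must have exactly one row for subject ", s$id,
           call. = FALSE)
    }
    row
  })
}
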