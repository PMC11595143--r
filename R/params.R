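#' Structural pharmacokinetic parameters
#'
#' Fixed-effect parameters of the parent-metabolite compartmental model:
#' a two-compartment disposition model for cholecalciferol with first-order
#' oral absorption and zero-order endogenous production, chained to
#' one-compartment models for 25D3, 1,25D3 and 24,25D3 with first-order
#' formation and elimination. Defaults are the final population estimates of
#' the chronic-kidney-disease study this package models; volumes and
#' clearances for the parent are apparent (scaled by the unknown oral
#' bioavailability F).
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param k_endog Zero-order endogenous production rate of cholecalciferol
#'   (nmol/h), representing diet and skin synthesis.
#' @param Vc_F,Vp_F Apparent central and peripheral volumes of the parent (L).
#' @param CL_F Apparent clearance of the parent (L/h); with `fm1 = 1` all of
#'   it forms 25D3.
#' @param Q_F Intercompartmental clearance of the parent (L/h).
#' @param C0 Parent baseline concentration (nmol/L).
#' @param fm1 Fraction of parent elimination forming 25D3 (0-1).
#' @param C0_m1,V_m1,CL_m1 Baseline (nmol/L), volume (L) and clearance (L/h)
#'   of 25D3.
#' @param fm2 Fraction of 25D3 elimination forming 1,25D3 (0-1); the
#'   remainder, `1 - fm2`, forms 24,25D3 and is never stored separately.
#' @param C0_m2,V_m2,CL_m2 Baseline, volume and clearance of 1,25D3.
#' @param C0_m3,V_m3,CL_m3 Baseline, volume and clearance of 24,25D3.
#' @return An object of class `vd_params`: a validated named list.
#' @seealso [params_preset()] for named parameter sets, [population_model()]
#'   for adding random-effect and residual-error structure.
#' @examples
#' p <- structural_params()
#' p$CL_m1
#' @export
structural_params <- function(ka = 0.054, k_endog = 0.55, Vc_F = 21.3,
                              CL_F = 1.4, Vp_F = 50, Q_F = 0.44, C0 = 0.98,
                              fm1 = 1, C0_m1 = 43.5, V_m1 = 58.3,
                              CL_m1 = 0.02, fm2 = 0.017, C0_m2 = 0.20,
                              V_m2 = 71.5, CL_m2 = 0.08, C0_m3 = 2.2,
                              V_m3 = 105.2, CL_m3 = 0.40) {
  p <- list(ka = ka, k_endog = k_endog, Vc_F = Vc_F, CL_F = CL_F,
            Vp_F = Vp_F, Q_F = Q_F, C0 = C0, fm1 = fm1, C0_m1 = C0_m1,
            V_m1 = V_m1, CL_m1 = CL_m1, fm2 = fm2, C0_m2 = C0_m2,
            V_m2 = V_m2, CL_m2 = CL_m2, C0_m3 = C0_m3, V_m3 = V_m3,
            CL_m3 = CL_m3)
  validate_params(p)
  structure(p, class = "vd_params")
}

#' @rdname structural_params
#' @param x A list (or `vd_params`) of parameter values to validate/coerce.
#' @export
as_structural_params <- function(x) {
  if (inherits(x, "vd_params")) return(x)
  do.call(structural_params, x[PARAM_NAMES])
}

validate_params <- function(p) {
  miss <- setdiff(PARAM_NAMES, names(p))
  if (length(miss) > 0L) {
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(p[PARAM_NAMES])
  if (any(!is.finite(vals))) stop("parameters must be finite", call. = FALSE)
  pos <- setdiff(PARAM_NAMES, FRACTION_PARAMS)
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad) > 0L) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (f in FRACTION_PARAMS) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop(f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(p)
}

#' Named structural parameter presets
#'
#' `"final"` is the canonical set (the final-model estimates, used as the
#' package default). `"early-fixed"` differs only in the fixed parent
#' disposition constants (`ka` 0.323 1/h, `Vp_F` 2333 L, `Q_F` 0.185 L/h),
#' an earlier literature-derived choice retained for sensitivity analyses.
#'
#' @param name Preset name.
#' @return A `vd_params` object.
#' @export
params_preset <- function(name = c("final", "early-fixed")) {
  name <- match.arg(name)
  switch(name,
    "final" = structural_params(),
    "early-fixed" = structural_params(ka = 0.323, Vp_F = 2333, Q_F = 0.185)
  )
}

#' @export
print.vd_params <- function(x, ...) {
  cat("Structural PK parameters (vitamin D3 parent + 3 metabolites)\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Population pharmacokinetic model
#'
#' Couples the structural fixed effects with log-normal inter-individual
#' variability (IIV) on a subset of parameters, a residual error model per
#' analyte, the fixed/estimated parameter split, and optional covariate
#' effects. Individual parameters follow `P_i = TVP * exp(eta_i)` with
#' `eta_i ~ N(0, omega2)`.
#'
#' @param params A [structural_params()] object (the typical values, TVP).
#' @param omega2 Named numeric vector of IIV variances (diagonal). Default
#'   places 0.09 (30% CV) on `C0`, `Vc_F` and `CL_F`, the random-effect set
#'   of the final model; the magnitude is a declared simulation assumption.
#' @param sigma Named numeric vector of residual-error coefficients per
#'   analyte. Under the (default, final-model) proportional form these are
#'   dimensionless CVs.
#' @param error_model Residual error form: `"proportional"` (sd =
#'   sigma * pred), `"additive"` (sd = sigma_add, nmol/L) or `"combined"`.
#' @param sigma_add Additive error sd per analyte (nmol/L), used by the
#'   additive and combined forms.
#' @param fixed Character vector of structural parameters excluded from
#'   estimation.
#' @param covariates Optional list of covariate effects created by
#'   [covariate_spec()].
#' @return An object of class `vd_popmodel`.
#' @examples
#' m <- population_model()
#' m$sigma
#' @export
population_model <- function(params = structural_params(),
                             omega2 = c(C0 = 0.09, Vc_F = 0.09, CL_F = 0.09),
                             sigma = c(VITD3 = 0.125, D25 = 0.657,
                                       D125 = 0.172, D2425 = 0.166),
                             error_model = c("proportional", "additive",
                                             "combined"),
                             sigma_add = c(VITD3 = 0, D25 = 0, D125 = 0,
                                           D2425 = 0),
                             fixed = DEFAULT_FIXED,
                             covariates = list()) {
  params <- as_structural_params(params)
  error_model <- match.arg(error_model)
  if (any(omega2 < 0)) stop("omega2 variances must be >= 0", call. = FALSE)
  if (length(omega2) > 0L && is.null(names(omega2))) {
    stop("omega2 must be named by parameter", call. = FALSE)
  }
  bad <- setdiff(names(omega2), PARAM_NAMES)
  if (length(bad) > 0L) {
    stop("omega2 names are not parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sigma <- sigma[ANALYTES]
  if (any(is.na(sigma)) || any(sigma < 0)) {
    stop("sigma must be a non-negative value per analyte", call. = FALSE)
  }
  if (error_model == "proportional" && any(sigma == 0)) {
    # tolerated: a zero-sigma model is only meaningful for noise-free
    # simulation, never for likelihood evaluation
  }
  sigma_add <- sigma_add[ANALYTES]
  sigma_add[is.na(sigma_add)] <- 0
  names(sigma_add) <- ANALYTES
  bad <- setdiff(fixed, PARAM_NAMES)
  if (length(bad) > 0L) {
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(params = params, omega2 = omega2, sigma = sigma,
                 sigma_add = sigma_add, error_model = error_model,
                 fixed = fixed, covariates = covariates),
            class = "vd_popmodel")
}

#' @export
print.vd_popmodel <- function(x, ...) {
  cat("Population PK model\n")
  cat("  error model:", x$error_model, "\n")
  cat("  sigma:", paste(sprintf("%s=%g", names(x$sigma), x$sigma),
                        collapse = ", "), "\n")
  cat("  omega2:", if (length(x$omega2) == 0) "(none)" else
      paste(sprintf("%s=%g", names(x$omega2), x$omega2), collapse = ", "),
      "\n")
  cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  if (length(x$covariates) > 0) {
    cat("  covariates:", paste(vapply(x$covariates, function(cv)
      paste0(cv$covariate, "->", cv$parameter), ""), collapse = ", "), "\n")
  }
  cat("Structural parameters:\n")
  print(unlist(x$params))
  invisible(x)
}

#' Read or write a model configuration file
#'
#' The configuration is a flat YAML (or JSON) mapping whose keys are exactly
#' the structural parameter names, plus `fixed` (list of non-estimated
#' parameters), `omega2`, `sigma`, `sigma_add` and `error_model`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_model_config()` returns a `vd_popmodel`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params <- as_structural_params(cfg[PARAM_NAMES])
  population_model(
    params = params,
    omega2 = unlist(cfg$omega2),
    sigma = unlist(cfg$sigma),
    error_model = cfg$error_model %||% "proportional",
    sigma_add = unlist(cfg$sigma_add) %||%
      c(VITD3 = 0, D25 = 0, D125 = 0, D2425 = 0),
    fixed = unlist(cfg$fixed) %||% DEFAULT_FIXED
  )
}

#' @rdname read_model_config
#' @param model A `vd_popmodel`.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "vd_popmodel"))
  cfg <- c(lapply(model$params[PARAM_NAMES], identity),
           list(fixed = as.list(model$fixed),
                omega2 = as.list(model$omega2),
                sigma = as.list(model$sigma),
                sigma_add = as.list(model$sigma_add),
                error_model = model$error_model))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

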