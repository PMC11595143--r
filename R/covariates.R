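#' Covariate effect specification
#'
#' A single-coefficient covariate-parameter relationship. Continuous
#' covariates use a power form centered at a reference value (the dataset
#' median unless given): `P_i = TVP * (x_i / ref)^beta`. Categorical
#' (indicator) covariates use a proportional shift: `P_i = TVP * (1 + beta *
#' x_i)`. Both add exactly one estimated coefficient, so likelihood-ratio
#' tests against the base model have one degree of freedom.
#'
#' @param covariate Covariate column name.
#' @param parameter Target structural parameter (must be estimated, i.e. not
#'   in the model's fixed set).
#' @param form `"power"` (continuous) or `"proportional"` (categorical
#'   indicator).
#' @param ref Reference value for the power form; `NULL` means the median of
#'   the covariate in the fitted dataset.
#' @param coef Starting coefficient (default 0, no effect).
#' @return A `vd_covspec` list.
#' @export
covariate_spec <- function(covariate, parameter,
                           form = c("power", "proportional"),
                           ref = NULL, coef = 0) {
  form <- match.arg(form)
  if (!parameter %in% PARAM_NAMES) {
    stop("unknown target parameter: ", parameter, call. = FALSE)
  }
  structure(list(covariate = covariate, parameter = parameter, form = form,
                 ref = ref, coef = coef), class = "vd_covspec")
}

covariate_term <- function(x, form, coef, ref = NULL) {
  switch(form,
    power = {
      if (is.null(ref)) ref <- stats::median(x)
      (x / ref)^coef
    },
    proportional = 1 + coef * x,
    stop("unknown covariate form: ", form, call. = FALSE)
  )
}

# fill in data-derived reference values (continuous forms centered at the
# observed median) so each covariate effect is frozen before optimization
resolve_covariate_refs <- function(model, covariates) {
  if (length(model$covariates) == 0L) return(model)
  if (is.null(covariates)) {
    stop("model declares covariate effects but no covariate table given",
         call. = FALSE)
  }
  for (i in seq_along(model$covariates)) {
    sp <- model$covariates[[i]]
    if (sp$form == "power" && is.null(sp$ref)) {
      x <- covariates[[sp$covariate]]
      if (is.null(x)) {
        stop("covariate not in table: ", sp$covariate, call. = FALSE)
      }
      model$covariates[[i]]$ref <- stats::median(x)
    }
    if (sp$parameter %in% model$fixed) {
      stop("covariate target ", sp$parameter, " is a fixed parameter",
           call. = FALSE)
    }
  }
  model
}

#' Stepwise covariate screen
#'
#' Forward addition followed by backward elimination on single-coefficient
#' covariate effects. Each forward step refits the model with one candidate
#' added and accepts the candidate with the largest drop in OFV, provided
#' the drop exceeds `forward_dofv` (3.841 = chi-square df 1, p < 0.05);
#' this repeats until no candidate qualifies. Backward elimination then
#' removes, one at a time, any retained covariate whose deletion raises the
#' OFV by less than `backward_dofv` (6.635 = chi-square df 1, p < 0.01).
#'
#' @param dataset A `vd_dataset`.
#' @param model Base [population_model()] (no covariates, or a starting
#'   set).
#' @param candidates List of [covariate_spec()] objects.
#' @param covariates Covariate table (one row per subject, `ID` column).
#' @param forward_dofv,backward_dofv Likelihood-ratio thresholds (df = 1).
#' @param ... Passed to [fit_population()] (e.g. `method`,
#'   `estimate_omega`, `compute_se`, `control`).
#' @return A list: `selected` (list of accepted specs with fitted
#'   coefficients), `fit` (final `vd_fit`), `base_fit`, and `trail` (a
#'   data.frame logging every tested step with its delta-OFV and decision).
#' @export
covariate_screen <- function(dataset, model, candidates,
                             covariates, forward_dofv = 3.841,
                             backward_dofv = 6.635, ...) {
  stopifnot(inherits(dataset, "vd_dataset"))
  for (sp in candidates) {
    if (!inherits(sp, "vd_covspec")) {
      stop("candidates must be covariate_spec objects", call. = FALSE)
    }
  }
  fit_with <- function(specs) {
    m <- model
    m$covariates <- specs
    fit_population(dataset, m, covariates = covariates, compute_se = FALSE,
                   ...)
  }
  base_fit <- fit_with(list())
  trail <- list()
  log_step <- function(phase, spec, dofv, decision) {
    trail[[length(trail) + 1L]] <<- data.frame(
      phase = phase,
      covariate = spec$covariate, parameter = spec$parameter,
      delta_ofv = dofv, decision = decision)
  }
  selected <- list()
  remaining <- candidates
  current_fit <- base_fit
  # forward addition
  repeat {
    if (length(remaining) == 0L) break
    fits <- lapply(remaining, function(sp) fit_with(c(selected, list(sp))))
    dofv <- current_fit$ofv - vapply(fits, `[[`, 0, "ofv")
    best <- which.max(dofv)
    for (j in seq_along(remaining)) {
      if (j != best) log_step("forward", remaining[[j]], dofv[j], "not best")
    }
    if (dofv[best] > forward_dofv) {
      log_step("forward", remaining[[best]], dofv[best], "added")
      sp <- remaining[[best]]
      sp$coef <- fits[[best]]$model$covariates[[length(selected) + 1L]]$coef
      sp$ref <- fits[[best]]$model$covariates[[length(selected) + 1L]]$ref
      selected <- c(selected, list(sp))
      current_fit <- fits[[best]]
      remaining <- remaining[-best]
    } else {
      if (length(remaining) > 0L) {
        log_step("forward", remaining[[best]], dofv[best], "rejected")
      }
      break
    }
  }
  # backward elimination
  repeat {
    if (length(selected) == 0L) break
    removed <- FALSE
    for (j in seq_along(selected)) {
      reduced <- selected[-j]
      fit_red <- if (length(reduced) > 0L) fit_with(reduced) else base_fit
      dofv <- fit_red$ofv - current_fit$ofv  # rise in OFV on deletion
      if (dofv < backward_dofv) {
        log_step("backward", selected[[j]], dofv, "removed")
        selected <- reduced
        current_fit <- fit_red
        removed <- TRUE
        break
      } else {
        log_step("backward", selected[[j]], dofv, "retained")
      }
    }
    if (!removed) break
  }
  trail <- if (length(trail) > 0L) do.call(rbind, trail) else
    data.frame(phase = character(0), covariate = character(0),
               parameter = character(0), delta_ofv = numeric(0),
               decision = character(0))
  list(selected = selected, fit = current_fit, base_fit = base_fit,
       trail = trail)
}
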