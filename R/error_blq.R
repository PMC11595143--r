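#' Apply inter-individual variability to the typical parameters
#'
#' Individual parameters follow the log-normal convention
#' `P_i = TVP * exp(eta_i)`: each named element of `eta` multiplies the
#' corresponding structural parameter by `exp(eta)`; all other parameters
#' are copied unchanged.
#'
#' @param pop A [structural_params()] object (typical values).
#' @param eta Named numeric vector of random effects (unitless), names being
#'   structural parameter names.
#' @return A `vd_params` object with the individual parameter values.
#' @examples
#' ind <- apply_iiv(structural_params(), c(CL_F = log(2)))
#' ind$CL_F  # doubled
#' @export
apply_iiv <- function(pop, eta) {
  pop <- as_structural_params(pop)
  if (length(eta) == 0L) return(pop)
  bad <- setdiff(names(eta), PARAM_NAMES)
  if (length(bad) > 0L) {
    stop("eta names are not parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(names(eta) %in% FRACTION_PARAMS)) {
    stop("log-normal IIV is not defined for fraction parameters",
         call. = FALSE)
  }
  for (nm in names(eta)) pop[[nm]] <- pop[[nm]] * exp(eta[[nm]])
  pop
}

#' Residual standard deviation
#'
#' Residual-error forms evaluated at a model prediction: `"additive"` gives
#' a constant sd, `"proportional"` scales with the prediction
#' (`sigma * pred`), and `"combined"` adds the two in quadrature. The final
#' model uses the proportional form for all four analytes.
#'
#' @param pred Model prediction(s), nmol/L, non-negative.
#' @param sigma Proportional-error coefficient (dimensionless).
#' @param sigma_add Additive-error sd (nmol/L).
#' @param form Error-model form.
#' @return Residual sd in nmol/L, same length as `pred`.
#' @export
residual_sd <- function(pred, sigma, sigma_add = 0,
                        form = c("proportional", "additive", "combined")) {
  form <- match.arg(form)
  switch(form,
    additive     = rep_len(sigma_add, length(pred)),
    proportional = sigma * pred,
    combined     = sqrt(sigma_add^2 + (sigma * pred)^2)
  )
}

#' Per-observation log-likelihood with censored-data support
#'
#' Quantified observations contribute a Gaussian log-density with mean
#' `pred` and the residual sd of the error model. Below-LLOQ (BLQ) records
#' are handled by Beal's M1 or M3 method: under M1 they are dropped
#' (contributing 0, counted in the `n_dropped` attribute); under M3 they
#' contribute the log of the Gaussian CDF at the LLOQ,
#' `log Phi((lloq - pred) / sd)`, i.e. the probability the model puts below
#' the quantification limit.
#'
#' Predictions are floored at `1e-10` nmol/L inside the evaluation so that a
#' proportional error model never yields a zero variance; the floor is far
#' below any physical concentration.
#'
#' @param conc Observed concentrations (nmol/L); `NA` for BLQ records.
#' @param blq Logical vector flagging BLQ records.
#' @param lloq Lower limit of quantification (nmol/L) per record; required
#'   for BLQ records under M3.
#' @param pred Model predictions (nmol/L), positive.
#' @param sigma,sigma_add,form Residual error model, as in [residual_sd()].
#' @param method `"M3"` (default; retain BLQ records via the censored
#'   likelihood) or `"M1"` (drop them).
#' @return Numeric vector of log-likelihood contributions with attribute
#'   `n_dropped` (number of records excluded under M1).
#' @examples
#' # a BLQ record whose prediction sits exactly at the LLOQ: log(0.5)
#' obs_loglik(NA, blq = TRUE, lloq = 2.5, pred = 2.5, sigma = 0.657)
#' @export
obs_loglik <- function(conc, blq, lloq, pred, sigma, sigma_add = 0,
                       form = c("proportional", "additive", "combined"),
                       method = c("M3", "M1")) {
  form <- match.arg(form)
  method <- match.arg(method)
  n <- max(length(conc), length(pred))
  conc <- rep_len(conc, n)
  blq <- rep_len(as.logical(blq), n)
  lloq <- rep_len(lloq, n)
  pred <- rep_len(pred, n)
  sigma <- rep_len(sigma, n)
  sigma_add <- rep_len(sigma_add, n)
  if (any(!is.finite(pred) | pred <= 0)) {
    stop("predictions must be positive and finite", call. = FALSE)
  }
  if (any(blq & !is.finite(lloq))) {
    stop("BLQ records require a finite lloq", call. = FALSE)
  }
  pred <- pmax(pred, 1e-10)
  sd <- residual_sd(pred, sigma, sigma_add, form)
  ll <- numeric(n)
  quant <- !blq
  if (any(quant)) {
    ll[quant] <- stats::dnorm(conc[quant], mean = pred[quant],
                              sd = sd[quant], log = TRUE)
  }
  n_dropped <- 0L
  if (any(blq)) {
    if (method == "M3") {
      ll[blq] <- stats::pnorm(lloq[blq], mean = pred[blq], sd = sd[blq],
                              log.p = TRUE)
    } else {
      ll[blq] <- 0
      n_dropped <- sum(blq)
    }
  }
  attr(ll, "n_dropped") <- n_dropped
  ll
}
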