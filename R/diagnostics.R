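#' Goodness-of-fit table
#'
#' Per-observation diagnostics for a converged fit: `PRED` (population
#' prediction at `eta = 0`, covariate effects included), `IPRED` (prediction
#' at the subject's empirical Bayes estimate) and `CWRES` (conditional
#' weighted residuals: the residual vector whitened by the covariance of a
#' first-order conditional linearization of the subject model around the
#' EBE). BLQ records carry `PRED`/`IPRED` but no residual.
#'
#' @param fit A `vd_fit`.
#' @param dataset Dataset to diagnose; defaults to the fitted one.
#' @return A `vd_gof` data.frame with columns `ID`, `time`, `analyte`,
#'   `OBS`, `PRED`, `IPRED`, `CWRES`, `BLQ`.
#' @export
gof <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "vd_fit"))
  dataset <- dataset %||% fit$dataset
  subs <- split_subjects(dataset)
  model <- fit$model
  cov_rows <- if (identical(dataset, fit$dataset)) fit$cov_rows else
    covariate_rows(attr(dataset, "covariates"), subs)
  om <- model$omega2[model$omega2 > 0]
  d <- length(om)
  Omega <- diag(as.numeric(om), d)
  out <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    mult <- if (length(model$covariates) > 0L) {
      subject_cov_mult(model, cov_rows[[i]])
    } else list()
    base_p <- apply_cov_mult(model$params, mult)
    pred_at <- function(eta) {
      subject_pred(sub, apply_iiv(base_p, stats::setNames(eta, names(om))))
    }
    pred0 <- subject_pred(sub, base_p)
    ebe <- if (d > 0L && nrow(fit$ebe) >= i &&
               identical(dataset, fit$dataset)) {
      fit$ebe[i, ]
    } else if (d > 0L) {
      marginal_loglik_subject(sub, model, fit$method,
                              cov_row = cov_rows[[i]])$eta
    } else numeric(0)
    ipred <- if (d > 0L) pred_at(ebe) else pred0
    cwres <- rep(NA_real_, length(sub$conc))
    quant <- !sub$blq
    if (any(quant)) {
      sd_i <- residual_sd(pmax(ipred[quant], 1e-10),
                          model$sigma[sub$analyte[quant]],
                          model$sigma_add[sub$analyte[quant]],
                          model$error_model)
      if (d > 0L) {
        # finite-difference sensitivity of predictions to eta at the EBE
        G <- matrix(0, sum(quant), d)
        h <- 1e-4
        for (k in seq_len(d)) {
          up <- ebe; up[k] <- up[k] + h
          G[, k] <- (pred_at(up)[quant] - ipred[quant]) / h
        }
        V <- G %*% Omega %*% t(G) + diag(sd_i^2, sum(quant))
        mu <- ipred[quant] - as.vector(G %*% ebe)
        L <- t(chol((V + t(V)) / 2))
        cwres[quant] <- as.vector(
          forwardsolve(L, sub$conc[quant] - mu))
      } else {
        cwres[quant] <- (sub$conc[quant] - ipred[quant]) / sd_i
      }
    }
    out[[i]] <- data.frame(ID = sub$id, time = sub$times[sub$time_idx],
                           analyte = sub$analyte, OBS = sub$conc,
                           PRED = pred0, IPRED = ipred, CWRES = cwres,
                           BLQ = as.integer(sub$blq))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("vd_gof", "data.frame")
  res
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicates of the observed design (same subjects,
#' dose histories and sampling times), applies the residual error and the
#' per-record LLOQ censoring, and summarizes the 5th/50th/95th percentiles
#' of the quantified simulated concentrations per analyte and nominal time
#' bin, next to the same percentiles of the quantified observations.
#' Simulated values below the LLOQ are excluded from the percentile
#' computation, mirroring the observed side; the censored fraction per bin
#' is reported separately.
#'
#' @param dataset A `vd_dataset` (defines the design and the observed
#'   percentiles).
#' @param model A [population_model()] to simulate from.
#' @param n_rep Number of replicate studies (default 200).
#' @param seed Integer seed.
#' @param band Probability span of the across-replicate band on each
#'   percentile statistic (default 0.90).
#' @return A `vd_vpc` data.frame: one row per analyte x time bin with
#'   observed percentiles (`obs_p5`, `obs_p50`, `obs_p95`), the median
#'   simulated percentiles (`sim_p5`, `sim_p50`, `sim_p95`), band limits
#'   (`p5_lo` ... `p95_hi`), the observed and mean simulated BLQ fractions,
#'   and `n_obs`. Attribute `n_replicates` records `n_rep`.
#' @export
vpc <- function(dataset, model = population_model(), n_rep = 200L,
                seed = 1L, band = 0.90) {
  stopifnot(inherits(dataset, "vd_dataset"), n_rep >= 1L)
  set.seed(seed)
  subs <- split_subjects(dataset)
  om <- model$omega2[model$omega2 > 0]
  eta_names <- names(om)
  obs <- dataset[dataset$EVID == 0L, , drop = FALSE]
  bins <- unique(obs[c("DVID", "TIME")])
  bins <- bins[order(match(bins$DVID, ANALYTES), bins$TIME), ]
  bin_key <- paste(obs$DVID, obs$TIME)
  keys <- paste(bins$DVID, bins$TIME)
  qs <- c(0.05, 0.50, 0.95)
  # observed percentiles over quantified records
  obs_stats <- t(vapply(keys, function(k) {
    v <- obs$DV[bin_key == k & obs$BLQ == 0L]
    n_tot <- sum(bin_key == k)
    c(if (length(v) > 0L) stats::quantile(v, qs, names = FALSE)
      else rep(NA_real_, 3L),
      sum(bin_key == k & obs$BLQ == 1L) / n_tot, n_tot)
  }, numeric(5L)))
  sim_pct <- array(NA_real_, c(length(keys), 3L, n_rep))
  sim_blq <- matrix(NA_real_, length(keys), n_rep)
  for (r in seq_len(n_rep)) {
    vals <- vector("list", length(subs))
    for (i in seq_along(subs)) {
      sub <- subs[[i]]
      eta <- stats::setNames(
        stats::rnorm(length(eta_names), 0, sqrt(om[eta_names])), eta_names)
      p_i <- apply_iiv(model$params, eta)
      pred <- subject_pred(sub, p_i)
      sd <- residual_sd(pmax(pred, 1e-10), model$sigma[sub$analyte],
                        model$sigma_add[sub$analyte], model$error_model)
      dv <- pred + sd * stats::rnorm(length(pred))
      vals[[i]] <- data.frame(key = paste(sub$analyte,
                                          sub$times[sub$time_idx]),
                              dv = dv, blq = dv < sub$lloq)
    }
    sim <- do.call(rbind, vals)
    for (j in seq_along(keys)) {
      rows <- sim$key == keys[j]
      v <- sim$dv[rows & !sim$blq]
      if (length(v) > 0L) {
        sim_pct[j, , r] <- stats::quantile(v, qs, names = FALSE)
      }
      sim_blq[j, r] <- mean(sim$blq[rows])
    }
  }
  lohi <- c((1 - band) / 2, 1 - (1 - band) / 2)
  agg <- function(j, k, probs) {
    v <- sim_pct[j, k, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) rep(NA_real_, length(probs)) else
      stats::quantile(v, probs, names = FALSE)
  }
  res <- data.frame(
    analyte = bins$DVID, time = bins$TIME,
    n_obs = obs_stats[, 5L],
    obs_p5 = obs_stats[, 1L], obs_p50 = obs_stats[, 2L],
    obs_p95 = obs_stats[, 3L], obs_blq_frac = obs_stats[, 4L],
    sim_p5 = vapply(seq_along(keys), agg, 0, k = 1L, probs = 0.5),
    sim_p50 = vapply(seq_along(keys), agg, 0, k = 2L, probs = 0.5),
    sim_p95 = vapply(seq_along(keys), agg, 0, k = 3L, probs = 0.5),
    p5_lo = vapply(seq_along(keys), agg, 0, k = 1L, probs = lohi[1]),
    p5_hi = vapply(seq_along(keys), agg, 0, k = 1L, probs = lohi[2]),
    p50_lo = vapply(seq_along(keys), agg, 0, k = 2L, probs = lohi[1]),
    p50_hi = vapply(seq_along(keys), agg, 0, k = 2L, probs = lohi[2]),
    p95_lo = vapply(seq_along(keys), agg, 0, k = 3L, probs = lohi[1]),
    p95_hi = vapply(seq_along(keys), agg, 0, k = 3L, probs = lohi[2]),
    sim_blq_frac = rowMeans(sim_blq, na.rm = TRUE))
  empty <- is.na(res$obs_p50)
  if (any(empty)) {
    warning(sum(empty), " bin(s) without quantified observations dropped",
            call. = FALSE)
    res <- res[!empty, , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "n_replicates") <- n_rep
  class(res) <- c("vd_vpc", "data.frame")
  res
}

#' Plot a visual predictive check
#'
#' @param x A `vd_vpc`.
#' @param log_y Plot concentrations on a log scale.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_vpc <- function(x, log_y = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  gg <- ggplot2::ggplot(x, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5_lo,
                                      ymax = .data$p95_hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p50),
                       colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_p5), colour = "red",
                        shape = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_p95), colour = "red",
                        shape = 6) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (nmol/L)")
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot goodness-of-fit panels
#'
#' Observed vs predicted and conditional-weighted-residual panels.
#'
#' @param x A `vd_gof`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_gof <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  quant <- x[x$BLQ == 0L, , drop = FALSE]
  ggplot2::ggplot(quant, ggplot2::aes(x = .data$PRED, y = .data$CWRES)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(-2, 0, 2), linetype = "dashed") +
    ggplot2::facet_wrap(~analyte, scales = "free_x") +
    ggplot2::labs(x = "population prediction (nmol/L)", y = "CWRES")
}
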