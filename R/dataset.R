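#' Longitudinal PK dataset container
#'
#' A `vd_dataset` is a validated NONMEM-style event table: one row per dose
#' event (`EVID = 1`, `AMT` in I.U.) or observation (`EVID = 0`, `DV` in
#' nmol/L), with `DVID` naming the analyte, `BLQ` flagging records censored
#' below the limit of quantification (whose `DV` is `NA`) and `LLOQ` the
#' per-record quantification limit in nmol/L. All stored concentrations are
#' molar; ng/mL is accepted on input and converted immediately.
#'
#' @param x A data.frame with columns `ID`, `TIME`, `AMT`, `EVID`, `DVID`,
#'   `DV`, `BLQ`, `LLOQ` (missing `AMT`/`BLQ`/`LLOQ` columns are filled with
#'   defaults for pure observation tables).
#' @param units Units of `DV` and `LLOQ` in `x`: `"nmol/L"` (canonical) or
#'   `"ng/mL"` (converted on ingestion using each analyte's molar mass).
#' @return A `vd_dataset`: the canonicalized data.frame with unit metadata
#'   in `attr(, "units")` (always `"nmol/L"`).
#' @seealso [read_pk_dataset()], [write_pk_dataset()], [generate_study()]
#' @export
as_pk_dataset <- function(x, units = c("nmol/L", "ng/mL")) {
  units <- match.arg(units)
  required <- c("ID", "TIME", "EVID", "DVID", "DV")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$AMT)) x$AMT <- 0
  if (is.null(x$BLQ)) x$BLQ <- 0L
  if (is.null(x$LLOQ)) x$LLOQ <- NA_real_
  x <- x[c("ID", "TIME", "AMT", "EVID", "DVID", "DV", "BLQ", "LLOQ")]
  x$BLQ <- as.integer(x$BLQ)
  x$AMT <- as.numeric(x$AMT)
  x$TIME <- as.numeric(x$TIME)
  x$DV <- as.numeric(x$DV)
  x$LLOQ <- as.numeric(x$LLOQ)
  obs <- x$EVID == 0L
  if (!any(obs)) stop("no observations in dataset", call. = FALSE)
  if (any(x$TIME < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(!x$EVID %in% c(0L, 1L))) {
    stop("EVID must be 0 (observation) or 1 (dose)", call. = FALSE)
  }
  if (any(x$EVID == 1L & x$AMT <= 0)) {
    stop("dose rows require AMT > 0", call. = FALSE)
  }
  check_analyte(x$DVID[obs])
  bad <- obs & x$BLQ == 1L & !is.na(x$DV)
  if (any(bad)) {
    stop(sum(bad), " BLQ record(s) carry a concentration value",
         call. = FALSE)
  }
  if (any(obs & x$BLQ == 0L & is.na(x$DV))) {
    stop("quantified observation(s) with missing DV", call. = FALSE)
  }
  if (units == "ng/mL") {
    x$DV[obs] <- ngml_to_nmoll(x$DV[obs], x$DVID[obs])
    x$LLOQ[obs] <- ngml_to_nmoll(x$LLOQ[obs], x$DVID[obs])
  }
  low <- obs & x$BLQ == 0L & !is.na(x$LLOQ) & x$DV < x$LLOQ
  if (any(low)) {
    warning(sum(low), " quantified record(s) fall below their LLOQ",
            call. = FALSE)
  }
  # canonical record order: subject, time, dose-first, analyte cascade;
  # this makes downstream random-number pairing order-independent
  x <- x[order(x$ID, x$TIME, -x$EVID, match(x$DVID, ANALYTES)), ,
         drop = FALSE]
  rownames(x) <- NULL
  structure(x, units = "nmol/L", class = c("vd_dataset", "data.frame"))
}

#' Read or write a PK dataset as CSV
#'
#' @param path CSV file path with the column layout of [as_pk_dataset()].
#' @inheritParams as_pk_dataset
#' @return `read_pk_dataset()`: a `vd_dataset` in nmol/L.
#'   `write_pk_dataset()`: `path`, invisibly. A write/read round trip in
#'   nmol/L mode is lossless.
#' @export
read_pk_dataset <- function(path, units = c("nmol/L", "ng/mL")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", "", "."))
  as_pk_dataset(x, units = match.arg(units))
}

#' @rdname read_pk_dataset
#' @param dataset A `vd_dataset`.
#' @export
write_pk_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "vd_dataset"))
  out <- as.data.frame(dataset)
  # full double precision so a write/read round trip is lossless
  for (nm in c("TIME", "AMT", "DV", "LLOQ")) {
    out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                        sprintf("%.17g", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.vd_dataset <- function(x, ...) {
  obs <- x$EVID == 0L
  cat(sprintf(
    "PK dataset: %d subjects, %d observations (%d BLQ), %d dose events\n",
    length(unique(x$ID)), sum(obs), sum(x$BLQ[obs] == 1L), sum(!obs)))
  NextMethod()
}

# per-subject split used by the fitter and diagnostics: list of
# list(id, doses, times, obs) where obs carries row indices into `times`
split_subjects <- function(dataset) {
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    rows <- dataset[dataset$ID == id, , drop = FALSE]
    doses <- rows[rows$EVID == 1L, c("TIME", "AMT")]
    names(doses) <- c("time", "amount_iu")
    obs <- rows[rows$EVID == 0L, , drop = FALSE]
    times <- sort(unique(obs$TIME))
    list(id = id,
         doses = doses,
         times = times,
         time_idx = match(obs$TIME, times),
         analyte = obs$DVID,
         conc = obs$DV,
         blq = obs$BLQ == 1L,
         lloq = obs$LLOQ)
  })
}

# predictions (nmol/L) for one split_subjects() element under params p
subject_pred <- function(sub, p) {
  states <- simulate_states(p, sub$doses, sub$times)
  vols <- obs_volumes(p)
  conc <- states[OBS_STATE_INDEX[sub$analyte] +
                 6L * (sub$time_idx - 1L)]
  conc / vols[sub$analyte]
}
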