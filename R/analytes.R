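#' Analytes of the vitamin D3 metabolic cascade
#'
#' The model tracks the parent compound cholecalciferol (`VITD3`) and its
#' three sequential metabolites: 25-hydroxyvitamin D3 (`D25`, the major
#' circulating form), 1,25-dihydroxyvitamin D3 (`D125`, the active hormone)
#' and 24,25-dihydroxyvitamin D3 (`D2425`, the catabolic product).
#' `analyte_table()` returns one row per analyte with its molar mass and the
#' default assay lower limit of quantification (LLOQ).
#'
#' @return A data.frame with columns `code`, `molar_mass` (g/mol),
#'   `lloq_ngml` (ng/mL) and `lloq_nmoll` (nmol/L).
#' @examples
#' analyte_table()
#' @export
analyte_table <- function() {
  tab <- data.frame(
    code       = ANALYTES,
    molar_mass = c(384.64, 400.64, 416.64, 416.64),
    lloq_ngml  = c(0.1, 1.0, 0.01, 0.1),
    stringsAsFactors = FALSE
  )
  tab$lloq_nmoll <- tab$lloq_ngml * 1000 / tab$molar_mass
  tab
}

#' @rdname analyte_table
#' @format `ANALYTES` is the character vector of the four analyte codes, in
#'   cascade order.
#' @export
ANALYTES <- c("VITD3", "D25", "D125", "D2425")

.analyte_molar_mass <- c(VITD3 = 384.64, D25 = 400.64, D125 = 416.64,
                         D2425 = 416.64)

check_analyte <- function(analyte) {
  analyte <- as.character(analyte)
  bad <- setdiff(unique(analyte), ANALYTES)
  if (length(bad) > 0L) {
    stop("unknown analyte(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(ANALYTES, collapse = ", "), ")",
         call. = FALSE)
  }
  analyte
}

#' Unit conversions
#'
#' All internal computation is carried out in molar units (nmol, nmol/L, h);
#' mass units (ng/mL) and international units (I.U.) appear only at the
#' input/output boundary. One international unit of cholecalciferol is
#' 0.025 ug (40 I.U. = 1 ug), so a dose in I.U. converts to nmol through the
#' parent molar mass of 384.64 g/mol.
#'
#' @param amount_iu Dose amount in international units (scalar or vector,
#'   non-negative).
#' @return `iu_to_nmol()`: the dose in nmol of cholecalciferol.
#' @examples
#' iu_to_nmol(5000)          # the study dose: 325 nmol
#' ngml_to_nmoll(30, "D25")  # the repletion target: 74.88 nmol/L
#' @export
iu_to_nmol <- function(amount_iu) {
  if (any(amount_iu < 0)) stop("dose amount must be non-negative", call. = FALSE)
  # I.U. -> ug (40 I.U./ug) -> nmol via 384.64 g/mol (ug/(g/mol) = nmol/1000)
  amount_iu / 40 / 384.64 * 1000
}

#' @rdname iu_to_nmol
#' @param value Concentration value(s), non-negative.
#' @param analyte Analyte code(s), recycled against `value`.
#' @return `ngml_to_nmoll()` / `nmoll_to_ngml()`: the converted
#'   concentration(s); the two are exact inverses.
#' @export
ngml_to_nmoll <- function(value, analyte) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  unname(value * 1000 / .analyte_molar_mass[check_analyte(analyte)])
}

#' @rdname iu_to_nmol
#' @export
nmoll_to_ngml <- function(value, analyte) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  unname(value * .analyte_molar_mass[check_analyte(analyte)] / 1000)
}
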