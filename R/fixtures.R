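# Published 2018 United States inventories and burden table, shipped as
# plain-text fixtures under extdata/ and loaded through the package's own
# readers.

published_chemicals <- c("BPA", "DEHP", "BBP", "DBP", "PFOA", "PFOS", "PBDE47")

#' Load a published chemical use inventory
#'
#' Reads one of the shipped inventory fixtures: the classified use-share
#' tables for BPA, DEHP, BBP, DBP (tons/y), PFOA (percent of
#' APFO/PFOA-attributed emissions), PFOS (metric tons), and PBDE-47. The PFOA
#' inventory stores the source's rescaled emissions column, whose printed
#' percentages sum to 99.9; a 0.1% synthetic residual row classified NONE
#' restores the exact-100 total so normalization reproduces the source's
#' arithmetic. `"PFOA_EMISSIONS"` loads the alternative raw emissions column
#' (57/10/5, percent of all PFCA-related emissions) instead.
#'
#' @param chemical One of `"BPA"`, `"DEHP"`, `"BBP"`, `"DBP"`, `"PFOA"`,
#'   `"PFOS"`, `"PBDE47"`, `"PFOA_EMISSIONS"`.
#' @return A validated `use_profile`.
#' @examples
#' compute_prf(published_profile("BPA"))  # 97.5% (96.25% - 98.75%)
#' @export
published_profile <- function(chemical = c("BPA", "DEHP", "BBP", "DBP", "PFOA",
                                       "PFOS", "PBDE47", "PFOA_EMISSIONS")) {
  chemical <- match.arg(chemical)
  file <- system.file("extdata", paste0(tolower(chemical), ".csv"),
                      package = "plastattr", mustWork = TRUE)
  id <- if (chemical == "PFOA_EMISSIONS") "PFOA" else chemical
  read_profile(file, format = "csv", chemical_id = id)
}

#' Load all seven published inventories
#'
#' @return Named list of `use_profile` objects for the seven chemicals with
#'   separately derived PRFs.
#' @export
published_profiles <- function() {
  out <- lapply(published_chemicals, published_profile)
  names(out) <- published_chemicals
  out
}

#' PRF triples for all published inventories
#'
#' Convenience wrapper: [compute_prf()] over [published_profiles()].
#'
#' @param imputation A [partial_imputation()].
#' @return Named list of [prf_triple()] objects keyed by chemical id.
#' @export
published_prfs <- function(imputation = partial_imputation()) {
  lapply(published_profiles(), compute_prf, imputation = imputation)
}

#' Load the published 2018 disease-burden table
#'
#' One row per (chemical class, exposure chemical, life stage, outcome) with
#' the cost of illness across exposure routes in billions of 2018 USD. The
#' source prints central cost estimates only, so low and high cost bounds
#' default to the base value and fixture sensitivity ranges reflect PRF
#' uncertainty alone.
#'
#' @return A [burden_table()] with 22 rows.
#' @export
published_burden <- function() {
  read_burden(system.file("extdata", "burden_2018.csv",
                          package = "plastattr", mustWork = TRUE))
}

#' Published class-level attributable costs
#'
#' The four chemical-class attributable cost triples as printed in the source
#' burden table (billions of 2018 USD), useful as inputs for reproducing the
#' grand total, which the source computes from its printed class subtotals.
#'
#' @return Data frame with columns `chemical_class`, `cost_base`, `cost_low`,
#'   `cost_high`.
#' @export
published_class_totals <- function() {
  data.frame(
    chemical_class = c("PBDE", "PHTHALATE", "BPA", "PFAS"),
    cost_base = c(159, 66.7, 1.02, 22.4),
    cost_low = c(157, 64.7, 1.00, 3.85),
    cost_high = c(161, 67.3, 1.03, 60.1),
    stringsAsFactors = FALSE)
}
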