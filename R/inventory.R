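#' Plasticity classification labels
#'
#' Every use category in an inventory is classified as fully plastic-related
#' (`FULL`), partially plastic-related (`PARTIAL`), or not plastic-related
#' (`NONE`). Classification is input data taken from the source literature,
#' never computed.
#' @export
PLASTICITY_LEVELS <- c("FULL", "PARTIAL", "NONE")

#' Bases on which use shares are expressed
#'
#' `PERCENT` for shares printed as percent of total use, `MASS` for tons or
#' metric tons per year, `EMISSIONS_PERCENT` for percent of emissions used as
#' a use proxy. All shares of one profile must share a basis; normalization
#' divides by the column total in every case.
#' @export
SHARE_BASES <- c("PERCENT", "MASS", "EMISSIONS_PERCENT")

#' Construct a chemical use profile
#'
#' A use profile is the inventory of one chemical's applications: one row per
#' use category with a nonnegative share (percent of use, mass, or percent of
#' emissions), a plasticity classification, and an optional known
#' plastic-related sub-fraction for partially plastic-related rows.
#'
#' @param chemical_id Short identifier, e.g. `"BPA"`, `"DBP"`, `"PFOS"`.
#' @param category Character vector of use-category labels (free text).
#' @param share_value Nonnegative numeric vector of shares, same length.
#' @param basis One of [SHARE_BASES]; a single basis for the whole profile.
#' @param plasticity Character vector of [PLASTICITY_LEVELS] labels.
#' @param partial_fraction_override Optional numeric vector on \[0, 1\]; may
#'   only be non-`NA` where `plasticity == "PARTIAL"`, and fixes that row's
#'   plastic-related sub-fraction in base, low, and high alike.
#' @param note Optional character vector of per-row provenance notes.
#' @param source_note Free-text provenance for the whole profile.
#' @return An object of class `use_profile`: a list with elements
#'   `chemical_id`, `basis`, `source_note`, and `shares` (a data frame with
#'   columns `category`, `share_value`, `plasticity`,
#'   `partial_fraction_override`, `note`).
#' @examples
#' use_profile("BPA",
#'   category    = c("Polycarbonate plastic", "Epoxy resins", "Other"),
#'   share_value = c(65, 30, 5),
#'   basis       = "PERCENT",
#'   plasticity  = c("FULL", "FULL", "PARTIAL"))
#' @export
use_profile <- function(chemical_id, category, share_value, basis,
                        plasticity, partial_fraction_override = NULL,
                        note = NULL, source_note = "") {
  n <- length(share_value)
  if (is.null(partial_fraction_override)) {
    partial_fraction_override <- rep(NA_real_, n)
  }
  if (is.null(note)) note <- rep("", n)
  shares <- data.frame(
    category = as.character(category),
    share_value = as.numeric(share_value),
    plasticity = as.character(plasticity),
    partial_fraction_override = as.numeric(partial_fraction_override),
    note = as.character(note),
    stringsAsFactors = FALSE
  )
  x <- structure(
    list(chemical_id = as.character(chemical_id),
         basis = as.character(basis),
         source_note = as.character(source_note),
         shares = shares),
    class = "use_profile"
  )
  validate_profile(x)
}

#' Validate a use profile
#'
#' Checks the structural invariants: nonempty shares, a single recognised
#' basis, recognised plasticity labels, nonnegative shares, and overrides only
#' on PARTIAL rows and only on \[0, 1\].
#'
#' @param x A `use_profile`.
#' @return `x`, invisibly unchanged, or an error naming the offending row and
#'   field.
#' @export
validate_profile <- function(x) {
  stopifnot(inherits(x, "use_profile"))
  s <- x$shares
  if (nrow(s) == 0L) {
    stop("profile '", x$chemical_id, "': empty inventory (no use shares)")
  }
  if (length(x$basis) != 1L || !x$basis %in% SHARE_BASES) {
    stop("profile '", x$chemical_id, "': basis must be one of ",
         paste(SHARE_BASES, collapse = ", "))
  }
  bad <- which(!s$plasticity %in% PLASTICITY_LEVELS)
  if (length(bad)) {
    stop("row ", bad[1], ", field 'plasticity': unknown label '",
         s$plasticity[bad[1]], "'")
  }
  bad <- which(is.na(s$share_value) | s$share_value < 0)
  if (length(bad)) {
    stop("row ", bad[1], ", field 'share_value': must be a nonnegative ",
         "number, got '", s$share_value[bad[1]], "'")
  }
  ov <- s$partial_fraction_override
  bad <- which(!is.na(ov) & s$plasticity != "PARTIAL")
  if (length(bad)) {
    stop("row ", bad[1], ", field 'partial_fraction_override': only allowed ",
         "on PARTIAL rows")
  }
  bad <- which(!is.na(ov) & (ov < 0 | ov > 1))
  if (length(bad)) {
    stop("row ", bad[1], ", field 'partial_fraction_override': must lie in ",
         "[0, 1]")
  }
  invisible(x)
}

#' Normalize use shares to fractions
#'
#' Divides each share by the column total so fractions sum to one, preserving
#' row order. Mass and emissions bases are always normalized by their total;
#' percent shares are rescaled too, with a warning when the printed percents
#' miss 100 by more than 1 (sources sometimes print columns that do not total
#' exactly 100).
#'
#' @param profile A validated `use_profile`.
#' @return Numeric vector of fractions, one per row, summing to 1.
#' @examples
#' dbp <- use_profile("DBP", letters[1:5], c(5900, 160, 1890, 80, 250),
#'                    "MASS", c("FULL", "FULL", "PARTIAL", "PARTIAL", "NONE"))
#' round(normalize_shares(dbp) * 100, 2)  # 71.26 1.93 22.83 0.97 3.02
#' @export
normalize_shares <- function(profile) {
  validate_profile(profile)
  v <- profile$shares$share_value
  total <- sum(v)
  if (total <= 0) {
    stop("profile '", profile$chemical_id,
         "': all shares are zero (empty inventory)")
  }
  if (profile$basis == "PERCENT" && abs(total - 100) > 1) {
    warning("profile '", profile$chemical_id, "': percent shares sum to ",
            format(total), ", rescaling to 100")
  }
  v / total
}

# ---- I/O ------------------------------------------------------------------

profile_columns <- c("category", "share_value", "basis", "plasticity",
                     "partial_fraction_override", "note")

#' Read a chemical use profile from CSV or JSON
#'
#' The CSV layout has one row per use category and columns
#' `category,share_value,basis,plasticity,partial_fraction_override,note`
#' (header required, UTF-8). The JSON layout is an object with fields
#' `chemical_id`, `source_note`, and `shares` (an array of row objects with
#' the same field names as the CSV columns).
#'
#' @param path File path; format is inferred from the extension unless
#'   `format` is given.
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @param chemical_id Identifier for CSV files (which carry no id column);
#'   defaults to the file name without extension, upper-cased.
#' @return A validated `use_profile` with row order preserved.
#' @seealso [write_profile()]
#' @export
read_profile <- function(path, format = c("auto", "csv", "json"),
                         chemical_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(obj$chemical_id) || is.null(obj$shares)) {
      stop("JSON profile must carry 'chemical_id' and 'shares' fields")
    }
    s <- as.data.frame(obj$shares, stringsAsFactors = FALSE)
    return(profile_from_rows(s, chemical_id = obj$chemical_id,
                             source_note = obj$source_note %||% ""))
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e))
  )
  if (nrow(raw) == 0L) stop("'", path, "': empty inventory file")
  if (is.null(chemical_id)) {
    chemical_id <- toupper(sub("\\.[^.]*$", "", basename(path)))
  }
  profile_from_rows(raw, chemical_id = chemical_id, source_note = "")
}

profile_from_rows <- function(rows, chemical_id, source_note = "") {
  missing <- setdiff(setdiff(profile_columns, "note"), names(rows))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(rows$note)) rows$note <- ""
  basis <- unique(rows$basis)
  if (length(basis) != 1L) {
    stop("row ", which(rows$basis != basis[1])[1],
         ", field 'basis': mixed bases (", paste(basis, collapse = ", "),
         ") in one profile")
  }
  sv <- suppressWarnings(as.numeric(rows$share_value))
  bad <- which(is.na(sv) & nzchar(trimws(rows$share_value)))
  if (length(bad)) {
    stop("row ", bad[1], ", field 'share_value': not a number: '",
         rows$share_value[bad[1]], "'")
  }
  ov <- rows$partial_fraction_override
  ov[is.na(ov) | !nzchar(trimws(as.character(ov)))] <- NA
  use_profile(chemical_id,
              category = rows$category,
              share_value = sv,
              basis = basis,
              plasticity = trimws(rows$plasticity),
              partial_fraction_override = suppressWarnings(as.numeric(ov)),
              note = rows$note,
              source_note = source_note)
}

#' Write a chemical use profile to CSV or JSON
#'
#' Inverse of [read_profile()]: the round trip reproduces the profile
#' field-by-field (CSV does not carry `chemical_id` or `source_note`; pass
#' `chemical_id` back to [read_profile()] when exactness matters, or use
#' JSON).
#'
#' @param profile A `use_profile`.
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("auto", "csv", "json")) {
  validate_profile(profile)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- list(chemical_id = profile$chemical_id,
                source_note = profile$source_note,
                shares = cbind(profile$shares[, c("category", "share_value")],
                               basis = profile$basis,
                               profile$shares[, c("plasticity",
                                                  "partial_fraction_override",
                                                  "note")]))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  } else {
    out <- cbind(profile$shares[, c("category", "share_value")],
                 basis = profile$basis,
                 profile$shares[, c("plasticity", "partial_fraction_override",
                                    "note")])
    # 17 significant digits make the numeric round trip bit-exact
    fmt17 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    out$share_value <- fmt17(out$share_value)
    out$partial_fraction_override <- fmt17(out$partial_fraction_override)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @export
print.use_profile <- function(x, ...) {
  cat("Chemical use profile:", x$chemical_id,
      sprintf("(%d categories, basis %s)\n", nrow(x$shares), x$basis))
  f <- normalize_shares(x)
  s <- x$shares
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-40s %10s  %6.2f%%  %s\n",
                s$category[i], format(s$share_value[i]), 100 * f[i],
                s$plasticity[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
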