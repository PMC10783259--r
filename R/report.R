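#' Round a percentage half-up
#'
#' Rounds with halves away from zero (97.375 -> 97.38, 99.125 -> 99.13), the
#' convention of the source inventory tables, unlike base [round()], which is
#' half-even. A relative guard of 1e-12 absorbs binary representation error
#' on exact halves.
#'
#' @param x Nonnegative numeric vector (already on the percent scale).
#' @param digits Decimal places to keep.
#' @return `x` rounded.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  z <- x * m
  floor(z + 0.5 + abs(z) * 1e-12) / m
}

#' Format a fraction as a percentage
#'
#' Multiplies by 100, rounds half-up to at most `decimals` places, and trims
#' trailing zeros, e.g. `0.975 -> "97.5%"`, `1 -> "100%"`, `0.9825 ->
#' "98.25%"`.
#'
#' @param x Fraction(s) on \[0, 1\].
#' @param decimals Maximum decimal places (default 2).
#' @return Character vector.
#' @export
format_percent <- function(x, decimals = 2) {
  v <- round_half_up(100 * x, decimals)
  s <- sprintf("%.*f", decimals, v)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  paste0(s, "%")
}

#' Format a cost in billions of USD
#'
#' Rounds half-even to `sig_figs` significant figures (via [signif()]) and
#' renders with a unit word; values below $0.1 billion are shown in millions.
#' Trailing significant zeros are kept (`0.035 -> "$35.0 million"`).
#'
#' @param value Nonnegative cost in billions of USD.
#' @param sig_figs Significant figures (default 3).
#' @return Display string such as `"$1.02 billion"`.
#' @examples
#' format_cost(1.0192)   # "$1.02 billion"
#' format_cost(22.413)   # "$22.4 billion"
#' format_cost(0.035)    # "$35.0 million"
#' @export
format_cost <- function(value, sig_figs = 3) {
  if (length(value) != 1L || is.na(value)) stop("value must be a single number")
  if (value < 0) stop("cost cannot be negative")
  if (value == 0) return("$0.00 billion")
  unit <- "billion"
  v <- value
  if (v < 0.1) {
    v <- v * 1000
    unit <- "million"
  }
  v <- signif(v, sig_figs)
  s <- formatC(v, digits = sig_figs, format = "fg", flag = "#")
  s <- sub("\\.$", "", s)
  paste0("$", s, " ", unit)
}

format_cost_triple <- function(base, low, high, sig_figs = 3) {
  sprintf("%s (%s - %s)", format_cost(base, sig_figs),
          format_cost(low, sig_figs), format_cost(high, sig_figs))
}

# Display frame shared by the CSV and markdown renderings: outcome rows in
# input order, each class subtotal after its class, grand total last.
display_frame <- function(table, sig_figs = 3, percent_decimals = 2) {
  stopifnot(inherits(table, "attributable_table"))
  o <- table$outcomes
  ct <- table$class_totals
  rows <- list()
  for (cl in ct$chemical_class) {
    sub <- o[o$chemical_class == cl, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- data.frame(
        row_type = "outcome",
        chemical_class = cl,
        exposure_chemical = sub$exposure_chemical[i],
        life_stage = sub$life_stage[i],
        outcome = sub$outcome[i],
        applied_prf = sprintf("%s (%s-%s)",
                              format_percent(sub$prf_base[i], percent_decimals),
                              format_percent(sub$prf_low[i], percent_decimals),
                              format_percent(sub$prf_high[i], percent_decimals)),
        attributable_cost = format_cost_triple(sub$cost_base[i],
                                               sub$cost_low[i],
                                               sub$cost_high[i], sig_figs),
        stringsAsFactors = FALSE)
    }
    k <- which(ct$chemical_class == cl)
    rows[[length(rows) + 1L]] <- data.frame(
      row_type = "class_total", chemical_class = cl,
      exposure_chemical = "All", life_stage = "All", outcome = "All",
      applied_prf = "",
      attributable_cost = format_cost_triple(ct$cost_base[k], ct$cost_low[k],
                                             ct$cost_high[k], sig_figs),
      stringsAsFactors = FALSE)
  }
  g <- table$grand_total
  rows[[length(rows) + 1L]] <- data.frame(
    row_type = "grand_total", chemical_class = "All",
    exposure_chemical = "All", life_stage = "All", outcome = "All",
    applied_prf = "",
    attributable_cost = format_cost_triple(g[["base"]], g[["low"]],
                                           g[["high"]], sig_figs),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Render an attributable table
#'
#' Formatting is presentation-only: the JSON rendering carries the unrounded
#' table (re-parsing it with [parse_table()] reproduces every value) next to
#' the rounded display rows, while CSV and markdown carry the same rounded
#' display values.
#'
#' @param table An [aggregate_results()] table.
#' @param format `"markdown"`, `"csv"`, or `"json"`.
#' @param sig_figs Significant figures for costs (default 3).
#' @param percent_decimals Maximum decimals for PRF percents (default 2).
#' @param path Optional file path; when given the rendering is also written
#'   there.
#' @return The rendering as a single character string, invisibly when `path`
#'   is given.
#' @export
render_table <- function(table, format = c("markdown", "csv", "json"),
                         sig_figs = 3, percent_decimals = 2, path = NULL) {
  format <- match.arg(format)
  disp <- display_frame(table, sig_figs, percent_decimals)
  out <- switch(format,
    json = as.character(jsonlite::toJSON(
      list(outcomes = table$outcomes,
           class_totals = table$class_totals,
           grand_total = as.list(table$grand_total),
           display = disp),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
      pretty = TRUE)),
    csv = {
      con <- textConnection("csv_out", "w", local = TRUE)
      utils::write.csv(disp, con, row.names = FALSE)
      close(con)
      paste0(paste(csv_out, collapse = "\n"), "\n")
    },
    markdown = {
      cols <- c("chemical_class", "exposure_chemical", "life_stage",
                "outcome", "applied_prf", "attributable_cost")
      header <- c("Class", "Chemical", "Life stage", "Outcome", "Applied PRF",
                  "Attributable cost")
      fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "),
                                        " |")
      lines <- c(fmt_row(header),
                 fmt_row(rep("---", length(header))),
                 vapply(seq_len(nrow(disp)), function(i) {
                   cells <- unlist(disp[i, cols], use.names = FALSE)
                   if (disp$row_type[i] != "outcome") {
                     cells <- paste0("**", cells, "**")
                   }
                   fmt_row(cells)
                 }, character(1)))
      paste0(paste(lines, collapse = "\n"), "\n")
    })
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

#' Re-parse a JSON report into an attributable table
#'
#' Inverse of `render_table(..., format = "json")` for the unrounded payload.
#'
#' @param json JSON string or file path as accepted by [jsonlite::fromJSON()].
#' @return An `attributable_table` equal (to numerical round-trip precision)
#'   to the rendered one.
#' @export
parse_table <- function(json) {
  obj <- jsonlite::fromJSON(json)
  outcomes <- as.data.frame(obj$outcomes, stringsAsFactors = FALSE)
  for (col in c("cases_base", "cases_low", "cases_high")) {
    if (is.null(outcomes[[col]])) outcomes[[col]] <- NA_real_
    outcomes[[col]] <- as.numeric(outcomes[[col]])
  }
  structure(list(outcomes = outcomes,
                 class_totals = as.data.frame(obj$class_totals,
                                              stringsAsFactors = FALSE),
                 grand_total = unlist(obj$grand_total)),
            class = "attributable_table")
}

#' @export
print.attributable_table <- function(x, ...) {
  cat(render_table(x, "markdown"))
  invisible(x)
}

#' @export
summary.attributable_table <- function(object, ...) {
  g <- object$grand_total
  cat("Plastic-attributable cost:",
      format_cost_triple(g[["base"]], g[["low"]], g[["high"]]), "\n")
  cat("Across", nrow(object$outcomes), "outcome(s) in",
      nrow(object$class_totals), "chemical class(es):\n")
  ct <- object$class_totals
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-12s %s\n", ct$chemical_class[i],
                format_cost_triple(ct$cost_base[i], ct$cost_low[i],
                                   ct$cost_high[i])))
  }
  invisible(object)
}
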