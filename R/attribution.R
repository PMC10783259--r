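#' Construct a disease-burden table
#'
#' One row per (chemical class, exposure chemical, life stage, outcome) with a
#' cost-of-illness triple in billions of 2018 USD and an optional case-count
#' triple. Burden estimates come from the primary cost studies; this package
#' only multiplies them by plastic-related fractions.
#'
#' Missing `cost_low`/`cost_high` (common when a source prints only central
#' estimates) default to `cost_base`, so sensitivity ranges then reflect PRF
#' uncertainty alone.
#'
#' @param df Data frame with columns `chemical_class`, `exposure_chemical`,
#'   `life_stage`, `outcome`, `cost_base` and optionally `cost_low`,
#'   `cost_high`, `cases_base`, `cases_low`, `cases_high`.
#' @return The data frame, validated, with all ten columns and class
#'   `burden_table`.
#' @export
burden_table <- function(df) {
  req <- c("chemical_class", "exposure_chemical", "life_stage", "outcome",
           "cost_base")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("burden table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("burden table is empty")
  for (col in c("cost_low", "cost_high")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
    df[[col]] <- ifelse(is.na(df[[col]]), df$cost_base, df[[col]])
  }
  for (col in c("cases_base", "cases_low", "cases_high")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  bad <- which(df$cost_base < 0 | df$cost_low < 0 | df$cost_high < 0)
  if (length(bad)) stop("row ", bad[1], ": negative cost")
  bad <- which(!(df$cost_low <= df$cost_base & df$cost_base <= df$cost_high))
  if (length(bad)) {
    stop("row ", bad[1], ": costs must satisfy low <= base <= high")
  }
  df <- df[, c(req[1:4], "cost_base", "cost_low", "cost_high",
               "cases_base", "cases_low", "cases_high")]
  class(df) <- c("burden_table", "data.frame")
  df
}

#' Read a disease-burden table from CSV
#'
#' Columns `chemical_class,exposure_chemical,life_stage,outcome,cost_base,
#' cost_low,cost_high,cases_base,cases_low,cases_high`; costs in billions of
#' USD; empty cost bounds default to the base value.
#'
#' @param path CSV file path.
#' @return A [burden_table()].
#' @export
read_burden <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  burden_table(df)
}

#' Construct an attribution rule
#'
#' A rule maps burden rows, selected by chemical class and outcome (either may
#' be the wildcard `"*"`), to the chemical whose PRF is applied in the base
#' case and to the set of chemicals whose low/high bounds form the
#' sensitivity envelope. A `prf_override` triple replaces the lookup entirely
#' (used where the source fixes the applied PRF directly).
#'
#' @param chemical_class Class selector or `"*"`.
#' @param outcome Outcome selector or `"*"`.
#' @param base_prf_chemical Chemical id whose base PRF is applied; `NULL`
#'   means "use the row's own `exposure_chemical`" (the catch-all default).
#' @param envelope_prf_chemicals Chemical ids whose low/high components bound
#'   the sensitivity envelope; defaults to the base chemical alone.
#' @param prf_override Optional [prf_triple()] applied verbatim.
#' @return An object of class `attribution_rule`.
#' @export
attribution_rule <- function(chemical_class = "*", outcome = "*",
                             base_prf_chemical = NULL,
                             envelope_prf_chemicals = base_prf_chemical,
                             prf_override = NULL) {
  if (!is.null(prf_override)) stopifnot(inherits(prf_override, "prf"))
  structure(list(chemical_class = chemical_class,
                 outcome = outcome,
                 base_prf_chemical = base_prf_chemical,
                 envelope_prf_chemicals = envelope_prf_chemicals,
                 prf_override = prf_override),
            class = "attribution_rule")
}

#' Default attribution rule set
#'
#' The shipped mapping from burden rows to PRFs:
#' \itemize{
#'   \item PBDE rows use the PBDE-47 PRF;
#'   \item phthalate rows use the DEHP PRF, except male infertility, which
#'     carries the fixed override triple (1.00, 0.71, 1.00) as applied in the
#'     source burden table;
#'   \item BPA rows use the BPA PRF;
#'   \item PFAS rows use PFOA in the base case with the sensitivity envelope
#'     spanning PFOA and PFOS;
#'   \item a catch-all applies the row's own exposure chemical.
#' }
#' @return List of [attribution_rule()] objects, most specific first.
#' @export
default_rules <- function() {
  list(
    attribution_rule("PHTHALATE", "Male infertility",
                     base_prf_chemical = "DBP",
                     prf_override = prf_triple("BBP_DBP", 1.00, 0.71, 1.00)),
    attribution_rule("PBDE", base_prf_chemical = "PBDE47"),
    attribution_rule("PHTHALATE", base_prf_chemical = "DEHP"),
    attribution_rule("BPA", base_prf_chemical = "BPA"),
    attribution_rule("PFAS", base_prf_chemical = "PFOA",
                     envelope_prf_chemicals = c("PFOA", "PFOS")),
    attribution_rule("*", "*")
  )
}

#' Read attribution rules from JSON
#'
#' A JSON array of objects with fields `chemical_class`, `outcome`,
#' `base_prf_chemical`, `envelope_prf_chemicals`, and optional `prf_override`
#' (`{base, low, high}`).
#'
#' @param path JSON file path.
#' @return List of [attribution_rule()] objects.
#' @export
read_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    ov <- NULL
    if (!is.null(r$prf_override)) {
      ov <- prf_triple(r$base_prf_chemical %||% "override",
                       r$prf_override$base, r$prf_override$low,
                       r$prf_override$high)
    }
    attribution_rule(r$chemical_class %||% "*", r$outcome %||% "*",
                     base_prf_chemical = r$base_prf_chemical,
                     envelope_prf_chemicals =
                       unlist(r$envelope_prf_chemicals) %||%
                       r$base_prf_chemical,
                     prf_override = ov)
  })
}

rule_specificity <- function(rule) {
  2L * (rule$chemical_class != "*") + 1L * (rule$outcome != "*")
}

match_rule <- function(row, rules) {
  ok <- vapply(rules, function(r) {
    (r$chemical_class == "*" || r$chemical_class == row$chemical_class) &&
      (r$outcome == "*" || r$outcome == row$outcome)
  }, logical(1))
  if (!any(ok)) {
    stop("no attribution rule matches row (", row$chemical_class, ", ",
         row$outcome, "); add a catch-all rule")
  }
  cand <- which(ok)
  cand[which.max(vapply(rules[cand], rule_specificity, integer(1)))]
}

#' Resolve the PRF applied to one burden row
#'
#' Finds the most specific matching rule (ties broken by rule order), then
#' builds the applied PRF: the base component from the rule's base chemical,
#' the low bound as the minimum low across the envelope chemicals, and the
#' high bound as the maximum high across them. A rule override returns its
#' triple verbatim.
#'
#' @param row One burden row (a list or one-row data frame with
#'   `chemical_class`, `outcome`, `exposure_chemical`).
#' @param rules List of [attribution_rule()]; see [default_rules()].
#' @param prfs Named list of [prf_triple()] objects keyed by chemical id.
#' @return The applied [prf_triple()].
#' @examples
#' prfs <- list(PFOA = prf_triple("PFOA", 0.93, 0.8955, 0.9645),
#'              PFOS = prf_triple("PFOS", 0.317, 0.158, 0.475))
#' row <- list(chemical_class = "PFAS", outcome = "Low birth weight",
#'             exposure_chemical = "PFOA")
#' resolve_prf(row, default_rules(), prfs)  # 93% (15.8% - 96.45%)
#' @export
resolve_prf <- function(row, rules, prfs) {
  rule <- rules[[match_rule(row, rules)]]
  if (!is.null(rule$prf_override)) return(rule$prf_override)
  base_chem <- rule$base_prf_chemical %||% row$exposure_chemical
  envelope <- rule$envelope_prf_chemicals %||% base_chem
  missing <- setdiff(c(base_chem, envelope), names(prfs))
  if (length(missing)) {
    stop("no PRF available for chemical(s): ", paste(missing, collapse = ", "))
  }
  low <- min(vapply(prfs[envelope], function(p) p$low, numeric(1)))
  high <- max(vapply(prfs[envelope], function(p) p$high, numeric(1)))
  prf_triple(base_chem, base = prfs[[base_chem]]$base, low = low, high = high)
}

#' Attribute one burden row to plastics
#'
#' Multiplies the cost (and case) triple by the PRF triple componentwise,
#' under the proportionality assumption that disease burden scales with
#' exposure. The multiway sensitivity convention pairs the low PRF with the
#' low cost bound and the high PRF with the high cost bound; there are no
#' cross terms.
#'
#' @param row One [burden_table()] row (list or one-row data frame).
#' @param prf The applied [prf_triple()], e.g. from [resolve_prf()].
#' @return A list of class `attributable_result` with the row's identity
#'   fields, `applied_prf`, `attributable_cost = c(base, low, high)` in
#'   billions USD, and `attributable_cases` (or `NULL` when the row has no
#'   case counts).
#' @examples
#' row <- list(chemical_class = "BPA", exposure_chemical = "BPA",
#'             life_stage = "Prenatal", outcome = "Childhood obesity",
#'             cost_base = 1.04, cost_low = 1.04, cost_high = 1.04)
#' attribute_row(row, prf_triple("BPA", 0.98, 0.96, 0.99))
#' @export
attribute_row <- function(row, prf) {
  stopifnot(inherits(prf, "prf"))
  cost_low <- row$cost_low %||% row$cost_base
  cost_high <- row$cost_high %||% row$cost_base
  if (is.na(cost_low)) cost_low <- row$cost_base
  if (is.na(cost_high)) cost_high <- row$cost_base
  cost <- c(base = row$cost_base * prf$base,
            low = cost_low * prf$low,
            high = cost_high * prf$high)
  cases <- NULL
  if (!is.null(row$cases_base) && !is.na(row$cases_base)) {
    cl <- row$cases_low %||% NA_real_
    ch <- row$cases_high %||% NA_real_
    if (is.na(cl)) cl <- row$cases_base
    if (is.na(ch)) ch <- row$cases_base
    cases <- c(base = row$cases_base * prf$base,
               low = cl * prf$low,
               high = ch * prf$high)
  }
  structure(list(chemical_class = row$chemical_class,
                 exposure_chemical = row$exposure_chemical,
                 life_stage = row$life_stage %||% "",
                 outcome = row$outcome %||% "",
                 applied_prf = prf,
                 attributable_cost = cost,
                 attributable_cases = cases),
            class = "attributable_result")
}

#' Aggregate attributable results to class and grand totals
#'
#' Sums attributable cost triples componentwise within each chemical class
#' and overall. Low and high totals are the sums of the row lows and highs,
#' the all-low / all-high convention of a multiway sensitivity analysis.
#'
#' @param results Nonempty list of [attribute_row()] results.
#' @return An object of class `attributable_table`: a list with `outcomes`
#'   (one data-frame row per result, input order preserved), `class_totals`
#'   (cost triples per chemical class, in first-appearance order), and
#'   `grand_total` (named numeric `c(base, low, high)` in billions USD).
#' @export
aggregate_results <- function(results) {
  if (length(results) == 0L) stop("no attributable results to aggregate")
  stopifnot(all(vapply(results, inherits, logical(1), "attributable_result")))
  outcomes <- do.call(rbind, lapply(results, function(r) {
    data.frame(chemical_class = r$chemical_class,
               exposure_chemical = r$exposure_chemical,
               life_stage = r$life_stage,
               outcome = r$outcome,
               prf_base = r$applied_prf$base,
               prf_low = r$applied_prf$low,
               prf_high = r$applied_prf$high,
               cost_base = r$attributable_cost[["base"]],
               cost_low = r$attributable_cost[["low"]],
               cost_high = r$attributable_cost[["high"]],
               cases_base = if (is.null(r$attributable_cases)) NA_real_
                            else r$attributable_cases[["base"]],
               cases_low = if (is.null(r$attributable_cases)) NA_real_
                           else r$attributable_cases[["low"]],
               cases_high = if (is.null(r$attributable_cases)) NA_real_
                            else r$attributable_cases[["high"]],
               stringsAsFactors = FALSE)
  }))
  classes <- unique(outcomes$chemical_class)
  class_totals <- do.call(rbind, lapply(classes, function(cl) {
    sub <- outcomes[outcomes$chemical_class == cl, , drop = FALSE]
    data.frame(chemical_class = cl,
               cost_base = sum(sub$cost_base),
               cost_low = sum(sub$cost_low),
               cost_high = sum(sub$cost_high),
               stringsAsFactors = FALSE)
  }))
  grand <- c(base = sum(class_totals$cost_base),
             low = sum(class_totals$cost_low),
             high = sum(class_totals$cost_high))
  structure(list(outcomes = outcomes, class_totals = class_totals,
                 grand_total = grand),
            class = "attributable_table")
}

#' Run the attribution pipeline on a burden table
#'
#' For each burden row, resolves the applied PRF through the rule set,
#' multiplies the cost (and case) triples by it, and aggregates to class and
#' grand totals.
#'
#' @param burden A [burden_table()].
#' @param prfs Named list of [prf_triple()] objects keyed by chemical id.
#' @param rules List of [attribution_rule()]; defaults to [default_rules()].
#' @param use_printed_prf_rounding If `TRUE`, each applied PRF component is
#'   rounded to the nearest whole percent (round-half-even) before
#'   multiplication, matching the precision at which the source burden table
#'   prints the PRFs it applies. Default `FALSE`: unrounded arithmetic.
#' @return An [aggregate_results()] table.
#' @export
attribute_burden <- function(burden, prfs, rules = default_rules(),
                             use_printed_prf_rounding = FALSE) {
  stopifnot(inherits(burden, "burden_table"))
  results <- lapply(seq_len(nrow(burden)), function(i) {
    row <- as.list(burden[i, , drop = FALSE])
    prf <- resolve_prf(row, rules, prfs)
    if (use_printed_prf_rounding) {
      prf <- prf_triple(prf$chemical_id,
                        base = round(prf$base, 2),
                        low = round(prf$low, 2),
                        high = round(prf$high, 2))
    }
    attribute_row(row, prf)
  })
  aggregate_results(results)
}
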