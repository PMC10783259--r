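#' Partial-use imputation fractions
#'
#' When a use category is only partly plastic-related and the plastic-related
#' part cannot be quantified from secondary sources, the base case assumes
#' half of the application is plastic-related, with 25% and 75% bounding the
#' sensitivity analysis.
#'
#' @param base,low,high Fractions on \[0, 1\] with `low <= base <= high`.
#' @return An object of class `partial_imputation`.
#' @export
partial_imputation <- function(base = 0.5, low = 0.25, high = 0.75) {
  x <- c(base = base, low = low, high = high)
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("imputation fractions must lie in [0, 1]")
  }
  if (!(low <= base && base <= high)) {
    stop("imputation fractions must satisfy low <= base <= high")
  }
  structure(as.list(x), class = "partial_imputation")
}

#' Plastic weight of one use category
#'
#' Maps a classification to its (base, low, high) plastic-related weight:
#' `FULL` uses weigh 1 in all three components and `NONE` uses weigh 0; a
#' `PARTIAL` use takes the imputation triple, unless the source quantifies
#' its plastic-related sub-fraction, in which case that override is used
#' identically in base, low, and high (bounds are varied only for
#' unquantifiable partial uses).
#'
#' @param plasticity One of [PLASTICITY_LEVELS].
#' @param override Optional fraction on \[0, 1\] for a PARTIAL row; `NA` to
#'   use the imputation.
#' @param imputation A [partial_imputation()].
#' @return Named numeric vector `c(base, low, high)`.
#' @examples
#' plastic_weight("PARTIAL")  # 0.50 0.25 0.75
#' @export
plastic_weight <- function(plasticity, override = NA_real_,
                           imputation = partial_imputation()) {
  stopifnot(inherits(imputation, "partial_imputation"),
            length(plasticity) == 1L)
  switch(plasticity,
    FULL = c(base = 1, low = 1, high = 1),
    NONE = c(base = 0, low = 0, high = 0),
    PARTIAL = if (!is.na(override)) {
      c(base = override, low = override, high = override)
    } else {
      c(base = imputation$base, low = imputation$low, high = imputation$high)
    },
    stop("unknown plasticity label '", plasticity, "'")
  )
}

#' Construct a PRF triple
#'
#' A plastic-related fraction (PRF) triple holds the base-case fraction of a
#' chemical's use (or emissions) attributable to plastic-related applications,
#' together with the low and high sensitivity bounds.
#'
#' @param chemical_id Identifier of the chemical the triple belongs to.
#' @param base,low,high Fractions on \[0, 1\] with `low <= base <= high`.
#' @return An object of class `prf`.
#' @export
prf_triple <- function(chemical_id, base, low, high) {
  v <- c(base, low, high)
  if (anyNA(v) || any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("PRF components must lie in [0, 1]")
  }
  if (!(low <= base + 1e-12 && base <= high + 1e-12)) {
    stop("PRF components must satisfy low <= base <= high")
  }
  structure(list(chemical_id = as.character(chemical_id),
                 base = min(max(base, 0), 1),
                 low = min(max(low, 0), 1),
                 high = min(max(high, 0), 1)),
            class = "prf")
}

#' Compute the plastic-related fraction of a chemical
#'
#' The PRF is the dot product of the normalized use shares with the per-row
#' plastic weights, computed separately for the base, low, and high weight
#' components:
#' \deqn{PRF_k = \sum_i f_i \, w_{i,k}, \qquad k \in \{base, low, high\}}
#' where \eqn{f_i} are the fractions from [normalize_shares()] and
#' \eqn{w_{i,k}} come from [plastic_weight()]. Values are kept unrounded;
#' rounding to a table's printed precision is a reporting concern (see
#' [format_percent()]).
#'
#' @param profile A validated `use_profile`.
#' @param imputation A [partial_imputation()]; configurable per run.
#' @return A [prf_triple()] for `profile$chemical_id`.
#' @examples
#' bpa <- use_profile("BPA", c("Polycarbonate", "Epoxy", "Other"),
#'                    c(65, 30, 5), "PERCENT", c("FULL", "FULL", "PARTIAL"))
#' compute_prf(bpa)  # 97.5% (96.25% - 98.75%)
#' @export
compute_prf <- function(profile, imputation = partial_imputation()) {
  f <- normalize_shares(profile)
  s <- profile$shares
  w <- vapply(seq_len(nrow(s)), function(i) {
    plastic_weight(s$plasticity[i], s$partial_fraction_override[i], imputation)
  }, numeric(3))          # 3 x n matrix: rows base, low, high
  v <- as.numeric(w %*% f)
  prf_triple(profile$chemical_id, base = v[1], low = v[2], high = v[3])
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("PRF %s: %s (%s - %s)\n", x$chemical_id,
              format_percent(x$base), format_percent(x$low),
              format_percent(x$high)))
  invisible(x)
}

#' @export
as.data.frame.prf <- function(x, ...) {
  data.frame(chemical_id = x$chemical_id, base = x$base, low = x$low,
             high = x$high, stringsAsFactors = FALSE)
}

#' @export
format.prf <- function(x, ...) {
  sprintf("%s (%s-%s)", format_percent(x$base), format_percent(x$low),
          format_percent(x$high))
}
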