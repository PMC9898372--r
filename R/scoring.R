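#' Replace missing dosages by their expectation
#'
#' Every missing genotype at variant `j` is replaced by the expected dosage
#' under Hardy–Weinberg proportions, twice the risk-allele frequency.  The
#' frequency comes from the panel (published summary statistics) by default;
#' set `from = "sample"` to use the observed sample allele frequency instead.
#'
#' @param dosage Individuals-by-variants dosage matrix (`NA` = missing).
#' @param panel Risk-oriented variant panel aligned to the columns.
#' @param from `"sumstats"` (panel `raf`, default) or `"sample"`.
#' @return The matrix with no missing entries; non-missing entries unchanged.
#' @export
impute_missing <- function(dosage, panel, from = c("sumstats", "sample")) {
  from <- match.arg(from)
  stopifnot(ncol(dosage) == nrow(panel))
  if (!anyNA(dosage)) {
    return(dosage)
  }
  raf <- if (from == "sumstats") {
    if (anyNA(panel$raf)) {
      abort(sprintf(
        "no risk-allele frequency for variant(s): %s",
        paste(head(panel$variant_id[is.na(panel$raf)], 5), collapse = ", ")
      ), class = "riskburden_validation_error")
    }
    panel$raf
  } else {
    colMeans(dosage, na.rm = TRUE) / 2
  }
  miss <- which(is.na(dosage), arr.ind = TRUE)
  dosage[miss] <- 2 * raf[miss[, 2]]
  dosage
}

#' Unweighted allele-count genetic risk score
#'
#' The number of risk alleles carried by each individual: the row sum of the
#' risk-oriented dosage matrix.  Missing entries must be imputed first (or
#' the check explicitly waived).
#'
#' @param dosage Dosage matrix with no missing entries.
#' @param allow_missing If `TRUE`, missing entries are summed over (i.e.
#'   treated as contributing nothing) instead of raising an error.
#' @return Numeric vector of counts, named by individual id.
#' @export
count_score <- function(dosage, allow_missing = FALSE) {
  if (anyNA(dosage) && !allow_missing) {
    abort("dosage matrix has missing entries: run impute_missing() first",
          class = "riskburden_validation_error")
  }
  rowSums(dosage, na.rm = allow_missing)
}

#' Log-odds-weighted genetic risk score
#'
#' Sum of risk-allele dosages weighted by the natural-log odds ratio of each
#' variant.  After risk orientation every weight is non-negative.
#'
#' @inheritParams count_score
#' @param panel Risk-oriented variant panel aligned to the columns.
#' @return Numeric vector of weighted scores, named by individual id.
#' @export
weighted_score <- function(dosage, panel, allow_missing = FALSE) {
  stopifnot(ncol(dosage) == nrow(panel))
  if (any(panel$odds_ratio <= 0)) {
    abort("odds ratio must be positive", class = "riskburden_validation_error")
  }
  if (anyNA(dosage) && !allow_missing) {
    abort("dosage matrix has missing entries: run impute_missing() first",
          class = "riskburden_validation_error")
  }
  w <- log(panel$odds_ratio)
  if (anyNA(dosage)) {
    d <- dosage
    d[is.na(d)] <- 0
    drop(d %*% w)
  } else {
    drop(dosage %*% w)
  }
}

#' Count and weighted scores in one table
#'
#' @inheritParams weighted_score
#' @param impute `"sumstats"` (default), `"sample"`, or `"off"` to skip
#'   imputation (an error if missing entries remain).
#' @return Tibble with `individual_id`, `count_score`, `weighted_score`.
#' @export
compute_scores <- function(dosage, panel,
                           impute = c("sumstats", "sample", "off")) {
  impute <- match.arg(impute)
  if (impute != "off") {
    dosage <- impute_missing(dosage, panel, from = impute)
  }
  tibble::tibble(
    individual_id = rownames(dosage) %||% as.character(seq_len(nrow(dosage))),
    count_score = count_score(dosage),
    weighted_score = weighted_score(dosage, panel)
  )
}

#' Round fractional allele counts for exact-count grouping
#'
#' Expectation imputation produces fractional counts; exact-count grouping
#' needs integers.  Rounds half to even (banker's rounding), the default used
#' before [group_by_count()].
#'
#' @param counts Numeric vector of (possibly fractional) allele counts.
#' @return Integer-valued numeric vector.
#' @export
round_counts <- function(counts) round(counts)
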