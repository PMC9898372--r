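#' Assign individuals to balanced score quantiles
#'
#' Partitions a cohort into `k` quantile strata (deciles by default) of a
#' score with stratum sizes differing by at most one.  Integer allele counts
#' produce massive ties at quantile boundaries; ties are broken by a seeded
#' random permutation within each tied value so the size guarantee holds and
#' the assignment is reproducible.  A `"value_complete"` mode keeps all
#' individuals sharing a score in one stratum (unequal sizes) for
#' sensitivity analysis.
#'
#' @param scores Numeric score vector.
#' @param k Number of strata (`k >= 2`); 10 for deciles, 100 for percentiles.
#' @param seed Seed for the within-tie permutation.
#' @param ties `"random"` (default, balanced sizes) or `"value_complete"`.
#' @return Integer vector of stratum labels in `1..k` (1 = lowest scores).
#' @export
assign_quantile_strata <- function(scores, k = 10, seed = 1,
                                   ties = c("random", "value_complete")) {
  ties <- match.arg(ties)
  n <- length(scores)
  if (k < 2) abort("k must be at least 2", class = "riskburden_validation_error")
  if (n < k) abort("fewer individuals than strata", class = "riskburden_validation_error")
  if (length(unique(scores)) == 1) {
    abort("all scores identical: quantile strata undefined",
          class = "riskburden_validation_error")
  }
  if (k == 100 && n < 10000) {
    warn("percentile strata on fewer than 10,000 individuals: sizes are small")
  }
  if (ties == "random") {
    jitter <- with_stream(seed, "strata_ties", runif(n))
    ord <- order(scores, jitter)
    labels <- integer(n)
    labels[ord] <- as.integer(floor((seq_len(n) - 1) * k / n)) + 1L
    labels
  } else {
    qs <- stats::quantile(scores, probs = seq_len(k - 1) / k, type = 1)
    as.integer(findInterval(scores, unique(qs), left.open = TRUE)) + 1L
  }
}

#' Per-stratum prevalence and per-allele prevalence table
#'
#' For each stratum: case/control counts, prevalence, mean (± sd) risk-allele
#' count, and the per-allele prevalence — the stratum's prevalence divided by
#' its mean allele count, the statistic that exposes amplification of a
#' single allele's effect by the carrier's total burden.
#'
#' @param labels Stratum labels (e.g. from [assign_quantile_strata()]).
#' @param status 0/1 case status aligned to `labels`.
#' @param count_scores Risk-allele counts aligned to `labels`.
#' @return A tibble (one row per stratum, sorted by label): `stratum`, `n`,
#'   `n_cases`, `n_controls`, `prevalence` (fraction), `mean_count`,
#'   `sd_count`, `per_allele_prevalence`.
#' @export
stratum_summary <- function(labels, status, count_scores) {
  stopifnot(length(labels) == length(status),
            length(labels) == length(count_scores))
  if (!is_binary01(status[!is.na(status)])) {
    abort("status must be 0/1", class = "riskburden_validation_error")
  }
  tab <- tibble::tibble(stratum = labels, status = status, count = count_scores) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_cases = sum(.data$status),
      n_controls = sum(1 - .data$status),
      prevalence = mean(.data$status),
      mean_count = mean(.data$count),
      sd_count = sd(.data$count),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$stratum)
  if (any(tab$n == 0)) {
    abort("empty stratum", class = "riskburden_validation_error")
  }
  tab$per_allele_prevalence <- tab$prevalence / tab$mean_count
  tab
}

#' Build a stratum table from published per-stratum counts
#'
#' Reconstructs prevalence and per-allele prevalence from printed case and
#' control counts and mean allele counts, e.g. a published decile table —
#' the same arithmetic [stratum_summary()] applies to individual-level data.
#'
#' @param stratum Stratum labels.
#' @param n_cases,n_controls Integer counts per stratum.
#' @param mean_count Mean risk-allele count per stratum.
#' @param sd_count Optional sd of the count per stratum.
#' @return A stratum table tibble as from [stratum_summary()].
#' @export
stratum_table <- function(stratum, n_cases, n_controls, mean_count,
                          sd_count = NA_real_) {
  tibble::tibble(
    stratum = stratum,
    n = n_cases + n_controls,
    n_cases = n_cases,
    n_controls = n_controls,
    prevalence = n_cases / (n_cases + n_controls),
    mean_count = mean_count,
    sd_count = sd_count,
    per_allele_prevalence = (n_cases / (n_cases + n_controls)) / mean_count
  )
}

#' Fold changes between two strata
#'
#' Ratios (comparison over reference, conventionally top over bottom decile)
#' of mean allele count, prevalence, and per-allele prevalence.
#'
#' @param table Stratum table from [stratum_summary()] or [stratum_table()].
#' @param reference,comparison Stratum labels (default bottom and top row).
#' @return Tibble with `allele_fold`, `risk_fold`, `per_allele_fold`.
#' @export
fold_summary <- function(table, reference = table$stratum[1],
                         comparison = table$stratum[nrow(table)]) {
  ref <- table[table$stratum == reference, ]
  cmp <- table[table$stratum == comparison, ]
  if (nrow(ref) != 1 || nrow(cmp) != 1) {
    abort("reference/comparison stratum not found (or not unique)",
          class = "riskburden_validation_error")
  }
  if (ref$prevalence == 0) {
    abort("reference stratum has zero prevalence: fold undefined",
          class = "riskburden_validation_error")
  }
  tibble::tibble(
    reference = reference,
    comparison = comparison,
    allele_fold = cmp$mean_count / ref$mean_count,
    risk_fold = cmp$prevalence / ref$prevalence,
    per_allele_fold = cmp$per_allele_prevalence / ref$per_allele_prevalence
  )
}

#' Histogram of allele counts in fixed-width bins
#'
#' Bins risk-allele counts into width-2 bins aligned to even integers,
#' optionally split by case status, and reports the case-minus-control mean
#' difference (cases typically carry a handful more risk alleles than
#' controls).
#'
#' @param count_scores Risk-allele counts.
#' @param status Optional 0/1 case status for separate case/control series.
#' @param width Bin width (default 2).
#' @return Tibble `bin_start`, `bin_label`, (`group`,) `n`.  When `status`
#'   is given, the attribute `"mean_difference"` holds mean(cases) -
#'   mean(controls).
#' @export
count_histogram <- function(count_scores, status = NULL, width = 2) {
  bin <- width * floor(count_scores / width)
  mk <- function(b) {
    tibble::tibble(bin_start = sort(unique(b))) |>
      dplyr::mutate(
        bin_label = sprintf("[%g,%g)", .data$bin_start, .data$bin_start + width),
        n = as.integer(table(factor(b, levels = sort(unique(b)))))
      )
  }
  if (is.null(status)) {
    return(mk(bin))
  }
  cases <- mk(bin[status == 1]) |> dplyr::mutate(group = "case")
  ctrls <- mk(bin[status == 0]) |> dplyr::mutate(group = "control")
  out <- dplyr::bind_rows(cases, ctrls)
  diff <- if (any(status == 1) && any(status == 0)) {
    mean(count_scores[status == 1]) - mean(count_scores[status == 0])
  } else {
    NA_real_
  }
  attr(out, "mean_difference") <- diff
  out
}

#' Kolmogorov–Smirnov check of allele-count normality
#'
#' One-sample KS statistic of the counts against a normal distribution with
#' the sample mean and standard deviation; the p value uses the asymptotic
#' KS distribution.  Because parameters are estimated from the same data the
#' p value is anti-conservative (the Lilliefors effect); set
#' `lilliefors = TRUE` for the corrected test.  Note that allele counts live
#' on an integer lattice, which bounds the statistic away from zero by about
#' half the maximal bin probability (~0.023 at sd 9) no matter how normal
#' the underlying distribution is; judge normality by the statistic against
#' that floor, not by the p value at biobank sample sizes.
#'
#' @param count_scores Numeric vector, at least 30 values.
#' @param lilliefors Use `nortest::lillie.test()` instead.
#' @return List with `statistic` and `p_value`.
#' @export
ks_normality <- function(count_scores, lilliefors = FALSE) {
  if (length(count_scores) < 30) {
    abort("at least 30 observations required", class = "riskburden_validation_error")
  }
  if (sd(count_scores) == 0) {
    abort("zero variance: normality check undefined",
          class = "riskburden_validation_error")
  }
  if (lilliefors) {
    t <- nortest::lillie.test(count_scores)
    return(list(statistic = unname(t$statistic), p_value = t$p.value))
  }
  t <- suppressWarnings(ks.test(
    count_scores, "pnorm",
    mean = mean(count_scores), sd = sd(count_scores),
    exact = FALSE
  ))
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

#' Linear trend in prevalence across ordered strata
#'
#' Ordinary least squares of stratum prevalence on the stratum index
#' (1..k), with the two-sided t test on the slope.
#'
#' @param table Stratum table (rows in stratum order).
#' @return List with `slope`, `p_value`, `intercept`.
#' @export
trend_test <- function(table) {
  if (nrow(table) < 3) {
    abort("at least 3 strata required for a trend test",
          class = "riskburden_validation_error")
  }
  idx <- seq_len(nrow(table))
  fit <- lm(table$prevalence ~ idx)
  sm <- summary(fit)$coefficients
  list(
    slope = unname(sm[2, 1]),
    p_value = unname(sm[2, 4]),
    intercept = unname(sm[1, 1])
  )
}
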