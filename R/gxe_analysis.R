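#' Exposure-stratified prevalence across genetic strata
#'
#' Tabulates disease prevalence in each genetic stratum separately for
#' exposed and unexposed individuals, with the per-stratum absolute
#' difference (exposed minus unexposed).  Empty cells yield `NA` prevalence
#' with `n = 0`, never a silent zero.  Strata may be deciles or the
#' low / medium / high trichotomy from [trichotomize_strata()].
#'
#' @param labels Genetic stratum labels.
#' @param status 0/1 case status.
#' @param exposure 0/1 exposure indicator, aligned.
#' @return Tibble (one row per stratum): `stratum`, `n_unexposed`,
#'   `cases_unexposed`, `prev_unexposed`, `n_exposed`, `cases_exposed`,
#'   `prev_exposed`, `difference`.
#' @export
stratified_prevalence <- function(labels, status, exposure) {
  stopifnot(length(labels) == length(status), length(labels) == length(exposure))
  if (!is_binary01(exposure)) {
    abort("exposure must be 0/1", class = "riskburden_validation_error")
  }
  cell <- function(e) {
    tibble::tibble(stratum = labels[exposure == e],
                   status = status[exposure == e]) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(n = dplyr::n(), cases = sum(.data$status),
                       .groups = "drop")
  }
  all_strata <- tibble::tibble(stratum = sort(unique(labels)))
  un <- dplyr::left_join(all_strata, cell(0L), by = "stratum")
  ex <- dplyr::left_join(all_strata, cell(1L), by = "stratum")
  fill0 <- function(x) ifelse(is.na(x), 0L, x)
  out <- tibble::tibble(
    stratum = all_strata$stratum,
    n_unexposed = fill0(un$n),
    cases_unexposed = fill0(un$cases),
    n_exposed = fill0(ex$n),
    cases_exposed = fill0(ex$cases)
  ) |>
    dplyr::mutate(
      prev_unexposed = ifelse(.data$n_unexposed == 0, NA_real_,
                              .data$cases_unexposed / .data$n_unexposed),
      prev_exposed = ifelse(.data$n_exposed == 0, NA_real_,
                            .data$cases_exposed / .data$n_exposed),
      difference = .data$prev_exposed - .data$prev_unexposed
    )
  out[, c("stratum", "n_unexposed", "cases_unexposed", "prev_unexposed",
          "n_exposed", "cases_exposed", "prev_exposed", "difference")]
}

#' Pool deciles into low / medium / high genetic strata
#'
#' Low = 1st decile, medium = 2nd–9th deciles pooled, high = 10th decile.
#'
#' @param decile Integer decile labels 1..10.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
trichotomize_strata <- function(decile) {
  factor(
    dplyr::case_when(decile == 1 ~ "low", decile == 10 ~ "high",
                     TRUE ~ "medium"),
    levels = c("low", "medium", "high")
  )
}

#' Amplification of an exposure's absolute effect by genetic burden
#'
#' The fold by which the absolute prevalence difference attributable to the
#' exposure grows between a low and a high genetic stratum:
#' `[prev(high, exposed) - prev(high, unexposed)] /
#'  [prev(low, exposed) - prev(low, unexposed)]`.
#' Under multiplicative joint action this fold tracks the prevalence ratio
#' of the strata; under additive joint action it is 1.
#'
#' @param table Output of [stratified_prevalence()].
#' @param low,high Stratum labels to compare (defaults: first and last row).
#' @return The fold (scalar).
#' @export
amplification_summary <- function(table, low = table$stratum[1],
                                  high = table$stratum[nrow(table)]) {
  rl <- table[table$stratum == low, ]
  rh <- table[table$stratum == high, ]
  if (nrow(rl) != 1 || nrow(rh) != 1 ||
        anyNA(c(rl$difference, rh$difference))) {
    abort("both strata must be populated at both exposure levels",
          class = "riskburden_validation_error")
  }
  if (rl$difference <= 0) {
    abort(sprintf(
      "exposure difference in the %s stratum is %.4g (<= 0): amplification undefined",
      as.character(low), rl$difference
    ), class = "riskburden_validation_error")
  }
  rh$difference / rl$difference
}

#' Prevalence trend within one exposure level
#'
#' Ordinary least squares of cell prevalence (as a fraction) on the stratum
#' index within the exposed or unexposed series.  Displaying curves as
#' deviations from each group's mean shifts the intercept only; the slope
#' is unchanged.
#'
#' @param table Output of [stratified_prevalence()] with ordered strata.
#' @param exposure_level `"exposed"` or `"unexposed"`.
#' @return List `form = "linear"`, `coefficients` (intercept, slope), `r`
#'   between fitted and observed, `ci`, `p_value`.
#' @export
per_stratum_trend <- function(table, exposure_level = c("exposed", "unexposed")) {
  exposure_level <- match.arg(exposure_level)
  y <- if (exposure_level == "exposed") table$prev_exposed else table$prev_unexposed
  idx <- seq_len(nrow(table))
  ok <- !is.na(y)
  if (sum(ok) < 3) {
    abort("at least 3 populated strata required",
          class = "riskburden_validation_error")
  }
  fit <- lm(y[ok] ~ idx[ok])
  pc <- pearson_ci(y[ok], fitted(fit))
  list(
    form = "linear",
    coefficients = c(intercept = unname(coef(fit)[1]),
                     slope = unname(coef(fit)[2])),
    r = pc$r, ci = pc$ci,
    p_value = summary(fit)$coefficients[2, 4]
  )
}

#' Quadratic fit to the exposed-minus-unexposed difference curve
#'
#' Fits the per-stratum absolute prevalence difference on stratum index and
#' index squared by least squares, reporting the correlation between fitted
#' and observed differences with a Fisher-z interval.  A rising, convex
#' difference curve is the signature of multiplicative gene-environment
#' action.
#'
#' @param table Output of [stratified_prevalence()].
#' @param form `"quadratic"` (default) or `"linear"`.
#' @return List `form`, `coefficients`, `r`, `ci`.
#' @export
difference_curve_fit <- function(table, form = c("quadratic", "linear")) {
  form <- match.arg(form)
  ok <- !is.na(table$difference)
  idx <- seq_len(nrow(table))[ok]
  d <- table$difference[ok]
  if (form == "quadratic") {
    if (length(unique(idx)) < 3) {
      abort("at least 3 distinct stratum indices required for a quadratic fit",
            class = "riskburden_validation_error")
    }
    if (length(idx) < 4) {
      abort("at least 4 populated strata required",
            class = "riskburden_validation_error")
    }
    fit <- lm(d ~ idx + I(idx^2))
  } else {
    if (length(idx) < 3) {
      abort("at least 3 populated strata required",
            class = "riskburden_validation_error")
    }
    fit <- lm(d ~ idx)
  }
  fv <- fitted(fit)
  if (sd(fv) == 0) {
    # perfectly flat differences: quadratic/linear terms vanish
    return(list(form = form, coefficients = coef(fit), r = NA_real_,
                ci = c(NA_real_, NA_real_)))
  }
  pc <- pearson_ci(d, fv)
  list(form = form, coefficients = coef(fit), r = pc$r, ci = pc$ci)
}

#' Derive binary exposures from raw measurements
#'
#' Dichotomizes raw covariates at conventional epidemiological cutpoints:
#' obesity as BMI >= 30 kg/m^2, sedentary lifestyle as < 7.5 MET-hours,
#' high cholesterol as > 6.18 mmol/L, and older age as >= 55 years.  Kept
#' separate from the analysis core, which consumes only 0/1 columns.
#'
#' @param data Tibble with any of `bmi`, `met_hours`, `cholesterol`, `age`.
#' @return `data` with added 0/1 columns `obesity`, `sedentary`,
#'   `high_cholesterol`, `age55` for whichever inputs are present.
#' @export
derive_exposures <- function(data) {
  if ("bmi" %in% names(data)) {
    data$obesity <- as.integer(data$bmi >= 30)
  }
  if ("met_hours" %in% names(data)) {
    data$sedentary <- as.integer(data$met_hours < 7.5)
  }
  if ("cholesterol" %in% names(data)) {
    data$high_cholesterol <- as.integer(data$cholesterol > 6.18)
  }
  if ("age" %in% names(data)) {
    data$age55 <- as.integer(data$age >= 55)
  }
  data
}
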