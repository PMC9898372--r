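#' Draw random variant subsets from a panel
#'
#' Each replicate is an independent uniform draw of `subset_size` variant
#' indices without replacement, reproducible from the seed.  Used to test
#' exchangeability: whether *which* risk alleles are counted matters, or
#' only how many.
#'
#' @param panel_size Number of variants in the full panel.
#' @param subset_size Variants per replicate (`<= panel_size`).
#' @param n_replicates Number of replicates.
#' @param seed Seed for the subset stream.
#' @return List of integer index vectors, one per replicate.
#' @export
random_subsets <- function(panel_size, subset_size, n_replicates, seed = 1) {
  if (subset_size > panel_size) {
    abort("subset_size exceeds panel_size", class = "riskburden_validation_error")
  }
  if (subset_size < 1) {
    abort("subset_size must be at least 1", class = "riskburden_validation_error")
  }
  with_stream(seed, "subsets", {
    lapply(seq_len(n_replicates), function(i) {
      sort(sample.int(panel_size, subset_size))
    })
  })
}

#' Link-fit distribution across random sub-panels
#'
#' For each variant subset: score individuals on the subset alone, group by
#' exact count, fit the requested links, and record the observed-vs-
#' predicted correlation.  Replicates whose grouped curve cannot be fitted
#' (no group above the size filter) are recorded as `NA`, never dropped
#' silently.  Tight distributions of `r` across random half-panels indicate
#' that risk alleles are exchangeable.
#'
#' @param dosage Imputed dosage matrix (individuals x variants).
#' @param status 0/1 case status.
#' @param subsets List of variant index vectors (see [random_subsets()]).
#' @param links Links to fit per replicate.
#' @param min_group_size Group-size filter (see [group_by_count()]).
#' @return Tibble `replicate`, `link`, `r`; per-link mean and sd in
#'   attribute `"summary"`.
#' @export
replicate_fit_distribution <- function(dosage, status, subsets,
                                       links = c("logit", "log"),
                                       min_group_size = 200) {
  if (any(lengths(subsets) == 0)) {
    abort("empty variant subset", class = "riskburden_validation_error")
  }
  rows <- purrr::imap_dfr(subsets, function(idx, i) {
    counts <- round_counts(rowSums(dosage[, idx, drop = FALSE]))
    r_of <- vapply(links, function(lk) {
      tryCatch({
        curve <- group_by_count(counts, status, min_group_size)
        fit <- fit_link(counts, status, link = lk)
        goodness_of_fit(curve, fit)$r
      }, error = function(e) NA_real_)
    }, numeric(1))
    tibble::tibble(replicate = i, link = links, r = unname(r_of))
  })
  summary <- rows |>
    dplyr::group_by(.data$link) |>
    dplyr::summarise(
      mean_r = mean(.data$r, na.rm = TRUE),
      sd_r = sd(.data$r, na.rm = TRUE),
      n_missing = sum(is.na(.data$r)),
      .groups = "drop"
    )
  attr(rows, "summary") <- summary
  rows
}

#' Match untagged variants to tagged ones by odds ratio
#'
#' Greedy nearest-neighbour matching on |difference in log odds ratio|,
#' without replacement, processing targets in descending odds ratio: for
#' each tagged variant (e.g. a lipid-associated CAD hit) the closest
#' still-unused variant from the pool is selected, yielding a comparison
#' panel with similar published effect sizes but without the annotation.
#'
#' @param target Variant tibble of tagged variants.
#' @param pool Variant tibble to draw matches from (disjoint from target).
#' @param tolerance Maximal acceptable |delta log OR| per pair; violations
#'   warn (or error with `strict = TRUE`).
#' @param strict Error instead of warning on tolerance violations.
#' @return The matched subset of `pool` (one row per target row, in target
#'   order) with column `matched_to` and attribute `"delta_log_or"`.
#' @export
match_by_or <- function(target, pool, tolerance = 0.05, strict = FALSE) {
  if (nrow(pool) < nrow(target)) {
    abort("pool smaller than target set", class = "riskburden_validation_error")
  }
  ord <- order(target$odds_ratio, decreasing = TRUE)
  pool_log <- log(pool$odds_ratio)
  used <- rep(FALSE, nrow(pool))
  pick <- integer(nrow(target))
  delta <- numeric(nrow(target))
  for (i in ord) {
    d <- abs(log(target$odds_ratio[i]) - pool_log)
    d[used] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    pick[i] <- j
    delta[i] <- d[j]
  }
  bad <- which(delta > tolerance)
  if (length(bad) > 0) {
    msg <- sprintf(
      "%d match(es) exceed tolerance %g (worst |delta log OR| = %.4g)",
      length(bad), tolerance, max(delta)
    )
    if (strict) abort(msg, class = "riskburden_validation_error") else warn(msg)
  }
  out <- pool[pick, ]
  out$matched_to <- target$variant_id
  attr(out, "delta_log_or") <- delta
  out
}

#' Cross-classification of two risk scores
#'
#' Fixes one stratum of score A (by default its top decile) and, within it,
#' tabulates prevalence across low / medium / high strata of score B —
#' where low, medium and high are the 1st decile, pooled 2nd–9th deciles,
#' and 10th decile of B's *whole-population* distribution.  If carrying
#' many B alleles raises prevalence even among individuals already in A's
#' top decile, the two sub-panels contribute interchangeably to risk.
#'
#' @param scores_a,scores_b Score vectors over the same individuals.
#' @param status 0/1 case status.
#' @param fixed_stratum Which decile of A to fix (default 10).
#' @param seed Seed for decile tie-breaking.
#' @return Tibble `b_level` (low/medium/high), `n`, `n_cases`,
#'   `prevalence` (`NA` when the cell is empty).
#' @export
cross_classification <- function(scores_a, scores_b, status,
                                 fixed_stratum = 10, seed = 1) {
  dec_a <- assign_quantile_strata(scores_a, 10, seed = stream_seed(seed, "cross_a"))
  dec_b <- assign_quantile_strata(scores_b, 10, seed = stream_seed(seed, "cross_b"))
  b_level <- dplyr::case_when(
    dec_b == 1 ~ "low",
    dec_b == 10 ~ "high",
    TRUE ~ "medium"
  )
  inside <- dec_a == fixed_stratum
  tibble::tibble(b_level = factor(b_level[inside],
                                  levels = c("low", "medium", "high")),
                 status = status[inside]) |>
    dplyr::group_by(.data$b_level, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(), n_cases = sum(.data$status), .groups = "drop"
    ) |>
    dplyr::mutate(
      prevalence = ifelse(.data$n == 0, NA_real_, .data$n_cases / .data$n)
    )
}
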