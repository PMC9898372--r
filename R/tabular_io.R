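#' Read GWAS summary statistics for a risk-variant panel
#'
#' Parses a tab-separated summary-statistics file into a validated variant
#' panel: one row per biallelic variant with its effect/other allele, risk
#' (effect) allele frequency and per-allele odds ratio.  Effect sizes given
#' as log odds ratios (a `beta`/`log_or` column) are converted to odds ratios
#' via `exp()`; which scale applies is decided by the column name, never
#' guessed from magnitude.
#'
#' @param path Path to a TSV file with a header row.
#' @param trait Optional trait label; when the file has no `trait` column the
#'   label is applied to every row, otherwise rows are filtered to the trait.
#' @param aliases Named list overriding default column-name aliases, e.g.
#'   `list(variant_id = "rsid")`.
#'
#' @return A tibble with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `raf`, `odds_ratio`, `trait`, `tags`
#'   (semicolon-separated annotation tags, `""` when absent).
#'
#' @details Every row is validated: `raf` must lie strictly inside (0, 1),
#'   the odds ratio must be positive, alleles must be single, distinct bases,
#'   and variant ids must be unique.  Validation failures are errors naming
#'   the offending row numbers.  The returned panel is *not* risk-oriented;
#'   apply [flip_to_risk()] before scoring.
#'
#' @seealso [flip_to_risk()], [write_sumstats()], [read_dosage()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "variant_id\tchrom\tpos\teffect_allele\tother_allele\teaf\tor",
#'   "rs1333049\t9\t22125503\tC\tG\t0.75\t1.23"
#' ), f)
#' read_sumstats(f, trait = "cad")
read_sumstats <- function(path, trait = NULL, aliases = list()) {
  defaults <- list(
    variant_id = c("variant_id", "id", "rsid", "snp", "marker"),
    chrom = c("chrom", "chr", "chromosome"),
    pos = c("pos", "bp", "position", "base_pair"),
    effect_allele = c("effect_allele", "ea", "a1", "risk_allele"),
    other_allele = c("other_allele", "oa", "a2", "ref_allele"),
    raf = c("eaf", "raf", "freq", "frequency", "effect_allele_frequency"),
    or = c("or", "odds_ratio"),
    beta = c("beta", "log_or", "logor", "b"),
    trait = c("trait", "phenotype", "disease"),
    tags = c("tags", "annotation", "category")
  )
  for (nm in names(aliases)) defaults[[nm]] <- c(aliases[[nm]], defaults[[nm]])

  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#", col_types = readr::cols(.default = "c"))
  cols <- tolower(names(raw))
  find_col <- function(key) {
    hit <- which(cols %in% defaults[[key]])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }

  mandatory <- c("variant_id", "effect_allele", "other_allele", "raf")
  idx <- vapply(names(defaults), find_col, integer(1))
  missing_cols <- mandatory[is.na(idx[mandatory])]
  if (is.na(idx[["or"]]) && is.na(idx[["beta"]])) {
    missing_cols <- c(missing_cols, "or|beta")
  }
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "summary-statistics file %s lacks mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ), class = "riskburden_format_error")
  }

  n <- nrow(raw)
  get_chr <- function(key, default = NA_character_) {
    if (is.na(idx[[key]])) rep(default, n) else as.character(raw[[idx[[key]]]])
  }
  num_field <- function(key, label) {
    if (is.na(idx[[key]])) return(rep(NA_real_, n))
    x <- suppressWarnings(as.numeric(raw[[idx[[key]]]]))
    bad <- which(is.na(x) & !is.na(raw[[idx[[key]]]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s at data row(s) %s",
                    label, paste(head(bad, 5), collapse = ", ")),
            class = "riskburden_format_error")
    }
    x
  }

  raf <- num_field("raf", "allele frequency")
  if (!is.na(idx[["or"]])) {
    odds_ratio <- num_field("or", "odds ratio")
  } else {
    odds_ratio <- exp(num_field("beta", "log odds ratio"))
  }

  panel <- tibble::tibble(
    variant_id = get_chr("variant_id"),
    chrom = get_chr("chrom"),
    pos = if (is.na(idx[["pos"]])) rep(NA_integer_, n) else
      as.integer(num_field("pos", "position")),
    effect_allele = toupper(get_chr("effect_allele")),
    other_allele = toupper(get_chr("other_allele")),
    raf = raf,
    odds_ratio = odds_ratio,
    trait = get_chr("trait", default = trait %||% NA_character_),
    tags = get_chr("tags", default = "")
  )
  panel$tags[is.na(panel$tags)] <- ""
  if (!is.null(trait) && !is.na(idx[["trait"]])) {
    panel <- panel[panel$trait %in% trait, , drop = FALSE]
  }
  validate_panel(panel)
  flag_ambiguous_strand(panel)
  panel
}

validate_panel <- function(panel) {
  if (nrow(panel) == 0) {
    return(invisible(panel))
  }
  fail <- function(rows, why) {
    abort(sprintf("%s at data row(s) %s", why,
                  paste(head(rows, 5), collapse = ", ")),
          class = "riskburden_validation_error")
  }
  bad <- which(is.na(panel$raf) | panel$raf <= 0 | panel$raf >= 1)
  if (length(bad)) fail(bad, "risk-allele frequency outside (0,1)")
  bad <- which(is.na(panel$odds_ratio) | panel$odds_ratio <= 0)
  if (length(bad)) fail(bad, "odds ratio must be positive")
  bad <- which(!grepl("^[ACGT]$", panel$effect_allele) |
                 !grepl("^[ACGT]$", panel$other_allele))
  if (length(bad)) fail(bad, "alleles must be single bases A/C/G/T")
  bad <- which(panel$effect_allele == panel$other_allele)
  if (length(bad)) fail(bad, "effect and other allele must differ")
  dup <- which(duplicated(panel$variant_id))
  if (length(dup)) fail(dup, "duplicate variant_id")
  invisible(panel)
}

# Strand-ambiguous (A/T, C/G) variants cannot be unambiguously matched to
# genotype data without strand information; they are flagged, never flipped
# by frequency.
flag_ambiguous_strand <- function(panel) {
  pair <- paste0(pmin(panel$effect_allele, panel$other_allele),
                 pmax(panel$effect_allele, panel$other_allele))
  amb <- panel$variant_id[pair %in% c("AT", "CG")]
  if (length(amb) > 0) {
    warn(sprintf(
      "%d strand-ambiguous (A/T or C/G) variant(s): %s",
      length(amb), paste(head(amb, 5), collapse = ", ")
    ))
  }
  invisible(amb)
}

#' Orient a variant panel so every stored allele increases risk
#'
#' For any variant whose odds ratio is below 1, the effect and other alleles
#' are swapped, the odds ratio replaced by its reciprocal, and the allele
#' frequency by its complement, so that downstream scores count alleles that
#' increase disease odds.  Variants with an odds ratio of exactly 1 are kept
#' as given.  The operation is idempotent.
#'
#' @param panel A variant panel tibble as returned by [read_sumstats()].
#' @return The panel with every `odds_ratio >= 1`.
#' @export
flip_to_risk <- function(panel) {
  if (any(panel$odds_ratio <= 0)) {
    abort("odds ratio must be positive", class = "riskburden_validation_error")
  }
  flip <- panel$odds_ratio < 1
  if (any(flip)) {
    ea <- panel$effect_allele
    panel$effect_allele[flip] <- panel$other_allele[flip]
    panel$other_allele[flip] <- ea[flip]
    panel$raf[flip] <- 1 - panel$raf[flip]
    panel$odds_ratio[flip] <- 1 / panel$odds_ratio[flip]
  }
  panel
}

#' Write a variant panel back to TSV
#'
#' Emits the canonical summary-statistics columns with a commented header
#' line recording the tool version (and config hash when supplied), so the
#' file round-trips through [read_sumstats()].
#'
#' @param panel Variant panel tibble.
#' @param path Output path.
#' @param config_hash Optional hash string recorded in the header comment.
#' @return The path, invisibly.
#' @export
write_sumstats <- function(panel, path, config_hash = NULL) {
  out <- panel[, c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "raf", "odds_ratio", "trait", "tags")]
  names(out)[names(out) == "raf"] <- "eaf"
  names(out)[names(out) == "odds_ratio"] <- "or"
  write_result_tsv(out, path, config_hash)
}

#' Read genotype dosages oriented to a risk panel
#'
#' Reads risk-allele dosages either from a VCF (using the `GT` or `DS`
#' fields) or from a plain individuals-by-variants TSV matrix, and orients
#' every dosage to the panel's risk allele: for a VCF record whose ALT equals
#' the risk allele the ALT count is used directly, whereas when REF is the
#' risk allele the count is reversed (`2 - alt dosage`).
#'
#' @param path Path to the genotype file.
#' @param panel Risk-oriented variant panel ([flip_to_risk()] already
#'   applied); defines the variant set, order and risk alleles.
#' @param format `"vcf"` or `"matrix"`.
#' @param field For VCF input, `"GT"` (default) or `"DS"`.
#'
#' @return A numeric matrix with one row per individual and one column per
#'   panel variant; entries in \[0, 2\], `NA` for missing genotypes.  Row
#'   names are individual ids, column names variant ids.
#'
#' @details Panel variants absent from the file yield an all-missing column
#'   with a warning.  Multi-allelic VCF records are rejected: the panels this
#'   package targets are biallelic genome-wide-significant hits.  In matrix
#'   input, `NA` or an empty cell marks a missing genotype; any other
#'   non-numeric content is an error.
#' @export
read_dosage <- function(path, panel, format = c("vcf", "matrix"),
                        field = c("GT", "DS")) {
  format <- match.arg(format)
  field <- match.arg(field)
  switch(format,
    vcf = read_dosage_vcf(path, panel, field),
    matrix = read_dosage_matrix(path, panel)
  )
}

read_dosage_vcf <- function(path, panel, field) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi & ids %in% panel$variant_id)) {
    abort(sprintf(
      "multi-allelic VCF record(s) for panel variant(s): %s",
      paste(head(ids[multi & ids %in% panel$variant_id], 5), collapse = ", ")
    ), class = "riskburden_format_error")
  }
  if (field == "GT") {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_dosage <- alt_count_from_gt(gt)
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    alt_dosage <- suppressWarnings(
      matrix(as.numeric(ds), nrow = nrow(ds), dimnames = dimnames(ds))
    )
  }
  samples <- colnames(alt_dosage)
  out <- matrix(NA_real_, nrow = length(samples), ncol = nrow(panel),
                dimnames = list(samples, panel$variant_id))
  for (j in seq_len(nrow(panel))) {
    vid <- panel$variant_id[j]
    k <- match(vid, ids)
    if (is.na(k)) {
      warn(sprintf("panel variant %s absent from %s: column set to missing",
                   vid, path))
      next
    }
    ref <- unname(fix[k, "REF"]); alt <- unname(fix[k, "ALT"])
    risk <- panel$effect_allele[j]
    d <- alt_dosage[k, ]
    if (isTRUE(risk == alt)) {
      out[, j] <- d
    } else if (isTRUE(risk == ref)) {
      out[, j] <- 2 - d
    } else {
      warn(sprintf(
        "risk allele %s of %s matches neither REF (%s) nor ALT (%s): missing",
        risk, vid, ref, alt
      ))
    }
  }
  out[out < 0 | out > 2] <- NA_real_
  out
}

# ALT-allele count from diploid GT strings; anything unparseable is missing.
alt_count_from_gt <- function(gt) {
  count1 <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2 || any(!alleles %in% c("0", "1"))) {
      return(NA_real_)
    }
    sum(alleles == "1")
  }
  matrix(vapply(gt, count1, numeric(1)), nrow = nrow(gt),
         dimnames = dimnames(gt))
}

read_dosage_matrix <- function(path, panel) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  id_col <- names(raw)[1]
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    abort("duplicate individual ids in dosage matrix",
          class = "riskburden_format_error")
  }
  out <- matrix(NA_real_, nrow = length(ids), ncol = nrow(panel),
                dimnames = list(ids, panel$variant_id))
  for (j in seq_len(nrow(panel))) {
    vid <- panel$variant_id[j]
    if (!vid %in% names(raw)) {
      warn(sprintf("panel variant %s absent from %s: column set to missing",
                   vid, path))
      next
    }
    cell <- trimws(raw[[vid]])
    x <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(x) & !is.na(cell) & cell != "" & cell != "NA")
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric dosage for %s at data row(s) %s (only NA or empty mark missing)",
        vid, paste(head(bad, 5), collapse = ", ")
      ), class = "riskburden_format_error")
    }
    if (any(x < 0 | x > 2, na.rm = TRUE)) {
      abort(sprintf("dosage outside [0,2] for %s", vid),
            class = "riskburden_validation_error")
    }
    out[, j] <- x
  }
  out
}

#' Write a dosage matrix as TSV
#'
#' @param dosage Numeric individuals-by-variants matrix with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dosage <- function(dosage, path) {
  df <- data.frame(individual_id = rownames(dosage), dosage,
                   check.names = FALSE)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a phenotype and exposure table
#'
#' Reads a CSV with one row per individual: an id column, optional `sex` and
#' `age` columns, and any number of binary case-status and exposure columns.
#' Binary columns accept `0/1`, `yes/no` and `true/false` (case-insensitive);
#' any other value is an error, never a silent `NA`.
#'
#' @param path Path to a CSV file.
#' @param id_col Name of the individual-id column (default first column).
#' @return A tibble with `individual_id` first, binary columns coerced to
#'   integer 0/1, and `sex`/`age` passed through when present.
#' @export
read_phenotypes <- function(path, id_col = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  id_col <- id_col %||% names(raw)[1]
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate individual id(s): %s",
                  paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", ")),
          class = "riskburden_format_error")
  }
  out <- tibble::tibble(individual_id = as.character(ids))
  for (nm in setdiff(names(raw), id_col)) {
    if (tolower(nm) == "sex") {
      out$sex <- tolower(raw[[nm]])
    } else if (tolower(nm) == "age") {
      out$age <- suppressWarnings(as.numeric(raw[[nm]]))
    } else {
      out[[nm]] <- coerce_binary(raw[[nm]], what = sprintf("value in column %s", sQuote(nm)))
    }
  }
  out
}
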