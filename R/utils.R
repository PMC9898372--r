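# Internal helpers shared across modules.

# Named RNG streams derived from a master seed, so that (e.g.) adding loci to
# the panel stream never perturbs the phenotype stream.  Purpose names are
# hashed to a fixed offset; the combined seed stays below 2^31 - 1.
stream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(purpose) == 1)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)) * 131L)
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

with_stream <- function(seed, purpose, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, purpose))
  force(code)
}

is_binary01 <- function(x) all(x %in% c(0L, 1L))

# Coerce common yes/no encodings to 0/1 integers; unknown values are an error,
# never a silent NA.
coerce_binary <- function(x, what = "value") {
  if (is.logical(x)) {
    return(as.integer(x))
  }
  key <- tolower(trimws(as.character(x)))
  map <- c(
    "0" = 0L, "1" = 1L, "no" = 0L, "yes" = 1L,
    "false" = 0L, "true" = 1L, "n" = 0L, "y" = 1L
  )
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(key))
  if (length(bad) > 0) {
    abort(sprintf(
      "non-binary %s %s at position(s) %s; expected 0/1, yes/no or true/false",
      what, paste(sQuote(unique(key[bad])), collapse = ", "),
      paste(head(bad, 5), collapse = ", ")
    ), class = "riskburden_validation_error")
  }
  out
}

# Pearson correlation with a Fisher-z 95% confidence interval.
pearson_ci <- function(x, y, conf = 0.95) {
  if (length(x) < 3) {
    abort("at least 3 points are required for a correlation with CI",
      class = "riskburden_validation_error"
    )
  }
  if (sd(y) == 0) {
    abort("predictor is constant: correlation undefined",
      class = "riskburden_degenerate_error"
    )
  }
  if (sd(x) == 0) {
    abort("observations are constant: correlation undefined",
      class = "riskburden_degenerate_error"
    )
  }
  r <- cor(x, y)
  k <- length(x)
  z <- atanh(r)
  se <- 1 / sqrt(k - 3)
  q <- qnorm(1 - (1 - conf) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = k)
}

# MD5 of an arbitrary R object, used for config hashes and file manifests.
object_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

pkg_version <- function() {
  as.character(utils::packageVersion("riskburden"))
}

# Writer used by every module that emits result tables: TSV with a commented
# header recording tool version and, when given, the config hash.
write_result_tsv <- function(x, path, config_hash = NULL) {
  header <- sprintf(
    "# riskburden %s%s", pkg_version(),
    if (is.null(config_hash)) "" else paste0(" config_hash=", config_hash)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
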