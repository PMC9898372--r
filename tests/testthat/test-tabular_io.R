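write_sumstats_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("summary statistics parse with OR, beta and alias columns", {
  f <- write_sumstats_file(c(
    "variant_id\tchrom\tpos\teffect_allele\tother_allele\teaf\tor\ttags",
    "rs1\t9\t22125503\tC\tT\t0.75\t1.23\tlipid;bp",
    "rs2\t2\t1000\tA\tG\t0.30\t1.05\t"
  ))
  panel <- read_sumstats(f, trait = "cad")
  expect_equal(nrow(panel), 2)
  expect_equal(panel$odds_ratio[1], 1.23)
  expect_equal(panel$raf[1], 0.75)
  expect_equal(panel$trait, c("cad", "cad"))
  expect_equal(panel$tags[1], "lipid;bp")

  # beta column converts via exp; beta 0 -> OR 1
  fb <- write_sumstats_file(c(
    "rsid\ta1\ta2\tfreq\tbeta",
    "rs1\tC\tT\t0.75\t0.2070142",
    "rs2\tA\tG\t0.30\t0.0"
  ))
  pb <- read_sumstats(fb)
  expect_equal(pb$odds_ratio, c(exp(0.2070142), 1.0))

  # header only -> empty panel
  fe <- write_sumstats_file("variant_id\tea\toa\teaf\tor")
  expect_equal(nrow(read_sumstats(fe)), 0)
})

test_that("summary statistics validation rejects malformed rows by index", {
  f <- write_sumstats_file(c(
    "variant_id\tea\toa\teaf\tor",
    "rs1\tC\tG\t1.75\t1.23"
  ))
  expect_error(read_sumstats(f), "frequency outside \\(0,1\\).*1",
               class = "riskburden_validation_error")

  f2 <- write_sumstats_file(c(
    "variant_id\tea\toa\tor",
    "rs1\tC\tG\t1.23"
  ))
  expect_error(read_sumstats(f2), "mandatory column",
               class = "riskburden_format_error")

  f3 <- write_sumstats_file(c(
    "variant_id\tea\toa\teaf\tor",
    "rs1\tC\tG\t0.5\t1.2",
    "rs1\tA\tG\t0.5\t1.2"
  ))
  expect_error(read_sumstats(f3), "duplicate variant_id")

  f4 <- write_sumstats_file(c(
    "variant_id\tea\toa\teaf\tor",
    "rs1\tA\tT\t0.5\t1.2"
  ))
  expect_warning(read_sumstats(f4), "strand-ambiguous")
})

test_that("flip_to_risk orients, is idempotent and keeps OR 1 as given", {
  panel <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    chrom = "1", pos = 1:3,
    effect_allele = c("C", "C", "C"), other_allele = c("G", "G", "G"),
    raf = c(0.30, 0.75, 0.5),
    odds_ratio = c(0.80, 1.23, 1.0),
    trait = "t", tags = ""
  )
  flipped <- flip_to_risk(panel)
  expect_equal(flipped$odds_ratio, c(1.25, 1.23, 1.0))
  expect_equal(flipped$raf, c(0.70, 0.75, 0.5))
  expect_equal(flipped$effect_allele, c("G", "C", "C"))
  expect_equal(flip_to_risk(flipped), flipped) # idempotent

  panel$odds_ratio[1] <- -1
  expect_error(flip_to_risk(panel), class = "riskburden_validation_error")
})

test_that("panels round-trip through write_sumstats/read_sumstats", {
  panel <- toy_panel()
  f <- tempfile(fileext = ".tsv")
  write_sumstats(panel, f)
  back <- read_sumstats(f)
  expect_equal(back$variant_id, panel$variant_id)
  expect_equal(back$raf, panel$raf, tolerance = 1e-12)
  expect_equal(back$odds_ratio, panel$odds_ratio, tolerance = 1e-12)
  expect_equal(back$tags, panel$tags)
  # header comment carries the tool version
  expect_match(readLines(f, n = 1), "^# riskburden")
})

test_that("VCF dosages are oriented to the risk allele", {
  panel <- toy_panel()[1:2, ]
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  d <- read_dosage(vcf, panel, format = "vcf")
  # v1 risk allele G is ALT: het -> 1, hom-alt -> 2, ./. -> NA
  expect_equal(unname(d[, "v1"]), c(1, 2, NA))
  # v2 risk allele T is REF: dosage reversed from ALT count
  expect_equal(unname(d[, "v2"]), c(2, 1, 0))
})

test_that("VCF and matrix dosage readers agree on the same genotypes", {
  panel <- toy_panel()[1:2, ]
  dv <- read_dosage(write_toy_vcf(tempfile(fileext = ".vcf")), panel, "vcf")
  dm <- read_dosage(write_toy_matrix(tempfile(fileext = ".tsv")), panel, "matrix")
  expect_equal(dv, dm)
})

test_that("dosage reader flags absent variants and rejects bad input", {
  panel <- toy_panel()[1:3, ] # v3 not in the fixture
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  expect_warning(d <- read_dosage(vcf, panel, "vcf"), "absent")
  expect_true(all(is.na(d[, "v3"])))

  multi <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "100", "v1", "A", "G,T", ".", ".", ".", "GT", "0/1", sep = "\t")
  ), multi)
  expect_error(read_dosage(multi, panel[1, ], "vcf"), "multi-allelic",
               class = "riskburden_format_error")

  badmat <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tv1", "S1\tx"), badmat)
  expect_error(read_dosage(badmat, panel[1, ], "matrix"), "non-numeric",
               class = "riskburden_format_error")
})

test_that("phenotype reader coerces binary aliases and rejects the rest", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,cad,smoking,sex,age",
               "A,1,yes,female,61",
               "B,0,no,male,49"), f)
  ph <- read_phenotypes(f)
  expect_equal(ph$cad, c(1L, 0L))
  expect_equal(ph$smoking, c(1L, 0L))
  expect_equal(ph$age, c(61, 49))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("id,cad", "A,2"), f2)
  expect_error(read_phenotypes(f2), "non-binary",
               class = "riskburden_validation_error")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("id,cad", "A,1", "A,0"), f3)
  expect_error(read_phenotypes(f3), "duplicate",
               class = "riskburden_format_error")
})
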