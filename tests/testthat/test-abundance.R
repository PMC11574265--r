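test_that("tRNA proportions divide counts by the mapped-read total", {
  p <- trna_proportions(c(A = 30, B = 10))
  expect_equal(p$proportions, c(A = 0.75, B = 0.25))
  expect_equal(trna_proportions(c(A = 7))$proportions, c(A = 1.0))
  expect_equal(trna_proportions(c(A = 1, B = 1, C = 2))$proportions,
               c(A = 0.25, B = 0.25, C = 0.5))
  expect_error(trna_proportions(c(A = 0, B = 0)), "all-zero")
  expect_error(trna_proportions(c(A = -1, B = 2)), "negative")
})

test_that("proportions are scale-invariant and respect the include filter", {
  counts <- c(`Phe-GAA` = 123, `His-GTG` = 456, `mt-X` = 789)
  a <- trna_proportions(counts, include = c("Phe-GAA", "His-GTG"))
  b <- trna_proportions(counts * 1000, include = c("Phe-GAA", "His-GTG"))
  expect_equal(a$proportions, b$proportions)
  expect_equal(sum(a$proportions), 1)
  expect_false("mt-X" %in% names(a$proportions))
  expect_error(trna_proportions(counts, include = "Gly-GCC"), "absent")
})

test_that("expression-weighted usage matches hand-computed sums", {
  cds_set <- make_cds_set(list(
    T1 = c("AAA", "GGG"),
    T2 = c("AAA")
  ))
  one <- weighted_codon_usage(cds_set["T1"], c(T1 = 10))
  expect_equal(unname(one$usage[c("AAA", "GGG")]), c(0.5, 0.5))
  # T1 freq {AAA:.5, GGG:.5} TPM 10; T2 freq {AAA:1} TPM 30
  # -> AAA (0.5*10 + 1*30)/40 = 0.875, GGG 0.5*10/40 = 0.125
  both <- weighted_codon_usage(cds_set, c(T1 = 10, T2 = 30))
  expect_equal(unname(both$usage[c("AAA", "GGG")]), c(0.875, 0.125))
  expect_equal(sum(both$usage), 1)
})

test_that("equal TPM reduces to pooled frequencies; scaling TPM is a no-op", {
  cds_set <- make_cds_set(list(
    a = c("AAA", "CCC", "GGG"),
    b = c("AAA", "AAA", "TTT")
  ))
  equal <- weighted_codon_usage(cds_set, c(a = 5, b = 5))
  pooled <- (codon_frequencies(cds_set$a) / 2)
  pooled2 <- (codon_frequencies(cds_set$b) / 2)
  expect_equal(unname(equal$usage["AAA"]),
               unname(pooled["AAA"] + pooled2["AAA"]))
  scaled <- weighted_codon_usage(cds_set, c(a = 5000, b = 5000))
  expect_equal(equal$usage, scaled$usage)
})

test_that("expressed transcripts missing from the CDS set are skipped with warning", {
  cds_set <- make_cds_set(list(a = c("AAA")))
  expect_warning(
    u <- weighted_codon_usage(cds_set, c(a = 1, ghost = 9)),
    "absent"
  )
  expect_equal(u$n_skipped, 1L)
  expect_equal(unname(u$usage["AAA"]), 1)
})

test_that("supply duplicates the family proportion onto wobble codons", {
  map <- build_decoding_map()
  profile <- uniform_profile()
  cds_set <- make_cds_set(list(a = c("TTC", "TTC", "TTC", "TTT", "TTT")))
  usage <- weighted_codon_usage(cds_set, c(a = 1))
  ds <- demand_supply(usage, profile, map)
  phe <- ds[ds$codon %in% c("TTT", "TTC"), ]
  expect_equal(phe$supply[1], phe$supply[2])
  expect_equal(ds$ratio[ds$codon == "TTC"],
               0.6 / profile$proportions[["Phe-GAA"]])
  expect_equal(ds$ratio[ds$codon == "TTT"],
               0.4 / profile$proportions[["Phe-GAA"]])
  # demand 0 with positive supply gives ratio 0
  expect_true(all(ds$ratio[!ds$codon %in% c("TTT", "TTC")] == 0))
})

test_that("demand sums to 1; supply sums to families + wobble duplicates", {
  map <- build_decoding_map()
  profile <- uniform_profile()
  cds_set <- gen_cds_set(11, n_transcripts = 10, length_range = c(30, 60))
  tpm <- stats::setNames(rep(1, 10), names(cds_set))
  usage <- weighted_codon_usage(cds_set, tpm)
  ds <- demand_supply(usage, profile, map)
  expect_equal(sum(ds$demand), 1)
  dup <- profile$proportions[map$wobble_pairs$family]
  expect_equal(sum(ds$supply), sum(profile$proportions) + sum(dup))
})

test_that("zero-supply codons are flagged undefined, not divided", {
  map <- build_decoding_map(phe_lys_repertoire(), code = local({
    gc <- genetic_code()
    gc$sense_codons <- c("TTT", "TTC", "AAA", "AAG")
    gc
  }))
  profile <- trna_proportions(
    c(`Phe-GAA` = 1, `Lys-TTT` = 0, `Lys-CTT` = 0)
  )
  cds_set <- make_cds_set(list(a = c("TTT", "AAA")))
  usage <- weighted_codon_usage(cds_set, c(a = 1))
  ds <- demand_supply(usage, profile, map)
  expect_true(ds$supply_zero[ds$codon == "AAA"])
  expect_true(is.na(ds$ratio[ds$codon == "AAA"]))
})

test_that("cross-stage CV uses the n-1 standard deviation", {
  v <- cross_stage_cv(list(s1 = c(x = 1, y = 2), s2 = c(x = 3, y = 2)))
  expect_equal(v$cv_percent[v$codon == "x"], 100 * sqrt(2) / 2)
  expect_equal(v$cv_percent[v$codon == "y"], 0)
  three <- cross_stage_cv(list(a = c(x = 2), b = c(x = 2), c = c(x = 2)))
  expect_equal(three$cv_percent, 0)
  zero <- cross_stage_cv(list(a = c(x = 0), b = c(x = 0)))
  expect_true(zero$zero_mean)
  expect_true(is.na(zero$cv_percent))
  expect_error(cross_stage_cv(list(a = c(x = 1))), "two stages")
})

test_that("count and expression TSV readers round trip generator output", {
  dir <- withr::local_tempdir()
  fix <- simulate_fixture(dir, seed = 3, n_transcripts = 12)
  counts <- read_anticodon_counts(fix$paths$anticodon_counts)
  expect_setequal(rownames(counts), names(fix$profile$proportions))
  p <- trna_proportions(counts[, "reads"])
  expect_equal(p$proportions[names(fix$profile$proportions)],
               fix$profile$proportions, tolerance = 1e-5)
  expr <- read_expression(fix$paths$expression)
  expect_equal(unname(expr[, "tpm"]), unname(fix$expression))
})
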