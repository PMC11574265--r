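test_that("CAI weights divide pooled counts by the synonymous maximum", {
  # 19 filler transcripts + 1 dominant reference transcript; with N = 20
  # the reference set is ceiling(0.05 * 20) = 1 transcript.
  filler <- stats::setNames(
    replicate(19, c("GGG"), simplify = FALSE),
    sprintf("f%02d", 1:19)
  )
  ref_codons <- c(rep("TTC", 90), rep("TTT", 10))
  cds_set <- make_cds_set(c(list(ref = ref_codons), filler))
  tpm <- stats::setNames(c(1e6, rep(1, 19)), names(cds_set))
  w <- cai_weights(cds_set, tpm)
  expect_equal(w$flavor, "CAI")
  expect_equal(unname(w$w["TTC"]), 1)
  expect_equal(unname(w$w["TTT"]), 1 / 9)
  # codons absent from the reference: 0.5 pseudo-occurrence
  expect_equal(unname(w$w["AAA"]), 0.5 / max(0.5, 0.5))  # Lys both absent
  expect_equal(unname(w$w["GGG"]), 1)  # filler-only codon, family max
  expect_true(all(w$w > 0 & w$w <= 1))
})

test_that("each synonymous family has weight 1 at its maximum", {
  cds_set <- gen_cds_set(5, n_transcripts = 30, length_range = c(200, 400))
  tpm <- stats::setNames(seq_len(30), names(cds_set))
  w <- cai_weights(cds_set, tpm)
  gc <- genetic_code()
  aa <- gc$codon_to_aa[names(w$w)]
  for (fam in split(w$w, aa)) expect_equal(max(fam), 1)
})

test_that("etAI weights are unscaled family proportions with duplication", {
  map <- build_decoding_map()
  profile <- uniform_profile()
  w <- etai_weights(profile, map)
  expect_equal(w$flavor, "etAI")
  expect_equal(unname(w$w["TTT"]), unname(w$w["TTC"]))
  expect_equal(unname(w$w["TTC"]), 1 / 45)
  expect_true(all(w$w == 1 / 45))
  # sum over Watson-Crick codons recovers the profile normalization
  asg <- map$assignments
  expect_equal(sum(w$w[asg$codon[asg$pairing == "watson_crick"]]), 1)
})

test_that("zero proportions abort unless floored", {
  map <- build_decoding_map()
  rep <- default_repertoire()
  fams <- rep$family[rep$class == "elongator"]
  counts <- stats::setNames(rep(10, length(fams)), fams)
  counts["Phe-GAA"] <- 0
  profile <- trna_proportions(counts)
  expect_error(etai_weights(profile, map), "Phe-GAA")
  w <- etai_weights(profile, map, floor_zero = TRUE)
  expect_gt(w$w[["TTC"]], 0)
  expect_equal(unname(w$w[["TTC"]]), min(profile$proportions[fams != "Phe-GAA"]) / 2)
})

test_that("etAI scale covariance: scaling proportions scales transcript scores", {
  map <- build_decoding_map()
  profile <- gen_trna_profile(4)
  w <- etai_weights(profile, map)
  cds <- make_cds("t", c("TTC", "AAA", "GGC", "CAT"))
  base <- transcript_score(cds, w$w)
  expect_equal(transcript_score(cds, w$w * 3), 3 * base)
})

test_that("geometric-mean scores: constants, hand case, permutation symmetry", {
  vals <- stats::setNames(rep(0.04, 61), genetic_code()$sense_codons)
  cds <- make_cds("t", c("AAA", "CCC", "GGG"))
  expect_equal(transcript_score(cds, vals), 0.04)
  two <- make_cds("t", c("AAA", "CCC"))
  w <- c(AAA = 1, CCC = 0.25)
  expect_equal(transcript_score(two, w), 0.5)
  perm <- make_cds("t", c("CCC", "AAA"))
  expect_equal(transcript_score(perm, w), 0.5)
  expect_error(transcript_score(two, c(AAA = 1)), "CCC")
  expect_error(transcript_score(two, c(AAA = 1, CCC = 0)), "CCC")
})

test_that("CAI of a maximal-weight-only CDS is exactly 1", {
  cds_set <- gen_cds_set(6, n_transcripts = 25, length_range = c(100, 200))
  tpm <- stats::setNames(rep(1, 25), names(cds_set))
  w <- cai_weights(cds_set, tpm)
  best <- names(w$w)[w$w == 1]
  cds <- make_cds("t", sample(best, 50, replace = TRUE))
  expect_equal(transcript_score(cds, w$w), 1)
  scores <- transcript_scores(cds_set, cai = w)
  expect_true(all(scores$cai > 0 & scores$cai <= 1))
})

test_that("decoding rates invert dwell times and reject non-positive ones", {
  expect_equal(decoding_rates(c(AAA = 2.0, CCC = 1.0)),
               c(AAA = 0.5, CCC = 1.0))
  expect_error(decoding_rates(c(AAA = 0)), "positive")
  expect_error(decoding_rates(c(AAA = -1)), "positive")
})

test_that("wobble-vs-WC comparison pairs 16 families and tests rank sums", {
  map <- build_decoding_map()
  profile <- gen_trna_profile(8)
  dt <- gen_dwell_times(profile, map, beta = 1, sigma = 0.2, seed = 9)
  res <- wobble_vs_wc_dt(dt, map)
  expect_equal(nrow(res$pairs), 16L)
  expect_equal(sum(res$pairs$inosine), 8L)
  # both pair members share a family, hence identical noiseless supply term
  expect_true(all(res$pairs$dt_wc > 0 & res$pairs$dt_wobble > 0))
  expect_true(res$test$p >= 0 && res$test$p <= 1)
  # identical groups: p = 1
  dt_flat <- stats::setNames(rep(1, 61), genetic_code()$sense_codons)
  flat <- wobble_vs_wc_dt(dt_flat, map)
  expect_equal(flat$test$p, 1)
  expect_error(wobble_vs_wc_dt(dt[names(dt) != "TTT"], map),
               "missing dwell times")
})

test_that("weights and dwell-time TSVs round trip", {
  map <- build_decoding_map()
  w <- etai_weights(gen_trna_profile(10), map)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w, tsv)
  back <- read_weights(tsv)
  expect_equal(back$flavor, "etAI")
  expect_equal(back$w, w$w)

  dtsv <- withr::local_tempfile(fileext = ".tsv")
  dt <- gen_dwell_times(gen_trna_profile(10), map, seed = 11)
  write.table(data.frame(codon = names(dt), dt = unname(dt)), dtsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_dwell_times(dtsv), dt)
})
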