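test_that("noiseless exponential decay recovers slope, k and half-life", {
  t <- 0:8
  fit <- fit_half_life(t, 100 * 2^(-t / 2), "t1")
  expect_equal(fit$status, "retained")
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$k, 0.5 * log(2), tolerance = 1e-12)
  expect_equal(fit$half_life, 2.0, tolerance = 1e-12)
  expect_lt(fit$fit_p, 1e-10)
})

test_that("filters apply in order: low t0, nondecreasing, poor fit", {
  t <- 0:8
  up <- fit_half_life(t, 100 * 2^(+t / 2), "up")
  expect_equal(up$status, "filtered_nondecreasing")
  expect_equal(up$slope, 0)
  expect_true(is.na(up$half_life))

  low <- fit_half_life(t, 5 * 2^(-t / 2), "low")
  expect_equal(low$status, "filtered_low_t0")

  # low t0 masks the nondecreasing check
  lowup <- fit_half_life(t, 5 * 2^(+t / 2), "lowup")
  expect_equal(lowup$status, "filtered_low_t0")

  set.seed(1)
  noisy <- fit_half_life(t, 100 * exp(rnorm(9, 0, 0.02)) *
                           2^(-0.001 * t), "flatnoise")
  expect_true(noisy$status %in% c("filtered_poor_fit",
                                  "filtered_nondecreasing"))

  expect_error(fit_half_life(c(0, 1), c(100, 50)), "3 usable")
  expect_error(fit_half_life(c(0, 1, 1), c(100, 50, 25)),
               "strictly increasing")
})

test_that("the t0 threshold is exclusive: TPM must exceed 10", {
  t <- 0:8
  at10 <- fit_half_life(t, 10 * 2^(-t / 2))
  expect_equal(at10$status, "filtered_low_t0")
  above <- fit_half_life(t, 10.01 * 2^(-t / 2))
  expect_equal(above$status, "retained")
})

test_that("zero TPM truncates the series at the first zero", {
  t <- 0:8
  tpm <- 100 * 2^(-t / 2)
  tpm[6:9] <- 0
  fit <- fit_half_life(t, tpm, "z")
  expect_equal(fit$n_points, 5L)
  expect_equal(fit$half_life, 2.0, tolerance = 1e-9)
  tpm2 <- c(100, 50, 0, 0, 0, 0, 0, 0, 0)
  expect_error(fit_half_life(t, tpm2), "3 usable")
})

test_that("batch fitting returns one row per fittable transcript", {
  cds <- gen_cds_set(21, n_transcripts = 40, length_range = c(50, 150))
  truth <- synthetic_truth(seed = 5, tpm_noise_sigma = 0)
  d <- gen_decay_dataset(cds, truth)
  hl <- fit_half_lives(d$tpm)
  expect_equal(nrow(hl), 40L)
  m <- merge(hl, d$truth_half_lives, by = "transcript_id")
  retained <- m[m$status == "retained", ]
  expect_gt(nrow(retained), 30)
  expect_equal(retained$half_life.x, retained$half_life.y,
               tolerance = 1e-9)
})

test_that("CSC equals the Pearson correlation and classifies by sign + p", {
  # transcripts whose AAA frequency is exactly proportional to half-life
  cds_set <- make_cds_set(list(
    a = c("AAA", rep("GGG", 9)),
    b = c(rep("AAA", 2), rep("GGG", 8)),
    c = c(rep("AAA", 3), rep("GGG", 7)),
    d = c(rep("AAA", 4), rep("GGG", 6)),
    e = c(rep("AAA", 5), rep("GGG", 5)),
    f = c(rep("AAA", 6), rep("GGG", 4)),
    g = c(rep("AAA", 7), rep("GGG", 3)),
    h = c(rep("AAA", 8), rep("GGG", 2)),
    i = c(rep("AAA", 9), "GGG"),
    j = c(rep("AAA", 10))
  ))
  hl <- data.frame(
    transcript_id = names(cds_set),
    half_life = seq(0.1, 1, by = 0.1) * 10,
    status = "retained"
  )
  csc <- compute_csc(cds_set, hl)
  aaa <- csc[csc$codon == "AAA", ]
  expect_equal(aaa$csc, 1, tolerance = 1e-12)
  expect_equal(aaa$class, "stabilizing")
  ggg <- csc[csc$codon == "GGG", ]
  expect_equal(ggg$class, "destabilizing")
  # j has no GGG so GGG frequency varies; TTT never occurs: zero variance
  ttt <- csc[csc$codon == "TTT", ]
  expect_true(is.na(ttt$csc))
  expect_equal(ttt$class, "neutral")
  expect_equal(attr(csc, "n_transcripts"), 10L)
})

test_that("CSC is invariant under positive affine transforms of half-life", {
  cds_set <- gen_cds_set(31, n_transcripts = 30, length_range = c(50, 150))
  set.seed(14)
  hl <- data.frame(
    transcript_id = names(cds_set),
    half_life = runif(30, 1, 5),
    status = "retained"
  )
  a <- compute_csc(cds_set, hl)
  hl$half_life <- 3 * hl$half_life + 7
  b <- compute_csc(cds_set, hl)
  expect_equal(a$csc, b$csc, tolerance = 1e-12)
  expect_equal(a$class, b$class)
})

test_that("classification is consistent and exhaustive", {
  cds_set <- gen_cds_set(32, n_transcripts = 60, length_range = c(80, 200))
  truth <- synthetic_truth(
    seed = 6,
    codon_decay_weights = c(AAA = 0.3, CCC = 0.3),
    tpm_noise_sigma = 0.05
  )
  d <- gen_decay_dataset(cds_set, truth)
  csc <- compute_csc(cds_set, fit_half_lives(d$tpm))
  expect_true(all(csc$class %in%
                    c("stabilizing", "neutral", "destabilizing")))
  expect_equal(sum(table(csc$class)), 61L)
  expect_true(all(csc$csc >= -1 & csc$csc <= 1, na.rm = TRUE))
  expect_false(any(csc$class == "stabilizing" & csc$csc < 0, na.rm = TRUE))
  expect_false(any(csc$class == "destabilizing" & csc$csc > 0, na.rm = TRUE))
})

test_that("too few retained transcripts abort CSC", {
  cds_set <- gen_cds_set(33, n_transcripts = 5, length_range = c(30, 60))
  hl <- data.frame(transcript_id = names(cds_set),
                   half_life = runif(5, 1, 3), status = "retained")
  expect_error(compute_csc(cds_set, hl), "fewer than 10")
})

test_that("class content proportions sum to 1 and group tests run", {
  csc <- data.frame(
    codon = genetic_code()$sense_codons,
    csc = 0, p = 1,
    class = "neutral",
    stringsAsFactors = FALSE
  )
  csc$class[csc$codon %in% c("GCC", "GGC")] <- "stabilizing"
  csc$class[csc$codon %in% c("AAA", "TTT")] <- "destabilizing"
  class(csc) <- c("csc_table", "data.frame")

  cds_set <- make_cds_set(list(
    s1 = rep(c("GCC", "GGC"), 10),
    s2 = c(rep("GCC", 15), rep("AAA", 5)),
    u1 = rep(c("AAA", "TTT"), 10),
    u2 = c(rep("TTT", 15), rep("GGG", 5))
  ))
  groups <- c(s1 = "stable", s2 = "stable", u1 = "unstable", u2 = "unstable")
  res <- transcript_class_codon_content(cds_set, csc, groups)
  sums <- rowSums(res$content[, c("stabilizing", "neutral", "destabilizing")])
  expect_equal(unname(sums), rep(1, 4))
  expect_equal(res$content$stabilizing[res$content$transcript_id == "s1"], 1)
  expect_equal(nrow(res$tests), 3L)  # one pair x three classes
  expect_true(all(res$tests$p >= 0 & res$tests$p <= 1))
  # groups with identical content distributions: p = 1 (exact rank test)
  twin_set <- make_cds_set(list(a1 = rep("GCC", 10), a2 = rep("GCC", 10),
                                b1 = rep("GCC", 10), b2 = rep("GCC", 10)))
  twin <- transcript_class_codon_content(
    twin_set, csc,
    c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  )
  expect_true(all(twin$tests$p == 1))
  expect_error(
    transcript_class_codon_content(cds_set, csc, c(ghost = "stable")),
    "missing"
  )
})
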