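# Deterministic generators emulating the statistical structure of the
# measured inputs: Dirichlet-like anticodon profiles, dwell times
# anti-correlated with tRNA supply, CDS sets with controlled codon bias, and
# exponential decay time-courses whose rates depend on codon content.

#' Generate a synthetic tRNA anticodon profile
#'
#' Proportions drawn from a symmetric Dirichlet distribution (gamma draws
#' normalized to sum 1). As concentration grows the profile approaches the
#' uniform 1/n profile; small concentrations give skewed pools.
#'
#' @param seed integer seed.
#' @param families family names; defaults to the 45 elongator families of
#'   [default_repertoire()].
#' @param concentration Dirichlet concentration parameter (> 0), default 5.
#' @param label profile label.
#' @return A `trna_profile`.
#' @export
gen_trna_profile <- function(seed, families = NULL, concentration = 5,
                             label = "synthetic") {
  if (is.null(families)) {
    rep <- default_repertoire()
    families <- rep$family[rep$class == "elongator"]
  }
  n <- length(families)
  if (n < 2L) stop("need at least 2 families")
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0")
  }
  g <- with_seed(seed, stats::rgamma(n, shape = concentration, rate = 1))
  # gamma draws of 0 (possible only for tiny shape) would break positivity
  if (any(g <= 0)) g <- g + .Machine$double.xmin
  new_trna_profile(stats::setNames(g / sum(g), families), label)
}

#' Generate dwell times anti-correlated with tRNA supply
#'
#' dt(codon) = supply(codon)^(-beta) * lognormal(0, sigma) noise, then
#' normalized to geometric mean 1 across codons. With beta > 0 codons served
#' by abundant tRNAs are decoded fast (low dwell time), mirroring the
#' anti-correlation between A-site dwell times and cognate tRNA levels.
#'
#' @param profile a `trna_profile` covering the map's families.
#' @param map a `decoding_map`.
#' @param beta supply-coupling exponent (>= 0).
#' @param sigma lognormal noise sigma (>= 0).
#' @param seed integer seed.
#' @return Named numeric vector of dwell times over the 61 sense codons.
#' @export
gen_dwell_times <- function(profile, map, beta = 1, sigma = 0.3, seed = 1) {
  stopifnot(inherits(profile, "trna_profile"), inherits(map, "decoding_map"),
            beta >= 0, sigma >= 0)
  asg <- map$assignments
  supply <- profile$proportions[asg$family]
  if (any(is.na(supply)) || any(supply == 0)) {
    stop("zero or missing supply for some codons")
  }
  noise <- with_seed(seed, stats::rlnorm(nrow(asg), 0, sigma))
  dt <- supply^(-beta) * noise
  dt <- dt / exp(mean(log(dt)))
  stats::setNames(unname(dt), asg$codon)
}

#' Generate a set of valid coding sequences with controlled codon bias
#'
#' Each record is ATG + L sampled sense codons + a sampled stop codon, so
#' every record passes [validate_cds()] by construction (stop codons are
#' never sampled internally). Per-transcript codon sampling weights are
#' drawn from a Dirichlet centred on `codon_bias` with concentration
#' `dispersion`, so transcripts differ in codon composition the way real
#' transcriptomes do; `dispersion = Inf` gives every transcript the same
#' weights.
#'
#' @param seed integer seed.
#' @param n_transcripts number of CDS to generate.
#' @param length_range inclusive range of internal codon counts (start and
#'   stop excluded), default c(100, 500).
#' @param codon_bias named sampling weights over sense codons; defaults to
#'   uniform. Stops are rejected.
#' @param dispersion Dirichlet concentration scaling for per-transcript
#'   weights (default 30).
#' @return Named list of valid `coding_sequence` objects (`tx0001`, ...).
#' @export
gen_cds_set <- function(seed, n_transcripts = 100,
                        length_range = c(100, 500), codon_bias = NULL,
                        dispersion = 30) {
  code <- genetic_code()
  if (is.null(codon_bias)) {
    codon_bias <- stats::setNames(rep(1, length(code$sense_codons)),
                                  code$sense_codons)
  }
  if (any(names(codon_bias) %in% code$stop_set)) {
    stop("stop codons cannot receive sampling weight")
  }
  bad <- setdiff(names(codon_bias), code$sense_codons)
  if (length(bad) > 0L) stop("unknown codons in bias: ",
                             paste(bad, collapse = ", "))
  if (any(codon_bias < 0) || sum(codon_bias) <= 0) {
    stop("degenerate codon bias")
  }
  if (length_range[1L] < 1L) stop("CDS needs at least 1 internal codon")
  p0 <- codon_bias / sum(codon_bias)

  with_seed(seed, {
    out <- vector("list", n_transcripts)
    ids <- sprintf("tx%04d", seq_len(n_transcripts))
    for (i in seq_len(n_transcripts)) {
      len <- sample(seq(length_range[1L], length_range[2L]), 1L)
      p <- if (is.finite(dispersion)) {
        g <- stats::rgamma(length(p0), shape = p0 * dispersion, rate = 1)
        if (sum(g) == 0) p0 else g / sum(g)
      } else p0
      body <- sample(names(p0), len, replace = TRUE, prob = p)
      stop_codon <- sample(code$stop_set, 1L)
      out[[i]] <- validate_cds(
        ids[[i]], paste(c("ATG", body, stop_codon), collapse = "")
      )
    }
    stats::setNames(out, ids)
  })
}

#' Write a CDS set to FASTA
#'
#' @param cds_set list of `coding_sequence` objects.
#' @param path output FASTA path.
#' @export
write_cds_fasta <- function(cds_set, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(cds_set, `[[`, character(1), "seq")
  )
  names(seqs) <- vapply(cds_set, `[[`, character(1), "transcript_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Ground-truth parameter set for synthetic decay data
#'
#' @param seed integer seed.
#' @param codon_decay_weights named numeric, per-unit-frequency contribution
#'   of each codon to the decay constant (/h). Defaults to no codon effect.
#' @param k0 baseline decay constant (/h), default 0.2 (half-life ~3.5 h,
#'   typical of maternal transcripts cleared over the first 8 h).
#' @param tpm_noise_sigma lognormal measurement noise on TPM, default 0.1.
#' @param times time grid in hours, default 0..8 hourly.
#' @param tpm0_meanlog,tpm0_sdlog lognormal parameters of the initial TPM,
#'   defaults log(100) and 0.5.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1, codon_decay_weights = NULL, k0 = 0.2,
                            tpm_noise_sigma = 0.1, times = 0:8,
                            tpm0_meanlog = log(100), tpm0_sdlog = 0.5) {
  if (is.null(codon_decay_weights)) codon_decay_weights <- numeric(0)
  stopifnot(k0 > 0, tpm_noise_sigma >= 0, 0 %in% times,
            !is.unsorted(times, strictly = TRUE))
  structure(
    list(seed = as.integer(seed), codon_decay_weights = codon_decay_weights,
         k0 = k0, tpm_noise_sigma = tpm_noise_sigma, times = times,
         tpm0_meanlog = tpm0_meanlog, tpm0_sdlog = tpm0_sdlog),
    class = "synthetic_truth"
  )
}

#' Graded codon decay weights from tRNA supply
#'
#' Derives per-codon decay weights from the tRNA profile as
#' lambda * scale * (-log supply), the synthetic analogue of decay driven by
#' slow decoding: codons served by rare tRNAs (low supply, high dwell time)
#' destabilize more. `lambda = 0` switches codon-dependent decay off.
#'
#' @param profile a `trna_profile`.
#' @param map a `decoding_map`.
#' @param lambda coupling strength in [0, 1].
#' @param scale overall magnitude (/h per unit -log supply), default 0.15.
#' @return Named numeric vector over the 61 sense codons.
#' @export
supply_coupled_weights <- function(profile, map, lambda, scale = 0.15) {
  stopifnot(lambda >= 0)
  asg <- map$assignments
  supply <- profile$proportions[asg$family]
  if (any(is.na(supply)) || any(supply <= 0)) stop("invalid supply")
  stats::setNames(lambda * scale * (-log(unname(supply))), asg$codon)
}

#' Generate exponential decay time-courses with codon-dependent rates
#'
#' Each transcript decays with constant k_i = k0 + sum_c w(c) * freq_i(c)
#' (frequencies from [codon_frequencies()] defaults), so codons with
#' positive weight destabilize transcripts that use them. Observed TPM is
#' TPM_i(0) * 2^(-t * k_i / ln 2) times multiplicative lognormal noise.
#'
#' @param cds_set named list of valid `coding_sequence` objects.
#' @param truth a `synthetic_truth`.
#' @return List with `tpm` (matrix transcripts x times, column names =
#'   hours) and `truth_half_lives` (data frame `transcript_id`, `k`,
#'   `half_life`).
#' @export
gen_decay_dataset <- function(cds_set, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- names(cds_set)
  w <- truth$codon_decay_weights
  k <- vapply(cds_set, function(cds) {
    freq <- codon_frequencies(cds)
    shared <- intersect(names(w), names(freq))
    truth$k0 + sum(w[shared] * freq[shared])
  }, numeric(1))
  if (any(k <= 0)) {
    stop("non-positive decay constant for: ",
         paste(ids[k <= 0], collapse = ", "))
  }
  times <- truth$times
  tpm <- with_seed(truth$seed, {
    tpm0 <- stats::rlnorm(length(ids), truth$tpm0_meanlog, truth$tpm0_sdlog)
    clean <- outer(k, times, function(ki, t) 2^(-t * ki / log(2)))
    noise <- matrix(
      stats::rlnorm(length(ids) * length(times), 0, truth$tpm_noise_sigma),
      nrow = length(ids)
    )
    tpm0 * clean * noise
  })
  dimnames(tpm) <- list(ids, as.character(times))
  list(
    tpm = tpm,
    truth_half_lives = data.frame(
      transcript_id = ids, k = unname(k), half_life = log(2) / unname(k),
      stringsAsFactors = FALSE
    )
  )
}

#' Materialize a complete synthetic fixture directory
#'
#' Writes, under `dir`: a CDS FASTA, an anticodon count TSV, a dwell-time
#' TSV, an expression TSV, a decay time-course TSV, and a truth manifest TSV
#' (ground-truth half-lives plus the decay weights) — the exact file
#' dialects consumed by the package's readers.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @param n_transcripts number of CDS.
#' @param lambda supply-decay coupling for [supply_coupled_weights()].
#' @param beta,dt_sigma dwell-time generator parameters.
#' @param tpm_noise_sigma decay time-course noise.
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects.
#' @export
simulate_fixture <- function(dir, seed = 1, n_transcripts = 200, lambda = 1,
                             beta = 1, dt_sigma = 0.3,
                             tpm_noise_sigma = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- build_decoding_map()
  profile <- gen_trna_profile(seed)
  cds_set <- gen_cds_set(seed + 1L, n_transcripts = n_transcripts)
  dt <- gen_dwell_times(profile, map, beta = beta, sigma = dt_sigma,
                        seed = seed + 2L)
  truth <- synthetic_truth(
    seed = seed + 3L,
    codon_decay_weights = supply_coupled_weights(profile, map, lambda),
    tpm_noise_sigma = tpm_noise_sigma
  )
  decay <- gen_decay_dataset(cds_set, truth)
  expr <- with_seed(seed + 4L, stats::setNames(
    stats::rlnorm(n_transcripts, log(50), 1), names(cds_set)
  ))

  paths <- list(
    cds = file.path(dir, "cds.fa"),
    anticodon_counts = file.path(dir, "anticodon_counts.tsv"),
    dwell_times = file.path(dir, "dwell_times.tsv"),
    expression = file.path(dir, "expression.tsv"),
    time_course = file.path(dir, "time_course.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_cds_fasta(cds_set, paths$cds)
  # counts on an arbitrary library-size scale; proportions are scale-free
  counts <- round(profile$proportions * 1e6)
  utils::write.table(
    data.frame(family = names(counts), reads = unname(counts)),
    paths$anticodon_counts, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(codon = names(dt), dt = unname(dt)),
    paths$dwell_times, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(transcript_id = names(expr), tpm = unname(expr)),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE
  )
  tc <- data.frame(transcript_id = rownames(decay$tpm), decay$tpm,
                   check.names = FALSE)
  utils::write.table(tc, paths$time_course, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_tab <- decay$truth_half_lives
  truth_tab$seed <- seed
  truth_tab$lambda <- lambda
  utils::write.table(truth_tab, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(paths = paths, map = map, profile = profile,
                 cds_set = cds_set, dwell_times = dt, truth = truth,
                 decay = decay, expression = expr))
}
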