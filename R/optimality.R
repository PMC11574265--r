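# Per-codon relative adaptiveness (CAI, etAI), decoding rates, and
# per-transcript geometric-mean scores.

#' CAI relative adaptiveness weights
#'
#' Sharp-Li codon adaptation index weights computed from a reference set of
#' highly expressed genes: the top `ceiling(top_fraction * N)` transcripts by
#' mean TPM (ties broken by lexicographic transcript_id). Codon counts are
#' pooled over the reference; within each synonymous family,
#' w(codon) = count / max(count). Codons never observed in the reference
#' receive a 0.5 pseudo-occurrence before division, so all weights are in
#' (0, 1] and each family's most-used codon has weight 1.
#'
#' @param cds_set named list of valid `coding_sequence` objects.
#' @param tpm named numeric vector of mean TPM, or replicate matrix.
#' @param top_fraction fraction of transcripts forming the reference set
#'   (default 0.05, the top 5% most expressed).
#' @return An object of class `adaptiveness_weights` with `flavor = "CAI"`,
#'   `w` (named numeric over the 61 sense codons) and `reference_label`
#'   describing the reference set.
#' @export
cai_weights <- function(cds_set, tpm, top_fraction = 0.05) {
  if (is.matrix(tpm)) tpm <- rowMeans(tpm)
  tpm <- tpm[names(tpm) %in% names(cds_set)]
  n <- length(tpm)
  n_ref <- ceiling(top_fraction * n)
  if (n_ref < 1L || n == 0L) stop("empty CAI reference set")
  ord <- order(-tpm, names(tpm))
  ref_ids <- names(tpm)[ord][seq_len(n_ref)]

  code <- genetic_code()
  pooled <- stats::setNames(numeric(length(code$sense_codons)),
                            code$sense_codons)
  for (id in ref_ids) {
    counts <- count_codons(cds_set[[id]])
    pooled[names(counts)] <- pooled[names(counts)] + counts
  }
  pooled[pooled == 0] <- 0.5

  w <- pooled
  for (codon in names(w)) {
    fam <- synonymous_codons(codon, code)
    w[[codon]] <- pooled[[codon]] / max(pooled[fam])
  }
  new_weights("CAI", w,
              sprintf("top %d/%d transcripts by mean TPM", n_ref, n))
}

#' etAI relative adaptiveness weights
#'
#' Expression-based tRNA adaptation index weights: each sense codon receives
#' the measured read proportion of its assigned anticodon family, with
#' wobble-decoded codons inheriting their family's full proportion
#' (duplication). No selective wobble penalties are applied and weights are
#' deliberately NOT rescaled to the maximum, so etAI tracks absolute tRNA
#' pool composition and transcript etAI values are not bounded by 1.
#'
#' @param profile a `trna_profile`.
#' @param map a `decoding_map`; every assigned family must appear in
#'   `profile`.
#' @param floor_zero replace zero family proportions by half the smallest
#'   nonzero proportion instead of erroring. Default `FALSE`: a zero weight
#'   aborts, since all cytosolic families are expected to be detected.
#' @return An `adaptiveness_weights` object with `flavor = "etAI"`.
#' @export
etai_weights <- function(profile, map, floor_zero = FALSE) {
  stopifnot(inherits(profile, "trna_profile"), inherits(map, "decoding_map"))
  asg <- map$assignments
  missing <- setdiff(asg$family, names(profile$proportions))
  if (length(missing) > 0L) {
    stop("families absent from the tRNA profile (codons ",
         paste(asg$codon[asg$family %in% missing], collapse = ", "), ")")
  }
  p <- profile$proportions
  if (any(p[unique(asg$family)] == 0)) {
    if (floor_zero) {
      fl <- min(p[p > 0]) / 2
      p[p == 0] <- fl
    } else {
      bad <- unique(asg$family)[p[unique(asg$family)] == 0]
      stop("zero tRNA proportion for families: ",
           paste(bad, collapse = ", "),
           " (set floor_zero = TRUE to floor them)")
    }
  }
  w <- stats::setNames(unname(p[asg$family]), asg$codon)
  new_weights("etAI", w, profile$label)
}

new_weights <- function(flavor, w, reference_label = "") {
  stopifnot(flavor %in% c("CAI", "etAI"), all(w >= 0))
  structure(list(flavor = flavor, w = w, reference_label = reference_label),
            class = "adaptiveness_weights")
}

#' @export
print.adaptiveness_weights <- function(x, ...) {
  cat(sprintf("<adaptiveness_weights> %s over %d codons (%s)\n",
              x$flavor, length(x$w), x$reference_label))
  invisible(x)
}

#' Write / read adaptiveness weights as TSV
#'
#' @param weights an `adaptiveness_weights` object.
#' @param path file path.
#' @return `read_weights` returns an `adaptiveness_weights` object.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "adaptiveness_weights"))
  utils::write.table(
    data.frame(codon = names(weights$w), weight = unname(weights$w),
               flavor = weights$flavor),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_weights(tab$flavor[[1L]], stats::setNames(tab$weight, tab$codon))
}

#' Geometric-mean score of a transcript
#'
#' The geometric mean, over the transcript's counted codons (start and stop
#' excluded by default, codons taken with multiplicity), of a per-codon
#' value: CAI weights, etAI weights, or decoding rates. Computed in the log
#' domain for numerical stability on long CDS.
#'
#' @param cds a valid `coding_sequence`.
#' @param per_codon named numeric vector of strictly positive per-codon
#'   values.
#' @param exclude_start,exclude_stop as in [count_codons()].
#' @return The geometric-mean score (a single number).
#' @export
transcript_score <- function(cds, per_codon, exclude_start = TRUE,
                             exclude_stop = TRUE) {
  counts <- count_codons(cds, exclude_start = exclude_start,
                         exclude_stop = exclude_stop)
  vals <- per_codon[names(counts)]
  bad <- names(counts)[is.na(vals) | vals <= 0]
  if (length(bad) > 0L) {
    stop("zero or missing per-codon value for: ",
         paste(bad, collapse = ", "))
  }
  exp(sum(counts * log(vals)) / sum(counts))
}

#' Score a CDS set with CAI, etAI and decoding rate
#'
#' @param cds_set named list of valid `coding_sequence` objects.
#' @param cai,etai `adaptiveness_weights` objects (optional).
#' @param rates named numeric vector of per-codon decoding rates (optional).
#' @return Data frame with `transcript_id`, `n_codons` and one column per
#'   supplied score (`cai`, `etai`, `decoding_rate`).
#' @export
transcript_scores <- function(cds_set, cai = NULL, etai = NULL,
                              rates = NULL) {
  out <- data.frame(
    transcript_id = names(cds_set),
    n_codons = vapply(cds_set, function(x) sum(count_codons(x)), numeric(1)),
    stringsAsFactors = FALSE
  )
  score_col <- function(per_codon) {
    vapply(cds_set, transcript_score, numeric(1), per_codon = per_codon)
  }
  if (!is.null(cai)) out$cai <- score_col(cai$w)
  if (!is.null(etai)) out$etai <- score_col(etai$w)
  if (!is.null(rates)) out$decoding_rate <- score_col(rates)
  rownames(out) <- NULL
  out
}

#' Per-codon decoding rates from dwell times
#'
#' The decoding rate of a codon is the inverse of its relative ribosome
#' A-site dwell time: rate = 1/DT.
#'
#' @param dt named numeric vector of strictly positive dwell times.
#' @return Named numeric vector of rates.
#' @export
decoding_rates <- function(dt) {
  if (any(is.na(dt)) || any(dt <= 0)) stop("dwell times must be positive")
  1 / dt
}

#' Read a dwell-time table from TSV
#'
#' @param path TSV with columns `codon`, `dt`.
#' @return Named numeric vector of dwell times.
#' @export
read_dwell_times <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "dt") %in% names(tab)))
  stats::setNames(tab$dt, normalize_seq(tab$codon))
}

#' Dwell times of Watson-Crick versus wobble codons of shared families
#'
#' For each wobble pair (two synonymous codons decoded by one anticodon
#' family) the dwell times of the Watson-Crick and the wobble-decoded codon
#' are tabulated, and the two groups are compared with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param dt named numeric vector of per-codon dwell times.
#' @param map a `decoding_map`.
#' @return List with `pairs` (data frame `family`, `dt_wc`, `dt_wobble`,
#'   `inosine`) and `test` (the [rank_tests()] result).
#' @export
wobble_vs_wc_dt <- function(dt, map) {
  stopifnot(inherits(map, "decoding_map"))
  pairs <- map$wobble_pairs
  need <- c(pairs$codon_wc, pairs$codon_wobble)
  missing <- setdiff(need, names(dt)[!is.na(dt)])
  if (length(missing) > 0L) {
    stop("missing dwell times for: ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    family = pairs$family,
    dt_wc = unname(dt[pairs$codon_wc]),
    dt_wobble = unname(dt[pairs$codon_wobble]),
    inosine = pairs$inosine,
    stringsAsFactors = FALSE
  )
  list(
    pairs = out,
    test = rank_tests(out$dt_wc, out$dt_wobble, kind = "wilcoxon_ranksum")
  )
}
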