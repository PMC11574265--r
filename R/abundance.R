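# tRNA anticodon proportions, TPM-weighted codon usage, demand vs supply.

#' tRNA anticodon family proportions
#'
#' Converts raw read counts per anticodon family into proportions of
#' tRNA-mapped reads: count / sum(counts) over the included families. By
#' default every family in `counts` is included; pass `include` to restrict
#' the denominator (e.g. to cytosolic families when the count table also
#' carries mitochondrial ones).
#'
#' @param counts named numeric vector, reads uniquely aligned per family.
#' @param include optional character vector of families to keep.
#' @param label stage/condition label.
#' @return An object of class `trna_profile`: list with `label` and
#'   `proportions` (named numeric, sums to 1).
#' @examples
#' trna_proportions(c(`Phe-GAA` = 30, `His-GTG` = 10))$proportions
#' @export
trna_proportions <- function(counts, include = NULL, label = "") {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by anticodon family")
  }
  if (any(counts < 0)) stop("negative read counts")
  if (!is.null(include)) {
    missing <- setdiff(include, names(counts))
    if (length(missing) > 0L) {
      stop("families absent from counts: ", paste(missing, collapse = ", "))
    }
    counts <- counts[include]
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero counts")
  new_trna_profile(counts / total, label)
}

new_trna_profile <- function(proportions, label = "") {
  stopifnot(!is.null(names(proportions)), all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-9)
  structure(list(label = label, proportions = proportions),
            class = "trna_profile")
}

#' @export
print.trna_profile <- function(x, ...) {
  cat(sprintf("<trna_profile> %s: %d families\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$proportions)))
  invisible(x)
}

#' Read anticodon read counts from TSV
#'
#' @param path TSV with a `family` column and one numeric column per sample.
#' @return Matrix of counts, rows = families.
#' @export
read_anticodon_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("family" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "family"), drop = FALSE])
  rownames(m) <- tab$family
  storage.mode(m) <- "double"
  m
}

#' Read a TPM expression table from TSV
#'
#' @param path TSV with a `transcript_id` column and one TPM column per
#'   sample.
#' @return Matrix of TPM, rows = transcripts.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("transcript_id" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "transcript_id"), drop = FALSE])
  rownames(m) <- tab$transcript_id
  storage.mode(m) <- "double"
  m
}

#' Expression-weighted proportional codon usage
#'
#' For each transcript the per-codon frequency (codon count divided by the
#' number of counted codons, start and stop excluded) is weighted by the
#' transcript's TPM, averaged across the stage's replicates. Weighted
#' frequencies are summed over transcripts and renormalized so the usage of
#' the tabulated sense codons sums to 1.
#'
#' @param cds_set named list of valid `coding_sequence` objects.
#' @param tpm named numeric vector (single sample or replicate mean), or a
#'   matrix of replicates (rows = transcripts) averaged arithmetically.
#' @param stage stage label.
#' @param mode `"frequency"` (default) weights per-transcript codon
#'   frequencies; `"count"` weights raw codon counts.
#' @return An object of class `codon_usage`: list with `stage`, `usage`
#'   (named numeric over the 61 sense codons, sums to 1) and `n_skipped`
#'   (expressed transcripts absent from `cds_set`).
#' @export
weighted_codon_usage <- function(cds_set, tpm, stage = "",
                                 mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  if (is.matrix(tpm)) tpm <- rowMeans(tpm)
  if (any(tpm < 0)) stop("negative TPM")
  code <- genetic_code()
  acc <- stats::setNames(numeric(length(code$sense_codons)),
                         code$sense_codons)
  missing <- setdiff(names(tpm), names(cds_set))
  if (length(missing) > 0L) {
    warning(length(missing),
            " expressed transcripts absent from the CDS set; skipped")
  }
  for (id in setdiff(names(tpm), missing)) {
    w <- tpm[[id]]
    if (w == 0) next
    counts <- count_codons(cds_set[[id]])
    vals <- if (mode == "frequency") counts / sum(counts) else counts
    acc[names(vals)] <- acc[names(vals)] + vals * w
  }
  total <- sum(acc)
  if (total <= 0) stop("no expressed transcripts with counted codons")
  structure(
    list(stage = stage, usage = acc / total, n_skipped = length(missing)),
    class = "codon_usage"
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %s: %d codons, %d transcripts skipped\n",
              if (nzchar(x$stage)) x$stage else "(unlabelled)",
              length(x$usage), x$n_skipped))
  invisible(x)
}

#' Codon demand versus tRNA anticodon supply
#'
#' Demand is the proportional usage of each codon; supply is the proportion
#' of its assigned anticodon family, with the family proportion duplicated
#' onto wobble-decoded codons. The ratio demand/supply is flagged undefined
#' (NA, `supply_zero = TRUE`) when the supply is zero.
#'
#' @param usage a `codon_usage` object.
#' @param profile a `trna_profile` covering every assigned family.
#' @param map a `decoding_map`.
#' @return Data frame with columns `codon`, `family`, `pairing`, `demand`,
#'   `supply`, `ratio`, `supply_zero`.
#' @export
demand_supply <- function(usage, profile, map) {
  stopifnot(inherits(usage, "codon_usage"), inherits(profile, "trna_profile"),
            inherits(map, "decoding_map"))
  asg <- map$assignments
  missing <- setdiff(asg$family, names(profile$proportions))
  if (length(missing) > 0L) {
    stop("families absent from the tRNA profile: ",
         paste(missing, collapse = ", "))
  }
  codons <- asg$codon
  demand <- usage$usage[codons]
  demand[is.na(demand)] <- 0
  supply <- unname(profile$proportions[asg$family])
  ratio <- ifelse(supply > 0, demand / supply, NA_real_)
  data.frame(
    codon = codons,
    family = asg$family,
    pairing = asg$pairing,
    demand = unname(demand),
    supply = supply,
    ratio = ratio,
    supply_zero = supply == 0,
    stringsAsFactors = FALSE
  )
}

#' Coefficient of variation across stages
#'
#' Per-codon CV (percent) of a quantity measured at two or more stages:
#' 100 * sd / mean, with the sample (n-1) standard deviation. Codons with a
#' zero mean are flagged (NA).
#'
#' @param values named list of stage vectors (each a named numeric over the
#'   same codons) or a matrix with one column per stage.
#' @return Data frame with columns `codon`, `mean`, `sd`, `cv_percent`,
#'   `zero_mean`.
#' @export
cross_stage_cv <- function(values) {
  if (is.list(values)) {
    keys <- Reduce(intersect, lapply(values, names))
    values <- do.call(cbind, lapply(values, function(v) v[keys]))
  }
  if (ncol(values) < 2L) stop("at least two stages required")
  m <- rowMeans(values)
  s <- apply(values, 1L, stats::sd)
  data.frame(
    codon = rownames(values),
    mean = unname(m),
    sd = unname(s),
    cv_percent = ifelse(m > 0, 100 * s / m, NA_real_),
    zero_mean = m == 0,
    stringsAsFactors = FALSE
  )
}
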