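# mRNA half-life estimation from expression time-courses and codon
# stabilization coefficients.

#' Fit an exponential-decay half-life to a TPM time-course
#'
#' Fits log2(TPM) against time (hours) by least squares with the slope
#' bounded in (-inf, 0]; for a simple linear regression the bounded solution
#' is the unconstrained slope when it is negative and 0 otherwise. The decay
#' constant is k = -slope * ln(2) per hour and the half-life t1/2 = ln(2)/k
#' = -1/slope hours. The fit p-value is the two-sided p-value of the slope
#' from the unconstrained regression.
#'
#' Transcripts are filtered in a fixed order: `filtered_low_t0` when TPM at
#' t = 0 is at or below `t0_min_tpm`; `filtered_nondecreasing` when the
#' bounded slope is 0 (expression not decreasing); `filtered_poor_fit` when
#' the fit p-value is at or above `alpha`; `retained` otherwise. Zero TPM
#' values truncate the time-course at the first zero (log2 undefined
#' beyond it).
#'
#' @param times strictly increasing time grid in hours, including 0.
#' @param tpm TPM values at each time.
#' @param transcript_id transcript identifier.
#' @param t0_min_tpm minimum TPM at t = 0 (default 10, exclusive bound).
#' @param alpha fit p-value threshold (default 0.05).
#' @return An object of class `half_life_fit`: list with `transcript_id`,
#'   `slope` (log2 units/h, <= 0), `k` (/h), `half_life` (h), `fit_p`,
#'   `status`, `n_points`. `k` and `half_life` are NA unless retained.
#' @examples
#' t <- 0:8
#' fit <- fit_half_life(t, 100 * 2^(-t / 2), "t1")
#' fit$half_life  # 2 hours
#' @export
fit_half_life <- function(times, tpm, transcript_id = "",
                          t0_min_tpm = 10, alpha = 0.05) {
  if (length(times) != length(tpm)) stop("times and tpm lengths differ")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  if (any(tpm < 0)) stop("negative TPM")

  # truncate at the first zero TPM (log2 undefined from there on)
  zero <- which(tpm == 0)
  if (length(zero) > 0L) {
    keep <- seq_len(zero[[1L]] - 1L)
    times <- times[keep]
    tpm <- tpm[keep]
  }
  if (length(times) < 3L) stop("fewer than 3 usable time points: ",
                               transcript_id)

  fit <- stats::lm(log2(tpm) ~ times)
  slope <- unname(stats::coef(fit)[[2L]])
  # noiseless fixtures fit perfectly; the p-value is then ~0, not unreliable
  fit_p <- suppressWarnings(summary(fit))$coefficients[2L, 4L]
  bounded <- min(slope, 0)

  status <-
    if (!(0 %in% times) || tpm[times == 0] <= t0_min_tpm) "filtered_low_t0"
    else if (bounded == 0) "filtered_nondecreasing"
    else if (fit_p >= alpha) "filtered_poor_fit"
    else "retained"

  k <- if (status == "retained") -bounded * log(2) else NA_real_
  structure(
    list(
      transcript_id = transcript_id,
      slope = bounded,
      k = k,
      half_life = if (status == "retained") log(2) / k else NA_real_,
      fit_p = fit_p,
      status = status,
      n_points = length(times)
    ),
    class = "half_life_fit"
  )
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("<half_life_fit> %s: %s%s\n", x$transcript_id, x$status,
              if (x$status == "retained")
                sprintf(", t1/2 = %.3g h (k = %.3g /h)", x$half_life, x$k)
              else ""))
  invisible(x)
}

#' Fit half-lives for a whole time-course table
#'
#' @param tc matrix of TPM (rows = transcripts, one column per time point)
#'   or the result of [read_time_course()].
#' @param times time grid in hours; taken from numeric column names when
#'   omitted.
#' @inheritParams fit_half_life
#' @return Data frame with one row per transcript: `transcript_id`, `slope`,
#'   `k`, `half_life`, `fit_p`, `status`. Transcripts whose time-course
#'   cannot be fitted (fewer than 3 usable points) are skipped with a
#'   warning.
#' @export
fit_half_lives <- function(tc, times = NULL, t0_min_tpm = 10, alpha = 0.05) {
  if (is.null(times)) times <- as.numeric(colnames(tc))
  if (any(is.na(times))) stop("non-numeric time grid in column names")
  rows <- vector("list", nrow(tc))
  skipped <- character(0)
  for (i in seq_len(nrow(tc))) {
    id <- rownames(tc)[[i]]
    fit <- tryCatch(
      fit_half_life(times, tc[i, ], id, t0_min_tpm = t0_min_tpm,
                    alpha = alpha),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      skipped <- c(skipped, id)
      next
    }
    rows[[i]] <- data.frame(
      transcript_id = id, slope = fit$slope, k = fit$k,
      half_life = fit$half_life, fit_p = fit$fit_p, status = fit$status,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " transcripts skipped (unfittable time-course)")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Read an expression time-course from TSV
#'
#' @param path TSV with a `transcript_id` column; remaining column names are
#'   the time grid in hours.
#' @return TPM matrix, rows = transcripts, numeric column names.
#' @export
read_time_course <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot("transcript_id" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "transcript_id"), drop = FALSE])
  rownames(m) <- tab$transcript_id
  storage.mode(m) <- "double"
  m
}

#' Codon stabilization coefficients
#'
#' The CSC of a codon is the Pearson correlation, across retained
#' transcripts, between the codon's per-transcript occurrence and the
#' transcript half-life. Occurrence is the per-transcript codon frequency by
#' default (count / counted codons, which removes CDS-length confounding); a
#' raw-count mode is provided. Codons with a significant (p < `alpha`)
#' positive correlation are classified stabilizing, significant negative
#' ones destabilizing, the remainder neutral. Codons with zero variance
#' across transcripts get an undefined (NA) CSC and class neutral.
#'
#' @param cds_set named list of valid `coding_sequence` objects.
#' @param half_lives data frame from [fit_half_lives()] (or any with
#'   `transcript_id`, `half_life`, `status`); only `status == "retained"`
#'   rows are used.
#' @param alpha significance threshold (default 0.05).
#' @param mode `"frequency"` (default) or `"count"`.
#' @param min_transcripts minimum retained transcripts (default 10).
#' @param adjust apply Benjamini-Hochberg to the p-values before
#'   classification. Default `FALSE` (unadjusted, classical CSC).
#' @return An object of class `csc_table`: data frame with `codon`, `csc`,
#'   `p` (and `q` when `adjust`), `class`, plus attribute `n_transcripts`.
#' @export
compute_csc <- function(cds_set, half_lives, alpha = 0.05,
                        mode = c("frequency", "count"),
                        min_transcripts = 10, adjust = FALSE) {
  mode <- match.arg(mode)
  hl <- half_lives[half_lives$status == "retained", , drop = FALSE]
  ids <- intersect(hl$transcript_id, names(cds_set))
  if (length(ids) < nrow(hl)) {
    stop("retained transcripts missing from the CDS set: ",
         paste(setdiff(hl$transcript_id, ids), collapse = ", "))
  }
  if (length(ids) < min_transcripts) {
    stop("fewer than ", min_transcripts, " retained transcripts")
  }
  hl <- hl[match(ids, hl$transcript_id), , drop = FALSE]

  code <- genetic_code()
  occ <- matrix(0, nrow = length(ids), ncol = length(code$sense_codons),
                dimnames = list(ids, code$sense_codons))
  for (id in ids) {
    counts <- count_codons(cds_set[[id]])
    vals <- if (mode == "frequency") counts / sum(counts) else counts
    occ[id, names(vals)] <- vals
  }

  res <- lapply(code$sense_codons, function(codon) {
    x <- occ[, codon]
    if (stats::sd(x) == 0 || stats::sd(hl$half_life) == 0) {
      return(data.frame(codon = codon, csc = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, hl$half_life, method = "pearson")
    data.frame(codon = codon, csc = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_class <- if (adjust) stats::p.adjust(out$p, method = "BH") else out$p
  if (adjust) out$q <- p_class
  out$class <- ifelse(
    is.na(out$csc) | p_class >= alpha, "neutral",
    ifelse(out$csc > 0, "stabilizing", "destabilizing")
  )
  rownames(out) <- NULL
  attr(out, "n_transcripts") <- length(ids)
  class(out) <- c("csc_table", "data.frame")
  out
}

#' Stabilizing/neutral/destabilizing codon content of transcripts
#'
#' Computes, per transcript, the proportions of counted codons that fall in
#' each CSC class (the three proportions sum to 1), and compares each class
#' proportion between every pair of transcript groups with a two-sided
#' Mann-Whitney U test.
#'
#' @param cds_set named list of valid `coding_sequence` objects.
#' @param csc a `csc_table`.
#' @param groups named character vector transcript_id -> group label.
#' @return List with `content` (data frame `transcript_id`, `group`,
#'   `stabilizing`, `neutral`, `destabilizing`) and `tests` (data frame
#'   `class`, `group1`, `group2`, `statistic`, `p`).
#' @export
transcript_class_codon_content <- function(cds_set, csc, groups) {
  stopifnot(inherits(csc, "csc_table"))
  unknown <- setdiff(names(groups), names(cds_set))
  if (length(unknown) > 0L) {
    stop("grouped transcripts missing from the CDS set: ",
         paste(unknown, collapse = ", "))
  }
  cls <- stats::setNames(csc$class, csc$codon)
  rows <- lapply(names(groups), function(id) {
    freq <- codon_frequencies(cds_set[[id]])
    codon_cls <- cls[names(freq)]
    if (any(is.na(codon_cls))) {
      stop("unclassified codons in ", id, ": ",
           paste(names(freq)[is.na(codon_cls)], collapse = ", "))
    }
    data.frame(
      transcript_id = id,
      group = unname(groups[[id]]),
      stabilizing = sum(freq[codon_cls == "stabilizing"]),
      neutral = sum(freq[codon_cls == "neutral"]),
      destabilizing = sum(freq[codon_cls == "destabilizing"]),
      stringsAsFactors = FALSE
    )
  })
  content <- do.call(rbind, rows)

  labels <- sort(unique(content$group))
  tests <- list()
  for (cl in c("stabilizing", "neutral", "destabilizing")) {
    if (length(labels) < 2L) break
    for (i in seq_len(length(labels) - 1L)) {
      for (j in seq(i + 1L, length(labels))) {
        x <- content[content$group == labels[[i]], cl]
        y <- content[content$group == labels[[j]], cl]
        rt <- rank_tests(x, y, kind = "mann_whitney")
        tests[[length(tests) + 1L]] <- data.frame(
          class = cl, group1 = labels[[i]], group2 = labels[[j]],
          statistic = rt$statistic, p = rt$p, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(content = content,
       tests = if (length(tests) > 0L) do.call(rbind, tests) else NULL)
}
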