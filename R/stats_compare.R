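# Correlation comparison, rank tests, and modification-stoichiometry
# log-odds comparison.

#' Compare two correlation coefficients with Fisher's z
#'
#' Tests the difference between two independent Pearson correlations via the
#' Fisher z-transform: z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) +
#' 1/(n2-3)), with a two-sided normal p-value. The independent-samples form
#' is used, appropriate when the two correlations come from different
#' transcript populations (e.g. two developmental stages).
#'
#' @param r1,r2 correlation coefficients, |r| < 1.
#' @param n1,n2 sample sizes, both at least 4.
#' @return List with `r1`, `n1`, `r2`, `n2`, `z_stat`, `p_two_sided`.
#' @examples
#' fisher_z_compare(0.59, 5000, 0.42, 5000)$p_two_sided
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("n must be at least 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z_stat = z,
       p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample rank tests (Mann-Whitney U / Wilcoxon rank-sum)
#'
#' Deterministic two-sided rank-sum test. For pooled sizes n1 + n2 <= 12 the
#' null distribution of U is obtained by exact enumeration of all
#' choose(n1+n2, n1) group assignments of the pooled values (ties handled
#' naturally through midranks), and p = min(1, 2 * min(P(U <= u),
#' P(U >= u))). For larger samples the normal approximation with the usual
#' tie-corrected variance is used (no continuity correction).
#'
#' The two kinds are the same test; they differ only in the reported
#' statistic: `mann_whitney` reports U for the first sample,
#' `wilcoxon_ranksum` reports the rank sum W = U + n1(n1+1)/2.
#'
#' @param x,y numeric samples.
#' @param kind `"mann_whitney"` or `"wilcoxon_ranksum"`.
#' @return List with `statistic`, `u`, `p`, `method` (`"exact"` or
#'   `"normal_approx"`), `kind`.
#' @examples
#' rank_tests(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, exact
#' @export
rank_tests <- function(x, y, kind = c("mann_whitney", "wilcoxon_ranksum")) {
  kind <- match.arg(kind)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (any(is.na(c(x, y)))) stop("NA in samples")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= 12L) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- apply(idx, 2L, function(ii) {
      sum(r[ii]) - n1 * (n1 + 1) / 2
    })
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  statistic <- if (kind == "mann_whitney") u_obs
               else u_obs + n1 * (n1 + 1) / 2
  list(statistic = statistic, u = u_obs, p = p, method = method, kind = kind)
}

#' Log odds ratio of misincorporation proportions at one site
#'
#' Forms the 2x2 table (misincorporated vs read-through, condition 1 vs
#' condition 2) and returns the natural-log odds ratio with the
#' Haldane-Anscombe 0.5 correction applied to all cells when any cell is
#' zero, together with a chi-square test with Yates continuity correction.
#'
#' @param a misincorporation count, condition 1.
#' @param c_cov coverage, condition 1.
#' @param b misincorporation count, condition 2.
#' @param d_cov coverage, condition 2.
#' @return List with `log_odds`, `chi2_p`, and the (possibly corrected)
#'   table cells.
#' @examples
#' modification_log_odds(80, 100, 20, 100)$log_odds  # log(16)
#' @export
modification_log_odds <- function(a, c_cov, b, d_cov) {
  if (a > c_cov || b > d_cov) stop("misincorporation count exceeds coverage")
  if (c_cov <= 0 || d_cov <= 0) stop("coverage must be positive")
  if (any(c(a, b) < 0)) stop("negative counts")
  cells <- c(a1 = a, a0 = c_cov - a, b1 = b, b0 = d_cov - b)
  or_cells <- cells
  if (any(cells == 0)) or_cells <- cells + 0.5
  log_odds <- log((or_cells[["a1"]] / or_cells[["a0"]]) /
                    (or_cells[["b1"]] / or_cells[["b0"]]))
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  chi2_p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  list(log_odds = log_odds, chi2_p = chi2_p, cells = cells)
}

#' Compare modification stoichiometry between two conditions
#'
#' Applies [modification_log_odds()] per site and adjusts the chi-square
#' p-values across all tested sites with Benjamini-Hochberg; sites with
#' q <= `q_max` are flagged significant.
#'
#' @param sites data frame with columns `transcript`, `position`,
#'   `misinc_1`, `coverage_1`, `misinc_2`, `coverage_2`.
#' @param q_max FDR threshold (default 0.01).
#' @return The input with added `log_odds`, `p`, `q`, `significant`.
#' @export
modification_compare <- function(sites, q_max = 0.01) {
  need <- c("transcript", "position", "misinc_1", "coverage_1",
            "misinc_2", "coverage_2")
  stopifnot(all(need %in% names(sites)))
  res <- lapply(seq_len(nrow(sites)), function(i) {
    modification_log_odds(sites$misinc_1[[i]], sites$coverage_1[[i]],
                          sites$misinc_2[[i]], sites$coverage_2[[i]])
  })
  sites$log_odds <- vapply(res, `[[`, numeric(1), "log_odds")
  sites$p <- vapply(res, `[[`, numeric(1), "chi2_p")
  sites$q <- stats::p.adjust(sites$p, method = "BH")
  sites$significant <- sites$q <= q_max
  sites
}

#' Read a modification site table from TSV
#'
#' Long format: columns `transcript`, `position`, `misinc`, `coverage`,
#' `condition` (exactly two condition labels); reshaped to the wide format
#' consumed by [modification_compare()].
#'
#' @param path TSV path.
#' @param conditions optional length-2 character vector fixing which label
#'   is condition 1; defaults to sorted order.
#' @return Wide data frame for [modification_compare()].
#' @export
read_modification_sites <- function(path, conditions = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "position", "misinc", "coverage", "condition")
  stopifnot(all(need %in% names(tab)))
  if (is.null(conditions)) conditions <- sort(unique(tab$condition))
  if (length(conditions) != 2L) stop("exactly two conditions required")
  c1 <- tab[tab$condition == conditions[[1L]], ]
  c2 <- tab[tab$condition == conditions[[2L]], ]
  key1 <- paste(c1$transcript, c1$position)
  key2 <- paste(c2$transcript, c2$position)
  common <- intersect(key1, key2)
  c1 <- c1[match(common, key1), ]
  c2 <- c2[match(common, key2), ]
  data.frame(
    transcript = c1$transcript, position = c1$position,
    misinc_1 = c1$misinc, coverage_1 = c1$coverage,
    misinc_2 = c2$misinc, coverage_2 = c2$coverage,
    stringsAsFactors = FALSE
  )
}
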