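# Genetic-code tables, CDS validation and codon counting.

#' The standard genetic code
#'
#' Returns the standard nuclear genetic code as used throughout the package:
#' 64 DNA-alphabet codons, of which 61 are sense codons and 3 (TAA, TAG, TGA)
#' are stops.
#'
#' @return A list with components `codon_to_aa` (named character vector of
#'   length 64, one-letter amino-acid symbols, `"*"` for stop), `stop_set`
#'   (character vector of the 3 stop codons) and `sense_codons` (character
#'   vector of the 61 non-stop codons, alphabetical order).
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' @export
genetic_code <- function() {
  codon_to_aa <- as.character(Biostrings::GENETIC_CODE)
  names(codon_to_aa) <- names(Biostrings::GENETIC_CODE)
  stop_set <- names(codon_to_aa)[codon_to_aa == "*"]
  list(
    codon_to_aa = codon_to_aa,
    stop_set = sort(stop_set),
    sense_codons = sort(names(codon_to_aa)[codon_to_aa != "*"])
  )
}

#' Synonymous codons of a codon
#'
#' @param codon a sense codon (DNA alphabet).
#' @param code genetic code, as from [genetic_code()].
#' @return Character vector of all sense codons encoding the same amino acid.
#' @keywords internal
synonymous_codons <- function(codon, code = genetic_code()) {
  aa <- code$codon_to_aa[[codon]]
  sort(names(code$codon_to_aa)[code$codon_to_aa == aa & code$codon_to_aa != "*"])
}

# Normalize a nucleotide string: uppercase, U -> T.
normalize_seq <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

split_codons <- function(seq) {
  substring(seq, seq(1L, nchar(seq), by = 3L), seq(3L, nchar(seq), by = 3L))
}

#' Validate a coding sequence
#'
#' Applies the CDS filters used to build a trusted reference transcriptome:
#' the sequence must start with ATG, end with a stop codon (TAA/TAG/TGA),
#' have a length that is a multiple of three, contain no ambiguous bases, and
#' contain no stop codon before the terminal one. `U` is accepted on input
#' and normalized to `T`; matching is case-insensitive.
#'
#' Failures are reported as the first failing check in the fixed order
#' `bad_length`, `no_start`, `no_stop`, `ambiguous_base`, `internal_stop`.
#'
#' @param transcript_id transcript identifier.
#' @param seq nucleotide string.
#' @return An object of class `coding_sequence`: a list with `transcript_id`,
#'   `seq` (normalized), `codons` (triplet decomposition; populated only when
#'   the length is a multiple of three), `valid` and `reject_reason` (one of
#'   `"none"`, `"bad_length"`, `"no_start"`, `"no_stop"`, `"ambiguous_base"`,
#'   `"internal_stop"`).
#' @examples
#' validate_cds("t1", "ATGAAATAA")$valid        # TRUE
#' validate_cds("t2", "ATGAAA")$reject_reason    # "no_stop"
#' @export
validate_cds <- function(transcript_id, seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("empty sequence")
  }
  seq <- normalize_seq(seq)
  code <- genetic_code()
  n <- nchar(seq)

  codons <- if (n %% 3L == 0L) split_codons(seq) else character(0)

  reason <- "none"
  if (n %% 3L != 0L) {
    reason <- "bad_length"
  } else if (codons[1L] != "ATG") {
    reason <- "no_start"
  } else if (!codons[length(codons)] %in% code$stop_set) {
    reason <- "no_stop"
  } else if (grepl("[^ACGT]", seq)) {
    reason <- "ambiguous_base"
  } else if (any(codons[-length(codons)] %in% code$stop_set)) {
    reason <- "internal_stop"
  }

  structure(
    list(
      transcript_id = transcript_id,
      seq = seq,
      codons = codons,
      valid = reason == "none",
      reject_reason = reason
    ),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(
    sprintf(
      "<coding_sequence> %s: %d nt, %s\n", x$transcript_id, nchar(x$seq),
      if (x$valid) "valid" else paste0("invalid (", x$reject_reason, ")")
    )
  )
  invisible(x)
}

#' Count codons in a validated CDS
#'
#' Counts occurrences of each sense codon. By default the start ATG and the
#' terminal stop codon are excluded, so internal ATG codons are counted as
#' elongator Met while the initiator is kept out of per-transcript codon
#' statistics.
#'
#' @param cds a valid `coding_sequence` from [validate_cds()].
#' @param exclude_start drop the first (ATG) codon. Default `TRUE`.
#' @param exclude_stop drop the terminal stop codon. Default `TRUE`.
#' @return Named integer vector of counts over the codons observed.
#' @examples
#' cds <- validate_cds("t", "ATGATGTAA")
#' count_codons(cds)  # c(ATG = 1): internal ATG kept, start excluded
#' @export
count_codons <- function(cds, exclude_start = TRUE, exclude_stop = TRUE) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (!cds$valid) {
    stop("cannot count codons of an invalid CDS (", cds$reject_reason, "): ",
         cds$transcript_id)
  }
  codons <- cds$codons
  if (exclude_start) codons <- codons[-1L]
  if (exclude_stop) codons <- codons[-length(codons)]
  counts <- table(codons)
  stats::setNames(as.integer(counts), names(counts))
}

#' Per-transcript codon frequencies
#'
#' Codon counts normalized to proportions of the counted codons.
#'
#' @inheritParams count_codons
#' @return Named numeric vector summing to 1.
#' @export
codon_frequencies <- function(cds, exclude_start = TRUE, exclude_stop = TRUE) {
  counts <- count_codons(cds, exclude_start = exclude_start,
                         exclude_stop = exclude_stop)
  counts / sum(counts)
}

#' Select the principal isoform among scored candidates
#'
#' The highest-scoring transcript wins; score ties are broken by CDS length
#' (longest wins); remaining ties are broken by a seeded uniform draw so the
#' choice is reproducible.
#'
#' @param candidates data frame with columns `transcript_id`, `score`,
#'   `length`.
#' @param seed integer seed for the tie-breaking draw.
#' @return The selected `transcript_id`.
#' @export
select_principal_isoform <- function(candidates, seed = 1L) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("empty candidate list")
  }
  stopifnot(all(c("transcript_id", "score", "length") %in% names(candidates)))
  best <- candidates[candidates$score == max(candidates$score), , drop = FALSE]
  best <- best[best$length == max(best$length), , drop = FALSE]
  if (nrow(best) == 1L) {
    return(best$transcript_id[[1L]])
  }
  ids <- sort(best$transcript_id)
  with_seed(seed, ids[[sample.int(length(ids), 1L)]])
}

#' GC classification of a codon
#'
#' @param codon a sense codon (DNA alphabet; `U` accepted).
#' @return List with `gc3` (`TRUE` iff the third base is G or C) and
#'   `gc_percent` (fraction of G/C bases among the three).
#' @examples
#' classify_codon_gc("GCA")  # gc3 FALSE, gc_percent 2/3
#' @export
classify_codon_gc <- function(codon) {
  codon <- normalize_seq(codon)
  code <- genetic_code()
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("malformed codon: ", codon)
  }
  if (codon %in% code$stop_set) {
    stop("stop codon has no GC3 classification: ", codon)
  }
  bases <- strsplit(codon, "")[[1L]]
  list(
    gc3 = bases[3L] %in% c("G", "C"),
    gc_percent = sum(bases %in% c("G", "C")) / 3
  )
}

#' Read coding sequences from a FASTA file
#'
#' Each record ID (up to the first whitespace) becomes the transcript_id and
#' every record is passed through [validate_cds()].
#'
#' @param path FASTA file of CDS nucleotide sequences.
#' @return Named list of `coding_sequence` objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    validate_cds(ids[[i]], as.character(seqs[[i]]))
  })
  stats::setNames(out, ids)
}

#' Keep only the valid CDS of a set
#'
#' @param cds_set list of `coding_sequence` objects.
#' @param warn warn with the number dropped.
#' @return The valid subset.
#' @export
valid_cds <- function(cds_set, warn = TRUE) {
  ok <- vapply(cds_set, function(x) isTRUE(x$valid), logical(1))
  if (warn && any(!ok)) {
    warning(sum(!ok), " invalid CDS dropped")
  }
  cds_set[ok]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
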