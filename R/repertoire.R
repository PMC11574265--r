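# Anticodon repertoires and the wobble-aware codon -> anticodon decoding map.

#' Default zebrafish cytosolic anticodon repertoire
#'
#' The 47 cytosolic tRNA anticodon families of the zebrafish nuclear genome:
#' 45 elongator families plus the initiator Met (CAT) and selenocysteine
#' (TCA) families. Anticodons are written 5'->3' in the DNA alphabet. The
#' eight families carrying inosine at position 34 are those with an A34
#' anticodon (Ala-AGC, Arg-ACG, Ile-AAT, Leu-AAG, Pro-AGG, Ser-AGA, Thr-AGT,
#' Val-AAC).
#'
#' @return Data frame with columns `amino_acid` (three-letter code, `iMet`
#'   and `SeC` for the non-elongator families), `anticodon`, `class`
#'   (`elongator`, `initiator` or `selenocysteine`).
#' @examples
#' rep <- default_repertoire()
#' nrow(rep)                                  # 47
#' sum(rep$class == "elongator")              # 45
#' @export
default_repertoire <- function() {
  el <- c(
    Ala = "AGC,CGC,TGC",
    Arg = "ACG,CCG,TCG,CCT,TCT",
    Asn = "GTT",
    Asp = "GTC",
    Cys = "GCA",
    Gln = "CTG,TTG",
    Glu = "CTC,TTC",
    Gly = "GCC,CCC,TCC",
    His = "GTG",
    Ile = "AAT,TAT",
    Leu = "AAG,CAG,TAG,CAA,TAA",
    Lys = "CTT,TTT",
    Met = "CAT",
    Phe = "GAA",
    Pro = "AGG,CGG,TGG",
    Ser = "AGA,CGA,TGA,GCT",
    Thr = "AGT,CGT,TGT",
    Trp = "CCA",
    Tyr = "GTA",
    Val = "AAC,CAC,TAC"
  )
  acs <- strsplit(el, ",", fixed = TRUE)
  out <- data.frame(
    amino_acid = rep(names(acs), lengths(acs)),
    anticodon = unlist(acs, use.names = FALSE),
    class = "elongator",
    stringsAsFactors = FALSE
  )
  out <- rbind(
    out,
    data.frame(amino_acid = "iMet", anticodon = "CAT", class = "initiator"),
    data.frame(amino_acid = "SeC", anticodon = "TCA", class = "selenocysteine")
  )
  rownames(out) <- NULL
  validate_repertoire(out)
}

validate_repertoire <- function(rep) {
  stopifnot(all(c("amino_acid", "anticodon", "class") %in% names(rep)))
  rep$anticodon <- normalize_seq(rep$anticodon)
  key <- paste(rep$anticodon, rep$class)
  if (anyDuplicated(key)) {
    stop("duplicate anticodon families: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(nchar(rep$anticodon) != 3L) || any(grepl("[^ACGT]", rep$anticodon))) {
    stop("malformed anticodon in repertoire")
  }
  rep$family <- family_label(rep$amino_acid, rep$anticodon)
  rep
}

#' Family label for an (amino acid, anticodon) pair, e.g. `"Phe-GAA"`.
#' @param amino_acid amino-acid labels.
#' @param anticodon anticodon strings.
#' @return Character vector of labels.
#' @export
family_label <- function(amino_acid, anticodon) {
  paste0(amino_acid, "-", anticodon)
}

#' Read an anticodon repertoire from TSV
#'
#' @param path TSV with columns `amino_acid`, `anticodon`, `class`.
#' @return Validated repertoire data frame (adds a `family` column).
#' @export
read_repertoire <- function(path) {
  rep <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_repertoire(rep)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build the wobble-aware codon decoding map
#'
#' Assigns each of the 61 sense codons to exactly one anticodon family.
#' A codon whose reverse complement matches an elongator anticodon is
#' Watson-Crick decoded by that family. Codons left uncovered are assigned
#' by the two wobble rules used for vertebrate cytosolic tRNAs:
#' a G34 family additionally decodes the U-ending synonymous codon, and an
#' A34 (inosine) family additionally decodes the C-ending synonymous codon.
#' Each such family therefore decodes a pair of synonymous codons and its
#' abundance is duplicated onto the wobble-decoded partner. Initiator Met
#' and selenocysteine families take no sense-codon assignments (the
#' elongator Met-CAT family decodes ATG).
#'
#' @param repertoire repertoire data frame, as [default_repertoire()].
#' @param code genetic code from [genetic_code()].
#' @return An object of class `decoding_map`: list with `assignments`
#'   (data frame `codon`, `amino_acid`, `anticodon`, `family`, `pairing`)
#'   and `wobble_pairs` (data frame `family`, `codon_wc`, `codon_wobble`,
#'   `inosine`).
#' @examples
#' map <- build_decoding_map()
#' nrow(map$wobble_pairs)  # 16
#' @export
build_decoding_map <- function(repertoire = default_repertoire(),
                               code = genetic_code()) {
  rep <- validate_repertoire(repertoire)
  el <- rep[rep$class == "elongator", , drop = FALSE]
  el$wc_codon <- revcomp(el$anticodon)

  sense <- code$sense_codons
  assign <- data.frame(
    codon = sense,
    amino_acid = NA_character_,
    anticodon = NA_character_,
    family = NA_character_,
    pairing = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(assign) <- sense

  # Watson-Crick assignments: full reverse complementarity, amino acid must
  # agree between the genetic code and the family (guards bad repertoires).
  for (i in seq_len(nrow(el))) {
    codon <- el$wc_codon[[i]]
    if (!codon %in% sense) next
    if (aa3(code$codon_to_aa[[codon]]) != el$amino_acid[[i]]) {
      stop("repertoire family ", el$family[[i]],
           " is not synonymous with its Watson-Crick codon ", codon)
    }
    if (!is.na(assign[codon, "family"])) {
      stop("codon ", codon, " Watson-Crick decoded by two families: ",
           assign[codon, "family"], ", ", el$family[[i]])
    }
    assign[codon, c("amino_acid", "anticodon", "family", "pairing")] <-
      c(el$amino_acid[[i]], el$anticodon[[i]], el$family[[i]], "watson_crick")
  }

  # Wobble duplication: G34 reads the U-ending synonym of its WC codon,
  # A34 (inosine) reads the C-ending synonym.
  wobble_base <- c(G = "T", A = "C")
  for (i in seq_len(nrow(el))) {
    b34 <- substr(el$anticodon[[i]], 1L, 1L)
    if (!b34 %in% names(wobble_base)) next
    target <- paste0(substr(el$wc_codon[[i]], 1L, 2L), wobble_base[[b34]])
    if (!target %in% sense) next
    if (code$codon_to_aa[[target]] != code$codon_to_aa[[el$wc_codon[[i]]]]) next
    if (!is.na(assign[target, "family"])) next  # WC coverage wins
    assign[target, c("amino_acid", "anticodon", "family", "pairing")] <-
      c(el$amino_acid[[i]], el$anticodon[[i]], el$family[[i]], "wobble")
  }

  uncovered <- assign$codon[is.na(assign$family)]
  if (length(uncovered) > 0L) {
    stop("sense codons with no assignable anticodon family: ",
         paste(uncovered, collapse = ", "))
  }

  wob <- assign[assign$pairing == "wobble", , drop = FALSE]
  wc_of <- stats::setNames(
    assign$codon[assign$pairing == "watson_crick"],
    assign$family[assign$pairing == "watson_crick"]
  )
  pairs <- data.frame(
    family = wob$family,
    codon_wc = unname(wc_of[wob$family]),
    codon_wobble = wob$codon,
    inosine = substr(wob$anticodon, 1L, 1L) == "A",
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$family), , drop = FALSE]
  rownames(pairs) <- NULL
  rownames(assign) <- NULL

  structure(
    list(assignments = assign, wobble_pairs = pairs,
         repertoire = rep),
    class = "decoding_map"
  )
}

# one-letter -> three-letter amino-acid code (as used in family labels)
aa3 <- function(a) {
  tab <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val"
  )
  unname(tab[a])
}

#' @export
print.decoding_map <- function(x, ...) {
  n_wc <- sum(x$assignments$pairing == "watson_crick")
  n_wo <- sum(x$assignments$pairing == "wobble")
  cat(sprintf(
    "<decoding_map> %d sense codons -> %d families (%d Watson-Crick, %d wobble; %d wobble pairs, %d inosine)\n",
    nrow(x$assignments), length(unique(x$assignments$family)), n_wc, n_wo,
    nrow(x$wobble_pairs), sum(x$wobble_pairs$inosine)
  ))
  invisible(x)
}

#' Family assigned to each codon
#'
#' @param map a `decoding_map`.
#' @return Named character vector codon -> family label.
#' @export
codon_family <- function(map) {
  stopifnot(inherits(map, "decoding_map"))
  stats::setNames(map$assignments$family, map$assignments$codon)
}

#' Export a decoding map to TSV
#'
#' @param map a `decoding_map`.
#' @param path output path.
#' @param rna write codons in the RNA alphabet.
#' @export
write_decoding_map <- function(map, path, rna = FALSE) {
  stopifnot(inherits(map, "decoding_map"))
  out <- map$assignments[, c("codon", "amino_acid", "anticodon", "pairing")]
  if (rna) out$codon <- chartr("T", "U", out$codon)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
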