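# Shared fixture builders: everything is constructed in code.

# A coding_sequence from an explicit internal codon vector.
make_cds <- function(id, codons, stop_codon = "TAA") {
  validate_cds(id, paste(c("ATG", codons, stop_codon), collapse = ""))
}

# A CDS set from a named list of codon vectors.
make_cds_set <- function(codon_lists) {
  out <- lapply(names(codon_lists), function(id) {
    make_cds(id, codon_lists[[id]])
  })
  stats::setNames(out, names(codon_lists))
}

# Minimal repertoire with just Phe-GAA and Lys-TTT/CTT (for targeted
# wobble-rule checks on an undersized codon space).
phe_lys_repertoire <- function() {
  data.frame(
    amino_acid = c("Phe", "Lys", "Lys"),
    anticodon = c("GAA", "TTT", "CTT"),
    class = "elongator",
    stringsAsFactors = FALSE
  )
}

# Uniform tRNA profile over the default elongator families.
uniform_profile <- function(label = "uniform") {
  rep <- default_repertoire()
  fams <- rep$family[rep$class == "elongator"]
  trna_proportions(stats::setNames(rep(1, length(fams)), fams),
                   label = label)
}
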