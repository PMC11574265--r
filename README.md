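# codonopt

Codon optimality, tRNA adaptation and codon-dependent mRNA stability.

`codonopt` is an R toolkit for researchers studying how tRNA pools shape
translation and mRNA turnover — for example during the zebrafish
maternal-to-zygotic transition, where transcripts enriched in slowly
decoded codons are selectively destabilized. It connects four layers of
measurement with explicit, testable models:

* **tRNA supply** — anticodon-family read proportions from tRNA-seq
  quantification, with a built-in repertoire of the 47 cytosolic zebrafish
  families (45 elongator + initiator Met + Sec), overridable from TSV.
* **Wobble-aware decoding** — every one of the 61 sense codons is assigned
  to exactly one anticodon family by reverse complementarity, with G34
  families also reading U-ending synonyms and inosine (A34) families also
  reading C-ending synonyms; the family abundance is duplicated onto the
  wobble partner. The default repertoire yields 16 wobble pairs, 8 of them
  inosine pairs.
* **Adaptation indices** — per-transcript geometric-mean scores:

  * CAI (Sharp–Li): `w(c) = count(c) / max(count over synonyms)` pooled
    over the top 5% most expressed transcripts, `CAI = (∏ w(c_i))^{1/n}`,
    in (0, 1];
  * etAI: `w(c) = p(anticodon family of c)` — measured tRNA proportions,
    unscaled, so etAI tracks absolute pool composition and is not bounded
    by 1;
  * decoding rate: geometric mean of per-codon `1/DT` (inverse A-site
    dwell times).
* **Decay and CSC** — per-transcript half-lives from bounded regression of
  log2(TPM) on time (`k = −slope·ln2`, `t½ = ln2/k`, with filters on
  initial TPM > 10, decreasing trend, and fit p < 0.05), and codon
  stabilization coefficients: `CSC(c) = Pearson r(occurrence of c,
  half-life)` across transcripts, classified stabilizing / neutral /
  destabilizing by sign and significance.

Statistical primitives used by these analyses (Fisher-z comparison of two
correlations, exact/approximate Mann–Whitney U, misincorporation log-odds
with BH-FDR) are implemented explicitly, and a deterministic synthetic-data
generator produces FASTA/TSV inputs with known ground truth so every stage
is verifiable end to end.

## Worked example

```r
library(codonopt)

map <- build_decoding_map()
map
#> <decoding_map> 61 sense codons -> 45 families (45 Watson-Crick, 16 wobble; 16 wobble pairs, 8 inosine)
map$wobble_pairs[map$wobble_pairs$family == "Phe-GAA", ]
#>     family codon_wc codon_wobble inosine
#> 10 Phe-GAA      TTC          TTT   FALSE

# a complete synthetic experiment: CDS FASTA, tRNA counts, dwell times,
# expression, and a decay time-course whose rates depend on codon content
fix <- simulate_fixture(tempfile("demo"), seed = 1, n_transcripts = 300,
                        lambda = 1)

profile <- trna_proportions(
  read_anticodon_counts(fix$paths$anticodon_counts)[, "reads"])
cds  <- valid_cds(read_cds_fasta(fix$paths$cds))
expr <- read_expression(fix$paths$expression)[, "tpm"]

scores <- transcript_scores(
  cds,
  cai  = cai_weights(cds, expr),
  etai = etai_weights(profile, map),
  rates = decoding_rates(read_dwell_times(fix$paths$dwell_times)))
head(scores, 3)
#>   transcript_id n_codons   cai   etai decoding_rate
#> 1        tx0001      440 0.635 0.0198         0.976
#> 2        tx0002      170 0.729 0.0218         0.941
#> 3        tx0003      289 0.702 0.0184         0.934

hl  <- fit_half_lives(read_time_course(fix$paths$time_course))
sum(hl$status == "retained")
#> [1] 300
csc <- compute_csc(cds, hl)
table(csc$class)
#> destabilizing       neutral   stabilizing
#>            10            41            10
```

The scores table reads per transcript: `cai` close to 1 means codon usage
resembling the most expressed genes; `etai` (here ≈ 0.02, on the scale of
family proportions) rises with use of abundant tRNAs; `decoding_rate` ≈ 1
is the geometric mean of relative per-codon rates. With decay coupled to
tRNA supply (`lambda = 1`), fitted half-lives correlate with etAI
(r ≈ 0.71 in this run), recover the programmed ground truth to ≈ 1% median
relative error, and yield a CSC table in which rare-tRNA codons score
destabilizing.

A command-line interface over the same functions lives at
`inst/cli/codonopt.R` (subcommands `validate-cds`, `decoding-map`, `usage`,
`weights`, `scores`, `halflife`, `csc`, `compare`, `simulate`, `run`).

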