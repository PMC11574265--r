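---
title: "Codon optimality, tRNA adaptation and mRNA stability with codonopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon optimality, tRNA adaptation and mRNA stability with codonopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
```

## The model

During early vertebrate embryogenesis the stability of maternal mRNAs
depends on their codon content: transcripts enriched in slowly decoded
codons are destabilized once translation ramps up. `codonopt` implements
the quantitative chain that links these layers — tRNA pools, codon decoding,
and mRNA decay — as a reusable analysis toolkit:

1. **tRNA supply.** tRNA-seq read counts per anticodon family are converted
   to proportions of tRNA-mapped reads. The default repertoire ships the 47
   cytosolic zebrafish families (45 elongator plus initiator Met and Sec);
   the analyses of sense codons use the 45 elongator families.
2. **Wobble-aware decoding.** Each of the 61 sense codons is assigned to
   exactly one anticodon family. A codon whose reverse complement matches
   an anticodon is Watson–Crick decoded. Two wobble rules cover the rest:
   G34 anticodons also read the U-ending synonymous codon, and A34
   anticodons — inosine-modified at position 34 in eight eukaryotic
   families — also read the C-ending synonymous codon. Each of these
   families decodes a *pair* of synonymous codons and its abundance is
   duplicated onto the wobble partner. With the default repertoire this
   yields 16 wobble pairs, 8 of them inosine pairs, and the identity
   `#pairs = 61 − #elongator families` holds for any repertoire.
3. **Codon demand.** Proportional codon usage is the TPM-weighted average
   of per-transcript codon frequencies: for each valid CDS the codon
   frequency (start ATG and terminal stop excluded) is multiplied by the
   transcript's TPM, summed over transcripts, and renormalized. Demand over
   supply gives the per-codon load on each tRNA family.
4. **Adaptiveness scores.** Two per-codon weight sets feed geometric-mean
   transcript scores:
   * **CAI** (Sharp–Li): weights are pooled codon counts in a reference set
     of the top 5% most expressed transcripts, divided by the synonymous
     maximum, so weights lie in (0, 1] and CAI of a transcript is in
     (0, 1]. Codons absent from the reference receive a 0.5
     pseudo-occurrence.
   * **etAI**: weights are the measured tRNA proportions of the assigned
     family (wobble codons inherit the full family proportion). The weights
     are deliberately *not* rescaled to the maximum — the identity of the
     most abundant family can change between conditions, and rescaling
     would erase exactly that signal — so etAI is not bounded by 1 and
     scales linearly with the profile (multiplying all proportions by *c*
     multiplies every transcript etAI by *c*).
   * **Decoding rate**: the inverse of the per-codon ribosome A-site dwell
     time, 1/DT; the transcript-level rate is again the geometric mean.
5. **Decay.** For each transcript, log2(TPM) is regressed on time with the
   slope bounded in (−∞, 0]; k = −slope·ln 2 and t½ = ln 2/k. Transcripts
   are filtered, in order, when TPM at t = 0 is ≤ 10, when the bounded
   slope is 0 (not decreasing), or when the slope p-value of the
   unconstrained regression is ≥ 0.05.
6. **CSC.** The codon stabilization coefficient is the Pearson correlation,
   across retained transcripts, between a codon's occurrence and the
   half-life; codons with significantly positive r (p < 0.05) are
   stabilizing, significantly negative destabilizing, the rest neutral.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_fraction` | 0.05 | CAI reference = ceiling(0.05·N) top transcripts by mean TPM |
| `t0_min_tpm` | 10 (exclusive) | minimum initial expression for half-life fitting |
| `alpha` | 0.05 | slope p-value filter and CSC significance threshold |
| `csc_mode` | `"frequency"` | codon occurrence: frequency (length-normalized) or raw count |
| `floor_zero` | `FALSE` | zero tRNA proportions abort etAI unless floored |
| `min_transcripts` | 10 | minimum retained transcripts for a CSC table |

Defaults for start/stop handling exclude the initiator ATG and terminal
stop from every per-transcript codon statistic (usage, CAI, etAI, decoding
rate, CSC): the initiator is handled by a dedicated tRNA and pooling it
with elongator Met codons would blur both. Internal ATGs are ordinary Met
codons. Both exclusions are configurable.

## Design choices where the design was open

* **"Weighing frequencies" by expression.** Codon usage weights
  per-transcript *frequencies* (count / counted codons) by TPM rather than
  raw counts: TPM already encodes molar abundance, and frequencies prevent
  long CDS from dominating. A `mode = "count"` option exists for
  sensitivity analysis, and the same pair of modes is exposed for CSC
  occurrences.
* **CAI reference-set rounding.** The reference is `ceiling(0.05 * N)`
  transcripts with lexicographic transcript-id tie-breaking, making the
  reference deterministic for any expression table.
* **Fit p-value.** The "regression predicts the trend well" filter is the
  two-sided slope p-value of the unconstrained simple regression; for
  simple regression this equals the model F-test, so the ambiguity between
  the two readings is immaterial.
* **Zero TPM within a time-course** truncates the series at the first zero
  (log2 undefined); transcripts left with fewer than three points are
  skipped by the batch fitter with a warning.
* **Zero tRNA proportions** abort etAI by default: all 47 families are
  detectable in practice, so a zero signals an input problem, not biology.
  For sparse synthetic profiles `floor_zero = TRUE` substitutes half the
  smallest nonzero proportion.
* **Wobble scope.** Only the two duplication rules above are implemented —
  no U34 superwobble, no I34 reading of A-ending codons — and no
  selective-efficiency penalties are applied to wobble interactions, since
  such constraints are species-specific and unknown for zebrafish.
* **Independent-samples Fisher z.** Correlations measured at two
  developmental stages come from different transcript populations, so the
  comparison uses the independent form
  z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)); the
  dependent-overlapping variant is out of scope.
* **Rank tests** are exact (full enumeration of group assignments, midrank
  ties) for pooled sizes ≤ 12 and use the tie-corrected normal
  approximation without continuity correction otherwise; determinism was
  preferred over the marginal small-sample accuracy of a continuity
  correction.
* **CSC multiplicity.** Classification uses unadjusted p-values, matching
  the classical CSC definition; `adjust = TRUE` switches to
  Benjamini–Hochberg.

## The synthetic-data generator

Every stage can be validated without downloads because the generator
emulates the statistical structure the analysis assumes:

* `gen_trna_profile()` draws family proportions from a symmetric Dirichlet
  (concentration 5 by default — skewed but never sparse, like measured
  anticodon pools).
* `gen_dwell_times()` sets dt ∝ supply^(−β) with lognormal noise
  (geometric-mean-normalized), so dwell times are log-anti-correlated with
  cognate tRNA abundance by construction.
* `gen_cds_set()` emits structurally valid CDS (ATG + sense codons + stop,
  never an internal stop). Per-transcript codon weights are drawn from a
  Dirichlet centred on the global bias with concentration 30, giving
  transcripts the broad codon-content variation real transcriptomes show;
  with identical compositions (`dispersion = Inf`) no codon–stability
  analysis would have variance to work with.
* `gen_decay_dataset()` uses an additive rate model
  k_i = k₀ + Σ_c w(c)·freq_i(c) with multiplicative lognormal TPM noise.
  The additive form keeps the ground truth analytic: the sign of w(c) is
  the programmed stability class of codon c. Default k₀ = 0.2/h (t½ ≈ 3.5 h,
  typical of maternal transcripts cleared over an 8-h window), initial TPM
  lognormal around 100, hourly sampling 0–8 h.
* `supply_coupled_weights()` derives graded decay weights
  w(c) = λ·0.15·(−log supply(c)), the synthetic analogue of decay driven by
  slow decoding. λ interpolates from no codon effect (λ = 0) to strong
  coupling (λ = 1); across λ ∈ {0, 0.5, 1} the correlation between
  transcript etAI and fitted half-life rises steeply, the synthetic
  counterpart of translation-driven sensitization between developmental
  stages.

A note on recovery metrics: with a *spike* design (a few codons at weight
+0.2/h, the rest 0) the programmed codons are reliably recovered as
destabilizing, but a rank correlation between the weight vector and −CSC is
bounded near 0.37 by the ties among the zero-weight codons — the midrank of
58 tied zeros caps the rank covariance regardless of how well the spiked
codons separate. Rank-recovery is therefore assessed on the graded design,
where every codon has a distinct programmed weight; there
Spearman(w, −CSC) ≥ 0.8 at 500 transcripts.

What the generator does **not** emulate: sequencing-depth noise on
anticodon counts, tRNA modification signatures, UTR- or poly(A)-mediated
decay, transcript-length biases, or zygotic re-transcription superimposed
on decay. Passing recovery suites therefore demonstrates the estimators are
correct and well-calibrated under the stated model, not that real data meet
that model.

## Problem sizes and numerical notes

The validation suites use 500 transcripts for CSC/coupling recovery, 1000
for noisy half-life recovery (9 time points, lognormal σ = 0.1, median
absolute relative error ≈ 4%), and 2000 replicates at n = 100 for the
Fisher-z type-I simulation — sizes at which all recovery margins are wide
while a full run stays under a minute. Geometric means are computed in the
log domain (long CDS would underflow a direct product); noiseless decay
fixtures recover t½ to better than 1e−9 relative error, limited only by
floating point. All generators are deterministic under a fixed seed, and
seeded tie-breaks (principal-isoform selection) restore the caller's RNG
state.

## Known limitations

* The 47-family repertoire is the standard eukaryotic cytosolic set; if a
  genome lacks a family (or carries extras), supply a TSV via
  `read_repertoire()` — the wobble-pair partition adapts automatically.
* Wobble duplication assigns each codon to exactly one family; decoding
  contributions from multiple isoacceptors to one codon are not modeled.
* Half-life fitting assumes first-order decay over the whole window; decay
  with delay or biphasic kinetics will be flagged as poor fits rather than
  modeled.
* Sec (TCA) readthrough of UGA is excluded from sense-codon assignment.
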