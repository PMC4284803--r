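---
title: "Defining transcription-factor-regulated lncRNAs and delta-Ct biomarker signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining transcription-factor-regulated lncRNAs and delta-Ct biomarker signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsig)
library(dplyr)
```

## The analysis

`lncsig` implements a generic version of a widely used integrative design in
regulatory genomics: given ChIP-seq peaks for a transcription factor (the
motivating case is p53 under DNA damage) and per-replicate differential
expression tables, define the set of genes — protein-coding and long
noncoding — that the factor *directly* regulates, and then ask whether the
lncRNAs in that set behave as biomarkers in paired tumour/normal patient
material.

The pipeline decomposes into stages that mirror how the field actually works
through such data:

1. **Annotation and biotypes.** Transcripts are read from a Gencode-dialect
   GTF and classified into mRNA, lncRNA subtypes (intergenic, antisense,
   sense-overlapping, sense-intronic), processed transcripts, pseudogenes and
   other ncRNAs; transcripts with no biotype tag are `unassigned` and flow
   into the triage stage.
2. **Peak-to-TSS assignment.** Each peak is assigned to the gene with the
   nearest TSS; peaks within 10 kb are *proximal*, beyond 10 kb *distal*.
3. **Chromatin evidence.** A transcript 5' end is promoter-supported when at
   least one of H3K4me3 / H3K4me1 / H3K27ac overlaps a ±5 kb window around
   its TSS.
4. **Coding potential.** A CPAT-style logistic score over four sequence
   features: longest-ORF length and coverage, the Fickett TESTCODE
   statistic, and the in-frame hexamer usage log-likelihood ratio.
5. **Motif scanning.** The dimeric p53 response element
   RRRCWWGYYY–N(0–13)–RRRCWWGYYY, scanned with a mismatch budget, plus
   generic log-odds PWM scanning; enrichment of peak sequences against
   length- and composition-matched shuffled backgrounds is assessed with a
   one-sided exact test.
6. **Direct targets.** A gene is a direct target when it has at least one
   differentially expressed transcript (p < 0.01 in at least one of the
   replicates, raw p-values) *and* at least one proximal peak.
7. **Signature.** Per-marker delta-Ct (target Ct minus reference-gene Ct, so
   higher delta-Ct means lower expression), a paired t-test per marker,
   per-marker ROC with tumour as the positive class, selection of markers
   with AUC strictly above 0.7, and a k-fold cross-validated logistic
   regression whose pooled out-of-fold probabilities give one summary AUC.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `proximal_threshold` | 10 000 | bp | the conventional proximal-binding rule; boundary inclusive ("within 10 kb") |
| `flank` | 5 000 | bp | half-window of the promoter-mark test (−5 kb..+5 kb around the 5' end) |
| `alpha` | 0.01 | — | per-replicate DE significance, raw p-values; an FDR mode is deliberately not the default because the consumed tables are per-transcript calls |
| `run_through_gap` | 5 000 | bp | largest gap between an unassigned transcript's 5' end and an upstream same-strand 3' end that still suggests a run-through assembly artefact |
| `coding_cutoff` | 0.364 | probability | the published human CPAT cutoff; the score is a generic logistic combination so the cutoff is configurable |
| `auc_cutoff` | 0.7 | AUC | strict inequality; markers at exactly 0.7 are excluded |
| `k_folds` | 10 | — | tenfold cross-validation of the signature |

Open choices we fixed, and why:

* **Gene-level vs isoform-level TSS.** Peak distances use one canonical TSS
  per gene (the 5'-most transcript TSS) so each peak has an unambiguous
  assignment; passing a transcript-level table to `annotate_peaks()` gives
  the per-isoform alternative.
* **Peak reference point.** The summit when the peak caller provides one,
  else the interval midpoint; the summit is the sharpest position estimate.
* **Tie-breaking.** Equidistant genes resolve to the lexicographically
  smallest `gene_id`; hierarchical clustering uses `hclust`'s index-based
  tie resolution. Both make reruns byte-identical.
* **ROC orientation.** Tumours express the signature lncRNAs *less*, so
  their delta-Ct is *higher*; scoring by delta-Ct with tumour as the
  positive class makes informative markers score AUC > 0.5, and selection
  reads "AUC > 0.7".
* **Cross-validation structure.** Folds are patient-grouped (both tissues of
  a patient share a fold — otherwise the paired design leaks) and thereby
  stratified, since every patient contributes one tumour and one normal
  sample. The fold shuffle is seeded and the seed is echoed into the output.
* **Triage cascade.** The three evidence types are combined in a fixed
  order: run-through position without promoter marks ⇒ artefact; coding
  probability at or above the cutoff ⇒ likely coding; promoter-active and
  low-coding ⇒ novel lncRNA; otherwise artefact for lack of promoter
  evidence. A cascade, rather than a score, keeps every verdict explainable
  by its rule tags.
* **Motif step.** De novo discovery is out of scope; scanning the canonical
  dimeric consensus (≤2 mismatches over the 20 informative positions,
  spacers 0–13 nt) or a supplied PWM covers the question the stage answers —
  whether response elements are present and enriched in bound loci. The
  dimer consensus is its own reverse complement, so one forward scan
  enumerates all hits.

## Numerical choices

* The trapezoidal AUC is computed over all distinct thresholds with tied
  scores crossing together, which makes it *exactly* the tie-corrected
  concordance statistic (concordant + ½·ties) / (n₁·n₀); the test suite
  asserts equality at 1e−12.
* Logistic models are fitted by IRLS with a log-likelihood convergence
  tolerance of 1e−8 and a coefficient cap of 30: crossing the cap flags
  quasi-complete separation, stops iterating, and returns a usable capped
  model with `converged = FALSE`. A ridge penalty is available for
  separable designs. Zero-variance features get weight 0 and the intercept
  reduces to the class log-odds.
* Hypergeometric enrichment uses the upper-tail `phyper`, which is computed
  stably in log space internally.
* The paired test handles zero-variance differences explicitly: all-zero
  differences give p = 1, identical nonzero differences are reported at the
  machine floor with a degeneracy flag.
* Fickett scores use the published position/composition lookup tables; `N`
  bases are excluded from the counts. Hexamer tables are pseudocounted
  (1/4096) before normalisation so log-ratios stay finite; coding training
  sequences are aligned to their longest ORF so the in-frame (step-3) table
  is codon-phased even when full transcripts with UTRs are supplied.

## What the simulator emulates — and what it does not

`simulation_config()` + `simulate_study()` generate every input the
pipeline consumes, with a planted truth table: a uniform-random genome with
non-overlapping gene loci on a 20-kb grid and an exact biotype mix;
response elements written into the sequence within −3 kb..+1 kb of planted
target TSSs; one treated peak covering each planted site plus proximal and
distal decoys; two independent DE replicates with planted p ~ Beta(0.01, 1)
against a uniform null; mark tracks covering a configured fraction of
genuine 5' ends while planted run-through artefacts stay bare; and a paired
cohort with per-patient random effects.

The cohort model is `delta_ct = mu_g + delta_g·tumour + u_i + eps` with
`u_i ~ N(0, tau²)` shared within a patient and `eps ~ N(0, sigma²)`. The
defaults are the study-like conditions: 35 patients, 12 markers, two
replicates, and a graded effect vector `delta = (2.0, 1.6, 1.3, 1.1, 0.9,
0.75, 0.6, 0.45, 0.3, 0.2, 0.1, 0)` delta-Ct units with `sigma = 1`,
`tau = 0.5`. These were chosen once as a realistic spread — a couple of
strong markers, a middle tier near the detection limit at n = 35, and
uninformative tails — and typically yield six-to-seven significant markers
and five-to-six selected ones, the regime the signature procedure is meant
to operate in. Under this model a marker with `delta = 2·sigma` and no
patient effect has closed-form binormal AUC Φ(√2) ≈ 0.921, which the
acceptance checks recover empirically at n = 1000 per class.

What passing tests on this simulator do **not** show: real annotations have
overlapping and multi-isoform loci, nucleotide composition far from
uniform, correlated DE replicates, peak callers with artefact modes, and
cohort batch structure. The simulator validates the *logic* of every stage
and the statistical calibration of the tests; it cannot certify performance
on real data.

## Problem sizes

The bundled test and acceptance runs use 50–500 genes, up to 40 planted
targets, cohorts of 35–1000 patients, and 10,000 null cohorts for the
type-I-error calibration — sizes chosen so the whole suite exercises every
stage at meaningful statistical resolution while remaining quick on a
laptop.

## A worked run

```{r run, eval = FALSE}
cfg <- simulation_config(seed = 42, n_genes = 100, n_planted_targets = 15)
sim <- simulate_study(cfg, dir = "simdir")

pc <- pipeline_config(
  annotation = sim$files[["annotation"]],
  peaks = sim$files[["peaks_treated"]],
  genome = sim$files[["genome"]],
  coverage = sim$files[["coverage"]],
  de_tables = c(sim$files[["de_rep1"]], sim$files[["de_rep2"]]),
  marks = c(H3K4me3 = sim$files[["mark_H3K4me3"]],
            H3K4me1 = sim$files[["mark_H3K4me1"]],
            H3K27ac = sim$files[["mark_H3K27ac"]]),
  cohort = sim$files[["cohort"]],
  out_dir = "outdir", seed = 7)
manifest <- run_pipeline(pc)
```

Each stage writes one table under `out_dir`; `manifest.json` records the
configuration and an md5 checksum per output, so two runs with the same
configuration can be compared file by file.

## Known limitations

* Biotype subtypes are taken from the annotation tag, not recomputed from
  overlap relations; a generic "lncRNA" tag maps to intergenic.
* `annotate_peaks()` is quadratic per chromosome in the worst case (a scan
  over genes per peak); adequate for peak sets in the thousands, not for
  millions of intervals.
* The conservation stage consumes peaks already mapped into the query
  coordinate space; no liftover is performed.
* Confidence intervals for AUCs (DeLong or bootstrap) are not provided; the
  cross-validated pooled AUC is the headline statistic.
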