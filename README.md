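# lncsig

Tools for defining **transcription-factor-regulated long noncoding RNAs**
from ChIP-seq peaks plus differential-expression tables, and for building
**paired tumour/normal delta-Ct biomarker signatures** from qPCR cohorts.
The package is aimed at regulatory-genomics analysts who have peak calls,
DE tables, histone-mark intervals and a genome in standard formats (GTF,
narrowPeak/BED, bedGraph, FASTA, TSV) and want the integration steps —
not the upstream alignment, assembly, DE testing or peak calling, which are
consumed as inputs.

## What it computes

**Direct-target definition.** Each peak is assigned to the gene with the
nearest TSS (signed, strand-aware distance; summit-based when available)
and classed *proximal* iff |d| ≤ 10 kb. A gene is a **direct target** when
it has ≥ 1 transcript with p < 0.01 in at least one DE replicate **and**
≥ 1 proximal peak. Transcripts lacking a biotype are triaged with three
lines of evidence: promoter marks (H3K4me3/H3K4me1/H3K27ac within ±5 kb of
the 5' end), position relative to the upstream gene (run-through artefact
detection), and a CPAT-style coding probability

  P(coding) = logistic(w₀ + w·[log ORF length, ORF coverage, Fickett, hexamer LLR]).

Peak sequences are scanned for the dimeric p53 response element
RRRCWWGYYY–N(0–13)–RRRCWWGYYY (≤ 2 mismatches) or any PWM, with enrichment
against shuffled backgrounds by a one-sided exact test, and cross-species
binding conservation is quantified as an interval-overlap fraction.
Gene-set enrichment uses the upper-tail hypergeometric test.

**Signature construction.** Per marker and sample, ΔCt = Ct(target) −
Ct(reference); higher ΔCt means lower expression, and tumours are the
positive class. Markers are tested with a paired t-test, ranked by
trapezoidal ROC AUC (exactly the tie-corrected concordance statistic
(concordant + ½ ties)/(n₁n₀)), selected at AUC > 0.7, and combined by
k-fold cross-validated logistic regression (IRLS, patient-grouped folds);
the pooled out-of-fold probabilities give a single summary AUC.

A fully seeded synthetic-data generator (`simulate_study()`) emulates every
input with a planted truth table, so the whole pipeline is testable offline.

## Worked example

```r
library(lncsig)

cfg <- simulation_config(seed = 42, n_genes = 100, n_planted_targets = 15,
                         n_decoy_proximal = 5, n_decoy_distal = 10,
                         n_decoy_de = 8)
sim <- simulate_study(cfg, dir = "simdir")

genes <- gene_table(transcript_table(read_gtf(sim$files[["annotation"]])))
ann   <- annotate_peaks(read_narrowpeak(sim$files[["peaks_treated"]]), genes)
table(ann$klass)
#>   distal proximal
#>       10       20

targets <- call_direct_targets(de_status(sim$de_tables), ann,
                               transcript_table(read_gtf(sim$files[["annotation"]])))
truth <- sim$truth_genes$gene_id[sim$truth_genes$is_direct_target]
mean(truth %in% targets$gene_id)   # recall against the planted truth
#> [1] 1

cohort <- delta_ct(sim$ct_table)
sum(paired_differential(cohort)$significant)   # markers with paired p < 0.01
#> [1] 7

sig <- crossval_signature(cohort, k = 10, seed = 7)
sig
#> Signature: 4 marker(s) selected of 12; pooled 10-fold CV AUC = 0.8971 (seed 7)
```

All 30 peaks are classed by the 10-kb rule (20 proximal — the 15 planted
target peaks plus 5 decoys near non-target TSSs), every planted target is
recovered, 7 of the 12 simulated cohort markers reach paired significance,
and the selected markers cross-validate to a pooled AUC of 0.90. `tidy()`,
`glance()` and `autoplot()` methods expose per-marker tables, fit summaries
and ROC plots; `run_pipeline(pipeline_config(...))` chains all stages and
writes one table per stage plus a checksummed `manifest.json`.

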