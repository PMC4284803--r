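Package: lncsig
Title: Transcription-Factor-Regulated lncRNA Discovery and Tumour/Normal
    Biomarker Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor ChIP-seq peaks and
    differential-expression tables to define directly regulated long noncoding
    RNAs (lncRNAs): biotype classification from GTF annotation, nearest-TSS
    peak assignment with a proximal/distal rule, chromatin-mark triage of
    unassigned transcripts, CPAT-style coding-potential scoring (longest ORF,
    Fickett statistic, hexamer usage bias), p53 response-element scanning and
    enrichment, cross-species binding overlap, and hypergeometric set
    enrichment. Builds paired tumour/normal qPCR delta-Ct biomarker signatures
    via per-marker ROC analysis, AUC-threshold selection and k-fold
    cross-validated logistic regression. Includes a fully seeded synthetic-data
    generator that emulates every input with planted ground truth, and a
    pipeline driver tying the stages together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
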