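# End-to-end pipeline driver: configuration, staged execution, manifest.

#' Pipeline configuration
#'
#' Paths to all inputs plus every threshold the stages use. Any path may be
#' `NULL`; stages whose inputs are absent are skipped. The configuration is
#' echoed verbatim into the output manifest.
#'
#' @param annotation GTF path (required).
#' @param peaks narrowPeak path (required).
#' @param genome FASTA path (enables motif scanning and coding features).
#' @param coverage bedGraph path (enables the metagene profile).
#' @param de_tables Character vector of per-replicate DE TSV paths.
#' @param marks Named character vector of per-mark BED paths.
#' @param cross_species_peaks BED/narrowPeak of peaks mapped from another
#'   species (enables the conservation summary).
#' @param cohort Paired Ct TSV path (enables the signature stage).
#' @param coding_model Path to a plain-text coding model
#'   ([write_coding_model()]); `NULL` trains one from simulated sequences.
#' @param out_dir Output directory.
#' @param alpha DE significance level.
#' @param proximal_threshold Proximal peak rule, bp.
#' @param flank Promoter-mark half-window, bp.
#' @param run_through_gap Run-through triage gap, bp.
#' @param coding_cutoff Coding-probability cutoff.
#' @param auc_cutoff Signature AUC selection cutoff.
#' @param k_folds Cross-validation folds.
#' @param seed Integer seed (mandatory).
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(annotation, peaks, genome = NULL,
                            coverage = NULL, de_tables = NULL, marks = NULL,
                            cross_species_peaks = NULL, cohort = NULL,
                            coding_model = NULL,
                            out_dir = "lncsig_out",
                            alpha = 0.01, proximal_threshold = 10000,
                            flank = 5000, run_through_gap = 5000,
                            coding_cutoff = 0.364, auc_cutoff = 0.7,
                            k_folds = 10, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(alpha > 0, alpha < 1, proximal_threshold > 0, flank > 0,
            coding_cutoff > 0, coding_cutoff < 1,
            auc_cutoff >= 0, auc_cutoff <= 1, k_folds >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, out_dir, fn) {
  tryCatch(fn(), error = function(e) {
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order -- biotype distribution; peak
#' annotation with positional histogram (and metagene profile when coverage
#' is given); promoter-mark evidence and triage of unassigned transcripts
#' (when marks and a genome are given); motif enrichment of peak sequences
#' against shuffled backgrounds (when a genome is given); direct-target
#' calling (when DE tables are given); cross-species conservation (when
#' mapped peaks are given); cohort signature (when a Ct table is given) --
#' writing one TSV/JSON per stage plus a manifest with md5 checksums and
#' the full configuration. Any stage failure aborts with the stage name and
#' leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(out, name)
    readr::write_tsv(as_tibble(x), p)
    files[[name]] <<- p
    p
  }
  log_msg <- function(...) message(sprintf(...))

  log_msg("[1/7] annotation")
  ann <- .stage("annotation", out, function() {
    exons <- read_gtf(config$annotation)
    transcripts <- transcript_table(exons)
    genes <- gene_table(transcripts)
    emit(biotype_distribution(transcripts), "biotype_distribution.tsv")
    list(exons = exons, transcripts = transcripts, genes = genes)
  })

  log_msg("[2/7] peak annotation")
  pa <- .stage("peak_annotation", out, function() {
    peaks <- read_narrowpeak(config$peaks)
    annotations <- annotate_peaks(peaks, ann$genes,
                                  proximal_threshold = config$proximal_threshold)
    emit(select(annotations, -dplyr::any_of(c("kind"))),
         "peak_annotation.tsv")
    emit(positional_histogram(annotations, bin_width = 1000,
                              window = config$proximal_threshold,
                              stratify_by =
                                if ("gene_biotype" %in% names(annotations))
                                  "gene_biotype" else NULL),
         "positional_histogram.tsv")
    if (!is.null(config$coverage)) {
      prof <- metagene_profile(read_bedgraph(config$coverage),
                               select(ann$genes, "chrom", "tss", "strand"),
                               window = config$proximal_threshold, bin = 100)
      emit(prof, "metagene_profile.tsv")
    }
    annotations
  })

  genome <- if (!is.null(config$genome)) read_fasta(config$genome) else NULL

  log_msg("[3/7] chromatin evidence + triage")
  triage <- .stage("triage", out, function() {
    if (is.null(config$marks) || is.null(genome)) return(NULL)
    marks <- read_mark_beds(config$marks)
    evidence <- promoter_mark_evidence(ann$transcripts, marks,
                                       flank = config$flank)
    emit(evidence, "promoter_evidence.tsv")
    unassigned <- filter(ann$transcripts, .data$biotype == "unassigned")
    if (nrow(unassigned) == 0) return(NULL)
    cm <- if (!is.null(config$coding_model)) {
      read_coding_model(config$coding_model)
    } else {
      train_coding_model(
        simulate_coding_sequences(150, TRUE, seed = config$seed + 11L),
        simulate_coding_sequences(150, FALSE, seed = config$seed + 12L),
        cutoff = config$coding_cutoff)
    }
    seqs <- extract_transcript_sequences(
      genome, filter(ann$exons,
                     .data$transcript_id %in% unassigned$transcript_id))
    probs <- coding_probability(coding_features(seqs, cm$hexamer_table), cm)
    ctx <- neighbor_context(unassigned, gene_spans(ann$transcripts))
    verdicts <- triage_unassigned(unassigned, evidence, probs, ctx,
                                  run_through_gap = config$run_through_gap,
                                  coding_cutoff = config$coding_cutoff)
    emit(verdicts, "triage.tsv")
    verdicts
  })

  log_msg("[4/7] motif enrichment")
  .stage("motif_enrichment", out, function() {
    if (is.null(genome)) return(NULL)
    peaks <- read_narrowpeak(config$peaks)
    fg <- extract_peak_sequences(genome, peaks, window = 250)
    set.seed(config$seed + 21L)
    bg <- vapply(fg, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1))  # length- and composition-matched shuffles
    enr <- motif_enrichment(fg, bg, scanner = p53re_scan)
    emit(enr, "motif_enrichment.tsv")
    enr
  })

  log_msg("[5/7] direct targets")
  targets <- .stage("direct_targets", out, function() {
    if (is.null(config$de_tables)) return(NULL)
    de_tables <- bind_rows(purrr::imap(config$de_tables, function(p, i) {
      read_de_table(p, replicate = i)
    }))
    de <- de_status(de_tables, alpha = config$alpha)
    tg <- call_direct_targets(de, pa, ann$transcripts)
    emit(tg, "direct_targets.tsv")
    emit(target_biotype_counts(tg), "direct_target_biotypes.tsv")
    tg
  })

  log_msg("[6/7] conservation")
  .stage("conservation", out, function() {
    if (is.null(config$cross_species_peaks) || is.null(targets)) return(NULL)
    other <- read_bed(config$cross_species_peaks)
    peaks <- read_narrowpeak(config$peaks)
    cons_all <- conservation_fraction(peaks, other)
    de_peaks <- filter(pa, .data$nearest_gene_id %in% targets$gene_id)
    cons_de <- if (nrow(de_peaks) > 0) {
      conservation_fraction(de_peaks, other)
    } else cons_all[0, ]
    emit(bind_rows(mutate(cons_all, set = "all_peaks"),
                   mutate(cons_de, set = "direct_target_peaks")),
         "conservation.tsv")
  })

  log_msg("[7/7] signature")
  .stage("signature", out, function() {
    if (is.null(config$cohort)) return(NULL)
    cohort <- delta_ct(read_ct_table(config$cohort))
    emit(paired_differential(cohort, alpha = config$alpha),
         "paired_differential.tsv")
    sig <- crossval_signature(cohort, k = config$k_folds,
                              seed = config$seed,
                              auc_cutoff = config$auc_cutoff)
    emit(tidy(sig), "marker_auc.tsv")
    emit(sig$predictions, "cv_predictions.tsv")
    jsonlite::write_json(
      list(selected = sig$selected, pooled_auc = sig$pooled_auc,
           k = sig$k, seed = sig$seed),
      file.path(out, "signature.json"), auto_unbox = TRUE, digits = NA)
    files[["signature.json"]] <<- file.path(out, "signature.json")
    sig
  })

  cfg_clean <- unclass(config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lncsig")),
    config = cfg_clean,
    outputs = lapply(files, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
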