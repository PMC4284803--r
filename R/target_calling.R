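# Direct-target calling: DE status x proximal binding; triage of unassigned
# transcripts; cross-species conservation; hypergeometric enrichment.

#' Read a per-replicate differential-expression table
#'
#' @param path TSV with columns `transcript_id`, `log2fc`, `p_value` and
#'   optionally `replicate`.
#' @param replicate Replicate label to assign when the file lacks the column.
#' @return Tibble with `transcript_id`, `log2fc`, `p_value`, `replicate`.
#' @export
read_de_table <- function(path, replicate = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("transcript_id", "log2fc", "p_value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) abort(sprintf("DE table lacks column(s): %s",
                                      paste(miss, collapse = ", ")))
  if (!"replicate" %in% names(x)) {
    x$replicate <- if (is.null(replicate)) 1L else replicate
  }
  x[, c("transcript_id", "log2fc", "p_value", "replicate")]
}

#' Differential-expression status per transcript
#'
#' A transcript is significant when its p-value is below `alpha` in at least
#' one replicate; its direction (`up`/`down`) follows the fold-change sign of
#' the most significant replicate. Transcripts absent from all tables, or
#' never reaching `alpha`, are `ns`.
#'
#' @param de_tables Tibble of stacked replicate tables
#'   (`transcript_id`, `log2fc`, `p_value`, `replicate`).
#' @param alpha Per-replicate significance level (default 0.01, no
#'   multiple-testing correction, mirroring raw per-transcript calls).
#' @param transcripts Optional character vector of transcript ids to report
#'   (ids absent from the tables come back `ns` with `n_tested = 0`).
#' @return Tibble with `transcript_id`, `n_tested`, `n_significant`, `min_p`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
de_status <- function(de_tables, alpha = 0.01, transcripts = NULL) {
  st <- de_tables %>%
    group_by(.data$transcript_id) %>%
    summarise(
      n_tested = n(),
      n_significant = sum(.data$p_value < alpha),
      min_p = min(.data$p_value),
      direction = if_else(sum(.data$p_value < alpha) > 0,
                          if_else(.data$log2fc[which.min(.data$p_value)] >= 0,
                                  "up", "down"),
                          "ns"),
      .groups = "drop"
    )
  if (!is.null(transcripts)) {
    st <- tibble(transcript_id = transcripts) %>%
      left_join(st, by = "transcript_id") %>%
      mutate(n_tested = dplyr::coalesce(.data$n_tested, 0L),
             n_significant = dplyr::coalesce(.data$n_significant, 0L),
             direction = dplyr::coalesce(.data$direction, "ns"))
  }
  st
}

#' Call direct targets from DE status and proximal binding
#'
#' A gene is a direct target when at least one of its transcripts is
#' differentially expressed and at least one proximal peak is assigned to
#' it. The gene direction is that of its most significant transcript; a
#' conflict among significant transcripts is flagged.
#'
#' @param de DE status tibble from [de_status()].
#' @param annotations Peak annotations from [annotate_peaks()] (computed with
#'   the proximal threshold in force).
#' @param transcripts Transcript table ([transcript_table()]), the
#'   transcript-to-gene map.
#' @return Tibble of class `"lncsig_targets"`, sorted by `gene_id`, with
#'   `gene_id`, `biotype`, `direction`, `direction_conflict`,
#'   `n_de_transcripts`, `de_transcript_ids`, `n_proximal_peaks`, `peak_ids`.
#' @export
call_direct_targets <- function(de, annotations, transcripts) {
  de_tx <- de %>% filter(.data$direction != "ns") %>%
    inner_join(select(transcripts, "transcript_id", "gene_id", "biotype"),
               by = "transcript_id")
  de_genes <- de_tx %>%
    group_by(.data$gene_id) %>%
    arrange(.data$min_p, .by_group = TRUE) %>%
    summarise(
      biotype = first(.data$biotype),
      direction = first(.data$direction),
      direction_conflict = dplyr::n_distinct(.data$direction) > 1,
      n_de_transcripts = n(),
      de_transcript_ids = paste(.data$transcript_id, collapse = ","),
      .groups = "drop"
    )
  prox <- annotations %>%
    filter(.data$klass == "proximal", !is.na(.data$nearest_gene_id)) %>%
    group_by(gene_id = .data$nearest_gene_id) %>%
    summarise(n_proximal_peaks = n(),
              peak_ids = paste(.data$peak_id, collapse = ","),
              .groups = "drop")
  out <- inner_join(de_genes, prox, by = "gene_id") %>%
    arrange(.data$gene_id)
  class(out) <- c("lncsig_targets", class(out))
  out
}

#' Per-biotype counts of direct targets
#'
#' @param targets Output of [call_direct_targets()].
#' @return Tibble `biotype`, `n`.
#' @export
target_biotype_counts <- function(targets) {
  targets %>% count(biotype = factor(.data$biotype,
                                     levels = biotype_levels()),
                    .drop = FALSE) %>%
    mutate(biotype = as.character(.data$biotype))
}

#' Nearest upstream same-strand gene context for transcripts
#'
#' For each transcript, finds the closest gene 3' end lying upstream of the
#' transcript's 5' end on the same strand and chromosome, and the gap between
#' them. Used by [triage_unassigned()] to spot run-through assembly
#' artefacts (e.g. an extended 3' UTR of the upstream gene).
#'
#' @param transcripts Transcript table rows to contextualise.
#' @param genes Gene-span tibble with `gene_id`, `chrom`, `strand` and spans
#'   `gene_start`, `gene_end` (see [gene_spans()]).
#' @return Tibble `transcript_id`, `upstream_gene_id`, `upstream_gap` (bp,
#'   `NA` when no upstream gene exists).
#' @export
neighbor_context <- function(transcripts, genes) {
  purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    g <- genes[genes$chrom == tx$chrom & genes$strand == tx$strand &
                 genes$gene_id != tx$gene_id, ]
    if (tx$strand == "-") {
      # upstream = to the right; gene 3' end is gene_start; gap from tx 5' end
      g <- g[g$gene_start >= tx$tx_end, ]
      gap <- g$gene_start - tx$tx_end
    } else {
      g <- g[g$gene_end <= tx$tx_start, ]
      gap <- tx$tx_start - g$gene_end
    }
    if (nrow(g) == 0) {
      return(tibble(transcript_id = tx$transcript_id,
                    upstream_gene_id = NA_character_,
                    upstream_gap = NA_integer_))
    }
    j <- which.min(gap)
    tibble(transcript_id = tx$transcript_id,
           upstream_gene_id = g$gene_id[j],
           upstream_gap = as.integer(gap[j]))
  }) %>% bind_rows()
}

#' Gene spans from a transcript table
#'
#' @param transcripts Transcript table ([transcript_table()]).
#' @return Tibble `gene_id`, `chrom`, `strand`, `gene_start`, `gene_end`.
#' @export
gene_spans <- function(transcripts) {
  transcripts %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              gene_start = min(.data$tx_start), gene_end = max(.data$tx_end),
              .groups = "drop")
}

#' Triage unassigned transcripts
#'
#' Applies a deterministic rule cascade combining the three lines of
#' evidence: (1) `likely_artefact` when the transcript's 5' end lies within
#' `run_through_gap` of an upstream same-strand gene's 3' end and its
#' promoter carries no active mark (a run-through / extended-3'UTR artefact);
#' (2) `likely_coding` when the coding probability reaches `coding_cutoff`;
#' (3) `novel_lncRNA` when the promoter is mark-active and the coding
#' probability is below the cutoff; (4) otherwise `likely_artefact`
#' (no promoter evidence).
#'
#' @param transcripts Transcript table rows with biotype `unassigned`.
#' @param evidence Promoter-mark evidence ([promoter_mark_evidence()]).
#' @param coding Coding probabilities: tibble with `seq_id` (= transcript id)
#'   and `coding_prob` ([coding_probability()]).
#' @param context Neighbour context ([neighbor_context()]).
#' @param run_through_gap Maximum 5'-end-to-upstream-3'-end gap for the
#'   run-through rule, bp (default 5000).
#' @param coding_cutoff Coding-probability cutoff (default 0.364).
#' @return Tibble `transcript_id`, `verdict`
#'   (`likely_artefact`/`novel_lncRNA`/`likely_coding`), `reasons`
#'   (comma-joined rule tags).
#' @export
triage_unassigned <- function(transcripts, evidence, coding, context,
                              run_through_gap = 5000, coding_cutoff = 0.364) {
  if (any(transcripts$biotype != "unassigned")) {
    abort("triage_unassigned expects only transcripts with biotype 'unassigned'")
  }
  x <- transcripts %>%
    left_join(select(evidence, "transcript_id", "active"),
              by = "transcript_id") %>%
    left_join(select(coding, transcript_id = "seq_id", "coding_prob"),
              by = "transcript_id") %>%
    left_join(context, by = "transcript_id")
  if (anyNA(x$coding_prob)) {
    abort(sprintf("missing coding probability for transcript(s): %s",
                  paste(utils::head(
                    x$transcript_id[is.na(x$coding_prob)], 5), collapse = ", ")))
  }
  x$active[is.na(x$active)] <- FALSE
  purrr::map(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    run_through <- !is.na(r$upstream_gap) && r$upstream_gap <= run_through_gap
    if (run_through && !r$active) {
      verdict <- "likely_artefact"
      reasons <- c("run_through_upstream_gene", "no_promoter_evidence")
    } else if (r$coding_prob >= coding_cutoff) {
      verdict <- "likely_coding"
      reasons <- "coding_potential_above_cutoff"
    } else if (r$active) {
      verdict <- "novel_lncRNA"
      reasons <- c("promoter_active", "low_coding_potential")
    } else {
      verdict <- "likely_artefact"
      reasons <- "no_promoter_evidence"
    }
    tibble(transcript_id = r$transcript_id, verdict = verdict,
           reasons = paste(reasons, collapse = ","))
  }) %>% bind_rows()
}

#' Cross-species binding conservation
#'
#' Fraction of query binding loci overlapped (>= 1 bp) by peaks from another
#' species already mapped into the query's coordinate space.
#'
#' @param query_loci,mapped_peaks Interval tibbles (`chrom`, `start`, `end`).
#' @return One-row tibble `n_query`, `n_overlapping`, `fraction`.
#' @export
conservation_fraction <- function(query_loci, mapped_peaks) {
  if (nrow(query_loci) == 0) abort("query locus set is empty")
  frac <- interval_overlap_fraction(query_loci, mapped_peaks)
  tibble(n_query = nrow(query_loci),
         n_overlapping = as.integer(round(frac * nrow(query_loci))),
         fraction = frac)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= hits_in_set)` where `X` is the number of annotated elements drawn
#' when sampling `set_size` elements without replacement from a universe of
#' `universe_size` containing `hits_in_universe` annotated ones. Computed via
#' the stable upper-tail of the hypergeometric distribution.
#'
#' @param hits_in_set,set_size,hits_in_universe,universe_size Integer scalars.
#' @return p-value in (0, 1].
#' @examples
#' hypergeometric_enrichment(4, 5, 4, 10)  # 6/252
#' @export
hypergeometric_enrichment <- function(hits_in_set, set_size,
                                      hits_in_universe, universe_size) {
  ok <- hits_in_set >= 0 && set_size <= universe_size &&
    hits_in_set <= min(set_size, hits_in_universe) &&
    hits_in_universe <= universe_size
  if (!ok) abort("inconsistent hypergeometric counts")
  stats::phyper(hits_in_set - 1, m = hits_in_universe,
                n = universe_size - hits_in_universe,
                k = set_size, lower.tail = FALSE)
}
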