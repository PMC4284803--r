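# Gene annotation: GTF parsing, transcript/gene tables, TSS, biotypes.

# Gencode biotype tag -> internal category. Unknown tags fall through to
# other_ncRNA with a warning (annotations evolve; hard failure helps nobody).
.biotype_map <- c(
  protein_coding          = "mRNA",
  lincRNA                 = "lnc_intergenic",
  lncRNA                  = "lnc_intergenic",
  antisense               = "lnc_antisense",
  antisense_RNA           = "lnc_antisense",
  sense_overlapping       = "lnc_sense_overlapping",
  sense_intronic          = "lnc_sense_intronic",
  processed_transcript    = "processed_transcript",
  pseudogene              = "pseudogene",
  processed_pseudogene    = "pseudogene",
  unprocessed_pseudogene  = "pseudogene",
  transcribed_unprocessed_pseudogene = "pseudogene",
  transcribed_processed_pseudogene   = "pseudogene",
  retained_intron         = "retained_intron",
  miRNA                   = "other_ncRNA",
  snoRNA                  = "other_ncRNA",
  snRNA                   = "other_ncRNA",
  rRNA                    = "other_ncRNA",
  misc_RNA                = "other_ncRNA"
)

#' Biotype categories used throughout the package
#'
#' The fixed set of transcript categories: protein-coding mRNA, the lncRNA
#' subtypes (intergenic, antisense, sense-overlapping, sense-intronic),
#' processed transcripts, pseudogene-derived transcripts, retained introns,
#' other short/structural ncRNAs, and `unassigned` for transcripts with no
#' annotation tag.
#'
#' @return Character vector of the category names.
#' @export
biotype_levels <- function() {
  c("mRNA", "lnc_intergenic", "lnc_antisense", "lnc_sense_overlapping",
    "lnc_sense_intronic", "processed_transcript", "pseudogene",
    "retained_intron", "other_ncRNA", "unassigned")
}

#' Map annotation biotype tags to package categories
#'
#' Deterministic mapping from Gencode-style biotype strings to the categories
#' in [biotype_levels()]. Empty or missing tags become `"unassigned"`;
#' unknown tags map to `"other_ncRNA"` with a warning.
#'
#' @param raw_tag Character vector of annotation biotype strings.
#' @return Character vector of categories, same length as `raw_tag`.
#' @examples
#' classify_biotype(c("protein_coding", "lincRNA", ""))
#' @export
classify_biotype <- function(raw_tag) {
  raw_tag <- as.character(raw_tag)
  out <- rep("unassigned", length(raw_tag))
  nonempty <- !is.na(raw_tag) & raw_tag != ""
  mapped <- unname(.biotype_map[raw_tag[nonempty]])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warn(sprintf("unknown biotype tag(s) mapped to other_ncRNA: %s",
                 paste(unique(raw_tag[nonempty][unknown]), collapse = ", ")))
    mapped[unknown] <- "other_ncRNA"
  }
  out[nonempty] <- mapped
  out
}

#' Read exon structures from a GTF file
#'
#' Imports a Gencode-dialect GTF and returns one row per exon with
#' coordinates converted from 1-based inclusive (GTF) to 0-based half-open.
#' Only `exon` features are retained. Exons are sorted by genomic start
#' within each transcript.
#'
#' @param path Path to a GTF file.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`, `biotype_tag` (raw annotation string, `""`
#'   when absent) and `biotype` (mapped category).
#' @seealso [write_gtf()], [transcript_table()]
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) abort("no exon features found in GTF")
  md <- S4Vectors::mcols(gr)
  get_attr <- function(name, default = NA_character_) {
    if (name %in% names(md)) as.character(md[[name]]) else
      rep(default, length(gr))
  }
  tx <- get_attr("transcript_id")
  gn <- get_attr("gene_id")
  if (anyNA(tx) || anyNA(gn)) {
    bad <- which(is.na(tx) | is.na(gn))[1]
    # locate the raw line for the error message
    lines <- readLines(path, warn = FALSE)
    exon_lines <- which(!startsWith(lines, "#") &
                          vapply(strsplit(lines, "\t"), function(f)
                            length(f) >= 3 && f[3] == "exon", logical(1)))
    ln <- if (bad <= length(exon_lines)) exon_lines[bad] else NA_integer_
    abort(sprintf(
      "exon record %d (file line %s) lacks a mandatory transcript_id/gene_id attribute",
      bad, ifelse(is.na(ln), "?", ln)))
  }
  bt <- get_attr("transcript_biotype")
  if (all(is.na(bt))) bt <- get_attr("transcript_type")
  if (all(is.na(bt))) bt <- get_attr("gene_biotype")
  bt[is.na(bt)] <- ""
  exons <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = tx,
    gene_id = gn,
    biotype_tag = bt
  ) %>%
    arrange(.data$transcript_id, .data$start)
  # structural checks per transcript
  chk <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      n_strand = dplyr::n_distinct(.data$strand),
      n_chrom = dplyr::n_distinct(.data$chrom),
      overlapping = any(.data$start[-1] < .data$end[-length(.data$end)]),
      .groups = "drop"
    )
  bad <- chk$transcript_id[chk$n_strand > 1 | chk$n_chrom > 1]
  if (length(bad) > 0) {
    abort(sprintf("transcript(s) with inconsistent chrom/strand across exons: %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(chk$overlapping)) {
    abort(sprintf("transcript(s) with overlapping exons: %s",
                  paste(utils::head(chk$transcript_id[chk$overlapping], 5),
                        collapse = ", ")))
  }
  exons$biotype <- classify_biotype(exons$biotype_tag)
  check_intervals(exons, "GTF exon table")
  exons
}

#' Write exon structures to a GTF file
#'
#' Emits one `exon` line per row in the Gencode attribute dialect
#' (`key "value";` pairs), converting back to 1-based inclusive coordinates.
#' Re-reading the file with [read_gtf()] reproduces the input table.
#'
#' @param exons Exon tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  check_intervals(exons, "exon table")
  bt <- if ("biotype_tag" %in% names(exons)) exons$biotype_tag else ""
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                   exons$gene_id, exons$transcript_id,
                   ifelse(bt == "", "",
                          sprintf(' transcript_biotype "%s";', bt)))
  lines <- sprintf("%s\tlncsig\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, exons$start + 1L, exons$end,
                   exons$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Summarise exons to one row per transcript
#'
#' Collapses an exon table into per-transcript records with span, exon count,
#' strand-aware TSS (5'-most transcribed base: first-exon start on `+`,
#' last-exon end minus one on `-`) and biotype.
#'
#' @param exons Exon tibble from [read_gtf()].
#' @return Tibble with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `n_exons`, `tx_start`, `tx_end`, `tss`, `biotype`.
#' @export
transcript_table <- function(exons) {
  check_intervals(exons, "exon table")
  exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_exons = n(),
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      biotype = first(.data$biotype),
      .groups = "drop"
    ) %>%
    mutate(tss = tss_position(.data$tx_start, .data$tx_end, .data$strand)) %>%
    select("transcript_id", "gene_id", "chrom", "strand", "n_exons",
           "tx_start", "tx_end", "tss", "biotype")
}

#' Strand-aware TSS position
#'
#' @param start,end Transcript span, 0-based half-open.
#' @param strand `"+"`, `"-"` or `"."` (treated as `"+"`).
#' @return Integer vector of TSS positions (0-based).
#' @export
tss_position <- function(start, end, strand) {
  as.integer(ifelse(strand == "-", end - 1L, start))
}

#' Summarise transcripts to one row per gene
#'
#' The gene-level TSS is the 5'-most transcript TSS on the gene strand
#' (minimum over transcript TSSs on `+`, maximum on `-`), giving one
#' unambiguous anchor per gene for peak assignment. The gene biotype is the
#' biotype of the transcript providing that TSS.
#'
#' @param transcripts Tibble from [transcript_table()].
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tss`, `n_transcripts`,
#'   `biotype`.
#' @export
gene_table <- function(transcripts) {
  split(transcripts, transcripts$gene_id) %>%
    purrr::imap(function(g, gid) {
      t5 <- if (g$strand[1] == "-") max(g$tss) else min(g$tss)
      tibble(gene_id = gid, chrom = g$chrom[1], strand = g$strand[1],
             tss = t5, n_transcripts = nrow(g),
             biotype = g$biotype[match(t5, g$tss)])
    }) %>%
    bind_rows()
}

#' Biotype distribution of a transcript set
#'
#' Counts transcripts per biotype category, with fractions, in the fixed
#' category order.
#'
#' @param transcripts Tibble from [transcript_table()].
#' @return Tibble `biotype`, `n`, `fraction`.
#' @export
biotype_distribution <- function(transcripts) {
  transcripts %>%
    count(biotype = factor(.data$biotype, levels = biotype_levels()),
          .drop = FALSE) %>%
    mutate(biotype = as.character(.data$biotype),
           fraction = .data$n / sum(.data$n))
}

#' Spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for `-` strand transcripts, yielding the 5'->3' transcript
#' sequence.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param exons Exon tibble ([read_gtf()]).
#' @return Named character vector, one sequence per transcript.
#' @export
extract_transcript_sequences <- function(genome, exons) {
  out <- vapply(split(exons, exons$transcript_id), function(e) {
    e <- e[order(e$start), ]
    chrom_seq <- genome[[e$chrom[1]]]
    if (is.null(chrom_seq)) abort(sprintf("chromosome %s absent from genome",
                                          e$chrom[1]))
    s <- paste(substring(chrom_seq, e$start + 1L, e$end), collapse = "")
    if (e$strand[1] == "-") .revcomp(s) else s
  }, character(1))
  out
}

#' Bar plot of a biotype distribution
#'
#' @param distribution Tibble from [biotype_distribution()].
#' @return A ggplot object.
#' @export
plot_biotype_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = stats::reorder(.data$biotype, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
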