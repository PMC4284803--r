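# Active-promoter histone-mark evidence at transcript 5' ends.

#' Read one BED file per histone mark
#'
#' @param paths Named character vector of BED paths; names are mark names
#'   (e.g. `c(H3K4me3 = "k4me3.bed")`).
#' @return Tibble with `chrom`, `start`, `end`, `mark`.
#' @export
read_mark_beds <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("paths must be named by mark")
  }
  purrr::imap(paths, function(p, mk) {
    x <- read_bed(p)
    x$mark <- mk
    x[, c("chrom", "start", "end", "mark")]
  }) %>% bind_rows()
}

#' Promoter-mark evidence per transcript
#'
#' A transcript's 5' end is called active when at least one called region of
#' any mark overlaps the window `[tss - flank, tss + flank)` by at least
#' `min_overlap` bp. The window is strand-agnostic (it is symmetric about
#' the TSS).
#'
#' @param transcripts Tibble from [transcript_table()] (needs
#'   `transcript_id`, `chrom`, `tss`).
#' @param marks Tibble with `chrom`, `start`, `end`, `mark`
#'   ([read_mark_beds()]); may have zero rows.
#' @param flank Half-window around the TSS in bp (default 5000).
#' @param min_overlap Minimum overlap in bp to count a mark (default 1).
#' @return Tibble with `transcript_id`, one logical column per mark present
#'   in `marks`, and `active` (any mark TRUE).
#' @export
promoter_mark_evidence <- function(transcripts, marks, flank = 5000,
                                   min_overlap = 1) {
  win_start <- pmax(transcripts$tss - flank, 0)
  win <- tibble(chrom = transcripts$chrom,
                start = win_start,
                end = transcripts$tss + flank)
  mark_names <- sort(unique(marks$mark))
  out <- tibble(transcript_id = transcripts$transcript_id)
  if (length(mark_names) == 0 || nrow(marks) == 0) {
    out$active <- FALSE
    return(out)
  }
  gw <- as_granges0(win)
  for (mk in mark_names) {
    m <- marks[marks$mark == mk, ]
    gm <- as_granges0(m)
    ov <- GenomicRanges::findOverlaps(gw, gm,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
    out[[mk]] <- seq_len(nrow(win)) %in% S4Vectors::queryHits(ov)
  }
  out$active <- apply(as.matrix(out[, mark_names, drop = FALSE]), 1, any)
  out
}
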