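# Peak-to-TSS assignment, positional histograms, metagene profiles,
# interval overlap fractions.

#' Read an ENCODE narrowPeak file
#'
#' Ten whitespace-separated columns; column 10 is the summit offset from the
#' peak start (`-1` meaning absent, returned as `NA`).
#'
#' @param path Path to a narrowPeak file.
#' @return Tibble with `chrom`, `start`, `end`, `peak_id`, `score`, `strand`,
#'   `signal`, `p_value`, `q_value`, `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "peak_id", "score", "strand",
                  "signal", "p_value", "q_value", "summit_offset"),
    col_types = "ciicicdddi", progress = FALSE)
  x$summit_offset[x$summit_offset < 0] <- NA_integer_
  check_intervals(x, "narrowPeak table")
  bad <- which(!is.na(x$summit_offset) &
                 x$summit_offset >= (x$end - x$start))
  if (length(bad) > 0) {
    abort(sprintf("summit offset outside peak for %d record(s) (first: %s)",
                  length(bad), x$peak_id[bad[1]]))
  }
  x
}

#' Write peaks as narrowPeak
#'
#' @param peaks Tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  so <- peaks$summit_offset
  so[is.na(so)] <- -1L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.10g\t%.10g\t%.10g\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   peaks$score, peaks$strand, peaks$signal,
                   peaks$p_value, peaks$q_value, so)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand")[1:max(
                                         utils::count.fields(path, sep = "\t"))])
  x <- as_tibble(x)
  check_intervals(x, "BED table")
  x
}

#' Read a bedGraph coverage track
#'
#' Bases not covered by any record have value 0.
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid", comment = "track", progress = FALSE)
  check_intervals(x, "bedGraph table")
  x
}

#' Signed TSS distance of a peak reference point
#'
#' The reference point is the summit when available, otherwise the interval
#' midpoint (floor). The distance is `point - tss` for `+` genes and
#' `tss - point` for `-` genes, so positive values are downstream in the
#' direction of transcription.
#'
#' @param peak_start,peak_end Peak interval (0-based half-open).
#' @param summit_offset Summit offset from `peak_start`, or `NA`.
#' @param tss Gene TSS position.
#' @param gene_strand Gene strand (`"+"`/`"-"`).
#' @param reference_point `"summit"` (default; falls back to midpoint when the
#'   summit is absent) or `"midpoint"`.
#' @return Integer vector of signed distances.
#' @export
signed_tss_distance <- function(peak_start, peak_end, summit_offset, tss,
                                gene_strand,
                                reference_point = c("summit", "midpoint")) {
  reference_point <- match.arg(reference_point)
  mid <- peak_start + (peak_end - peak_start) %/% 2L
  point <- if (reference_point == "midpoint") mid else
    ifelse(is.na(summit_offset), mid, peak_start + summit_offset)
  as.integer(ifelse(gene_strand == "-", tss - point, point - tss))
}

#' Assign peaks to the nearest gene TSS
#'
#' Each peak is assigned to the gene (on the same chromosome) minimising the
#' absolute signed TSS distance; ties are broken by lexicographically
#' smallest `gene_id`. Peaks within `proximal_threshold` of the TSS
#' (boundary inclusive) are classed `proximal`, the rest `distal`. Peaks on
#' chromosomes absent from the gene set are kept with `NA` gene and class
#' `distal`.
#'
#' @param peaks Peak tibble ([read_narrowpeak()] columns; `summit_offset`
#'   optional).
#' @param genes Gene tibble with `gene_id`, `chrom`, `strand`, `tss`
#'   ([gene_table()]); pass a transcript-level table renamed accordingly for
#'   per-isoform assignment.
#' @param proximal_threshold Proximal cutoff in bp (default 10000).
#' @param reference_point See [signed_tss_distance()].
#' @return Input peaks plus `nearest_gene_id`, `signed_distance`, `klass`
#'   and, when `genes` carries a `biotype` column, `gene_biotype`.
#' @export
annotate_peaks <- function(peaks, genes, proximal_threshold = 10000,
                           reference_point = c("summit", "midpoint")) {
  reference_point <- match.arg(reference_point)
  check_intervals(peaks, "peak table")
  if (!"summit_offset" %in% names(peaks)) peaks$summit_offset <- NA_integer_
  genes <- arrange(genes, .data$gene_id)
  has_bt <- "biotype" %in% names(genes)
  out <- purrr::map(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) {
      return(tibble(nearest_gene_id = NA_character_,
                    signed_distance = NA_integer_, klass = "distal",
                    gene_biotype = NA_character_))
    }
    d <- signed_tss_distance(peaks$start[i], peaks$end[i],
                             peaks$summit_offset[i], g$tss, g$strand,
                             reference_point)
    j <- which(abs(d) == min(abs(d)))[1]  # genes sorted by id: lexicographic tie-break
    tibble(nearest_gene_id = g$gene_id[j],
           signed_distance = d[j],
           klass = if (abs(d[j]) <= proximal_threshold) "proximal" else "distal",
           gene_biotype = if (has_bt) g$biotype[j] else NA_character_)
  }) %>% bind_rows()
  res <- dplyr::bind_cols(peaks, out)
  if (!has_bt) res$gene_biotype <- NULL
  n_orphan <- sum(is.na(res$nearest_gene_id))
  if (n_orphan > 0) {
    warn(sprintf("%d peak(s) on chromosomes absent from the annotation; classed distal with no gene", n_orphan))
  }
  res
}

#' Histogram of peak positions around the TSS
#'
#' Counts annotated peaks by signed TSS distance in fixed-width bins covering
#' `[-window, +window)`, optionally stratified by a grouping column
#' (typically `gene_biotype`). Annotations beyond the window, or without an
#' assigned gene, are dropped.
#'
#' @param annotations Output of [annotate_peaks()].
#' @param bin_width Bin width in bp; must divide `2 * window`.
#' @param window Half-window in bp.
#' @param stratify_by Optional column name to stratify counts by.
#' @return Tibble with `bin_start`, `bin_end` (bp, signed), optional stratum
#'   column, and `count`; class `"lncsig_histogram"` for [autoplot()].
#' @export
positional_histogram <- function(annotations, bin_width = 1000,
                                 window = 10000, stratify_by = NULL) {
  if ((2 * window) %% bin_width != 0) {
    abort("bin_width must divide 2 * window")
  }
  edges <- seq(-window, window, by = bin_width)
  keep <- !is.na(annotations$signed_distance) &
    abs(annotations$signed_distance) <= window
  x <- annotations[keep, ]
  # |d| == +window falls in the last bin (top edge closed)
  bin <- pmin(findInterval(x$signed_distance, edges),
              length(edges) - 1L)
  grid <- tibble(bin = seq_len(length(edges) - 1L),
                 bin_start = edges[-length(edges)],
                 bin_end = edges[-1])
  if (is.null(stratify_by)) {
    counts <- tibble(bin = bin) %>% count(.data$bin)
    out <- left_join(grid, counts, by = "bin") %>%
      mutate(count = dplyr::coalesce(.data$n, 0L)) %>%
      select("bin_start", "bin_end", "count")
  } else {
    strata <- unique(x[[stratify_by]])
    full <- tidyr::expand_grid(grid, stratum = strata)
    counts <- tibble(bin = bin, stratum = x[[stratify_by]]) %>%
      count(.data$bin, .data$stratum)
    out <- left_join(full, counts, by = c("bin", "stratum")) %>%
      mutate(count = dplyr::coalesce(.data$n, 0L)) %>%
      select("bin_start", "bin_end", "stratum", "count")
  }
  class(out) <- c("lncsig_histogram", class(out))
  out
}

#' @method autoplot lncsig_histogram
#' @export
autoplot.lncsig_histogram <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                    y = .data$count)) +
    ggplot2::geom_col(fill = "firebrick", width = diff(object$bin_end[1:2] -
                                                         object$bin_start[1:2])) +
    ggplot2::labs(x = "signed distance to TSS (bp)", y = "peaks") +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~stratum, scales = "free_y")
  }
  p
}

# per-base signal over [lo, hi); overlapping records sum, absent bases are 0
.coverage_window <- function(cov_chrom, lo, hi) {
  vals <- numeric(hi - lo)
  if (is.null(cov_chrom) || nrow(cov_chrom) == 0) return(vals)
  hit <- cov_chrom$end > lo & cov_chrom$start < hi
  cc <- cov_chrom[hit, ]
  for (i in seq_len(nrow(cc))) {
    a <- max(cc$start[i], lo) - lo + 1L
    b <- min(cc$end[i], hi) - lo
    vals[a:b] <- vals[a:b] + cc$value[i]
  }
  vals
}

#' Strand-oriented average signal profile around anchors
#'
#' For each anchor (typically a TSS), signal over `[anchor - window,
#' anchor + window)` is extracted from a bedGraph-style track (absent bases
#' count 0), reversed for `-` strand anchors so that positive offsets point
#' downstream in the direction of transcription, averaged within fixed-width
#' bins, then averaged across anchors. Windows reaching past position 0 are
#' zero-padded and the anchor is flagged truncated.
#'
#' @param coverage Coverage tibble from [read_bedgraph()].
#' @param anchors Tibble with `chrom`, `tss`, `strand`.
#' @param window Half-window in bp.
#' @param bin Bin width in bp; must divide `2 * window`.
#' @return Tibble with `offset` (bin centre, bp) and `mean_signal`; class
#'   `"lncsig_profile"`, with attributes `n_anchors` and `n_truncated`.
#' @export
metagene_profile <- function(coverage, anchors, window = 10000, bin = 100) {
  if ((2 * window) %% bin != 0) abort("bin must divide 2 * window")
  if (nrow(anchors) == 0) abort("anchors must be non-empty")
  n_bins <- as.integer(2 * window / bin)
  acc <- numeric(n_bins)
  n_trunc <- 0L
  cov_split <- split(coverage, coverage$chrom)
  for (i in seq_len(nrow(anchors))) {
    lo <- anchors$tss[i] - window
    hi <- anchors$tss[i] + window
    vals <- numeric(2L * window)
    if (lo < 0) {
      n_trunc <- n_trunc + 1L
      vals[(1L - lo):(2L * window)] <-
        .coverage_window(cov_split[[anchors$chrom[i]]], 0L, hi)
    } else {
      vals <- .coverage_window(cov_split[[anchors$chrom[i]]], lo, hi)
    }
    if (anchors$strand[i] == "-") vals <- rev(vals)
    acc <- acc + colMeans(matrix(vals, nrow = bin))
  }
  out <- tibble(
    offset = seq(-window, window - bin, by = bin) + bin / 2,
    mean_signal = acc / nrow(anchors)
  )
  attr(out, "n_anchors") <- nrow(anchors)
  attr(out, "n_truncated") <- n_trunc
  class(out) <- c("lncsig_profile", class(out))
  out
}

#' @method autoplot lncsig_profile
#' @export
autoplot.lncsig_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean_signal)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Fraction of intervals in A overlapped by B
#'
#' The fraction of `a` intervals having at least one bp of overlap with any
#' interval in `b` (strand-agnostic).
#'
#' @param a,b Interval tibbles with `chrom`, `start`, `end`.
#' @return A length-1 numeric in `[0, 1]`.
#' @export
interval_overlap_fraction <- function(a, b) {
  if (nrow(a) == 0) abort("interval set A is empty; overlap fraction undefined")
  check_intervals(a, "set A"); check_intervals(b, "set B")
  if (nrow(b) == 0) return(0)
  ga <- as_granges0(a); gb <- as_granges0(b)
  hits <- GenomicRanges::countOverlaps(ga, gb, ignore.strand = TRUE)
  mean(hits > 0)
}
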