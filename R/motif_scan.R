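# PWM scanning, dimeric p53 response-element matching, enrichment testing.

.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
               S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a position-weight matrix from an IUPAC consensus
#'
#' Each consensus letter's allowed bases share probability
#' `1 - pseudo_mass`; the remaining mass is spread over disallowed bases, so
#' every entry is strictly positive.
#'
#' @param consensus IUPAC consensus string.
#' @param pseudo_mass Total probability assigned to disallowed bases per
#'   column (default 0.04).
#' @param background Background base distribution (default uniform).
#' @return Object of class `"pwm"`: list with `mat` (4 x width probability
#'   matrix, rows A/C/G/T), `background`, `width`.
#' @export
pwm_from_consensus <- function(consensus, pseudo_mass = 0.04,
                               background = c(A = .25, C = .25,
                                              G = .25, T = .25)) {
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters_, names(.iupac))
  if (length(bad) > 0) abort(sprintf("unknown IUPAC code(s): %s",
                                     paste(unique(bad), collapse = ", ")))
  mat <- vapply(letters_, function(l) {
    allowed <- .iupac[[l]]
    p <- rep(pseudo_mass / (4 - length(allowed)), 4)
    if (length(allowed) == 4) p <- rep(0, 4)
    names(p) <- c("A", "C", "G", "T")
    p[allowed] <- (1 - sum(p[setdiff(names(p), allowed)])) / length(allowed)
    p
  }, numeric(4))
  new_pwm(mat, background)
}

#' Construct a PWM object from a probability matrix
#'
#' @param mat 4 x width matrix of column-stochastic probabilities, rows
#'   named A, C, G, T.
#' @param background Background base distribution summing to 1.
#' @return A `"pwm"` object.
#' @export
new_pwm <- function(mat, background = c(A = .25, C = .25, G = .25, T = .25)) {
  mat <- as.matrix(mat)
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-6)) abort("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  if (any(mat <= 0)) abort("PWM entries must be strictly positive (apply a pseudocount)")
  structure(list(mat = mat, background = background[c("A", "C", "G", "T")],
                 width = ncol(mat)),
            class = "pwm")
}

#' Read a PWM from MEME minimal text format
#'
#' Parses the first `letter-probability matrix` block. A zero entry is
#' replaced by `pseudo` and the column renormalised.
#'
#' @param path Path to a MEME minimal-format motif file.
#' @param pseudo Floor applied to zero probabilities (default 1e-4).
#' @return A `"pwm"` object.
#' @export
read_meme_pwm <- function(path, pseudo = 1e-4) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix", lines)
  if (length(hdr) == 0) abort("no letter-probability matrix block found")
  rows <- list()
  i <- hdr[1] + 1
  while (i <= length(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 4 || anyNA(v)) break
    rows[[length(rows) + 1]] <- v
    i <- i + 1
  }
  if (length(rows) == 0) abort("empty letter-probability matrix")
  mat <- t(do.call(rbind, rows))
  mat[mat <= 0] <- pseudo
  mat <- sweep(mat, 2, colSums(mat), "/")
  # background from the "Background letter frequencies" line when present
  bgl <- grep("^Background letter frequencies", lines)
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  if (length(bgl) > 0 && bgl[1] + 1 <= length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    if (length(tok) >= 8) {
      v <- as.numeric(tok[c(2, 4, 6, 8)])
      if (!anyNA(v)) bg <- setNames(v, tok[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
    }
  }
  new_pwm(mat, bg)
}

#' Canonical dimeric p53 response-element consensus PWM
#'
#' Two `RRRCWWGYYY` half-sites with no spacer, as a probability PWM. For
#' spacer-aware consensus matching use [p53re_scan()] instead.
#'
#' @inheritParams pwm_from_consensus
#' @return A `"pwm"` object of width 20.
#' @export
p53_pwm <- function(pseudo_mass = 0.04) {
  pwm_from_consensus("RRRCWWGYYYRRRCWWGYYY", pseudo_mass = pseudo_mass)
}

# log2-odds score of every window on the forward strand of one sequence
.pwm_scores_forward <- function(chars, pwm) {
  n <- length(chars)
  w <- pwm$width
  if (n < w) return(numeric(0))
  lo <- log2(pwm$mat / matrix(pwm$background, nrow = 4, ncol = w))
  idx <- match(chars, c("A", "C", "G", "T"))  # NA for N: scores 0
  scores <- numeric(n - w + 1)
  for (j in seq_len(w)) {
    contrib <- lo[, j][idx[j:(n - w + j)]]
    contrib[is.na(contrib)] <- 0
    scores <- scores + contrib
  }
  scores
}

#' Scan sequences with a PWM
#'
#' Reports every window on both strands whose log2-odds score (PWM versus
#' background) reaches `threshold`. `N` bases contribute a score of 0.
#' Offsets are 0-based positions of the window start on the forward strand;
#' results are sorted by offset.
#'
#' @param seqs Named character vector of sequences.
#' @param pwm A `"pwm"` object.
#' @param threshold Minimum log2-odds score in bits.
#' @return Tibble with `seq_id`, `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(seqs, pwm, threshold) {
  stopifnot(inherits(pwm, "pwm"))
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  purrr::map2(seqs, ids, function(s, id) {
    s <- toupper(s)
    n <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    fwd <- .pwm_scores_forward(chars, pwm)
    rc <- strsplit(.revcomp(s), "")[[1]]
    rev_ <- .pwm_scores_forward(rc, pwm)
    hits <- bind_rows(
      tibble(offset = which(fwd >= threshold) - 1L, strand = "+",
             score = fwd[fwd >= threshold]),
      tibble(offset = n - pwm$width - (which(rev_ >= threshold) - 1L),
             strand = "-", score = rev_[rev_ >= threshold])
    )
    if (nrow(hits) == 0) return(tibble(seq_id = character(), offset = integer(),
                                       strand = character(), score = numeric()))
    hits %>% mutate(seq_id = id, offset = as.integer(.data$offset)) %>%
      select("seq_id", "offset", "strand", "score") %>%
      arrange(.data$offset, .data$strand)
  }) %>% bind_rows()
}

# half-site RRRCWWGYYY mismatch counts at every start of a character vector
.halfsite_mismatches <- function(chars) {
  pattern <- c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y")
  n <- length(chars)
  if (n < 10) return(integer(0))
  m <- integer(n - 9L)
  for (j in seq_len(10)) {
    m <- m + as.integer(!(chars[j:(n - 10L + j)] %in% .iupac[[pattern[j]]]))
  }
  m
}

#' Scan for dimeric p53 response elements
#'
#' Matches the canonical element `RRRCWWGYYY-N(s)-RRRCWWGYYY` (two half-sites
#' with a spacer of `s` nt) allowing up to `max_mismatch` mismatches over the
#' 20 informative positions, for every spacer in `spacer_range`. The dimer
#' consensus is exactly its own reverse complement, so a forward scan
#' enumerates all hits; each is reported once with strand `"+"`. `N` bases
#' count as mismatches.
#'
#' @param seqs Named character vector of sequences.
#' @param max_mismatch Maximum total mismatches (default 2).
#' @param spacer_range Integer vector of allowed spacer lengths (default 0:13).
#' @return Tibble with `seq_id`, `offset` (0-based), `strand`, `spacer`,
#'   `mismatches`, sorted by offset then spacer.
#' @examples
#' p53re_scan(c(x = "GGGCATGTCCGGGCATGTCC"))
#' @export
p53re_scan <- function(seqs, max_mismatch = 2, spacer_range = 0:13) {
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  purrr::map2(seqs, ids, function(s, id) {
    chars <- strsplit(toupper(s), "")[[1]]
    n <- length(chars)
    m <- .halfsite_mismatches(chars)
    out <- purrr::map(spacer_range, function(sp) {
      total_w <- 20L + sp
      if (n < total_w) return(NULL)
      i <- seq_len(n - total_w + 1L)
      mm <- m[i] + m[i + 10L + sp]
      hit <- which(mm <= max_mismatch)
      if (length(hit) == 0) return(NULL)
      tibble(offset = hit - 1L, spacer = sp, mismatches = mm[hit])
    }) %>% bind_rows()
    if (nrow(out) == 0) return(tibble(seq_id = character(), offset = integer(),
                                      strand = character(), spacer = integer(),
                                      mismatches = integer()))
    out %>% mutate(seq_id = id, strand = "+",
                   offset = as.integer(.data$offset),
                   spacer = as.integer(.data$spacer),
                   mismatches = as.integer(.data$mismatches)) %>%
      select("seq_id", "offset", "strand", "spacer", "mismatches") %>%
      arrange(.data$offset, .data$spacer)
  }) %>% bind_rows()
}

#' Motif enrichment in foreground versus background sequences
#'
#' Applies a scanner to both sets, reduces each sequence to a binary hit
#' indicator, and tests enrichment with a one-sided exact test
#' (foreground more often hit) on the 2x2 table. Fold is the ratio of hit
#' fractions (`Inf` when the background fraction is 0 and the foreground
#' fraction is positive).
#'
#' @param foreground_seqs,background_seqs Non-empty character vectors; the
#'   background should be length-matched to the foreground.
#' @param scanner Scanning function, e.g. [p53re_scan()] or [scan_pwm()];
#'   must accept a character vector first and return a tibble with `seq_id`.
#' @param ... Passed to `scanner`.
#' @return One-row tibble of class `"lncsig_enrichment"` with `fg_hits`,
#'   `fg_n`, `bg_hits`, `bg_n`, `fg_fraction`, `bg_fraction`, `fold`,
#'   `p_value`.
#' @export
motif_enrichment <- function(foreground_seqs, background_seqs,
                             scanner = p53re_scan, ...) {
  if (length(foreground_seqs) == 0 || length(background_seqs) == 0) {
    abort("both sequence sets must be non-empty")
  }
  hit_flags <- function(seqs) {
    ids <- paste0("s", seq_along(seqs))
    names(seqs) <- ids
    hits <- scanner(seqs, ...)
    ids %in% unique(hits$seq_id)
  }
  fg <- hit_flags(foreground_seqs)
  bg <- hit_flags(background_seqs)
  tab <- matrix(c(sum(fg), sum(!fg), sum(bg), sum(!bg)), nrow = 2,
                byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  fg_frac <- mean(fg); bg_frac <- mean(bg)
  out <- tibble(fg_hits = sum(fg), fg_n = length(fg),
                bg_hits = sum(bg), bg_n = length(bg),
                fg_fraction = fg_frac, bg_fraction = bg_frac,
                fold = if (bg_frac == 0 && fg_frac == 0) NaN
                       else fg_frac / bg_frac,
                p_value = p)
  class(out) <- c("lncsig_enrichment", class(out))
  out
}

#' Extract peak sequences from a genome
#'
#' Takes `window` bp either side of each peak's reference point (summit when
#' present, else midpoint), clipped to chromosome bounds.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param peaks Peak tibble (narrowPeak columns).
#' @param window Half-width in bp (default 250).
#' @return Named character vector of sequences (names = `peak_id`).
#' @export
extract_peak_sequences <- function(genome, peaks, window = 250) {
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  so <- if ("summit_offset" %in% names(peaks)) peaks$summit_offset else
    rep(NA_integer_, nrow(peaks))
  point <- ifelse(is.na(so), mid, peaks$start + so)
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    chrom_seq <- genome[[peaks$chrom[i]]]
    if (is.null(chrom_seq)) abort(sprintf("chromosome %s absent from genome",
                                          peaks$chrom[i]))
    a <- max(point[i] - window, 0)
    b <- min(point[i] + window, nchar(chrom_seq))
    substring(chrom_seq, a + 1L, b)
  }, character(1))
  names(out) <- if ("peak_id" %in% names(peaks)) peaks$peak_id else
    paste0("peak_", seq_len(nrow(peaks)))
  out
}
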