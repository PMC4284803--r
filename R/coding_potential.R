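# CPAT-style coding potential: longest ORF, Fickett TESTCODE statistic,
# hexamer usage bias, logistic combination.

#' Read sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.norm_seq <- function(seq) chartr("u", "T", chartr("U", "T", toupper(seq)))

.stop_codons <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the sense strand
#'
#' Scans the three sense frames for the longest ATG-to-stop reading frame
#' (length includes the stop codon). Codons containing `N` match neither
#' start nor stop. Transcripts are oriented, so the antisense strand is not
#' scanned. Ties on length are broken by the smallest start offset.
#'
#' @param seq Character vector of nucleotide sequences (`A`/`C`/`G`/`T`/`U`/`N`).
#' @return Tibble with one row per input: `orf_start` (0-based nt offset, `NA`
#'   when no ORF), `orf_length` (nt, multiple of 3, 0 when none) and
#'   `orf_coverage` (`orf_length / nchar(seq)`).
#' @examples
#' longest_orf("ATGAAATAA")
#' @export
longest_orf <- function(seq) {
  purrr::map(seq, function(s) {
    s <- .norm_seq(s)
    n <- nchar(s)
    best_len <- 0L; best_start <- NA_integer_
    if (n >= 6) {
      for (f in 0:2) {
        n_codons <- (n - f) %/% 3L
        if (n_codons < 2) next
        pos <- f + 3L * (seq_len(n_codons) - 1L)
        codons <- substring(s, pos + 1L, pos + 3L)
        starts <- which(codons == "ATG")
        stops <- which(codons %in% .stop_codons)
        if (length(starts) == 0 || length(stops) == 0) next
        for (i in starts) {
          j <- stops[stops > i]
          if (length(j) == 0) next
          len <- (j[1] - i + 1L) * 3L
          st <- pos[i]
          if (len > best_len || (len == best_len && !is.na(best_start) &&
                                 st < best_start)) {
            best_len <- len; best_start <- st
          }
        }
      }
    }
    tibble(orf_start = best_start, orf_length = best_len,
           orf_coverage = if (n > 0) best_len / n else 0)
  }) %>% bind_rows()
}

# Fickett (1982) TESTCODE lookup tables, as used by CPAT.
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0.0)

.fickett_lookup <- function(value, para, prob) {
  idx <- which(value >= para)
  if (length(idx) == 0) prob[length(prob)] else prob[idx[1]]
}

#' Fickett TESTCODE statistic
#'
#' Computes the classic position-bias and base-composition statistic from the
#' published lookup tables. For each base, the position parameter is the
#' maximum count over the three codon positions divided by the minimum plus
#' one; the content parameter is the base's overall fraction. Both are
#' converted through the lookup tables and combined as a weighted sum. `N`
#' bases are ignored in the counts. Sequences shorter than `min_length` are
#' still scored but flagged in the `low_confidence` attribute.
#'
#' @param seq Character vector of sequences.
#' @param min_length Minimum length for a confident score (default 200 nt,
#'   the conventional lncRNA length floor).
#' @return Numeric vector of Fickett scores, with attribute
#'   `low_confidence` (logical vector).
#' @export
fickett_score <- function(seq, min_length = 200) {
  scores <- vapply(seq, function(s) {
    s <- .norm_seq(s)
    chars <- strsplit(s, "")[[1]]
    keep <- chars %in% c("A", "C", "G", "T")
    if (!any(keep)) return(0)
    phase <- ((seq_along(chars) - 1L) %% 3L) + 1L
    total <- 0
    for (b in c("A", "C", "G", "T")) {
      cnt <- vapply(1:3, function(p) sum(chars == b & phase == p & keep),
                    numeric(1))
      pos_val <- max(cnt) / (min(cnt) + 1)
      cont_val <- sum(cnt) / sum(keep)
      total <- total +
        .fickett_lookup(pos_val, .fickett_position_para,
                        .fickett_position_prob[[b]]) *
        .fickett_position_weight[[b]] +
        .fickett_lookup(cont_val, .fickett_content_para,
                        .fickett_content_prob[[b]]) *
        .fickett_content_weight[[b]]
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
  attr(scores, "low_confidence") <- nchar(seq) < min_length
  scores
}

.all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste0, collapse = ""))
}

.count_hexamers <- function(seqs, step) {
  counts <- setNames(numeric(4096), .all_hexamers())
  for (s in seqs) {
    s <- .norm_seq(s)
    n <- nchar(s)
    if (n < 6) next
    pos <- seq.int(1L, n - 5L, by = step)
    hx <- substring(s, pos, pos + 5L)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx) > 0) {
      tb <- table(hx)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  counts
}

#' Train a hexamer usage table
#'
#' In-frame hexamer frequencies (step 3, frame of the sequence start) for the
#' coding training set and all-frame frequencies (step 1) for the noncoding
#' set. A pseudocount is added to every hexamer count before normalisation so
#' all probabilities are strictly positive.
#'
#' @param coding_seqs,noncoding_seqs Non-empty character vectors of training
#'   sequences (coding ones expected to start in-frame, e.g. CDS sequences).
#' @param pseudocount Added to each of the 4096 counts (default `1/4096`).
#' @return Object of class `"hexamer_table"`: list with `coding` and
#'   `noncoding` probability vectors (each summing to 1) and `pseudocount`.
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1 / 4096) {
  if (length(coding_seqs) == 0 || length(noncoding_seqs) == 0) {
    abort("both training sets must be non-empty")
  }
  cod <- .count_hexamers(coding_seqs, step = 3L) + pseudocount
  noncod <- .count_hexamers(noncoding_seqs, step = 1L) + pseudocount
  structure(list(coding = cod / sum(cod),
                 noncoding = noncod / sum(noncod),
                 pseudocount = pseudocount),
            class = "hexamer_table")
}

#' Hexamer log-likelihood ratio of a sequence
#'
#' Mean `log(p_coding / p_noncoding)` over the sequence's hexamers taken with
#' step 3 in the frame of the longest ORF (frame 0 when no ORF exists).
#' Hexamers containing `N` are skipped. Sequences shorter than 6 nt score 0.
#'
#' @param seq Character vector of sequences.
#' @param table A `"hexamer_table"` from [train_hexamer_table()].
#' @return Numeric vector of mean log-likelihood ratios.
#' @export
hexamer_llr <- function(seq, table) {
  stopifnot(inherits(table, "hexamer_table"))
  lr <- log(table$coding / table$noncoding)
  orf <- longest_orf(seq)
  vapply(seq_along(seq), function(i) {
    s <- .norm_seq(seq[i])
    n <- nchar(s)
    if (n < 6) return(0)
    frame <- if (is.na(orf$orf_start[i])) 0L else orf$orf_start[i] %% 3L
    pos <- seq.int(frame + 1L, n - 5L, by = 3L)
    if (length(pos) == 0) return(0)
    hx <- substring(s, pos, pos + 5L)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx) == 0) return(0)
    mean(lr[hx])
  }, numeric(1))
}

#' Coding-potential features of transcript sequences
#'
#' @param seqs Named character vector of sequences.
#' @param hexamer_table A trained [train_hexamer_table()] object.
#' @return Tibble with `seq_id`, `orf_length`, `orf_coverage`, `fickett`,
#'   `hexamer_llr`.
#' @export
coding_features <- function(seqs, hexamer_table) {
  orf <- longest_orf(seqs)
  tibble(
    seq_id = if (is.null(names(seqs))) as.character(seq_along(seqs))
             else names(seqs),
    orf_length = orf$orf_length,
    orf_coverage = orf$orf_coverage,
    fickett = as.numeric(fickett_score(seqs)),
    hexamer_llr = hexamer_llr(seqs, hexamer_table)
  )
}

.coding_feature_names <- c("orf_length", "orf_coverage", "fickett",
                           "hexamer_llr")

#' Train a coding-potential model
#'
#' Trains the hexamer table on the provided sets, extracts the four features
#' for every training sequence and fits a logistic model (coding = 1) by
#' IRLS ([fit_logistic()]). ORF length enters the model as `log1p`.
#'
#' @param coding_seqs,noncoding_seqs Training sequences.
#' @param pseudocount Hexamer pseudocount.
#' @param cutoff Decision cutoff on the coding probability, strictly in
#'   (0, 1). The default 0.364 is the published human CPAT cutoff.
#' @return Object of class `"coding_model"` with elements `weights`
#'   (named, incl. `(Intercept)`), `cutoff`, `hexamer_table`, `fit`.
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs,
                               pseudocount = 1 / 4096, cutoff = 0.364) {
  if (cutoff <= 0 || cutoff >= 1) abort("cutoff must be strictly in (0, 1)")
  # align coding training sequences to their longest ORF so the in-frame
  # hexamer table is codon-phased even for full transcripts with 5' UTRs
  orf <- longest_orf(coding_seqs)
  aligned <- substring(coding_seqs,
                       ifelse(is.na(orf$orf_start), 1L, orf$orf_start + 1L))
  ht <- train_hexamer_table(aligned, noncoding_seqs, pseudocount)
  feats <- coding_features(c(coding_seqs, noncoding_seqs), ht)
  y <- c(rep(1L, length(coding_seqs)), rep(0L, length(noncoding_seqs)))
  x <- .coding_design(feats)
  fit <- fit_logistic(x, y)
  structure(list(weights = c(fit$intercept, fit$weights),
                 cutoff = cutoff, hexamer_table = ht, fit = fit),
            class = "coding_model")
}

.coding_design <- function(features) {
  miss <- setdiff(.coding_feature_names, names(features))
  if (length(miss) > 0) {
    abort(sprintf("missing coding feature(s): %s", paste(miss, collapse = ", ")))
  }
  cbind(orf_length = log1p(features$orf_length),
        orf_coverage = features$orf_coverage,
        fickett = features$fickett,
        hexamer_llr = features$hexamer_llr)
}

#' Coding probability of transcripts
#'
#' Logistic transform of the weighted feature sum; `coding` is TRUE when the
#' probability is at or above the model cutoff.
#'
#' @param features Feature tibble from [coding_features()].
#' @param model A `"coding_model"` from [train_coding_model()].
#' @return `features` with added `coding_prob` and `coding` columns.
#' @export
coding_probability <- function(features, model) {
  stopifnot(inherits(model, "coding_model"))
  x <- .coding_design(features)
  eta <- drop(x %*% unname(model$weights[-1])) + unname(model$weights[1])
  p <- unname(stats::plogis(eta))
  features %>% mutate(coding_prob = p, coding = p >= model$cutoff)
}

#' Write a coding model as a plain-text key/value file
#'
#' @param model A `"coding_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coding_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("cutoff\t%.17g", model$cutoff), con)
  writeLines(sprintf("pseudocount\t%.17g", model$hexamer_table$pseudocount), con)
  nm <- c("intercept", .coding_feature_names)
  writeLines(sprintf("weight_%s\t%.17g", nm, model$weights), con)
  hx <- names(model$hexamer_table$coding)
  writeLines(sprintf("hexamer_%s\t%.17g\t%.17g", hx,
                     model$hexamer_table$coding,
                     model$hexamer_table$noncoding), con)
  invisible(path)
}

#' Read a coding model written by [write_coding_model()]
#'
#' @param path Path to the model file.
#' @return A `"coding_model"` object.
#' @export
read_coding_model <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, character(1), 1)
  val1 <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  wnames <- paste0("weight_", c("intercept", .coding_feature_names))
  weights <- val1[match(wnames, keys)]
  hx_rows <- startsWith(keys, "hexamer_")
  hx <- sub("^hexamer_", "", keys[hx_rows])
  cod <- setNames(val1[hx_rows], hx)
  noncod <- setNames(vapply(parts[hx_rows], function(p) as.numeric(p[3]),
                            numeric(1)), hx)
  ht <- structure(list(coding = cod[.all_hexamers()],
                       noncoding = noncod[.all_hexamers()],
                       pseudocount = val1[keys == "pseudocount"]),
                  class = "hexamer_table")
  structure(list(weights = weights, cutoff = val1[keys == "cutoff"],
                 hexamer_table = ht, fit = NULL),
            class = "coding_model")
}
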