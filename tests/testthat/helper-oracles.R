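# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops, substring walks and direct summations.

# tie-corrected all-pairs concordance AUC
bf_auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# fraction of intervals in a overlapped by >= 1 interval of b (quadratic)
bf_overlap_fraction <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  mean(hit)
}

# positional histogram recount (single stratum)
bf_histogram_counts <- function(distances, bin_width, window) {
  edges <- seq(-window, window, by = bin_width)
  counts <- integer(length(edges) - 1)
  for (d in distances) {
    if (is.na(d) || abs(d) > window) next
    for (k in seq_len(length(counts))) {
      top_closed <- k == length(counts)
      if (d >= edges[k] && (d < edges[k + 1] || (top_closed && d <= edges[k + 1]))) {
        counts[k] <- counts[k] + 1
        break
      }
    }
  }
  counts
}

# exhaustive longest-ORF scan: every ATG anywhere, walk codons to a stop
bf_longest_orf <- function(s) {
  s <- toupper(chartr("Uu", "TT", s))
  n <- nchar(s)
  best_len <- 0L
  best_start <- NA_integer_
  i <- 1L
  while (i + 2 <= n) {
    if (substring(s, i, i + 2) == "ATG") {
      k <- i + 3L
      while (k + 2 <= n) {
        cod <- substring(s, k, k + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          len <- k + 2L - i + 1L
          if (len > best_len ||
              (len == best_len && !is.na(best_start) && i - 1L < best_start)) {
            best_len <- as.integer(len)
            best_start <- i - 1L
          }
          break
        }
        k <- k + 3L
      }
    }
    i <- i + 1L
  }
  list(start = best_start, length = best_len)
}

# second, loop-based Fickett implementation from the published tables
bf_fickett <- function(s) {
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  con_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0.0)
  look <- function(v, para, prob) {
    for (i in seq_along(para)) if (v >= para[i]) return(prob[i])
    prob[length(prob)]
  }
  chars <- strsplit(toupper(s), "")[[1]]
  total <- 0
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(0, 0, 0)
    for (i in seq_along(chars)) {
      if (chars[i] == b) {
        cnt[(i - 1) %% 3 + 1] <- cnt[(i - 1) %% 3 + 1] + 1
      }
    }
    pv <- max(cnt) / (min(cnt) + 1)
    cv <- sum(cnt) / n_acgt
    total <- total + look(pv, pos_para, pos_prob[[b]]) * pos_w[[b]] +
      look(cv, con_para, con_prob[[b]]) * con_w[[b]]
  }
  total
}

# hexamer counting by explicit walk
bf_hexamer_counts <- function(seqs, step) {
  counts <- new.env()
  for (s in seqs) {
    s <- toupper(s)
    i <- 1L
    while (i + 5 <= nchar(s)) {
      h <- substring(s, i, i + 5)
      if (!grepl("[^ACGT]", h)) {
        counts[[h]] <- (if (is.null(counts[[h]])) 0 else counts[[h]]) + 1
      }
      i <- i + step
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) numeric(0) else out
}

# exhaustive dimeric response-element enumeration by substring comparison
bf_p53re_hits <- function(s, max_mismatch = 2, spacer_range = 0:13) {
  iupac <- list(R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                C = "C", G = "G")
  pat <- c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y")
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  half_mm <- function(at) {
    mm <- 0L
    for (j in 1:10) {
      if (!(chars[at + j - 1] %in% iupac[[pat[j]]])) mm <- mm + 1L
    }
    mm
  }
  hits <- list()
  for (sp in spacer_range) {
    total_w <- 20L + sp
    if (n < total_w) next
    for (i in seq_len(n - total_w + 1L)) {
      mm <- half_mm(i) + half_mm(i + 10L + sp)
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- c(offset = i - 1L, spacer = sp,
                                      mismatches = mm)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), spacer = integer(),
                      mismatches = integer()))
  }
  out <- as.data.frame(do.call(rbind, hits))
  out[order(out$offset, out$spacer), ]
}

# exhaustive PWM log2-odds scoring on both strands
bf_pwm_hits <- function(s, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_at <- function(chars, i) {
    sc <- 0
    for (j in seq_len(pwm$width)) {
      b <- chars[i + j - 1]
      if (b %in% c("A", "C", "G", "T")) {
        sc <- sc + log2(pwm$mat[b, j] / pwm$background[[b]])
      }
    }
    sc
  }
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  rc <- rev(unname(comp[chars]))
  hits <- list()
  if (n >= pwm$width) {
    for (i in seq_len(n - pwm$width + 1L)) {
      sc <- score_at(chars, i)
      if (sc >= threshold) {
        hits[[length(hits) + 1]] <- data.frame(offset = i - 1L, strand = "+",
                                               score = sc)
      }
      sc_rc <- score_at(rc, i)
      if (sc_rc >= threshold) {
        hits[[length(hits) + 1]] <- data.frame(offset = n - pwm$width - i + 1L,
                                               strand = "-", score = sc_rc)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), ]
}

# hypergeometric upper tail by direct PMF summation
bf_hyper_tail <- function(q, m, n, k) {
  sum(stats::dhyper(q:min(k, m), m, n, k))
}

# direct Newton maximisation of the logistic log-likelihood
bf_newton_logistic <- function(x, y, iters = 50) {
  X <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(X))
  for (it in seq_len(iters)) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    grad <- drop(t(X) %*% (y - mu))
    hess <- -t(X) %*% (X * (mu * (1 - mu)))
    beta <- beta - solve(hess, grad)
  }
  beta
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
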