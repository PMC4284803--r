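toy_genes <- function(...) {
  g <- tibble::tibble(...)
  if (!"biotype" %in% names(g)) g$biotype <- "mRNA"
  g
}

toy_peak <- function(chrom, start, end, summit_offset = NA_integer_,
                     peak_id = "p1") {
  tibble::tibble(chrom = chrom, start = start, end = end, peak_id = peak_id,
                 score = 0L, strand = ".", signal = 1, p_value = 1,
                 q_value = 1, summit_offset = summit_offset)
}

test_that("signed TSS distance follows the strand-aware sign convention", {
  # summit exactly at the TSS
  expect_equal(signed_tss_distance(990L, 1010L, 10L, 1000L, "+"), 0L)
  # downstream of a + gene
  expect_equal(signed_tss_distance(12900L, 13100L, 100L, 10000L, "+"), 3000L)
  # same point, - gene: sign flips
  expect_equal(signed_tss_distance(12900L, 13100L, 100L, 10000L, "-"), -3000L)
  # midpoint fallback when the summit is absent
  expect_equal(signed_tss_distance(100L, 200L, NA_integer_, 150L, "+"), 0L)
  # antisymmetry under gene strand flip, vectorised
  d_plus <- signed_tss_distance(0L, 50L, 10L, c(5L, 30L, 200L), "+")
  d_minus <- signed_tss_distance(0L, 50L, 10L, c(5L, 30L, 200L), "-")
  expect_equal(d_plus, -d_minus)
})

test_that("proximal/distal classification is inclusive at the 10 kb boundary", {
  genes <- toy_genes(gene_id = "g1", chrom = "chr1", strand = "+",
                     tss = 100000L)
  at <- function(d) annotate_peaks(toy_peak("chr1", 100000L + d - 50L,
                                            100000L + d + 50L, 50L), genes)
  expect_equal(at(9999L)$klass, "proximal")
  expect_equal(at(10000L)$klass, "proximal")
  expect_equal(at(10001L)$klass, "distal")
  expect_equal(at(-10001L)$klass, "distal")
})

test_that("equidistant genes resolve to the lexicographically smallest id", {
  genes <- toy_genes(gene_id = c("gB", "gA"), chrom = "chr1",
                     strand = c("+", "+"), tss = c(900L, 1100L))
  ann <- annotate_peaks(toy_peak("chr1", 950L, 1050L, 50L), genes)
  expect_equal(ann$nearest_gene_id, "gA")
})

test_that("peaks on unannotated chromosomes are kept, flagged distal", {
  genes <- toy_genes(gene_id = "g1", chrom = "chr1", strand = "+", tss = 0L)
  pk <- dplyr::bind_rows(toy_peak("chr1", 10L, 110L, 50L, "p1"),
                         toy_peak("chrUn", 10L, 110L, 50L, "p2"))
  expect_warning(ann <- annotate_peaks(pk, genes), "absent")
  expect_equal(nrow(ann), 2)
  expect_true(is.na(ann$nearest_gene_id[2]))
  expect_equal(ann$klass[2], "distal")
})

test_that("growing the proximal threshold never shrinks the proximal set", {
  set.seed(11)
  genes <- toy_genes(gene_id = sprintf("g%02d", 1:8), chrom = "chr1",
                     strand = sample(c("+", "-"), 8, TRUE),
                     tss = sort(sample.int(2e5, 8)))
  pk <- dplyr::bind_rows(lapply(1:40, function(i) {
    s <- sample.int(2e5, 1)
    toy_peak("chr1", s, s + 200L, 100L, sprintf("p%02d", i))
  }))
  prox <- function(thr) {
    a <- annotate_peaks(pk, genes, proximal_threshold = thr)
    a$peak_id[a$klass == "proximal"]
  }
  sets <- lapply(c(2000, 5000, 10000, 50000), prox)
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  # partition: every peak classed exactly once
  a <- annotate_peaks(pk, genes)
  expect_equal(sort(a$peak_id), sort(pk$peak_id))
  expect_true(all(a$klass %in% c("proximal", "distal")))
})

test_that("positional histogram matches a direct recount", {
  genes <- toy_genes(gene_id = "g1", chrom = "chr1", strand = "+", tss = 0L)
  one <- annotate_peaks(toy_peak("chr1", 2450L, 2550L, 50L), genes)
  h <- positional_histogram(one, bin_width = 5000, window = 10000)
  expect_equal(h$count[h$bin_start == 0], 1)
  expect_equal(sum(h$count), 1)

  empty <- one[0, ]
  h0 <- positional_histogram(empty, bin_width = 5000, window = 10000)
  expect_true(all(h0$count == 0))

  set.seed(21)
  rnd <- one[rep(1, 1000), ]
  rnd$signed_distance <- as.integer(sample(-12000:12000, 1000, TRUE))
  h1 <- positional_histogram(rnd, bin_width = 1000, window = 10000)
  expect_equal(h1$count,
               bf_histogram_counts(rnd$signed_distance, 1000, 10000))
  expect_equal(sum(h1$count), sum(abs(rnd$signed_distance) <= 10000))

  expect_error(positional_histogram(one, bin_width = 3000, window = 10000),
               "divide")
})

test_that("metagene profile handles constants, impulses and strand flips", {
  anchors <- tibble::tibble(chrom = "chr1", tss = c(5000L, 9000L),
                            strand = c("+", "+"))
  const <- tibble::tibble(chrom = "chr1", start = 0L, end = 20000L,
                          value = 3.5)
  prof <- metagene_profile(const, anchors, window = 1000, bin = 100)
  expect_true(all(abs(prof$mean_signal - 3.5) < 1e-12))

  impulse <- tibble::tibble(chrom = "chr1", start = c(5000L, 9000L),
                            end = c(5001L, 9001L), value = 1)
  prof2 <- metagene_profile(impulse, anchors, window = 1000, bin = 100)
  expect_equal(prof2$offset[which.max(prof2$mean_signal)], 50)  # bin [0,100)

  # impulse 100 bp 3' of a minus-strand TSS appears at +100 after the flip
  minus <- tibble::tibble(chrom = "chr1", tss = 5000L, strand = "-")
  imp <- tibble::tibble(chrom = "chr1", start = 4900L, end = 4901L, value = 1)
  prof3 <- metagene_profile(imp, minus, window = 1000, bin = 100)
  # offset +100 lands in the (0,100] bin under the orientation flip
  expect_equal(prof3$offset[which.max(prof3$mean_signal)], 50)

  # linearity: profile of a sum of tracks = sum of profiles
  t1 <- tibble::tibble(chrom = "chr1", start = c(4000L, 5500L),
                       end = c(5200L, 6100L), value = c(2, 1))
  prof_t1 <- metagene_profile(t1, minus, window = 1000, bin = 100)
  prof_c <- metagene_profile(const, minus, window = 1000, bin = 100)
  both <- dplyr::bind_rows(t1, const)
  prof_sum <- metagene_profile(both, minus, window = 1000, bin = 100)
  expect_equal(prof_sum$mean_signal,
               prof_t1$mean_signal + prof_c$mean_signal, tolerance = 1e-12)

  # windows past the chromosome start are zero-padded and flagged
  near0 <- tibble::tibble(chrom = "chr1", tss = 100L, strand = "+")
  prof4 <- metagene_profile(const, near0, window = 1000, bin = 100)
  expect_equal(attr(prof4, "n_truncated"), 1L)
  expect_equal(prof4$mean_signal[1], 0)
})

test_that("overlap fraction equals the quadratic brute force", {
  a <- tibble::tibble(chrom = "c", start = c(0L, 100L), end = c(50L, 150L))
  expect_equal(interval_overlap_fraction(a, a), 1)
  b <- tibble::tibble(chrom = "c", start = 1000L, end = 1100L)
  expect_equal(interval_overlap_fraction(a, b), 0)
  expect_error(interval_overlap_fraction(a[0, ], b), "empty")

  set.seed(31)
  rand_set <- function(n) {
    s <- sample.int(5000, n, TRUE)
    tibble::tibble(chrom = sample(c("c1", "c2"), n, TRUE),
                   start = s, end = s + sample.int(80, n, TRUE))
  }
  for (i in 1:5) {
    A <- rand_set(100)
    B <- rand_set(100)
    expect_equal(interval_overlap_fraction(A, B), bf_overlap_fraction(A, B))
  }
})

test_that("narrowPeak and bedGraph files round-trip", {
  pk <- dplyr::bind_rows(toy_peak("chr1", 100L, 400L, 150L, "p1"),
                         toy_peak("chr2", 5L, 205L, NA_integer_, "p2"))
  p <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, p)
  expect_equal(read_narrowpeak(p), pk)

  bg <- tibble::tibble(chrom = "chr1", start = c(0L, 10L), end = c(10L, 20L),
                       value = c(1.5, 0.25))
  pb <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(sprintf("%s\t%d\t%d\t%g", bg$chrom, bg$start, bg$end, bg$value),
             pb)
  expect_equal(read_bedgraph(pb), bg)
})
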