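de_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("a transcript is significant with p < alpha in any one replicate", {
  tabs <- de_tbl(
    transcript_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    log2fc = c(1.2, 0.1, 0.5, 0.4, -2, 1.5),
    p_value = c(0.005, 0.5, 0.02, 0.02, 0.001, 0.04),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L))
  st <- de_status(tabs, alpha = 0.01)
  expect_equal(st$direction[st$transcript_id == "t1"], "up")
  expect_equal(st$direction[st$transcript_id == "t2"], "ns")
  # conflicting signs: direction follows the most significant replicate
  expect_equal(st$direction[st$transcript_id == "t3"], "down")
  # absent transcripts come back ns with zero tests
  st2 <- de_status(tabs, transcripts = c("t1", "missing"))
  expect_equal(st2$direction[st2$transcript_id == "missing"], "ns")
  expect_equal(st2$n_tested[st2$transcript_id == "missing"], 0L)
})

toy_world <- function() {
  tx <- tibble::tibble(
    transcript_id = c("tA", "tB", "tC"),
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1", strand = "+", n_exons = 1L,
    tx_start = c(10000L, 200000L, 400000L),
    tx_end = c(12000L, 202000L, 402000L),
    tss = c(10000L, 200000L, 400000L),
    biotype = c("mRNA", "lnc_intergenic", "mRNA"))
  genes <- gene_table(tx)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(13900L, 239900L, 399000L),
    end = c(14100L, 240100L, 399200L),
    peak_id = c("p1", "p2", "p3"), score = 0L, strand = ".",
    signal = 1, p_value = 1, q_value = 1,
    summit_offset = c(100L, 100L, 100L))
  ann <- annotate_peaks(peaks, genes)
  list(tx = tx, genes = genes, ann = ann)
}

test_that("direct targets need one DE transcript and one proximal peak", {
  w <- toy_world()
  de <- de_status(de_tbl(
    transcript_id = c("tA", "tB"), log2fc = c(2, 1.5),
    p_value = c(0.001, 0.002), replicate = 1L))
  tg <- call_direct_targets(de, w$ann, w$tx)
  # gA: DE + peak at |d| = 4 kb -> target
  expect_true("gA" %in% tg$gene_id)
  # gB: DE but its only peak is ~40 kb away -> not a target
  expect_false("gB" %in% tg$gene_id)
  # gC: proximal peak, never DE -> not a target
  expect_false("gC" %in% tg$gene_id)
  expect_equal(tg$biotype[tg$gene_id == "gA"], "mRNA")
  counts <- target_biotype_counts(tg)
  expect_equal(counts$n[counts$biotype == "mRNA"], 1)
})

test_that("relaxing alpha or the proximal threshold never removes a target", {
  set.seed(51)
  n <- 40
  tx <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:n),
    gene_id = sprintf("g%02d", 1:n),
    chrom = "chr1", strand = "+", n_exons = 1L,
    tx_start = seq(10000L, by = 30000L, length.out = n))
  tx$tx_end <- tx$tx_start + 1000L
  tx$tss <- tx$tx_start
  tx$biotype <- "mRNA"
  genes <- gene_table(tx)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = tx$tss + sample(-15000:15000, n),
    peak_id = sprintf("p%02d", 1:n), score = 0L, strand = ".",
    signal = 1, p_value = 1, q_value = 1, summit_offset = 50L)
  peaks$start <- pmax(peaks$start, 0L)
  peaks$end <- peaks$start + 100L
  de_tabs <- de_tbl(transcript_id = tx$transcript_id,
                    log2fc = rnorm(n), p_value = runif(n, 0, 0.2),
                    replicate = 1L)
  call_at <- function(alpha, thr) {
    ann <- annotate_peaks(peaks, genes, proximal_threshold = thr)
    call_direct_targets(de_status(de_tabs, alpha = alpha), ann, tx)$gene_id
  }
  base <- call_at(0.01, 10000)
  expect_true(all(base %in% call_at(0.05, 10000)))
  expect_true(all(base %in% call_at(0.01, 20000)))
})

test_that("the triage cascade applies its rules in order", {
  mk_tx <- function(id) {
    tibble::tibble(transcript_id = id, gene_id = id, chrom = "chr1",
                   strand = "+", n_exons = 1L, tx_start = 10000L,
                   tx_end = 10400L, tss = 10000L, biotype = "unassigned")
  }
  ev <- function(id, act) tibble::tibble(transcript_id = id, active = act)
  cp <- function(id, p) tibble::tibble(seq_id = id, coding_prob = p)
  ctx <- function(id, gap) tibble::tibble(transcript_id = id,
                                          upstream_gene_id = "host",
                                          upstream_gap = gap)
  # run-through, unmarked -> artefact regardless of coding score
  v1 <- triage_unassigned(mk_tx("a"), ev("a", FALSE), cp("a", 0.9),
                          ctx("a", 1000L))
  expect_equal(v1$verdict, "likely_artefact")
  expect_match(v1$reasons, "run_through")
  # promoter-active, low coding potential -> novel lncRNA
  v2 <- triage_unassigned(mk_tx("b"), ev("b", TRUE), cp("b", 0.1),
                          ctx("b", 1000L))
  expect_equal(v2$verdict, "novel_lncRNA")
  # promoter-active but high coding potential -> likely coding (rule order)
  v3 <- triage_unassigned(mk_tx("c"), ev("c", TRUE), cp("c", 0.9),
                          ctx("c", 1000L))
  expect_equal(v3$verdict, "likely_coding")
  # no upstream neighbour, unmarked, low coding -> artefact by default rule
  v4 <- triage_unassigned(mk_tx("d"), ev("d", FALSE), cp("d", 0.1),
                          ctx("d", NA_integer_))
  expect_equal(v4$verdict, "likely_artefact")
  expect_equal(v4$reasons, "no_promoter_evidence")
  # a gap beyond the run-through limit disables rule 1
  v5 <- triage_unassigned(mk_tx("e"), ev("e", FALSE), cp("e", 0.1),
                          ctx("e", 8000L))
  expect_equal(v5$reasons, "no_promoter_evidence")
  # missing coding probability is an error naming the transcript
  expect_error(triage_unassigned(mk_tx("f"), ev("f", TRUE),
                                 cp("other", 0.5), ctx("f", 1000L)), "f")
  # verdicts partition: one row, one verdict per transcript
  many <- dplyr::bind_rows(mk_tx("a"), mk_tx("b"))
  vv <- triage_unassigned(many,
                          dplyr::bind_rows(ev("a", FALSE), ev("b", TRUE)),
                          dplyr::bind_rows(cp("a", 0.9), cp("b", 0.1)),
                          dplyr::bind_rows(ctx("a", 1000L), ctx("b", 1000L)))
  expect_equal(nrow(vv), 2)
  expect_true(all(vv$verdict %in% c("likely_artefact", "novel_lncRNA",
                                    "likely_coding")))
})

test_that("neighbour context finds the nearest same-strand upstream 3' end", {
  tx <- tibble::tibble(transcript_id = "u1", gene_id = "u1", chrom = "chr1",
                       strand = "+", n_exons = 1L, tx_start = 10000L,
                       tx_end = 10500L, tss = 10000L, biotype = "unassigned")
  genes <- tibble::tibble(
    gene_id = c("gNear", "gFar", "gWrongStrand", "u1"),
    chrom = "chr1", strand = c("+", "+", "-", "+"),
    gene_start = c(8000L, 1000L, 9500L, 10000L),
    gene_end = c(9000L, 2000L, 9900L, 10500L))
  ctx <- neighbor_context(tx, genes)
  expect_equal(ctx$upstream_gene_id, "gNear")
  expect_equal(ctx$upstream_gap, 1000L)
  # minus-strand transcript: upstream is to the genomic right
  tx2 <- dplyr::mutate(tx, strand = "-", tss = 10499L)
  genes2 <- tibble::tibble(gene_id = c("gRight", "u1"), chrom = "chr1",
                           strand = "-", gene_start = c(12000L, 10000L),
                           gene_end = c(13000L, 10500L))
  ctx2 <- neighbor_context(tx2, genes2)
  expect_equal(ctx2$upstream_gene_id, "gRight")
  expect_equal(ctx2$upstream_gap, 1500L)
})

test_that("conservation fractions agree with the interval brute force", {
  q <- tibble::tibble(chrom = "c", start = c(0L, 100L, 200L),
                      end = c(50L, 150L, 250L))
  expect_equal(conservation_fraction(q, q)$fraction, 1)
  far <- dplyr::mutate(q, start = start + 10000L, end = end + 10000L)
  expect_equal(conservation_fraction(q, far)$fraction, 0)
  expect_error(conservation_fraction(q[0, ], q), "empty")
  set.seed(52)
  A <- tibble::tibble(chrom = "c", start = sample.int(2000, 60))
  A$end <- A$start + sample.int(50, 60, TRUE)
  B <- tibble::tibble(chrom = "c", start = sample.int(2000, 40))
  B$end <- B$start + sample.int(50, 40, TRUE)
  got <- conservation_fraction(A, B)
  expect_equal(got$fraction, bf_overlap_fraction(A, B))
  expect_equal(got$n_overlapping / got$n_query, got$fraction)
  # restricting the query restricts numerator and denominator consistently
  sub <- A[1:20, ]
  expect_equal(conservation_fraction(sub, B)$fraction,
               bf_overlap_fraction(sub, B))
})

test_that("hypergeometric enrichment matches direct tail summation", {
  # worked example: universe 10, set 5, 4 annotated, all 4 in the set
  expect_equal(hypergeometric_enrichment(4, 5, 4, 10), 6 / 252,
               tolerance = 1e-14)
  expect_equal(hypergeometric_enrichment(0, 5, 4, 10), 1)
  expect_error(hypergeometric_enrichment(6, 5, 4, 10), "inconsistent")
  set.seed(53)
  for (i in 1:300) {
    N <- sample(5:200, 1)
    K <- sample.int(N, 1)
    m <- sample.int(N, 1)
    q <- sample(0:min(K, m), 1)
    expect_equal(hypergeometric_enrichment(q, K, m, N),
                 bf_hyper_tail(q, m, N - m, K), tolerance = 1e-12)
  }
})
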