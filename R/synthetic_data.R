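# Fully seeded synthetic inputs with planted ground truth: genome + GTF,
# peaks + coverage with planted response elements, DE tables, mark tracks,
# paired qPCR cohort.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate the study design the package targets: two DE replicates, a
#' treated/untreated peak pair, three promoter marks, and a 35-patient
#' paired tumour/normal cohort of 12 markers with graded effect sizes.
#'
#' @param seed Integer master seed (mandatory); per-stage substreams are
#'   derived from it so stages can be regenerated independently.
#' @param n_chromosomes,chrom_lengths Chromosome count and lengths
#'   (`NULL` = sized automatically to fit the genes on a 20-kb locus grid).
#' @param n_genes Total gene loci.
#' @param biotype_mix Named fractions over biotype categories (must sum
#'   to 1); applied with exact largest-remainder rounding.
#' @param artefact_fraction Fraction of `unassigned` loci planted as
#'   run-through artefacts downstream of an mRNA host gene (default 7/16).
#' @param n_planted_targets Genes planted as direct targets (response
#'   element + proximal peak + DE transcript).
#' @param prop_up Fraction of planted targets upregulated (default 0.75).
#' @param peak_width,summit_jitter Peak geometry in bp.
#' @param n_decoy_proximal,n_decoy_distal Decoy peaks near non-target gene
#'   TSSs and far (>12 kb) from every TSS.
#' @param n_decoy_de Non-target genes given a planted DE transcript (never
#'   overlapping decoy-proximal-peak genes, so truth stays unambiguous).
#' @param re_spacer_range Spacer lengths sampled for planted dimeric
#'   response elements.
#' @param de_lfc_mean,de_lfc_sd,de_p_shape Planted DE effect: |log2FC| ~
#'   Normal(mean, sd), p ~ Beta(shape, 1).
#' @param null_lfc_sd Null transcripts: log2FC ~ Normal(0, sd), p ~ U(0,1).
#' @param de_noiseless Deterministic DE p-values (planted 1e-6, null 0.5)
#'   for exact truth-recovery checks.
#' @param n_replicates DE replicates (default 2).
#' @param mark_fraction Fraction of genuine 5' ends carrying at least one
#'   mark; artefact transcripts never do.
#' @param mark_width Mark interval width in bp.
#' @param n_patients,marker_names,marker_delta,sigma,patient_sd,mu_range
#'   Cohort design: per-patient effect ~ N(0, patient_sd^2), residual
#'   ~ N(0, sigma^2), tumour shift `marker_delta` per marker (delta-Ct
#'   units; positive = lower expression in tumour), baseline delta-Ct drawn
#'   uniformly from `mu_range`.
#' @param coverage_baseline,bump_sd Coverage track: constant baseline plus
#'   Gaussian bumps (sd bp) at peak summits.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(
    seed,
    n_chromosomes = 2, chrom_lengths = NULL,
    n_genes = 200,
    biotype_mix = c(mRNA = 0.60, lnc_intergenic = 0.15, lnc_antisense = 0.05,
                    processed_transcript = 0.05, pseudogene = 0.07,
                    unassigned = 0.08),
    artefact_fraction = 7 / 16,
    n_planted_targets = 30, prop_up = 0.75,
    peak_width = 300, summit_jitter = 50,
    n_decoy_proximal = 10, n_decoy_distal = 30,
    n_decoy_de = 15,
    re_spacer_range = 0:3,
    de_lfc_mean = 2, de_lfc_sd = 0.5, de_p_shape = 0.01,
    null_lfc_sd = 0.2, de_noiseless = FALSE, n_replicates = 2,
    mark_fraction = 0.85, mark_width = 1000,
    n_patients = 35,
    marker_names = sprintf("lnc_%02d", 1:12),
    marker_delta = c(2.0, 1.6, 1.3, 1.1, 0.9, 0.75,
                     0.6, 0.45, 0.3, 0.2, 0.1, 0.0),
    sigma = 1, patient_sd = 0.5, mu_range = c(4, 9),
    coverage_baseline = 0.05, bump_sd = 100) {
  if (missing(seed)) abort("seed is mandatory")
  if (abs(sum(biotype_mix) - 1) > 1e-8) abort("biotype_mix must sum to 1")
  if (length(marker_delta) != length(marker_names)) {
    abort("marker_delta and marker_names lengths differ")
  }
  cfg <- as.list(environment())
  slot_width <- 20000L
  cnts <- .exact_counts(n_genes, biotype_mix)
  n_unassigned <- if ("unassigned" %in% names(cnts)) cnts[["unassigned"]] else 0L
  n_artefact <- round(artefact_fraction * n_unassigned)
  n_slots <- n_genes - n_artefact
  if (is.null(chrom_lengths)) {
    per <- ceiling(n_slots / n_chromosomes) + 1L
    cfg$chrom_lengths <- rep(per * slot_width + 2000L, n_chromosomes)
  }
  cfg$slot_width <- slot_width
  structure(cfg, class = "simulation_config")
}

# exact integer counts from fractions (largest remainder)
.exact_counts <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(mix)
  counts
}

.stage_seed <- function(config, k) (config$seed %% 100000000L) + 7L * k

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome and gene annotation with planted truth
#'
#' Generates uniform-random chromosome sequences and places non-overlapping
#' gene loci on a 20-kb slot grid with the requested biotype mix (exact
#' counts). Unassigned loci are split into run-through artefacts
#' (monoexonic, same strand, a short gap downstream of an mRNA host gene's
#' 3' end, positioned so that promoter marks of the host never reach the
#' artefact's 5-kb evidence window) and genuinely novel loci. Direct-target
#' genes are chosen among loci with genuine promoters and given a
#' regulation direction and a response-element position within 3 kb
#' upstream to 1 kb downstream of their TSS. Decoy-DE genes and
#' decoy-proximal-peak genes are chosen disjointly from targets and from
#' each other.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character), `exons` (GTF-style exon
#'   tibble), `transcripts`, `genes`, `truth_genes`, `truth_transcripts`,
#'   `artefact_hosts`, `config`.
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.stage_seed(config, 1L))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome <- setNames(
    vapply(config$chrom_lengths, .random_dna, character(1)), chroms)

  counts <- .exact_counts(config$n_genes, config$biotype_mix)
  n_art <- if ("unassigned" %in% names(counts)) {
    round(config$artefact_fraction * counts[["unassigned"]])
  } else 0L
  biotypes <- rep(names(counts), counts)
  art_flag <- rep(FALSE, length(biotypes))
  ua <- which(biotypes == "unassigned")
  if (n_art > 0) art_flag[ua[seq_len(n_art)]] <- TRUE
  ord <- sample(length(biotypes))
  biotypes <- biotypes[ord]; art_flag <- art_flag[ord]

  slot_width <- config$slot_width
  slots_per_chrom <- (config$chrom_lengths - 2000L) %/% slot_width
  slot_tbl <- tibble(
    chrom = rep(chroms, slots_per_chrom),
    slot_start = unlist(lapply(slots_per_chrom,
                               function(k) (seq_len(k) - 1L) * slot_width)))
  n_slots <- sum(!art_flag)
  if (n_slots > nrow(slot_tbl)) abort("genes do not fit chromosome lengths")
  slot_tbl <- slot_tbl[seq_len(n_slots), ]

  gid <- sprintf("G%04d", seq_along(biotypes))
  tid <- sprintf("T%04d", seq_along(biotypes))
  tag_of <- c(mRNA = "protein_coding", lnc_intergenic = "lincRNA",
              lnc_antisense = "antisense",
              lnc_sense_overlapping = "sense_overlapping",
              lnc_sense_intronic = "sense_intronic",
              processed_transcript = "processed_transcript",
              pseudogene = "pseudogene", retained_intron = "retained_intron",
              other_ncRNA = "misc_RNA", unassigned = "")

  exons_list <- vector("list", length(biotypes))
  placed <- tibble(gene_id = gid, biotype = biotypes, artefact = art_flag,
                   chrom = NA_character_, strand = NA_character_,
                   gene_start = NA_integer_, gene_end = NA_integer_)
  slot_i <- 0L
  for (i in seq_along(biotypes)) {
    if (art_flag[i]) next
    slot_i <- slot_i + 1L
    ch <- slot_tbl$chrom[slot_i]; s0 <- slot_tbl$slot_start[slot_i]
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:3, 1)
    ex_len <- sample(200:800, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE) else integer(0)
    starts <- s0 + 500L + cumsum(c(0L, ex_len[-n_ex] + gaps))
    ends <- starts + ex_len
    exons_list[[i]] <- tibble(chrom = ch, start = as.integer(starts),
                              end = as.integer(ends), strand = strand,
                              transcript_id = tid[i], gene_id = gid[i],
                              biotype_tag = unname(tag_of[biotypes[i]]))
    placed$chrom[i] <- ch; placed$strand[i] <- strand
    placed$gene_start[i] <- as.integer(starts[1])
    placed$gene_end[i] <- as.integer(ends[n_ex])
  }
  # artefacts ride downstream of distinct mRNA hosts, spaced so that host
  # promoter marks (placed on the host's upstream side) stay out of the
  # artefact's +/-5 kb evidence window
  n_art_total <- sum(art_flag)
  chrom_len_of <- setNames(config$chrom_lengths, chroms)
  host_pool <- which(placed$biotype == "mRNA" & !placed$artefact &
                       (placed$gene_end - placed$gene_start) >= 500L &
                       placed$gene_start >= 3000L &
                       placed$gene_end <= chrom_len_of[placed$chrom] - 3000L)
  if (n_art_total > length(host_pool)) {
    abort("not enough mRNA genes to host the requested artefact transcripts")
  }
  hosts <- if (n_art_total > 0) sample(host_pool, n_art_total) else integer(0)
  artefact_hosts <- tibble(artefact_gene_id = character(),
                           host_gene_id = character())
  hi <- 0L
  for (i in seq_along(biotypes)) {
    if (!art_flag[i]) next
    hi <- hi + 1L
    h <- hosts[hi]
    span <- placed$gene_end[h] - placed$gene_start[h]
    gap <- sample(seq.int(max(200L, 5000L - span), 4500L), 1)
    len <- sample(300:600, 1)
    if (placed$strand[h] == "-") {
      # host 3' end is gene_start; the artefact continues leftwards
      a_end <- placed$gene_start[h] - gap
      a_start <- a_end - len
    } else {
      a_start <- placed$gene_end[h] + gap
      a_end <- a_start + len
    }
    exons_list[[i]] <- tibble(chrom = placed$chrom[h],
                              start = as.integer(a_start),
                              end = as.integer(a_end),
                              strand = placed$strand[h],
                              transcript_id = tid[i], gene_id = gid[i],
                              biotype_tag = "")
    placed$chrom[i] <- placed$chrom[h]; placed$strand[i] <- placed$strand[h]
    placed$gene_start[i] <- as.integer(a_start)
    placed$gene_end[i] <- as.integer(a_end)
    artefact_hosts <- bind_rows(artefact_hosts,
                                tibble(artefact_gene_id = gid[i],
                                       host_gene_id = gid[h]))
  }
  exons <- bind_rows(exons_list)
  exons$biotype <- classify_biotype(exons$biotype_tag)
  transcripts <- transcript_table(exons)
  genes <- gene_table(transcripts)

  # plant direct targets among genuine (non-artefact) loci
  eligible <- placed$gene_id[!placed$artefact]
  if (config$n_planted_targets > length(eligible)) {
    abort("more planted targets requested than eligible genes")
  }
  targets <- sample(eligible, config$n_planted_targets)
  rest <- setdiff(eligible, targets)
  n_up <- round(config$prop_up * length(targets))
  direction <- sample(rep(c("up", "down"), c(n_up, length(targets) - n_up)))
  decoy_prox <- sample(rest, min(config$n_decoy_proximal, length(rest)))
  rest2 <- setdiff(rest, decoy_prox)
  decoy_de <- sample(rest2, min(config$n_decoy_de, length(rest2)))

  gmeta <- genes %>% left_join(select(placed, "gene_id", "artefact"),
                               by = "gene_id")
  site_pos <- rep(NA_integer_, nrow(gmeta))
  ti <- match(targets, gmeta$gene_id)
  site_pos[ti] <- gmeta$tss[ti] + sample(-3000:1000, length(ti), replace = TRUE)
  site_pos <- pmax(site_pos, 30L)
  truth_genes <- gmeta %>%
    mutate(is_direct_target = .data$gene_id %in% targets,
           direction = if_else(.data$is_direct_target,
                               direction[match(.data$gene_id, targets)],
                               "none"),
           planted_site_pos = site_pos,
           is_decoy_proximal = .data$gene_id %in% decoy_prox,
           is_decoy_de = .data$gene_id %in% decoy_de) %>%
    select("gene_id", "chrom", "strand", "tss", "biotype", "artefact",
           "is_direct_target", "direction", "planted_site_pos",
           "is_decoy_proximal", "is_decoy_de")
  truth_transcripts <- transcripts %>%
    left_join(select(placed, "gene_id", "artefact"), by = "gene_id") %>%
    mutate(novel = .data$biotype == "unassigned" & !.data$artefact) %>%
    select("transcript_id", "gene_id", "biotype", "artefact", "novel")
  list(genome = genome, exons = exons, transcripts = transcripts,
       genes = genes, truth_genes = truth_genes,
       truth_transcripts = truth_transcripts,
       artefact_hosts = artefact_hosts, config = config)
}

# overwrite characters of a chromosome string at 0-based pos
.splice_into <- function(seq, pos, insert) {
  paste0(substring(seq, 1, pos), insert,
         substring(seq, pos + nchar(insert) + 1, nchar(seq)))
}

.sample_p53re <- function(spacer) {
  half <- function() {
    paste0(paste(sample(c("A", "G"), 3, TRUE), collapse = ""), "C",
           paste(sample(c("A", "T"), 2, TRUE), collapse = ""), "G",
           paste(sample(c("C", "T"), 3, TRUE), collapse = ""))
  }
  sp <- if (spacer > 0) .random_dna(spacer) else ""
  paste0(half(), sp, half())
}

#' Simulate peaks and a coverage track; plant response elements
#'
#' Writes a dimeric response element into the genome at each planted
#' target's site, emits one treated-condition peak covering each site
#' (summit jittered), adds decoy peaks (proximal to decoy genes' TSSs and
#' distal, >12 kb from every TSS), an untreated peak set as a subset of the
#' treated one, and a non-overlapping bedGraph coverage track of Gaussian
#' bumps (10-bp bins around each summit) over a constant baseline.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @return `sim` with `genome` updated and `peaks_treated`,
#'   `peaks_untreated`, `coverage` added.
#' @export
simulate_peaks_and_coverage <- function(sim) {
  config <- sim$config
  set.seed(.stage_seed(config, 2L))
  genome <- sim$genome
  tg <- sim$truth_genes
  chrom_len <- setNames(nchar(genome), names(genome))
  w <- config$peak_width

  planted <- tg %>% filter(.data$is_direct_target)
  peak_rows <- list()
  for (i in seq_len(nrow(planted))) {
    sp <- sample(config$re_spacer_range, 1)
    re <- .sample_p53re(sp)
    ch <- planted$chrom[i]
    pos <- min(planted$planted_site_pos[i],
               chrom_len[[ch]] - nchar(re) - 10L)
    planted$planted_site_pos[i] <- pos
    genome[[ch]] <- .splice_into(genome[[ch]], pos, re)
    site_center <- pos + nchar(re) %/% 2L
    summit <- site_center +
      sample(seq.int(-config$summit_jitter, config$summit_jitter), 1)
    start <- max(summit - w %/% 2L, 0L)
    start <- min(start, pos)  # peak must cover the whole planted site
    end <- max(start + w, pos + nchar(re))
    peak_rows[[length(peak_rows) + 1]] <- tibble(
      chrom = ch, start = as.integer(start), end = as.integer(end),
      gene_id = planted$gene_id[i], kind = "planted",
      summit = as.integer(summit))
  }
  # propagate any boundary-clipped site positions back into the truth table
  sim$truth_genes$planted_site_pos[match(planted$gene_id, tg$gene_id)] <-
    planted$planted_site_pos

  dp <- tg %>% filter(.data$is_decoy_proximal)
  for (i in seq_len(nrow(dp))) {
    summit <- dp$tss[i] + sample(c(-8000:-2000, 2000:8000), 1)
    summit <- min(max(summit, w), chrom_len[[dp$chrom[i]]] - w)
    peak_rows[[length(peak_rows) + 1]] <- tibble(
      chrom = dp$chrom[i], start = as.integer(summit - w %/% 2L),
      end = as.integer(summit + w - w %/% 2L),
      gene_id = dp$gene_id[i], kind = "decoy_proximal",
      summit = as.integer(summit))
  }
  # distal decoys: uniform positions at least 12 kb from every TSS
  n_dist <- config$n_decoy_distal
  tries <- 0L
  while (n_dist > 0 && tries < 5000L) {
    tries <- tries + 1L
    ch <- sample(names(genome), 1)
    summit <- sample(seq.int(w, chrom_len[[ch]] - w), 1)
    tss_here <- tg$tss[tg$chrom == ch]
    if (length(tss_here) == 0 || min(abs(tss_here - summit)) > 12000) {
      peak_rows[[length(peak_rows) + 1]] <- tibble(
        chrom = ch, start = as.integer(summit - w %/% 2L),
        end = as.integer(summit + w - w %/% 2L),
        gene_id = NA_character_, kind = "decoy_distal",
        summit = as.integer(summit))
      n_dist <- n_dist - 1L
    }
  }
  pk <- bind_rows(peak_rows) %>% arrange(.data$chrom, .data$start)
  pk <- pk %>% mutate(
    peak_id = sprintf("peak_%03d", row_number()),
    score = sample(100:1000, n(), replace = TRUE),
    strand = ".",
    signal = stats::runif(n(), 5, 15),
    p_value = stats::runif(n(), 5, 50),
    q_value = stats::runif(n(), 2, 20),
    summit_offset = as.integer(.data$summit - .data$start))
  peaks_treated <- pk %>%
    select("chrom", "start", "end", "peak_id", "score", "strand", "signal",
           "p_value", "q_value", "summit_offset", "gene_id", "kind")
  keep_untreated <- sort(sample(nrow(pk), round(0.4 * nrow(pk))))
  peaks_untreated <- peaks_treated[keep_untreated, ]

  # coverage: 10-bp-aligned Gaussian bump bins summed where bumps overlap,
  # baseline everywhere else -- records never overlap
  bump_bins <- purrr::map(seq_len(nrow(pk)), function(i) {
    b0 <- ((pk$summit[i] - 500L) %/% 10L) * 10L
    starts <- pmax(seq.int(b0, b0 + 990L, by = 10L), 0L)
    starts <- starts[starts + 10L <= chrom_len[[pk$chrom[i]]]]
    centers <- starts + 5L
    tibble(chrom = pk$chrom[i], start = starts,
           value = pk$signal[i] *
             exp(-((centers - pk$summit[i])^2) / (2 * config$bump_sd^2)))
  }) %>% bind_rows() %>%
    group_by(.data$chrom, .data$start) %>%
    summarise(value = sum(.data$value), .groups = "drop")
  base_v <- config$coverage_baseline
  cov_rows <- purrr::map(names(genome), function(ch) {
    b <- bump_bins %>% filter(.data$chrom == ch) %>% arrange(.data$start)
    len <- chrom_len[[ch]]
    if (nrow(b) == 0) {
      return(tibble(chrom = ch, start = 0L, end = len, value = base_v))
    }
    gap_start <- c(0L, b$start + 10L)
    gap_end <- c(b$start, len)
    gaps <- tibble(chrom = ch, start = gap_start, end = gap_end,
                   value = base_v) %>% filter(.data$start < .data$end)
    bind_rows(gaps,
              tibble(chrom = ch, start = b$start, end = b$start + 10L,
                     value = b$value + base_v)) %>%
      arrange(.data$start)
  }) %>% bind_rows()
  sim$genome <- genome
  sim$peaks_treated <- peaks_treated
  sim$peaks_untreated <- peaks_untreated
  sim$coverage <- cov_rows
  sim
}

#' Simulate per-replicate differential-expression tables
#'
#' Transcripts of planted target genes and decoy-DE genes receive
#' `p ~ Beta(shape, 1)` and `|log2FC| ~ Normal(mean, sd)` signed by the
#' planted direction; all others are null (`p ~ U(0,1)`,
#' `log2FC ~ Normal(0, sd0)`), independently per replicate. In noiseless
#' mode planted p-values are fixed at 1e-6 and null ones at 0.5.
#'
#' @param sim Output of [simulate_genome_annotation()] (or later stage).
#' @return `sim` with `de_tables` (stacked tibble: `transcript_id`,
#'   `log2fc`, `p_value`, `replicate`) added.
#' @export
simulate_expression_tables <- function(sim) {
  config <- sim$config
  set.seed(.stage_seed(config, 3L))
  tg <- sim$truth_genes
  de_genes <- tg %>% filter(.data$is_direct_target | .data$is_decoy_de)
  dir_of <- setNames(ifelse(de_genes$direction == "down", -1, 1),
                     de_genes$gene_id)
  tx <- sim$transcripts
  planted <- tx$gene_id %in% de_genes$gene_id
  tabs <- purrr::map(seq_len(config$n_replicates), function(r) {
    n <- nrow(tx)
    p <- if (config$de_noiseless) rep(0.5, n) else stats::runif(n)
    lfc <- stats::rnorm(n, 0, config$null_lfc_sd)
    np <- sum(planted)
    if (np > 0) {
      p[planted] <- if (config$de_noiseless) rep(1e-6, np) else
        stats::rbeta(np, config$de_p_shape, 1)
      lfc[planted] <- dir_of[tx$gene_id[planted]] *
        abs(stats::rnorm(np, config$de_lfc_mean, config$de_lfc_sd))
    }
    tibble(transcript_id = tx$transcript_id, log2fc = lfc, p_value = p,
           replicate = r)
  })
  sim$de_tables <- bind_rows(tabs)
  sim
}

#' Simulate histone-mark tracks
#'
#' A configured fraction of genuine (non-artefact) transcript 5' ends carry
#' at least one of H3K4me3/H3K4me1/H3K27ac; planted artefact transcripts
#' never do. Intervals of the configured width are centred within +/- 2 kb
#' of the marked TSS, except for artefact-host genes whose marks sit on the
#' host's upstream side only, keeping them out of the artefact's evidence
#' window.
#'
#' @param sim Output of an earlier simulation stage.
#' @return `sim` with `marks` (tibble `chrom`, `start`, `end`, `mark`) and
#'   `truth_transcripts$marked` added.
#' @export
simulate_marks <- function(sim) {
  config <- sim$config
  set.seed(.stage_seed(config, 4L))
  mark_names <- c("H3K4me3", "H3K4me1", "H3K27ac")
  tt <- sim$truth_transcripts %>%
    left_join(select(sim$transcripts, "transcript_id", "chrom", "strand",
                     "tss"),
              by = "transcript_id")
  host_ids <- sim$artefact_hosts$host_gene_id
  genuine <- !tt$artefact
  marked <- genuine & stats::runif(nrow(tt)) < config$mark_fraction
  rows <- list()
  for (i in which(marked)) {
    present <- stats::runif(3) < 0.6
    if (!any(present)) present[sample(3, 1)] <- TRUE
    is_host <- tt$gene_id[i] %in% host_ids
    for (m in which(present)) {
      off <- if (is_host) {
        # upstream side only (5' of the TSS in transcription direction)
        s <- sample(600:2000, 1)
        if (tt$strand[i] == "-") s else -s
      } else {
        sample(-2000:2000, 1)
      }
      center <- max(tt$tss[i] + off, config$mark_width %/% 2L)
      rows[[length(rows) + 1]] <- tibble(
        chrom = tt$chrom[i],
        start = as.integer(center - config$mark_width %/% 2L),
        end = as.integer(center + config$mark_width -
                           config$mark_width %/% 2L),
        mark = mark_names[m])
    }
  }
  sim$marks <- if (length(rows) > 0) {
    bind_rows(rows) %>% arrange(.data$mark, .data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           mark = character())
  }
  sim$truth_transcripts$marked <- marked
  sim
}

#' Simulate a paired tumour/normal qPCR cohort
#'
#' Per patient i and marker g: normal delta-Ct = mu_g + u_i + eps, tumour
#' delta-Ct = mu_g + delta_g + u_i + eps, with patient effect
#' u_i ~ N(0, patient_sd^2) shared between the two tissues and residual
#' eps ~ N(0, sigma^2). Positive delta_g means higher delta-Ct (lower
#' expression) in tumours. Emitted as raw Ct pairs with the reference gene
#' fixed at Ct 20.
#'
#' @param config A [simulation_config()].
#' @return List with `ct_table` (long tibble: `patient`, `tissue`, `marker`,
#'   `ct`, `reference_ct`) and `truth_markers` (`marker`, `delta`, `mu`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.stage_seed(config, 5L))
  n <- config$n_patients
  mk <- config$marker_names
  mu <- stats::runif(length(mk), config$mu_range[1], config$mu_range[2])
  u <- stats::rnorm(n, 0, config$patient_sd)
  grid <- tidyr::expand_grid(patient = sprintf("P%03d", seq_len(n)),
                             marker = mk)
  grid <- bind_rows(mutate(grid, tissue = "normal"),
                    mutate(grid, tissue = "tumour"))
  gi <- match(grid$marker, mk)
  pi_ <- as.integer(sub("^P", "", grid$patient))
  eps <- stats::rnorm(nrow(grid), 0, config$sigma)
  dct <- mu[gi] + u[pi_] + eps +
    ifelse(grid$tissue == "tumour", config$marker_delta[gi], 0)
  ct_table <- grid %>%
    mutate(ct = 20 + dct, reference_ct = 20) %>%
    arrange(.data$patient, .data$marker, .data$tissue)
  list(ct_table = ct_table,
       truth_markers = tibble(marker = mk, delta = config$marker_delta,
                              mu = mu))
}

#' Run every simulator stage and optionally write all input files
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created); `NULL` keeps everything in memory.
#' @return The full simulation list; when `dir` is given, also `files`
#'   (named paths of everything written).
#' @export
simulate_study <- function(config, dir = NULL) {
  sim <- simulate_genome_annotation(config)
  sim <- simulate_peaks_and_coverage(sim)
  sim <- simulate_expression_tables(sim)
  sim <- simulate_marks(sim)
  cohort <- simulate_cohort(config)
  sim$ct_table <- cohort$ct_table
  sim$truth_markers <- cohort$truth_markers
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(...) file.path(dir, ...)
    files <- c(genome = f("genome.fa"), annotation = f("annotation.gtf"),
               peaks_treated = f("peaks_treated.narrowPeak"),
               peaks_untreated = f("peaks_untreated.narrowPeak"),
               coverage = f("coverage.bedGraph"),
               cohort = f("cohort_ct.tsv"),
               truth_genes = f("truth_genes.tsv"),
               truth_transcripts = f("truth_transcripts.tsv"),
               truth_markers = f("truth_markers.tsv"),
               truth = f("truth.json"))
    write_fasta(sim$genome, files[["genome"]])
    write_gtf(sim$exons, files[["annotation"]])
    np_cols <- c("chrom", "start", "end", "peak_id", "score", "strand",
                 "signal", "p_value", "q_value", "summit_offset")
    write_narrowpeak(sim$peaks_treated[, np_cols], files[["peaks_treated"]])
    write_narrowpeak(sim$peaks_untreated[, np_cols],
                     files[["peaks_untreated"]])
    readr::write_tsv(sim$coverage, files[["coverage"]], col_names = FALSE)
    for (r in unique(sim$de_tables$replicate)) {
      files[[sprintf("de_rep%d", r)]] <- f(sprintf("de_rep%d.tsv", r))
      readr::write_tsv(filter(sim$de_tables, .data$replicate == r),
                       files[[sprintf("de_rep%d", r)]])
    }
    for (m in unique(sim$marks$mark)) {
      files[[paste0("mark_", m)]] <- f(sprintf("mark_%s.bed", m))
      x <- filter(sim$marks, .data$mark == m)
      writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, x$mark),
                 files[[paste0("mark_", m)]])
    }
    readr::write_tsv(sim$ct_table, files[["cohort"]])
    readr::write_tsv(sim$truth_genes, files[["truth_genes"]])
    readr::write_tsv(sim$truth_transcripts, files[["truth_transcripts"]])
    readr::write_tsv(sim$truth_markers, files[["truth_markers"]])
    jsonlite::write_json(
      list(seed = config$seed,
           n_genes = config$n_genes,
           n_planted_targets = config$n_planted_targets,
           target_gene_ids = sim$truth_genes$gene_id[
             sim$truth_genes$is_direct_target]),
      files[["truth"]], auto_unbox = TRUE, digits = NA)
    sim$files <- files
  }
  sim
}

#' Validate that truth table and emitted data agree
#'
#' Checks that every planted response element is present in the genome at
#' its recorded position (the dimeric scanner finds a 0-mismatch hit at
#' offset 0), that every planted target has a covering treated peak within
#' the proximal threshold of its TSS and at least one DE transcript record,
#' and that artefact transcripts' 5-kb evidence windows overlap no mark.
#'
#' @param sim Output of [simulate_study()] (or the individual stages).
#' @param proximal_threshold Proximal rule in bp (default 10000).
#' @return TRUE invisibly; aborts with a message on any inconsistency.
#' @export
validate_truth <- function(sim, proximal_threshold = 10000) {
  tg <- sim$truth_genes %>% filter(.data$is_direct_target)
  for (i in seq_len(nrow(tg))) {
    pos <- tg$planted_site_pos[i]
    region <- substring(sim$genome[[tg$chrom[i]]], pos + 1, pos + 40)
    hits <- p53re_scan(setNames(region, "r"), max_mismatch = 0)
    if (nrow(hits) == 0 || !any(hits$offset == 0)) {
      abort(sprintf("planted site missing in genome for %s", tg$gene_id[i]))
    }
    pk <- sim$peaks_treated %>%
      filter(.data$chrom == tg$chrom[i], .data$start <= pos,
             .data$end >= pos + 20)
    if (nrow(pk) == 0) abort(sprintf("no peak covers planted site of %s",
                                     tg$gene_id[i]))
    if (min(abs((pk$start + pk$summit_offset) - tg$tss[i])) >
        proximal_threshold) {
      abort(sprintf("planted peak not proximal for %s", tg$gene_id[i]))
    }
    de <- sim$de_tables %>%
      inner_join(filter(sim$transcripts, .data$gene_id == tg$gene_id[i]),
                 by = "transcript_id")
    if (nrow(de) == 0) abort(sprintf("no DE record for %s", tg$gene_id[i]))
  }
  art <- sim$truth_transcripts %>% filter(.data$artefact)
  if (nrow(art) > 0 && nrow(sim$marks) > 0) {
    atx <- sim$transcripts %>%
      filter(.data$transcript_id %in% art$transcript_id)
    win <- tibble(chrom = atx$chrom, start = pmax(atx$tss - 5000, 0),
                  end = atx$tss + 5000)
    if (interval_overlap_fraction(win, sim$marks) > 0) {
      abort("artefact transcript 5' end overlaps a mark track")
    }
  }
  invisible(TRUE)
}

#' Simulate coding and noncoding training sequences
#'
#' Coding sequences are ATG-initiated stop-free codon strings drawn from a
#' GC-biased codon distribution, terminated by a stop codon and padded with
#' short random UTRs; noncoding sequences are uniform random nucleotides.
#' Used to train and exercise the coding-potential model.
#'
#' @param n Number of sequences.
#' @param coding Generate coding (TRUE) or noncoding (FALSE) sequences.
#' @param length_range Total sequence length range in nt.
#' @param seed Integer seed.
#' @param utr Pad coding sequences with random UTRs (default TRUE); with
#'   FALSE the sequence starts at the ATG, i.e. a CDS.
#' @return Named character vector of sequences.
#' @export
simulate_coding_sequences <- function(n, coding, length_range = c(400, 1200),
                                      seed, utr = TRUE) {
  set.seed(seed)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0,
                  collapse = "")
  sense <- setdiff(codons, .stop_codons)
  wts <- 1 + 2 * (stringr::str_count(sense, "[GC]") / 3)
  out <- vapply(seq_len(n), function(i) {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    if (coding) {
      utr5 <- if (utr) .random_dna(sample(10:50, 1)) else ""
      utr3 <- if (utr) .random_dna(sample(10:50, 1)) else ""
      n_codons <- max((len - nchar(utr5) - 60) %/% 3, 30)
      body <- paste(sample(sense, n_codons, replace = TRUE, prob = wts),
                    collapse = "")
      paste0(utr5, "ATG", body, sample(.stop_codons, 1), utr3)
    } else {
      .random_dna(len)
    }
  }, character(1))
  names(out) <- sprintf("%s_%03d", if (coding) "cod" else "nc", seq_len(n))
  out
}
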