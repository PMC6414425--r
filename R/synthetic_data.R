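#' Simulation configuration
#'
#' Parameters of the synthetic study: a genome with three planted gene
#' classes (Polycomb-repressed, active, inactive), R-loop peaks planted on
#' a class-dependent subset of genes, stranded nascent-RNA coverage with
#' class-dependent intensity, ChIP reads with class-dependent enrichment
#' mixed with exogenous spike-in reads and PCR duplicates, and an RNase H1
#' condition that depletes enrichment at R-loop-positive Polycomb genes.
#'
#' Defaults define the reference study conditions: per-class R-loop
#' probabilities 0.25 / 0.76 / 0.05 (Polycomb-repressed / active /
#' inactive), nascent rates spanning the poised-to-active range, and a 0.5
#' depletion of Polycomb-gene ChIP enrichment under RNase H1.
#'
#' @param n_genes named integer vector: genes per class.
#' @param genome_size total target-genome size in bases.
#' @param n_chromosomes number of equally sized chromosomes.
#' @param gene_length_range min/max gene length (bases).
#' @param min_spacing minimum gap between consecutive gene bodies (bases);
#'   with the default 3000 and 1-kb flanks, non-pair gene windows never
#'   overlap.
#' @param gap_mean mean of the exponential jitter added to `min_spacing`.
#' @param overlap_fraction fraction of genes deliberately placed in pairs
#'   whose 1-kb windows overlap (exercises the proximity rule).
#' @param p_rloop named per-class probability that a gene is planted
#'   R-loop positive.
#' @param p_nascent named per-class probability that a gene is transcribed
#'   at all (drawn independently of R-loop status); untranscribed genes
#'   get zero sense reads. Defaults mirror a Polycomb system where less
#'   than half the repressed genes yield detectable run-on signal.
#' @param nascent_rate named per-class sense-strand nascent-RNA rate of
#'   transcribed genes (reads per kb of gene).
#' @param antisense_rate antisense background rate (reads per kb).
#' @param read_length simulated read length (bases).
#' @param chip_enrichment named per-class ChIP enrichment (fold over
#'   background) at the 2-kb TSS-centred window.
#' @param chip_background_per_kb genome-wide ChIP background depth
#'   (reads/kb); the default 5 matches the per-kb depth of a typical
#'   mammalian ChIP-seq library (tens of millions of reads).
#' @param rnaseh1_depletion multiplier applied to ChIP enrichment at
#'   R-loop-positive Polycomb-repressed genes under the `rnaseh1`
#'   condition (default 0.5).
#' @param spikein_fraction expected proportion of the sequenced library
#'   coming from the exogenous spike-in genome.
#' @param spikein_genome_size size of the spike-in genome (one chromosome
#'   named `spike_1`).
#' @param duplication_rate per-read PCR duplication parameter; each read's
#'   copy count is `1 + Geometric(duplication_rate)` (0 means all
#'   signatures unique).
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_genes = c(pcg_repressed = 300, active_top = 300, inactive_bottom = 300),
    genome_size = 2e7,
    n_chromosomes = 4,
    gene_length_range = c(2000, 10000),
    min_spacing = 3000,
    gap_mean = 2000,
    overlap_fraction = 0,
    p_rloop = c(pcg_repressed = 0.25, active_top = 0.76,
                inactive_bottom = 0.05),
    p_nascent = c(pcg_repressed = 0.42, active_top = 1,
                  inactive_bottom = 0.05),
    nascent_rate = c(pcg_repressed = 2, active_top = 60,
                     inactive_bottom = 0.5),
    antisense_rate = 0.1,
    read_length = 50,
    chip_enrichment = c(pcg_repressed = 50, active_top = 5,
                        inactive_bottom = 1),
    chip_background_per_kb = 5,
    rnaseh1_depletion = 0.5,
    spikein_fraction = 0.05,
    spikein_genome_size = 2e6,
    duplication_rate = 0.1,
    seed = 1) {
  cfg <- list(
    n_genes = n_genes, genome_size = genome_size,
    n_chromosomes = n_chromosomes, gene_length_range = gene_length_range,
    min_spacing = min_spacing, gap_mean = gap_mean,
    overlap_fraction = overlap_fraction, p_rloop = p_rloop,
    p_nascent = p_nascent,
    nascent_rate = nascent_rate, antisense_rate = antisense_rate,
    read_length = read_length, chip_enrichment = chip_enrichment,
    chip_background_per_kb = chip_background_per_kb,
    rnaseh1_depletion = rnaseh1_depletion,
    spikein_fraction = spikein_fraction,
    spikein_genome_size = spikein_genome_size,
    duplication_rate = duplication_rate, seed = as.integer(seed)
  )
  stopifnot(
    all(cfg$p_rloop >= 0 & cfg$p_rloop <= 1),
    all(cfg$p_nascent >= 0 & cfg$p_nascent <= 1),
    all(cfg$nascent_rate >= 0), cfg$antisense_rate >= 0,
    cfg$spikein_fraction >= 0, cfg$spikein_fraction < 0.5,
    cfg$duplication_rate >= 0, cfg$duplication_rate < 1,
    cfg$overlap_fraction >= 0, cfg$overlap_fraction <= 1,
    all(names(cfg$n_genes) %in% gene_class_levels())
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Chromosome sizes of a simulation configuration
#'
#' @param cfg a [simulation_config()].
#' @return Named numeric vector of target-genome chromosome lengths.
#' @export
sim_chrom_sizes <- function(cfg) {
  len <- floor(cfg$genome_size / cfg$n_chromosomes)
  stats::setNames(rep(len, cfg$n_chromosomes),
                  paste0("chr", seq_len(cfg$n_chromosomes)))
}

#' Simulate a gene annotation with planted classes
#'
#' Places non-nested genes along the chromosomes with at least
#' `min_spacing` between bodies, shuffled class labels and random strands.
#' A fraction `overlap_fraction` of the genes is placed in adjacent pairs
#' whose 1-kb windows overlap (body gap 200-1500 bp), recorded in the
#' `overlap_pair` column, so the uncertain-due-to-proximity rule can be
#' exercised; all other gene windows are mutually disjoint.
#'
#' @param cfg a [simulation_config()].
#' @return Gene tibble ([as_gene_table()]) plus an `overlap_pair` column
#'   (pair index, `NA` for isolated genes), in genomic order.
#' @export
simulate_annotation <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    n <- sum(cfg$n_genes)
    classes <- sample(rep(names(cfg$n_genes), cfg$n_genes))
    lens <- round(stats::runif(n, cfg$gene_length_range[1],
                               cfg$gene_length_range[2]))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    sizes <- sim_chrom_sizes(cfg)

    n_pairs <- floor(cfg$overlap_fraction * n / 2)
    # consecutive placement slots (2i-1, 2i) form the planted pairs; class
    # labels are already shuffled so pairing is class-random
    pair_of <- rep(NA_integer_, n)
    if (n_pairs > 0) {
      pair_of[seq_len(2 * n_pairs)] <- rep(seq_len(n_pairs), each = 2)
    }

    chrom <- character(n)
    start <- numeric(n)
    ci <- 1L
    pos <- cfg$min_spacing  # next free coordinate on current chromosome
    i <- 1L
    while (i <= n) {
      second_of_pair <- !is.na(pair_of[i]) && i > 1 &&
        identical(pair_of[i], pair_of[i - 1])
      if (second_of_pair) {
        gap <- round(stats::runif(1, 200, 1500))  # windows overlap, bodies don't
      } else {
        gap <- cfg$min_spacing + round(stats::rexp(1, 1 / cfg$gap_mean))
      }
      s <- pos + gap
      # keep the trailing 1-kb window inside the chromosome; for a pair's
      # first member reserve room for the partner as well
      reserve <- lens[i] + 1000
      if (!is.na(pair_of[i]) && !second_of_pair) {
        reserve <- reserve + 1500 + cfg$gene_length_range[2] + 1000
      }
      while (s + reserve > sizes[ci]) {
        ci <- ci + 1L
        if (ci > length(sizes)) {
          stop("genome too small to place ", n, " genes; increase ",
               "genome_size or reduce n_genes/spacing", call. = FALSE)
        }
        pos <- cfg$min_spacing
        s <- pos + gap
      }
      chrom[i] <- names(sizes)[ci]
      start[i] <- s
      pos <- s + lens[i]
      i <- i + 1L
    }

    genes <- tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = chrom,
      start = start,
      end = start + lens,
      strand = strands,
      class_label = classes,
      overlap_pair = pair_of
    )
    out <- as_gene_table(genes)
    out$overlap_pair <- genes$overlap_pair
    out
  })
}

#' Plant R-loop peaks on a subset of genes
#'
#' Each gene is drawn R-loop positive with its class probability
#' `p_rloop`; both members of planted window-overlapping pairs are forced
#' positive so that every planted pair exercises the proximity rule. Each
#' positive gene receives one peak placed inside its 1-kb window. The
#' truth table records the planted status each classifier call should
#' recover (`uncertain_proximity` for pair members, `positive` /
#' `negative` otherwise).
#'
#' @param genes output of [simulate_annotation()].
#' @param cfg a [simulation_config()].
#' @return List with `peaks` (interval tibble with peak `name`s) and
#'   `truth` (tibble `gene_id`, `rloop_planted`, `planted_status`).
#' @export
simulate_rloop_peaks <- function(genes, cfg) {
  withr::with_seed(cfg$seed + 202L, {
    p <- cfg$p_rloop[genes$class_label]
    p[is.na(p)] <- 0
    positive <- stats::runif(nrow(genes)) < p
    in_pair <- !is.na(genes[["overlap_pair"]] %||% rep(NA, nrow(genes)))
    positive[in_pair] <- TRUE

    win <- gene_window(genes, 1000)
    idx <- which(positive)
    peaks <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), strand = character(),
                            name = character())
    if (length(idx)) {
      wstart <- win$start[idx]
      wend <- win$end[idx]
      width <- pmin(round(stats::runif(length(idx), 300, 1500)),
                    wend - wstart)
      pstart <- wstart +
        round(stats::runif(length(idx)) * (wend - wstart - width))
      peaks <- tibble::tibble(
        chrom = win$chrom[idx],
        start = pstart,
        end = pstart + width,
        strand = "*",
        name = paste0("rloop_", genes$gene_id[idx])
      )
    }
    truth <- tibble::tibble(
      gene_id = genes$gene_id,
      rloop_planted = positive,
      planted_status = dplyr::case_when(
        positive & in_pair ~ "uncertain_proximity",
        positive ~ "positive",
        .default = "negative"
      )
    )
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate stranded nascent-transcription (run-on) coverage
#'
#' Each gene is drawn transcribed with probability `p_nascent[class]`
#' (independently of its R-loop status). Transcribed genes get sense-strand
#' reads placed uniformly over the gene body with count
#' `Poisson(nascent_rate[class] x length_kb)`; untranscribed genes get
#' none. Antisense background is placed at `antisense_rate` on every gene.
#' Reads are stacked into strand-separated coverage tracks whose
#' `total_mapped` equals the read count of that strand.
#'
#' @inheritParams simulate_rloop_peaks
#' @return List with `track_plus`, `track_minus` ([signal_track()]s) and
#'   `truth` (tibble `gene_id`, `nascent_planted`, `sense_reads`,
#'   `antisense_reads`).
#' @export
simulate_groseq <- function(genes, cfg) {
  withr::with_seed(cfg$seed + 303L, {
    len_kb <- (genes$end - genes$start) / 1000
    p_on <- cfg$p_nascent[genes$class_label]
    p_on[is.na(p_on)] <- 0
    transcribed <- stats::runif(nrow(genes)) < p_on
    rate <- cfg$nascent_rate[genes$class_label]
    rate[is.na(rate)] <- 0
    rate[!transcribed] <- 0
    n_sense <- stats::rpois(nrow(genes), rate * len_kb)
    n_anti <- stats::rpois(nrow(genes), cfg$antisense_rate * len_kb)

    place <- function(counts, strand_of) {
      gi <- rep.int(seq_len(nrow(genes)), counts)
      if (!length(gi)) {
        return(tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric(), strand = character()))
      }
      span <- pmax(1, genes$end[gi] - genes$start[gi] - cfg$read_length)
      s <- genes$start[gi] + floor(stats::runif(length(gi)) * span)
      tibble::tibble(chrom = genes$chrom[gi], start = s,
                     end = s + cfg$read_length, strand = strand_of[gi])
    }
    sense <- place(n_sense, genes$strand)
    anti <- place(n_anti, ifelse(genes$strand == "+", "-", "+"))
    reads <- dplyr::bind_rows(sense, anti)

    mk <- function(st) {
      coverage_track(reads[reads$strand == st, ], strand = st,
                     read_length = cfg$read_length)
    }
    list(
      track_plus = mk("+"),
      track_minus = mk("-"),
      truth = tibble::tibble(gene_id = genes$gene_id,
                             nascent_planted = transcribed,
                             sense_reads = n_sense,
                             antisense_reads = n_anti)
    )
  })
}

#' Simulate spike-in-mixed, duplicated ChIP reads
#'
#' Target-genome reads are a genome-wide Poisson background plus per-gene
#' enrichment at the 2-kb TSS-centred window,
#' `Poisson(chip_enrichment[class] x background_per_kb x 2)`. Under the
#' `rnaseh1` condition the enrichment of R-loop-positive Polycomb-repressed
#' genes is multiplied by `rnaseh1_depletion`. Exogenous spike-in reads are
#' appended so the expected spike-in proportion of the library is
#' `spikein_fraction`, and each read is then PCR-amplified to
#' `1 + Geometric(duplication_rate)` copies.
#'
#' @inheritParams simulate_rloop_peaks
#' @param condition `"control"` or `"rnaseh1"`.
#' @param rloop_truth truth tibble from [simulate_rloop_peaks()]; required
#'   for the `rnaseh1` condition.
#' @return List with `reads` (read-collection tibble) and `truth` (tibble
#'   `gene_id`, `enrichment_lambda`, `n_enriched_reads`).
#' @export
simulate_chip_reads <- function(genes, cfg,
                                condition = c("control", "rnaseh1"),
                                rloop_truth = NULL) {
  condition <- match.arg(condition)
  seed_off <- if (condition == "control") 404L else 505L
  withr::with_seed(cfg$seed + seed_off, {
    fold <- cfg$chip_enrichment[genes$class_label]
    fold[is.na(fold)] <- 1
    if (condition == "rnaseh1") {
      if (is.null(rloop_truth)) {
        stop("rloop_truth is required for the rnaseh1 condition",
             call. = FALSE)
      }
      depleted <- genes$class_label == "pcg_repressed" &
        genes$gene_id %in% rloop_truth$gene_id[rloop_truth$rloop_planted]
      fold[depleted] <- fold[depleted] * cfg$rnaseh1_depletion
    }
    lambda <- fold * cfg$chip_background_per_kb * 2
    # unique-fragment library first: positions drawn without replacement so
    # the only signature copies are the PCR duplicates injected below
    n_slots <- 2000 - cfg$read_length
    n_enr <- pmin(stats::rpois(nrow(genes), lambda), n_slots)
    es <- unlist(lapply(which(n_enr > 0), function(g) {
      pmax(0, genes$tss[g] - 1000 + sample.int(n_slots, n_enr[g]) - 1)
    }))
    gi <- rep.int(seq_len(nrow(genes)), n_enr)
    enriched <- tibble::tibble(chrom = genes$chrom[gi], start = es,
                               end = es + cfg$read_length,
                               strand = sample(c("+", "-"), length(gi),
                                               replace = TRUE))

    sizes <- sim_chrom_sizes(cfg)
    n_bg <- stats::rpois(1, cfg$chip_background_per_kb *
                           cfg$genome_size / 1000)
    bg_chrom <- sample(names(sizes), n_bg, replace = TRUE)
    background <- dplyr::bind_rows(lapply(names(sizes), function(chr) {
      k <- sum(bg_chrom == chr)
      bs <- sample.int(sizes[[chr]] - cfg$read_length, k) - 1
      tibble::tibble(chrom = chr, start = bs, end = bs + cfg$read_length,
                     strand = sample(c("+", "-"), k, replace = TRUE))
    }))

    target <- dplyr::distinct(dplyr::bind_rows(enriched, background))
    n_spike <- stats::rbinom(
      1, size = round(nrow(target) / (1 - cfg$spikein_fraction)),
      prob = cfg$spikein_fraction
    )
    ss <- sample.int(cfg$spikein_genome_size - cfg$read_length, n_spike) - 1
    spike <- tibble::tibble(chrom = "spike_1", start = ss,
                            end = ss + cfg$read_length,
                            strand = sample(c("+", "-"), n_spike,
                                            replace = TRUE))
    reads <- read_collection(dplyr::bind_rows(target, spike))

    if (cfg$duplication_rate > 0) {
      copies <- 1L + stats::rgeom(nrow(reads),
                                  prob = 1 - cfg$duplication_rate)
      reads <- reads[rep.int(seq_len(nrow(reads)), copies), ]
    }
    reads <- dplyr::arrange(tibble::as_tibble(reads), .data$chrom,
                            .data$start, .data$end, .data$strand)
    list(
      reads = reads,
      truth = tibble::tibble(gene_id = genes$gene_id,
                             enrichment_lambda = unname(lambda),
                             n_enriched_reads = n_enr)
    )
  })
}

#' Simulate qPCR Ct measurements with known percent input
#'
#' The undiluted input has a baseline Ct of `base_ct`; the measured input
#' Ct is shifted up by `log2(1 / input_dilution)` for the diluted aliquot.
#' The IP Ct is `base_ct - log2(true_percent_input / 100)` — a target
#' present at x% of input amplifies `log2(100 / x)` cycles later — with
#' Gaussian noise of `ct_noise_sd` on both measurements. With zero noise,
#' [percent_input()] inverts the simulation exactly for any dilution.
#'
#' @param true_percent_input true enrichment as percent of input.
#' @param ct_noise_sd Gaussian Ct noise SD (cycles).
#' @param input_dilution fraction of chromatin used as input (0, 1].
#' @param n_replicates replicate measurements.
#' @param target_id,condition labels carried into the output.
#' @param base_ct baseline Ct of the undiluted input.
#' @param seed optional seed for this draw.
#' @return qPCR tibble (`target_id`, `condition`, `replicate`, `ct_ip`,
#'   `ct_input`, `input_fraction`, `true_percent_input`).
#' @export
simulate_qpcr <- function(true_percent_input, ct_noise_sd = 0,
                          input_dilution = 1, n_replicates = 3,
                          target_id = "amplicon", condition = "mock",
                          base_ct = 25, seed = NULL) {
  stopifnot(true_percent_input > 0,
            input_dilution > 0, input_dilution <= 1)
  draw <- function() {
    tibble::tibble(
      target_id = target_id,
      condition = condition,
      replicate = seq_len(n_replicates),
      ct_ip = base_ct - log2(true_percent_input / 100) +
        stats::rnorm(n_replicates, 0, ct_noise_sd),
      ct_input = base_ct + log2(1 / input_dilution) +
        stats::rnorm(n_replicates, 0, ct_noise_sd),
      input_fraction = input_dilution,
      true_percent_input = true_percent_input
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Run every generator of the synthetic study
#'
#' Annotation, R-loop peaks, stranded nascent coverage, and spike-in ChIP
#' reads for the control and RNase H1 conditions, all deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return List with `genes`, `peaks`, `rloop_truth`, `groseq`
#'   (tracks + truth), `chip_control`, `chip_rnaseh1` (reads + truth) and
#'   `chrom_sizes`.
#' @export
simulate_study <- function(cfg) {
  genes <- simulate_annotation(cfg)
  rl <- simulate_rloop_peaks(genes, cfg)
  gro <- simulate_groseq(genes, cfg)
  chip_c <- simulate_chip_reads(genes, cfg, "control", rl$truth)
  chip_r <- simulate_chip_reads(genes, cfg, "rnaseh1", rl$truth)
  list(
    genes = genes,
    peaks = rl$peaks,
    rloop_truth = rl$truth,
    groseq = gro,
    chip_control = chip_c,
    chip_rnaseh1 = chip_r,
    chrom_sizes = sim_chrom_sizes(cfg)
  )
}

#' Write a simulated study to disk
#'
#' Standard formats plus machine-readable truth sidecars: gene table and
#' truth tables as TSV, peaks and reads as BED, coverage as bedGraph.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gene_table(sim$genes, p("genes.tsv"))
  write_bed(sim$peaks, p("rloop_peaks.bed"))
  readr::write_tsv(sim$rloop_truth, p("rloop_truth.tsv"))
  write_bedgraph(sim$groseq$track_plus, p("groseq_plus.bedgraph"))
  write_bedgraph(sim$groseq$track_minus, p("groseq_minus.bedgraph"))
  readr::write_tsv(sim$groseq$truth, p("groseq_truth.tsv"))
  write_bed(sim$chip_control$reads, p("chip_control_reads.bed"))
  write_bed(sim$chip_rnaseh1$reads, p("chip_rnaseh1_reads.bed"))
  readr::write_tsv(sim$chip_control$truth, p("chip_control_truth.tsv"))
  readr::write_tsv(sim$chip_rnaseh1$truth, p("chip_rnaseh1_truth.tsv"))
  readr::write_tsv(
    tibble::tibble(chrom = names(sim$chrom_sizes),
                   size = unname(sim$chrom_sizes)),
    p("chrom_sizes.tsv")
  )
  invisible(dir)
}
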