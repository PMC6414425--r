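small_cfg <- function(...) {
  simulation_config(
    n_genes = c(pcg_repressed = 30, active_top = 30, inactive_bottom = 30),
    genome_size = 3e6, seed = 7, ...
  )
}

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg(overlap_fraction = 0.1)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("annotation respects spacing, non-nesting and planted pairs", {
  cfg <- small_cfg(overlap_fraction = 0.2)
  genes <- simulate_annotation(cfg)
  expect_equal(nrow(genes), 90)
  expect_true(all(table(genes$class_label) == 30))
  # ~20% of genes in pairs
  n_paired <- sum(!is.na(genes$overlap_pair))
  expect_equal(n_paired, 2 * floor(0.2 * 90 / 2))

  win <- gene_window(genes, 1000)
  pairs <- self_overlap_pairs(win)
  # every window overlap is a planted pair
  planted <- genes$overlap_pair
  expect_true(all(!is.na(planted[pairs$i])))
  expect_true(all(planted[pairs$i] == planted[pairs$j]))
  # and every planted pair overlaps
  expect_equal(2 * nrow(pairs), n_paired)

  # zero overlap fraction -> all windows disjoint
  genes0 <- simulate_annotation(small_cfg(overlap_fraction = 0))
  expect_equal(nrow(self_overlap_pairs(gene_window(genes0, 1000))), 0)

  expect_error(simulate_annotation(simulation_config(
    n_genes = c(pcg_repressed = 500, active_top = 500,
                inactive_bottom = 500),
    genome_size = 1e6, seed = 1
  )), "too small")
})

test_that("degenerate R-loop probabilities plant everything or nothing", {
  cfg1 <- small_cfg(p_rloop = c(pcg_repressed = 1, active_top = 1,
                                inactive_bottom = 1))
  rl1 <- simulate_rloop_peaks(simulate_annotation(cfg1), cfg1)
  expect_true(all(rl1$truth$rloop_planted))
  expect_equal(nrow(rl1$peaks), 90)

  cfg0 <- small_cfg(p_rloop = c(pcg_repressed = 0, active_top = 0,
                                inactive_bottom = 0))
  rl0 <- simulate_rloop_peaks(simulate_annotation(cfg0), cfg0)
  expect_false(any(rl0$truth$rloop_planted))
  expect_equal(nrow(rl0$peaks), 0)
})

test_that("planted positive fraction is binomially consistent", {
  cfg <- simulation_config(
    n_genes = c(pcg_repressed = 0, active_top = 1000, inactive_bottom = 0),
    genome_size = 1.5e7, seed = 19
  )
  genes <- simulate_annotation(cfg)
  rl <- simulate_rloop_peaks(genes, cfg)
  p <- 0.76
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(mean(rl$truth$rloop_planted) - p), 3 * se)
})

test_that("peaks sit inside their gene's 1-kb window", {
  cfg <- small_cfg()
  genes <- simulate_annotation(cfg)
  rl <- simulate_rloop_peaks(genes, cfg)
  win <- gene_window(genes, 1000)
  owner <- match(sub("^rloop_", "", rl$peaks$name), win$gene_id)
  expect_true(all(rl$peaks$start >= win$start[owner]))
  expect_true(all(rl$peaks$end <= win$end[owner]))
})

test_that("run-on reads land on the sense strand over the gene body", {
  cfg <- small_cfg(antisense_rate = 0,
                   p_nascent = c(pcg_repressed = 1, active_top = 1,
                                 inactive_bottom = 1),
                   nascent_rate = c(pcg_repressed = 5, active_top = 5,
                                    inactive_bottom = 0))
  genes <- simulate_annotation(cfg)
  gro <- simulate_groseq(genes, cfg)

  body <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                         end = genes$end)
  int_plus <- track_integral(gro$track_plus, body)
  int_minus <- track_integral(gro$track_minus, body)
  # inactive genes: zero sense coverage
  inact <- genes$class_label == "inactive_bottom"
  sense_int <- ifelse(genes$strand == "+", int_plus, int_minus)
  anti_int <- ifelse(genes$strand == "+", int_minus, int_plus)
  expect_true(all(sense_int[inact] == 0))
  # no antisense anywhere when antisense_rate = 0
  expect_true(all(anti_int == 0))
  # coverage integral equals read count x read length
  expect_equal(sum(sense_int),
               sum(gro$truth$sense_reads) * cfg$read_length)
})

test_that("sense read counts follow the planted Poisson law", {
  # one fixed 2-kb gene at 100 reads/kb; mean over seeds ~ Poisson(200)
  counts <- vapply(1:40, function(s) {
    cfg <- simulation_config(
      n_genes = c(pcg_repressed = 1, active_top = 0, inactive_bottom = 0),
      genome_size = 1e5, gene_length_range = c(2000, 2000),
      p_nascent = c(pcg_repressed = 1, active_top = 1, inactive_bottom = 1),
      nascent_rate = c(pcg_repressed = 100, active_top = 0,
                       inactive_bottom = 0),
      seed = s
    )
    g <- simulate_annotation(cfg)
    simulate_groseq(g, cfg)$truth$sense_reads
  }, numeric(1))
  # mean within 4 SE of 200; variance on the Poisson scale
  expect_lt(abs(mean(counts) - 200), 4 * sqrt(200 / 40))
  expect_gt(stats::var(counts), 200 * 0.4)
  expect_lt(stats::var(counts), 200 * 2.5)
})

test_that("chip reads carry spike-ins and duplicates as configured", {
  cfg <- small_cfg(duplication_rate = 0, spikein_fraction = 0.1)
  genes <- simulate_annotation(cfg)
  rl <- simulate_rloop_peaks(genes, cfg)
  chip <- simulate_chip_reads(genes, cfg, "control", rl$truth)
  # no duplicates: all signatures unique
  expect_equal(anyDuplicated(chip$reads[c("chrom", "start", "end", "strand")]),
               0L)
  # spike-in fraction near 0.1
  frac <- mean(chip$reads$genome_tag == "spikein")
  n <- nrow(chip$reads)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # duplicates appear at a positive duplication rate
  cfg2 <- small_cfg(duplication_rate = 0.4)
  chip2 <- simulate_chip_reads(genes, cfg2, "control", rl$truth)
  expect_gt(nrow(chip2$reads),
            nrow(dplyr::distinct(chip2$reads[c("chrom", "start", "end",
                                               "strand")])))
})

test_that("depletion factor 1 leaves the rnaseh1 enrichment model unchanged", {
  cfg <- small_cfg(rnaseh1_depletion = 1)
  genes <- simulate_annotation(cfg)
  rl <- simulate_rloop_peaks(genes, cfg)
  ctl <- simulate_chip_reads(genes, cfg, "control", rl$truth)
  rnh <- simulate_chip_reads(genes, cfg, "rnaseh1", rl$truth)
  expect_equal(ctl$truth$enrichment_lambda, rnh$truth$enrichment_lambda)
})

test_that("qPCR simulation obeys the delta-Ct closed forms", {
  # 100% input, no dilution, no noise: IP and input amplify together
  s <- simulate_qpcr(100, ct_noise_sd = 0, input_dilution = 1,
                     n_replicates = 2)
  expect_equal(s$ct_ip, s$ct_input)
  # 1% input: IP lags by log2(100) cycles
  s1 <- simulate_qpcr(1, ct_noise_sd = 0, input_dilution = 1,
                      n_replicates = 1)
  expect_equal(s1$ct_ip - s1$ct_input, log2(100))
  # dilution shifts the measured input Ct up by log2(1/dilution)
  s10 <- simulate_qpcr(100, ct_noise_sd = 0, input_dilution = 0.1,
                       n_replicates = 1)
  expect_equal(s10$ct_input - s10$ct_ip, log2(10))
})
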