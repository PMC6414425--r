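test_that("uniform coverage gives a constant profile", {
  genes <- toy_genes()
  tr <- flat_track(value = 3, end = 2e5)
  pm <- profile_matrix(tr, genes, anchor = "tss", flank_bp = 2000)
  expect_equal(dim(pm$matrix), c(3, 400))
  expect_true(all(pm$matrix == 3))
  ap <- average_profile(pm)
  expect_equal(ap$mean_coverage, rep(3, 400))
})

test_that("minus-strand profiles mirror the plus-strand case", {
  mk <- function(strand) {
    as_gene_table(tibble::tibble(
      gene_id = "g", chrom = "chr1", start = 10000, end = 14000,
      strand = strand, class_label = "other"
    ))
  }
  # step: coverage 5 downstream of position 10000, 0 upstream
  step_up <- signal_track(tibble::tibble(chrom = "chr1", start = 10000,
                                         end = 30000, value = 5))
  pm_plus <- profile_matrix(step_up, mk("+"), flank_bp = 1000)
  # minus-strand gene with TSS at 14000 and coverage 5 upstream of it
  step_dn <- signal_track(tibble::tibble(chrom = "chr1", start = 0,
                                         end = 14000, value = 5))
  pm_minus <- profile_matrix(step_dn, mk("-"), flank_bp = 1000)
  expect_equal(pm_minus$matrix[1, ], pm_plus$matrix[1, ])
  # 5' half is empty, 3' half is at 5
  expect_equal(unname(pm_plus$matrix[1, c(1, 200)]), c(0, 5))
})

test_that("bins match brute-force per-base averaging on random tracks", {
  withr::local_seed(37)
  # sparse non-overlapping runs of width 50 on a 75-bp grid
  starts <- sort(sample(seq(0, 44925, by = 75), 300))
  tr <- signal_track(tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 50,
    value = stats::rexp(length(starts))
  ))
  genes <- toy_genes()
  pm <- profile_matrix(tr, genes, flank_bp = 500)
  for (g in 1:3) {
    centre <- genes$tss[g]
    offs <- seq(-500, 490, by = 10)
    want <- vapply(offs, function(o) {
      brute_track_integral(tr, genes$chrom[g], centre + o,
                           centre + o + 10) / 10
    }, numeric(1))
    if (genes$strand[g] == "-") want <- rev(want)
    expect_equal(unname(pm$matrix[g, ]), want)
  }
})

test_that("profile mass is conserved over unmasked windows", {
  withr::local_seed(41)
  cfg <- simulation_config(
    n_genes = c(pcg_repressed = 15, active_top = 15, inactive_bottom = 15),
    genome_size = 2e6, seed = 41
  )
  sim <- simulate_study(cfg)
  tr <- sim$groseq$track_plus
  pm <- profile_matrix(tr, sim$genes, flank_bp = 2000)
  win <- tibble::tibble(chrom = sim$genes$chrom,
                        start = sim$genes$tss - 2000,
                        end = sim$genes$tss + 2000)
  ok <- win$start >= 0
  integrals <- track_integral(tr, win[ok, ])
  expect_equal(unname(rowSums(pm$matrix[ok, , drop = FALSE]) * 10),
               integrals)
})

test_that("out-of-bounds bins are zero and masked", {
  genes <- as_gene_table(tibble::tibble(
    gene_id = "edge", chrom = "chr1", start = 500, end = 3000,
    strand = "+", class_label = "other"
  ))
  pm <- profile_matrix(flat_track(value = 2), genes, flank_bp = 1000)
  # TSS at 500: the first 50 bins (500 bp) fall before the chromosome start
  expect_true(all(!pm$mask[1, 1:50]))
  expect_true(all(pm$matrix[1, 1:50] == 0))
  expect_true(all(pm$mask[1, 51:200]))
  sizes <- c(chr1 = 1200)
  pm2 <- profile_matrix(flat_track(value = 2), genes, flank_bp = 1000,
                        chrom_sizes = sizes)
  # bins past position 1200 (TSS + 700 onward) masked too
  expect_true(all(!pm2$mask[1, 171:200]))
  expect_true(all(pm2$mask[1, 51:170]))
})

test_that("exact Wilcoxon enumeration matches closed-form combinatorics", {
  # x = {1,2}, y = {3,4}: one-sided tail 1/C(4,2), two-sided 1/3
  ht <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(ht$statistic, 3)
  expect_equal(ht$p_value, 1 / 3)
  # identical samples: symmetric, p = 1
  expect_equal(wilcoxon_rank_sum(c(5, 9, 2), c(5, 9, 2))$p_value, 1)
})

test_that("enumeration p-values match the exact reference distribution", {
  withr::local_seed(53)
  for (rep in 1:40) {
    n1 <- sample(1:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(1000, n1)
    y <- setdiff(sample(1000, n1 + n2), x)[seq_len(n2)]
    ht <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ht$p_value, ref$p.value, tolerance = 1e-12,
                 info = paste(n1, n2))
  }
})

test_that("normal approximation tracks enumeration on moderate samples", {
  withr::local_seed(59)
  # force the approximation by exceeding the exact-size cutoff
  x <- stats::rnorm(20)
  y <- stats::rnorm(20, 1)
  ht <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ht$p_value, ref$p.value, tolerance = 1e-10)
  # ties handled through midranks + tie correction
  xt <- c(1, 1, 2, 2, 3)
  yt <- c(2, 3, 3, 4, 4)
  ht_t <- wilcoxon_rank_sum(xt, yt)
  ref_t <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                               correct = TRUE))
  expect_equal(ht_t$p_value, ref_t$p.value, tolerance = 1e-10)
})

test_that("test statistics are order- and swap-invariant", {
  withr::local_seed(61)
  x <- stats::rnorm(8)
  y <- stats::rnorm(9, 0.5)
  w1 <- wilcoxon_rank_sum(x, y)
  w2 <- wilcoxon_rank_sum(sample(x), sample(y))
  expect_equal(w1$p_value, w2$p_value)
  expect_equal(wilcoxon_rank_sum(y, x)$p_value, w1$p_value)
  t1 <- t_test_two_tailed(x, y)
  expect_equal(t_test_two_tailed(y, x)$statistic, -t1$statistic)
  expect_equal(t_test_two_tailed(y, x)$p_value, t1$p_value)
})

test_that("pooled t-test matches the reference implementation", {
  withr::local_seed(67)
  for (rep in 1:20) {
    x <- stats::rnorm(sample(3:15, 1))
    y <- stats::rnorm(sample(3:15, 1), mean = stats::runif(1, -1, 1))
    ht <- t_test_two_tailed(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ht$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ht$p_value, ref$p.value, tolerance = 1e-8)
    htw <- t_test_two_tailed(x, y, var_equal = FALSE)
    refw <- stats::t.test(x, y)
    expect_equal(htw$p_value, refw$p.value, tolerance = 1e-8)
  }
  expect_equal(t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(t_test_two_tailed(c(1, 1), c(2, 2)), "pooled variance")
  expect_error(t_test_two_tailed(1, c(1, 2)), "at least 2")
})

test_that("star annotation follows the legend convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
  expect_equal(p_stars(0.05), "ns")  # boundary is strict
})

test_that("htest objects tidy into one-row tibbles", {
  ht <- wilcoxon_rank_sum(1:5, 6:10)
  td <- tidy(ht)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "p.value", "stars", "method"))
})
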