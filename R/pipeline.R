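#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtain inputs (simulate under `cfg`, or read
#' the files named in `inputs`), deduplicate and spike-in-normalize the
#' ChIP reads of both conditions, classify genes for R-loops, compute
#' nascent RPKMs and the R-loop x nascent intersection, summarise 1-kb
#' TSS-window signal per condition, and run the comparison statistics.
#' Everything is deterministic under `cfg$seed`.
#'
#' @param cfg a [simulation_config()]; drives the simulation and seeds.
#' @param inputs optional named list of file paths (`genes`, `peaks`,
#'   `groseq_plus`, `groseq_minus`, `reads_control`, `reads_rnaseh1`);
#'   when given these are read instead of simulating.
#' @param flank_bp R-loop window flank (default 1000).
#' @param tss_window_bp TSS window for normalized signal (default 1000).
#' @param rpkm_threshold nascent positivity cutoff (default 0.1).
#' @param rank_fraction top/bottom expression fraction (default 0.15).
#' @param percentile duplicate-threshold percentile (default 0.95).
#' @param output_dir optional directory; stage outputs are written as
#'   TSV/BED/bedGraph plus a `summary.json`.
#' @return An `rloop_pipeline` object: list with `calls`, `proportions`,
#'   `expression`, `intersection`, `signal` (per-gene normalized TSS
#'   signal, both conditions), `factors`, `dedup`, `tests` and `summary`.
#' @export
run_pipeline <- function(cfg = simulation_config(), inputs = NULL,
                         flank_bp = 1000, tss_window_bp = 1000,
                         rpkm_threshold = 0.1, rank_fraction = 0.15,
                         percentile = 0.95, output_dir = NULL) {
  if (is.null(inputs)) {
    sim <- simulate_study(cfg)
    genes <- sim$genes
    peaks <- sim$peaks
    track_plus <- sim$groseq$track_plus
    track_minus <- sim$groseq$track_minus
    reads <- list(control = sim$chip_control$reads,
                  rnaseh1 = sim$chip_rnaseh1$reads)
    truth <- sim$rloop_truth
  } else {
    need <- c("genes", "peaks", "groseq_plus", "groseq_minus",
              "reads_control", "reads_rnaseh1")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop("missing input paths: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    genes <- read_gene_table(inputs$genes)
    peaks <- read_bed(inputs$peaks)
    track_plus <- read_bedgraph(inputs$groseq_plus, strand = "+",
                                read_length = cfg$read_length)
    track_minus <- read_bedgraph(inputs$groseq_minus, strand = "-",
                                 read_length = cfg$read_length)
    reads <- list(control = read_reads_bed(inputs$reads_control),
                  rnaseh1 = read_reads_bed(inputs$reads_rnaseh1))
    sim <- NULL
    truth <- NULL
  }

  dedup <- lapply(reads, deduplicate, percentile = percentile)
  factors <- lapply(dedup, function(d) normalization_factors(d$retained))
  signal <- dplyr::bind_rows(
    lapply(names(dedup), function(cond) {
      dplyr::mutate(
        window_signal(dedup[[cond]]$retained, genes,
                      factors = factors[[cond]],
                      window_bp = tss_window_bp),
        condition = cond
      )
    })
  )

  calls <- classify_rloop(genes, peaks, flank_bp = flank_bp)
  proportions <- group_proportions(calls)
  expr <- nascent_rpkm(genes, track_plus, track_minus,
                       threshold = rpkm_threshold)
  inter <- intersection_counts(calls, expr)

  # transcription of R-loop positive vs negative Polycomb-repressed genes
  pcg <- calls$class_label == "pcg_repressed"
  rpkm_pos <- expr$rpkm[pcg & calls$status == "positive"]
  rpkm_neg <- expr$rpkm[pcg & calls$status == "negative"]
  wt <- if (length(rpkm_pos) && length(rpkm_neg)) {
    wilcoxon_rank_sum(rpkm_pos, rpkm_neg)
  } else NULL

  # condition effect on normalized TSS signal, per class and R-loop status
  sig2 <- dplyr::left_join(signal, calls[c("gene_id", "status")],
                           by = "gene_id")
  medians <- sig2 |>
    dplyr::group_by(.data$condition, .data$class_label, .data$status) |>
    dplyr::summarise(median_signal = stats::median(.data$signal),
                     n = dplyr::n(), .groups = "drop")
  ratio_of <- function(class, status) {
    sel <- sig2$class_label == class & sig2$status %in% status
    ctl <- stats::median(sig2$signal[sel & sig2$condition == "control"])
    trt <- stats::median(sig2$signal[sel & sig2$condition == "rnaseh1"])
    trt / ctl
  }
  depletion_ratio <- ratio_of("pcg_repressed",
                              c("positive", "uncertain_proximity"))
  active_ratio <- ratio_of("active_top",
                           c("positive", "negative", "uncertain_proximity"))

  summary <- list(
    n_genes = nrow(genes),
    proportions = proportions,
    intersection = inter,
    wilcoxon_p_rloop_rpkm = if (is.null(wt)) NA_real_ else wt$p_value,
    normalized_depth = lapply(factors, `[[`, "normalized_depth"),
    dedup_threshold = lapply(dedup, `[[`, "threshold"),
    median_tss_signal = medians,
    rnaseh1_depletion_ratio_pcg_rloop_pos = depletion_ratio,
    rnaseh1_ratio_active = active_ratio
  )

  out <- structure(
    list(
      genes = genes, peaks = peaks, calls = calls,
      proportions = proportions, expression = expr, intersection = inter,
      signal = signal, factors = factors,
      dedup = lapply(dedup, function(d) d[c("threshold", "removed")]),
      tests = list(wilcoxon_rloop_rpkm = wt),
      truth = truth, summary = summary, seed = cfg$seed
    ),
    class = "rloop_pipeline"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sim)) write_simulation(sim, file.path(output_dir, "inputs"))
    readr::write_tsv(calls, file.path(output_dir, "rloop_calls.tsv"))
    readr::write_tsv(proportions, file.path(output_dir, "proportions.tsv"))
    readr::write_tsv(expr, file.path(output_dir, "nascent_rpkm.tsv"))
    readr::write_tsv(inter, file.path(output_dir, "intersection.tsv"))
    readr::write_tsv(signal, file.path(output_dir, "tss_signal.tsv"))
    jsonlite::write_json(
      summary_to_json(summary),
      file.path(output_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

summary_to_json <- function(s) {
  list(
    n_genes = s$n_genes,
    proportions = s$proportions,
    intersection = s$intersection,
    wilcoxon_p_rloop_rpkm = s$wilcoxon_p_rloop_rpkm,
    normalized_depth = s$normalized_depth,
    dedup_threshold = s$dedup_threshold,
    rnaseh1_depletion_ratio_pcg_rloop_pos =
      s$rnaseh1_depletion_ratio_pcg_rloop_pos,
    rnaseh1_ratio_active = s$rnaseh1_ratio_active
  )
}

#' @export
print.rloop_pipeline <- function(x, ...) {
  cat("rloop_pipeline:", x$summary$n_genes, "genes, seed", x$seed, "\n\n")
  cat("R-loop status proportions by class:\n")
  print(as.data.frame(x$proportions), row.names = FALSE)
  cat("\nPolycomb-repressed intersection (R-loop x nascent RNA):\n")
  print(as.data.frame(x$intersection), row.names = FALSE)
  if (!is.null(x$tests$wilcoxon_rloop_rpkm)) {
    cat("\nRPKM, R-loop+ vs R-loop- Polycomb genes: p =",
        format(x$tests$wilcoxon_rloop_rpkm$p_value, digits = 4), "\n")
  }
  cat("RNase H1 / control median TSS signal at R-loop+ Polycomb genes:",
      format(x$summary$rnaseh1_depletion_ratio_pcg_rloop_pos, digits = 4),
      "\n")
  invisible(x)
}

#' @method tidy rloop_pipeline
#' @export
tidy.rloop_pipeline <- function(x, ...) {
  tidyr::pivot_longer(
    x$proportions,
    dplyr::starts_with("prop_"),
    names_to = "status", names_prefix = "prop_",
    values_to = "proportion"
  )
}

#' @method glance rloop_pipeline
#' @export
glance.rloop_pipeline <- function(x, ...) {
  tibble::tibble(
    n_genes = x$summary$n_genes,
    wilcoxon_p_rloop_rpkm = x$summary$wilcoxon_p_rloop_rpkm,
    rnaseh1_depletion_ratio = x$summary$rnaseh1_depletion_ratio_pcg_rloop_pos,
    rnaseh1_ratio_active = x$summary$rnaseh1_ratio_active,
    normalized_depth_control = x$factors$control$normalized_depth,
    normalized_depth_rnaseh1 = x$factors$rnaseh1$normalized_depth
  )
}
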