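#' Read collections
#'
#' A read collection is a tibble with one row per aligned read: columns
#' `chrom`, `start`, `end`, `strand` and `genome_tag` (`"target"` or
#' `"spikein"`). The read *signature* is the tuple (chrom, start, end,
#' strand); PCR duplicates are exact signature copies. Reads aligned to the
#' exogenous spike-in genome live on chromosomes named `spike_*`, from
#' which `genome_tag` can be inferred.
#'
#' @param reads interval tibble with a `strand` column; one row per read.
#' @param genome_tag optional character vector (`"target"`/`"spikein"`);
#'   inferred from the `spike_` chromosome prefix when omitted.
#' @return Read-collection tibble.
#' @export
read_collection <- function(reads, genome_tag = NULL) {
  validate_intervals(reads, "read collection")
  if (is.null(genome_tag)) {
    genome_tag <- ifelse(startsWith(reads$chrom, "spike_"),
                         "spikein", "target")
  }
  stopifnot(all(genome_tag %in% c("target", "spikein")))
  reads <- tibble::as_tibble(reads)[c("chrom", "start", "end", "strand")]
  reads$genome_tag <- genome_tag
  reads
}

#' Read aligned reads from BED into a read collection
#'
#' @inheritParams read_bed
#' @return Read-collection tibble (spike-in reads recognised by the
#'   `spike_` chromosome namespace).
#' @export
read_reads_bed <- function(path) {
  read_collection(read_bed(path))
}

# per-signature occurrence counts of a read collection
signature_counts <- function(reads) {
  dplyr::count(reads, .data$chrom, .data$start, .data$end, .data$strand,
               .data$genome_tag, name = "n_copies")
}

#' Duplicate-read frequency threshold
#'
#' The per-dataset duplication cutoff: the nearest-rank 95th percentile of
#' the frequency distribution of read signatures, i.e. the
#' `ceiling(p * n)`-th smallest per-signature occurrence count. Computed on
#' the full dataset (target and spike-in reads together).
#'
#' @param reads read-collection tibble.
#' @param percentile percentile of the signature-frequency distribution
#'   (default 0.95).
#' @return Positive integer threshold.
#' @export
dedup_threshold <- function(reads, percentile = 0.95) {
  if (nrow(reads) == 0L) {
    stop("cannot compute a duplication threshold on an empty read collection",
         call. = FALSE)
  }
  counts <- sort(signature_counts(reads)$n_copies)
  k <- ceiling(percentile * length(counts))
  max(1L, as.integer(counts[k]))
}

#' Remove over-threshold duplicate reads
#'
#' Signatures occurring more often than the dataset-wide threshold are
#' trimmed. By default excess copies are removed and `threshold` copies are
#' kept (`mode = "cap"`); `mode = "drop"` removes the whole over-threshold
#' signature group instead.
#'
#' @inheritParams dedup_threshold
#' @param threshold override the computed threshold.
#' @param mode `"cap"` (keep `threshold` copies) or `"drop"` (remove the
#'   whole signature group).
#' @return List with `threshold` (integer), `removed` (reads removed) and
#'   `retained` (the deduplicated read-collection tibble).
#' @export
deduplicate <- function(reads, percentile = 0.95, threshold = NULL,
                        mode = c("cap", "drop")) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- dedup_threshold(reads, percentile)
  sig <- signature_counts(reads)
  keep <- if (mode == "cap") pmin(sig$n_copies, threshold) else {
    ifelse(sig$n_copies > threshold, 0L, sig$n_copies)
  }
  retained <- sig[rep.int(seq_len(nrow(sig)), keep),
                  c("chrom", "start", "end", "strand", "genome_tag")]
  retained <- dplyr::arrange(retained, .data$chrom, .data$start, .data$end,
                             .data$strand)
  list(
    threshold = as.integer(threshold),
    removed = nrow(reads) - nrow(retained),
    retained = tibble::as_tibble(retained)
  )
}

#' Spike-in normalization factors
#'
#' Between-sample comparability is obtained by scaling target-genome signal
#' by the exogenous (spike-in) library: each target read carries a weight
#' of `1e6 / n_spikein`, so the normalized depth is
#' `n_target / n_spikein * 1e6`.
#'
#' @param reads read-collection tibble (post-deduplication).
#' @return List with `n_target`, `n_spikein`, `per_read_weight`,
#'   `normalized_depth`.
#' @export
normalization_factors <- function(reads) {
  n_target <- sum(reads$genome_tag == "target")
  n_spikein <- sum(reads$genome_tag == "spikein")
  if (n_spikein == 0L) {
    stop("no spike-in reads: spike-in normalization failed", call. = FALSE)
  }
  w <- 1e6 / n_spikein
  list(
    n_target = n_target,
    n_spikein = n_spikein,
    per_read_weight = w,
    normalized_depth = n_target * w
  )
}

#' Spike-in-normalized signal in TSS-centred windows
#'
#' Counts target-genome reads overlapping a window of `window_bp` bases
#' centred on each gene's TSS (clipped at the chromosome start) and scales
#' the count by the spike-in per-read weight.
#'
#' @param reads read-collection tibble.
#' @param genes gene tibble ([as_gene_table()]).
#' @param factors normalization factors ([normalization_factors()]);
#'   computed from `reads` when omitted.
#' @param window_bp window width in bases centred on the TSS (even).
#' @return Tibble `gene_id`, `class_label`, `n_reads`, `signal`.
#' @export
window_signal <- function(reads, genes, factors = NULL, window_bp = 1000) {
  if (window_bp %% 2 != 0) stop("window_bp must be even", call. = FALSE)
  if (is.null(factors)) factors <- normalization_factors(reads)
  half <- window_bp / 2
  win <- tibble::tibble(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - half),
    end = genes$tss + half
  )
  target <- reads[reads$genome_tag == "target", ]
  n <- count_interval_overlaps(win, target)
  tibble::tibble(
    gene_id = genes$gene_id,
    class_label = genes$class_label,
    n_reads = n,
    signal = n * factors$per_read_weight
  )
}
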