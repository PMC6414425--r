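#' Gene window: TSS - flank to TES + flank
#'
#' The genomic region from `flank_bp` before the TSS to `flank_bp` after
#' the TES. Because the flank is symmetric this is the gene body extended
#' by `flank_bp` on both sides regardless of strand, clipped at the
#' chromosome start.
#'
#' @param genes gene tibble ([as_gene_table()]).
#' @param flank_bp flank in bases (default 1000).
#' @return Interval tibble (`gene_id`, `chrom`, `start`, `end`).
#' @export
gene_window <- function(genes, flank_bp = 1000) {
  stopifnot(flank_bp >= 0)
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0, genes$start - flank_bp),
    end = genes$end + flank_bp
  )
}

#' Classify genes as R-loop positive, negative or uncertain
#'
#' A gene is R-loop **positive** when at least one DRIP peak overlaps its
#' window (gene body extended `flank_bp` each side; >= 1 shared base; peak
#' strand ignored). Positive genes whose windows overlap the window of
#' another positive gene are reassigned **uncertain_proximity**, since the
#' peak cannot be unambiguously attributed between neighbours. All
#' remaining genes are **negative**. The reassignment is a single pass over
#' the initial positive set; output rows keep the input gene order.
#'
#' @param genes gene tibble ([as_gene_table()]).
#' @param peaks interval tibble of R-loop (DRIP) peaks; may be empty.
#' @param flank_bp window flank in bases (default 1000).
#' @param proximity one of `"gene"` (default: positive genes whose windows
#'   overlap another positive gene's *window*) or `"peak"` (positive genes
#'   whose window overlaps a peak that also overlaps another positive
#'   gene's window).
#' @return Tibble `gene_id`, `class_label`, `chrom`, `window_start`,
#'   `window_end`, `status` (`positive` / `negative` /
#'   `uncertain_proximity`), `n_overlapping_peaks`.
#' @export
classify_rloop <- function(genes, peaks, flank_bp = 1000,
                           proximity = c("gene", "peak")) {
  proximity <- match.arg(proximity)
  win <- gene_window(genes, flank_bp)
  n_peaks <- count_interval_overlaps(win, peaks)
  positive <- n_peaks >= 1
  status <- ifelse(positive, "positive", "negative")

  pos_idx <- which(positive)
  if (length(pos_idx) >= 2) {
    uncertain <- if (proximity == "gene") {
      pairs <- self_overlap_pairs(win[pos_idx, ])
      pos_idx[unique(c(pairs$i, pairs$j))]
    } else {
      # peak-mediated reading: a positive gene is uncertain when one of the
      # peaks in its window also hits another positive gene's window
      pw <- win[pos_idx, ]
      hit_counts <- count_interval_overlaps(peaks, pw)
      shared <- peaks[hit_counts >= 2, , drop = FALSE]
      pos_idx[count_interval_overlaps(pw, shared) >= 1]
    }
    status[uncertain] <- "uncertain_proximity"
  }

  tibble::tibble(
    gene_id = genes$gene_id,
    class_label = genes$class_label,
    chrom = win$chrom,
    window_start = win$start,
    window_end = win$end,
    status = status,
    n_overlapping_peaks = n_peaks
  )
}

#' Per-class R-loop status proportions
#'
#' For each gene class, the fraction of genes called positive (overlap an
#' R-loop peak and no other positive gene), uncertain_proximity (overlap
#' peaks shared with neighbouring positive genes) and negative.
#'
#' @param calls output of [classify_rloop()] (carries `class_label`).
#' @param classes classes to report; defaults to those present. A requested
#'   class with no genes is an error.
#' @return Tibble `class_label`, `n_genes`, `prop_positive`,
#'   `prop_uncertain`, `prop_negative` (rows sum to 1).
#' @export
group_proportions <- function(calls, classes = NULL) {
  if (is.null(classes)) classes <- unique(calls$class_label)
  missing <- setdiff(classes, calls$class_label)
  if (length(missing)) {
    stop("no genes in class: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  calls |>
    dplyr::filter(.data$class_label %in% classes) |>
    dplyr::group_by(class_label = factor(.data$class_label, levels = classes)) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      prop_positive = mean(.data$status == "positive"),
      prop_uncertain = mean(.data$status == "uncertain_proximity"),
      prop_negative = mean(.data$status == "negative"),
      .groups = "drop"
    ) |>
    dplyr::mutate(class_label = as.character(.data$class_label))
}
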