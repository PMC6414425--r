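#' Meta-profile matrix in fixed-width bins around TSS or TES
#'
#' Average coverage in non-overlapping `bin_bp` windows across a region of
#' `flank_bp` either side of each gene's anchor (TSS or TES). Minus-strand
#' rows are flipped so that columns always read 5' to 3' (upstream of the
#' anchor first). Bins extending beyond the chromosome start (or past
#' `chrom_sizes` when given) are set to 0 and masked.
#'
#' @param track a [signal_track()].
#' @param genes gene tibble ([as_gene_table()]).
#' @param anchor `"tss"` or `"tes"`.
#' @param flank_bp half-width of the profiled region (multiple of
#'   `bin_bp`; default 2000).
#' @param bin_bp bin width in bases (default 10).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   right-edge masking.
#' @return A `profile_matrix` object: list with `matrix` (genes x bins,
#'   mean coverage per bin), logical `mask` (TRUE where the bin lies inside
#'   the chromosome), `bin_mid` (bin midpoints relative to the anchor, 5'
#'   to 3'), `anchor`, `bin_bp`, `flank_bp` and `gene_id`.
#' @export
profile_matrix <- function(track, genes, anchor = c("tss", "tes"),
                           flank_bp = 2000, bin_bp = 10,
                           chrom_sizes = NULL) {
  anchor <- match.arg(anchor)
  if (flank_bp %% bin_bp != 0) {
    stop("flank_bp must be a multiple of bin_bp", call. = FALSE)
  }
  n_bins <- as.integer(2 * flank_bp / bin_bp)
  centre <- if (anchor == "tss") genes$tss else genes$tes
  # genomic bin edges left->right, one row per gene
  offs <- seq.int(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  m <- matrix(0, nrow = nrow(genes), ncol = n_bins)
  mask <- matrix(TRUE, nrow = nrow(genes), ncol = n_bins)
  for (b in seq_len(n_bins)) {
    s <- centre + offs[b]
    e <- s + bin_bp
    inside <- s >= 0
    if (!is.null(chrom_sizes)) {
      lim <- unname(chrom_sizes[genes$chrom])
      inside <- inside & e <= lim & !is.na(lim)
    }
    if (any(inside)) {
      q <- tibble::tibble(chrom = genes$chrom[inside],
                          start = s[inside], end = e[inside])
      m[inside, b] <- track_integral(track, q) / bin_bp
    }
    mask[, b] <- inside
  }
  flip <- genes$strand == "-"
  if (any(flip)) {
    m[flip, ] <- m[flip, n_bins:1, drop = FALSE]
    mask[flip, ] <- mask[flip, n_bins:1, drop = FALSE]
  }
  structure(
    list(
      matrix = m, mask = mask,
      bin_mid = offs + bin_bp / 2,
      anchor = anchor, bin_bp = bin_bp, flank_bp = flank_bp,
      gene_id = genes$gene_id, class_label = genes$class_label
    ),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "bins of", x$bin_bp, "bp around", toupper(x$anchor), "\n")
  invisible(x)
}

#' Average meta-profile
#'
#' Column means of a [profile_matrix()] over unmasked entries.
#'
#' @param m a `profile_matrix`.
#' @return Tibble `position` (bin midpoint relative to the anchor, 5'->3'),
#'   `mean_coverage`, `n_genes` (unmasked genes per bin).
#' @export
average_profile <- function(m) {
  sums <- colSums(m$matrix * m$mask)
  ns <- colSums(m$mask)
  tibble::tibble(
    position = m$bin_mid,
    mean_coverage = ifelse(ns > 0, sums / ns, NA_real_),
    n_genes = as.integer(ns)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy profile_matrix
#' @export
tidy.profile_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(x$gene_id, times = ncol(x$matrix)),
    class_label = rep(x$class_label, times = ncol(x$matrix)),
    position = rep(x$bin_mid, each = nrow(x$matrix)),
    coverage = as.vector(x$matrix),
    masked = !as.vector(x$mask)
  )
}

#' @method glance profile_matrix
#' @export
glance.profile_matrix <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$matrix),
    n_bins = ncol(x$matrix),
    bin_bp = x$bin_bp,
    flank_bp = x$flank_bp,
    anchor = x$anchor,
    mean_coverage = mean(x$matrix[x$mask])
  )
}
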