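#' Sense-strand nascent-RNA RPKM per gene
#'
#' For each gene, integrates coverage of the sense-strand run-on track over
#' TSS-TES, converts the integral to read equivalents, and normalizes per
#' kilobase of gene length per million mapped reads (both strands). Genes
#' with RPKM strictly greater than `threshold` are called nascent-positive.
#'
#' @param genes gene tibble ([as_gene_table()]).
#' @param track_plus,track_minus stranded [signal_track()]s (`+` and `-`).
#' @param threshold RPKM positivity cutoff; strictly greater-than
#'   (default 0.1).
#' @param read_length bases per read, to convert coverage integrals to read
#'   counts; default taken from the tracks' `read_length` attribute.
#' @return Tibble `gene_id`, `class_label`, `sense_reads`, `length_kb`,
#'   `library_millions`, `rpkm`, `nascent_positive`.
#' @export
nascent_rpkm <- function(genes, track_plus, track_minus, threshold = 0.1,
                         read_length = NULL) {
  if (!identical(attr(track_plus, "strand"), "+") ||
      !identical(attr(track_minus, "strand"), "-")) {
    stop("track_plus/track_minus must be '+' and '-' stranded signal tracks",
         call. = FALSE)
  }
  if (is.null(read_length)) {
    read_length <- attr(track_plus, "read_length") %||% 1
  }
  lib <- attr(track_plus, "total_mapped") + attr(track_minus, "total_mapped")
  if (lib <= 0) stop("zero library size: no mapped reads", call. = FALSE)
  body <- tibble::tibble(chrom = genes$chrom,
                         start = pmin(genes$tss, genes$tes),
                         end = pmax(genes$tss, genes$tes))
  int_plus <- track_integral(track_plus, body)
  int_minus <- track_integral(track_minus, body)
  sense <- ifelse(genes$strand == "+", int_plus, int_minus) / read_length
  length_kb <- (body$end - body$start) / 1000
  lib_m <- lib / 1e6
  rpkm <- sense / (length_kb * lib_m)
  tibble::tibble(
    gene_id = genes$gene_id,
    class_label = genes$class_label,
    sense_reads = sense,
    length_kb = length_kb,
    library_millions = lib_m,
    rpkm = rpkm,
    nascent_positive = rpkm > threshold
  )
}

#' Top / bottom expression rank classes
#'
#' Splits an eligible gene set (typically genes negative for Polycomb
#' marks) into the most-active and least-active `fraction` by expression.
#' Each set has `floor(fraction * n)` genes; ties are broken by ascending
#' `gene_id` so the split is deterministic.
#'
#' @param expr tibble with columns `gene_id` and the expression value named
#'   by `value`.
#' @param fraction proportion in each tail (default 0.15; must be in
#'   (0, 0.5)).
#' @param value name of the expression column (default `"rpkm"`).
#' @return Tibble `gene_id`, value column, `rank_class`
#'   (`"top"` / `"bottom"`), one row per selected gene.
#' @export
expression_rank_classes <- function(expr, fraction = 0.15, value = "rpkm") {
  if (!(fraction > 0 && fraction < 0.5)) {
    stop("fraction must be in (0, 0.5)", call. = FALSE)
  }
  if (nrow(expr) == 0L) stop("eligible gene set is empty", call. = FALSE)
  v <- expr[[value]]
  n <- nrow(expr)
  k <- floor(fraction * n)
  ord <- order(v, expr$gene_id)  # ascending value, gene_id tie-break
  bottom <- ord[seq_len(k)]
  top <- ord[seq.int(n - k + 1, length.out = k)]  # disjoint: 2k < n
  out <- tibble::tibble(
    gene_id = expr$gene_id[c(top, bottom)],
    value = v[c(top, bottom)],
    rank_class = rep(c("top", "bottom"), each = k)
  )
  names(out)[2] <- value
  out
}

#' R-loop x nascent-RNA intersection counts
#'
#' Cross-tabulates R-loop status against nascent-RNA positivity within one
#' gene class (default the Polycomb-repressed genes), mirroring the
#' question of how many repressed genes give rise to both nascent RNA and
#' R-loops. Genes called `uncertain_proximity` are excluded by default.
#'
#' @param calls output of [classify_rloop()].
#' @param expr output of [nascent_rpkm()].
#' @param class gene class to restrict to (default `"pcg_repressed"`).
#' @param drop_uncertain exclude uncertain_proximity genes entirely
#'   (default `TRUE`); when `FALSE` they count as R-loop positive.
#' @return One-row tibble with counts `n_both`, `n_nascent_only`,
#'   `n_rloop_only`, `n_neither`, `n_genes`, and percentages `pct_nascent`
#'   (nascent-positive among all genes considered) and
#'   `pct_rloop_of_nascent` (R-loop positive among nascent-positive; `NaN`
#'   with a warning when no gene is nascent-positive).
#' @export
intersection_counts <- function(calls, expr, class = "pcg_repressed",
                                drop_uncertain = TRUE) {
  joined <- dplyr::inner_join(
    calls[c("gene_id", "class_label", "status")],
    expr[c("gene_id", "nascent_positive")],
    by = "gene_id"
  ) |>
    dplyr::filter(.data$class_label == class)
  if (drop_uncertain) {
    joined <- dplyr::filter(joined, .data$status != "uncertain_proximity")
  }
  rl <- joined$status != "negative"
  na <- joined$nascent_positive
  n_both <- sum(rl & na)
  n_nascent <- sum(na)
  pct_rloop_of_nascent <- if (n_nascent == 0) {
    warning("no nascent-positive genes in class '", class,
            "'; pct_rloop_of_nascent is NaN", call. = FALSE)
    NaN
  } else {
    100 * n_both / n_nascent
  }
  tibble::tibble(
    class_label = class,
    n_both = n_both,
    n_nascent_only = sum(!rl & na),
    n_rloop_only = sum(rl & !na),
    n_neither = sum(!rl & !na),
    n_genes = nrow(joined),
    pct_nascent = 100 * n_nascent / nrow(joined),
    pct_rloop_of_nascent = pct_rloop_of_nascent
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
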