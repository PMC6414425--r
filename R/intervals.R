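#' Genomic interval tibbles
#'
#' All coordinates in rloopr are 0-based, half-open `[start, end)` — the BED
#' convention — on named sequences. An interval table is an ordinary tibble
#' with columns `chrom` (character), `start`, `end` (integer-valued doubles
#' or integers) and optionally `strand` (one of `"+"`, `"-"`, `"*"`).
#'
#' @param chrom character vector of sequence names.
#' @param start,end 0-based half-open bounds; `0 <= start < end`.
#' @param strand strand per interval; `"*"` means unstranded.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  tbl <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand)
  )
  validate_intervals(tbl)
  tbl
}

# shared invariant checks; `what` names the offending table in messages
validate_intervals <- function(tbl, what = "interval table") {
  if (!all(c("chrom", "start", "end") %in% names(tbl))) {
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  }
  if (any(is.na(tbl$chrom) | !nzchar(tbl$chrom))) {
    stop(what, ": chrom must be non-empty", call. = FALSE)
  }
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad)) {
    stop(
      what, ": invalid coordinates (need 0 <= start < end) at row ",
      bad[1], ": ", tbl$chrom[bad[1]], ":", tbl$start[bad[1]], "-",
      tbl$end[bad[1]],
      call. = FALSE
    )
  }
  if ("strand" %in% names(tbl) && !all(tbl$strand %in% c("+", "-", "*"))) {
    stop(what, ": strand must be one of '+', '-', '*'", call. = FALSE)
  }
  invisible(tbl)
}

# IRanges view of a 0-based half-open interval tibble (1-based closed)
as_iranges0 <- function(tbl) {
  IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
}

#' Count overlaps between two interval tables
#'
#' Overlap means at least one shared base; strand is ignored (DRIP peaks are
#' unstranded). Backed by [IRanges::countOverlaps()] per chromosome.
#'
#' @param query,subject interval tibbles (see [genomic_intervals()]).
#' @return Integer vector, one count per `query` row.
#' @export
count_interval_overlaps <- function(query, subject) {
  validate_intervals(query, "query")
  validate_intervals(subject, "subject")
  out <- integer(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(out)
  }
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (!length(si)) next
    out[qi] <- IRanges::countOverlaps(
      as_iranges0(query[qi, ]),
      as_iranges0(subject[si, ])
    )
  }
  out
}

#' Pairs of mutually overlapping intervals within one table
#'
#' Self-overlap pairs (i, j), i < j, sharing at least one base on the same
#' chromosome. Used for the proximity rule between R-loop-positive gene
#' windows.
#'
#' @param tbl interval tibble.
#' @return Tibble with integer columns `i`, `j` (row indices into `tbl`).
#' @export
self_overlap_pairs <- function(tbl) {
  validate_intervals(tbl)
  if (nrow(tbl) < 2L) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  res <- list()
  for (chr in unique(tbl$chrom)) {
    idx <- which(tbl$chrom == chr)
    if (length(idx) < 2L) next
    hits <- IRanges::findOverlaps(as_iranges0(tbl[idx, ]), drop.self = TRUE,
                                  drop.redundant = TRUE)
    if (length(hits)) {
      res[[chr]] <- tibble::tibble(
        i = idx[S4Vectors_from(hits)],
        j = idx[S4Vectors_to(hits)]
      )
    }
  }
  if (!length(res)) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  out <- dplyr::bind_rows(res)
  tibble::tibble(i = pmin(out$i, out$j), j = pmax(out$i, out$j))
}

# thin indirection so IRanges' S4Vectors accessors are the only S4 touchpoint
S4Vectors_from <- function(h) IRanges::from(h)
S4Vectors_to <- function(h) IRanges::to(h)
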