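#' Integrate coverage over query intervals
#'
#' For a piecewise-constant [signal_track()], returns for each query
#' interval the integral of coverage (value x bases) over `[start, end)`.
#' Runs in O((runs + queries) log runs) via cumulative integrals.
#'
#' @param track a `signal_track`.
#' @param query interval tibble (`chrom`, `start`, `end`).
#' @return Numeric vector of integrals, one per query row.
#' @export
track_integral <- function(track, query) {
  validate_intervals(query, "query")
  out <- numeric(nrow(query))
  if (nrow(track) == 0L || nrow(query) == 0L) return(out)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    ti <- which(track$chrom == chr)
    if (!length(ti)) next
    s <- track$start[ti]
    e <- track$end[ti]
    v <- track$value[ti]
    cum <- c(0, cumsum(v * (e - s)))
    ff <- function(x) {
      i <- findInterval(x, s)
      val <- cum[i + 1]
      inside <- i >= 1
      ii <- i[inside]
      # subtract the part of run ii beyond x
      val[inside] <- val[inside] - v[ii] * pmax(0, e[ii] - pmax(x[inside], s[ii]))
      val
    }
    out[qi] <- ff(query$end[qi]) - ff(query$start[qi])
  }
  out
}

#' Mean coverage over query intervals
#'
#' @inheritParams track_integral
#' @return Numeric vector: integral divided by interval width.
#' @export
track_mean <- function(track, query) {
  track_integral(track, query) / (query$end - query$start)
}

#' Build a signal track from read intervals
#'
#' Stacks reads into per-base coverage ([IRanges::coverage()]) and returns
#' the run-length encoding as a `signal_track`. `total_mapped` is the
#' number of reads.
#'
#' @param reads interval tibble, one row per read.
#' @param strand strand label stored on the track.
#' @param read_length bases per read recorded on the track (used to convert
#'   coverage integrals back to read equivalents).
#' @return A `signal_track`.
#' @export
coverage_track <- function(reads, strand = "*",
                           read_length = if (nrow(reads)) {
                             stats::median(reads$end - reads$start)
                           } else 1) {
  pieces <- list()
  for (chr in unique(reads$chrom)) {
    ri <- which(reads$chrom == chr)
    cov <- IRanges::coverage(as_iranges0(reads[ri, ]))
    ends <- cumsum(S4Vectors::runLength(cov))
    starts <- c(0, ends[-length(ends)])
    vals <- as.numeric(S4Vectors::runValue(cov))
    keep <- vals > 0
    pieces[[chr]] <- tibble::tibble(
      chrom = chr, start = starts[keep], end = ends[keep], value = vals[keep]
    )
  }
  tbl <- if (length(pieces)) dplyr::bind_rows(pieces) else {
    tibble::tibble(chrom = character(), start = numeric(),
                   end = numeric(), value = numeric())
  }
  signal_track(tbl, strand = strand, total_mapped = nrow(reads),
               read_length = read_length)
}
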