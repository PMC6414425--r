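# Brute-force oracles, independent of the package's interval machinery.

# O(n*m) overlap count on 0-based half-open intervals
brute_count_overlaps <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, integer(1))
}

# nearest-rank percentile of a count multiset: ceil(p * n)-th order statistic
brute_nearest_rank <- function(counts, p = 0.95) {
  sorted <- sort(counts)
  max(1, sorted[ceiling(p * length(sorted))])
}

# per-base coverage integral over [a, b) from a run tibble
brute_track_integral <- function(track, chrom, a, b) {
  rows <- track[track$chrom == chrom, ]
  if (!nrow(rows)) return(0)
  sum(vapply(seq_len(nrow(rows)), function(i) {
    rows$value[i] * max(0, min(b, rows$end[i]) - max(a, rows$start[i]))
  }, numeric(1)))
}

# random interval tibble on a couple of chromosomes
random_intervals <- function(n, max_pos = 10000, max_len = 500,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE),
    strand = "*"
  )
}

# read collection with prescribed per-signature copy counts
reads_with_counts <- function(counts, chrom = "chr1", spike = FALSE) {
  start <- seq_along(counts) * 1000
  base <- tibble::tibble(
    chrom = if (spike) "spike_1" else chrom,
    start = start, end = start + 50, strand = "+"
  )
  rloopr::read_collection(base[rep.int(seq_along(counts), counts), ])
}

# tiny deterministic gene table
toy_genes <- function() {
  rloopr::as_gene_table(tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(5000, 20000, 40000),
    end = c(8000, 26000, 43000),
    strand = c("+", "-", "+"),
    class_label = c("pcg_repressed", "active_top", "inactive_bottom")
  ))
}

# constant-coverage track over one interval
flat_track <- function(chrom = "chr1", start = 0, end = 1e5, value = 1,
                       strand = "*", total_mapped = NULL, read_length = 1) {
  rloopr::signal_track(
    tibble::tibble(chrom = chrom, start = start, end = end, value = value),
    strand = strand, total_mapped = total_mapped, read_length = read_length
  )
}
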