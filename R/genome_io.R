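#' Read a BED file of intervals
#'
#' Parses BED3/BED6 (0-based, half-open). Lines starting with `#`, `track`
#' or `browser` are skipped. Strand is taken from column 6 when present,
#' otherwise intervals are unstranded (`"*"`).
#'
#' @param path path to a BED file.
#' @return Interval tibble with columns `chrom`, `start`, `end`, `strand`,
#'   plus `name` and `score` when the file has six columns.
#' @seealso [write_bed()], [read_bedgraph()]
#' @export
read_bed <- function(path) {
  fields <- read_genomic_lines(path, min_fields = 3, format = "BED")
  n <- length(fields$lines)
  name <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  strand <- rep("*", n)
  has6 <- fields$nf >= 6
  if (n) {
    name[fields$nf >= 4] <- vapply(
      fields$split[fields$nf >= 4], `[[`, "", 4
    )
    score[fields$nf >= 5] <- suppressWarnings(as.numeric(vapply(
      fields$split[fields$nf >= 5], `[[`, "", 5
    )))
    if (any(has6)) {
      s6 <- vapply(fields$split[has6], `[[`, "", 6)
      s6[s6 == "."] <- "*"
      strand[has6] <- s6
    }
  }
  tbl <- tibble::tibble(
    chrom = fields$chrom, start = fields$start, end = fields$end,
    strand = strand, name = name, score = score
  )
  if (all(is.na(tbl$name))) tbl$name <- NULL
  if (all(is.na(tbl$score))) tbl$score <- NULL
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad)) {
    stop(
      "BED '", path, "' line ", fields$lineno[bad[1]],
      ": start must be < end (got ", tbl$start[bad[1]], " >= ",
      tbl$end[bad[1]], ")",
      call. = FALSE
    )
  }
  validate_intervals(tbl, what = paste0("BED '", path, "'"))
  tbl
}

#' Write intervals as BED
#'
#' @param x interval tibble; optional `name` and `score` columns become BED
#'   columns 4-5 (with strand as column 6).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  nm <- x[["name"]]
  sc <- x[["score"]]
  st <- x[["strand"]]
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  if (!is.null(st) && any(st != "*")) {
    cols <- c(cols, list(
      nm %||% rep(".", nrow(x)),
      sc %||% rep(0, nrow(x)),
      ifelse(st == "*", ".", st)
    ))
  } else if (!is.null(nm)) {
    cols <- c(cols, list(nm))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a gene annotation table
#'
#' Tab-separated table with columns `gene_id`, `chrom`, `start`, `end`,
#' `strand`, `class_label`. The TSS is the 5' end of the gene: `start` for
#' `+` genes and `end` (the exclusive bound, i.e. the biological 5' base
#' boundary in half-open coordinates) for `-` genes; the TES is the opposite
#' end. Allowed class labels are `pcg_repressed`, `active_top`,
#' `inactive_bottom` and `other`.
#'
#' @param path path to the TSV.
#' @return Gene tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `class_label`, `tss`, `tes`.
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      gene_id = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      strand = readr::col_character(),
      class_label = readr::col_character()
    ),
    progress = FALSE
  )
  as_gene_table(tbl)
}

#' Validate a gene data frame and derive TSS/TES
#'
#' @param tbl data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `class_label`.
#' @return Gene tibble (see [read_gene_table()]).
#' @export
as_gene_table <- function(tbl) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "class_label")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("gene table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!all(tbl$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  bad <- setdiff(unique(tbl$class_label), gene_class_levels())
  if (length(bad)) {
    stop(
      "unknown class_label: ", paste(bad, collapse = ", "),
      " (allowed: ", paste(gene_class_levels(), collapse = ", "), ")",
      call. = FALSE
    )
  }
  validate_intervals(tbl, "gene table")
  tbl$tss <- ifelse(tbl$strand == "+", tbl$start, tbl$end)
  tbl$tes <- ifelse(tbl$strand == "+", tbl$end, tbl$start)
  tbl
}

#' Allowed gene class labels
#'
#' `pcg_repressed` (Polycomb-marked, poised), `active_top` (top of the
#' expression ranking), `inactive_bottom` (bottom of the ranking, not
#' Polycomb-silenced) and `other`.
#'
#' @return Character vector of labels.
#' @export
gene_class_levels <- function() {
  c("pcg_repressed", "active_top", "inactive_bottom", "other")
}

#' Write a gene table as TSV
#'
#' @param genes gene tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(
    genes[c("gene_id", "chrom", "start", "end", "strand", "class_label")],
    path
  )
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Four-column bedGraph giving piecewise-constant coverage. Intervals are
#' sorted on read; overlapping intervals or negative values are rejected.
#'
#' @param path path to the bedGraph file.
#' @param strand strand the track measures: `"+"`, `"-"` or `"*"`.
#' @param total_mapped total mapped reads the track derives from, used as
#'   the RPKM library size. Defaults to the track's coverage integral
#'   divided by `read_length`.
#' @param read_length bases per read, used to convert the coverage integral
#'   into read equivalents when `total_mapped` is not given.
#' @return A `signal_track`: a tibble (`chrom`, `start`, `end`, `value`)
#'   with attributes `strand`, `total_mapped` and `read_length`.
#' @export
read_bedgraph <- function(path, strand = "*", total_mapped = NULL,
                          read_length = 1) {
  stopifnot(strand %in% c("+", "-", "*"))
  fields <- read_genomic_lines(path, min_fields = 4, format = "bedGraph")
  value <- suppressWarnings(as.numeric(vapply(fields$split, `[[`, "", 4)))
  bad <- which(is.na(value))
  if (length(bad)) {
    stop("bedGraph '", path, "' line ", fields$lineno[bad[1]],
         ": non-numeric value", call. = FALSE)
  }
  bad <- which(value < 0)
  if (length(bad)) {
    stop("bedGraph '", path, "' line ", fields$lineno[bad[1]],
         ": negative coverage value ", value[bad[1]], call. = FALSE)
  }
  tbl <- tibble::tibble(
    chrom = fields$chrom, start = fields$start, end = fields$end,
    value = value
  )
  signal_track(tbl, strand = strand, total_mapped = total_mapped,
               read_length = read_length)
}

#' Construct a signal track from a coverage tibble
#'
#' @param tbl tibble with columns `chrom`, `start`, `end`, `value`
#'   (non-negative piecewise-constant coverage, 0-based half-open).
#' @inheritParams read_bedgraph
#' @return A `signal_track` tibble; intervals sorted, non-overlapping.
#' @export
signal_track <- function(tbl, strand = "*", total_mapped = NULL,
                         read_length = 1) {
  stopifnot(strand %in% c("+", "-", "*"))
  tbl <- tibble::as_tibble(tbl)[c("chrom", "start", "end", "value")]
  validate_intervals(tbl, "signal track")
  if (any(tbl$value < 0)) stop("signal track values must be >= 0",
                               call. = FALSE)
  tbl <- dplyr::arrange(tbl, .data$chrom, .data$start)
  ovl <- tbl$chrom[-1] == tbl$chrom[-nrow(tbl)] &
    tbl$start[-1] < tbl$end[-nrow(tbl)]
  if (nrow(tbl) > 1 && any(ovl)) {
    k <- which(ovl)[1]
    stop(
      "signal track has overlapping intervals: ", tbl$chrom[k], ":",
      tbl$start[k], "-", tbl$end[k], " and ", tbl$chrom[k + 1], ":",
      tbl$start[k + 1], "-", tbl$end[k + 1],
      call. = FALSE
    )
  }
  if (is.null(total_mapped)) {
    total_mapped <- sum((tbl$end - tbl$start) * tbl$value) / read_length
  }
  structure(
    tbl,
    strand = strand,
    total_mapped = total_mapped,
    read_length = read_length,
    class = c("signal_track", class(tbl))
  )
}

#' Write a signal track as bedGraph
#'
#' Zero-coverage runs are omitted.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  keep <- track$value != 0
  writeLines(
    paste(track$chrom[keep], format_coord(track$start[keep]),
          format_coord(track$end[keep]),
          format(track$value[keep], scientific = FALSE, trim = TRUE),
          sep = "\t"),
    path
  )
  invisible(path)
}

#' Read gene features from a GTF file
#'
#' Only `gene` feature rows are used. GTF's 1-based inclusive coordinates
#' are converted to the package's 0-based half-open convention on read.
#' Class labels come from a separate table (see [read_gene_table()]) or the
#' optional `classes` argument keyed by `gene_id`.
#'
#' @param path path to the GTF.
#' @param classes optional tibble (`gene_id`, `class_label`); genes absent
#'   from it get class `other`.
#' @return Gene tibble (see [read_gene_table()]).
#' @export
read_gtf_genes <- function(path, classes = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  split <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(split, function(f) length(f) >= 9 && f[3] == "gene",
                 logical(1))
  split <- split[keep]
  if (!length(split)) {
    stop("no gene features in GTF '", path, "'", call. = FALSE)
  }
  attr9 <- vapply(split, `[[`, "", 9)
  m <- regmatches(attr9, regexpr('gene_id "[^"]+"', attr9))
  if (length(m) != length(attr9)) {
    stop("GTF '", path, "': gene feature without gene_id attribute",
         call. = FALSE)
  }
  gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  tbl <- tibble::tibble(
    gene_id = gene_id,
    chrom = vapply(split, `[[`, "", 1),
    start = as.numeric(vapply(split, `[[`, "", 4)) - 1,  # GTF is 1-based
    end = as.numeric(vapply(split, `[[`, "", 5)),
    strand = vapply(split, `[[`, "", 7),
    class_label = "other"
  )
  if (!is.null(classes)) {
    idx <- match(tbl$gene_id, classes$gene_id)
    tbl$class_label[!is.na(idx)] <- classes$class_label[idx[!is.na(idx)]]
  }
  as_gene_table(tbl)
}

# Shared low-level reader for whitespace-delimited genomic formats.
# Returns split fields plus parsed chrom/start/end and original line numbers.
read_genomic_lines <- function(path, min_fields, format) {
  if (!file.exists(path)) {
    stop(format, " file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_lines(path, progress = FALSE)
  lineno <- seq_along(raw)
  keep <- nzchar(trimws(raw)) & !startsWith(raw, "#") &
    !startsWith(raw, "track") & !startsWith(raw, "browser")
  raw <- raw[keep]
  lineno <- lineno[keep]
  split <- strsplit(trimws(raw), "[ \t]+")
  nf <- lengths(split)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop(format, " '", path, "' line ", lineno[bad[1]], ": expected >= ",
         min_fields, " fields, got ", nf[bad[1]], call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(split, function(f) f[2], "")))
  end <- suppressWarnings(as.numeric(vapply(split, function(f) f[3], "")))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(format, " '", path, "' line ", lineno[bad[1]],
         ": non-numeric coordinates", call. = FALSE)
  }
  list(
    lines = raw, lineno = lineno, split = split, nf = nf,
    chrom = vapply(split, function(f) f[1], ""),
    start = start, end = end
  )
}
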