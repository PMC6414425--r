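#' Percent-of-input quantification from qPCR Ct values
#'
#' Standard adjusted-input delta-Ct with perfect (2.0) amplification
#' efficiency: the input Ct is first corrected for the fraction of
#' chromatin used as input, `ct_adj = ct_input - log2(1 / input_fraction)`,
#' and the immunoprecipitated material is expressed as
#' `100 * 2^(ct_adj - ct_ip)` percent of the (undiluted) input.
#'
#' @param samples tibble with columns `ct_ip`, `ct_input`,
#'   `input_fraction` (in (0, 1]); typically also `target_id`, `condition`,
#'   `replicate` as produced by [simulate_qpcr()] or [read_qpcr_table()].
#' @return The input tibble with a `percent_input` column appended.
#' @export
percent_input <- function(samples) {
  stopifnot(all(c("ct_ip", "ct_input", "input_fraction") %in% names(samples)))
  if (any(!(samples$input_fraction > 0 & samples$input_fraction <= 1))) {
    stop("input_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(samples$ct_ip)) || any(!is.finite(samples$ct_input))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  adj <- samples$ct_input - log2(1 / samples$input_fraction)
  dplyr::mutate(tibble::as_tibble(samples),
                percent_input = 100 * 2^(adj - .data$ct_ip))
}

#' Read a qPCR Ct table
#'
#' TSV with columns `target_id`, `condition`, `replicate`, `ct_ip`,
#' `ct_input`, `input_fraction`.
#'
#' @param path path to the TSV.
#' @return Tibble of qPCR samples.
#' @export
read_qpcr_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      target_id = readr::col_character(),
      condition = readr::col_character(),
      replicate = readr::col_integer(),
      ct_ip = readr::col_double(),
      ct_input = readr::col_double(),
      input_fraction = readr::col_double()
    ),
    progress = FALSE
  )
  tbl
}

#' Replicate summary of percent-input values
#'
#' Mean, sample standard deviation (n - 1 denominator) and replicate count
#' per target and condition — the numbers behind bar plots with SD error
#' bars.
#'
#' @param samples qPCR tibble; `percent_input` is computed when absent.
#' @return Tibble `target_id`, `condition`, `mean_percent`, `sd_percent`,
#'   `n`.
#' @export
condition_summary <- function(samples) {
  if (!"percent_input" %in% names(samples)) {
    samples <- percent_input(samples)
  }
  samples |>
    dplyr::group_by(.data$target_id, .data$condition) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent_input),
      sd_percent = stats::sd(.data$percent_input),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Compare two conditions per amplicon
#'
#' Fold change of mean percent-input (treatment over reference) with a
#' two-tailed unpaired t-test and star annotation, per target.
#'
#' @param samples qPCR tibble; `percent_input` computed when absent.
#' @param reference,treatment condition labels to compare.
#' @param var_equal pooled-variance t (default `TRUE`).
#' @return Tibble `target_id`, `mean_reference`, `mean_treatment`,
#'   `fold_change`, `t`, `p_value`, `stars`, `n_reference`, `n_treatment`.
#' @export
condition_compare <- function(samples, reference, treatment,
                              var_equal = TRUE) {
  if (!"percent_input" %in% names(samples)) {
    samples <- percent_input(samples)
  }
  samples |>
    dplyr::filter(.data$condition %in% c(reference, treatment)) |>
    dplyr::group_by(.data$target_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$percent_input[d$condition == reference]
      b <- d$percent_input[d$condition == treatment]
      if (length(a) < 2 || length(b) < 2) {
        stop("condition_compare: need >= 2 replicates per condition for '",
             key$target_id, "'", call. = FALSE)
      }
      ht <- t_test_two_tailed(b, a, var_equal = var_equal)
      tibble::tibble(
        mean_reference = mean(a),
        mean_treatment = mean(b),
        fold_change = mean(b) / mean(a),
        t = ht$statistic,
        p_value = ht$p_value,
        stars = ht$stars,
        n_reference = length(a),
        n_treatment = length(b)
      )
    }) |>
    dplyr::ungroup()
}
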