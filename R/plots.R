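#' Plot an average meta-profile
#'
#' Mean coverage per 10-bp bin around the anchor, optionally comparing
#' several profile matrices (e.g. conditions).
#'
#' @param object a [profile_matrix()].
#' @param ... further named `profile_matrix` objects to overlay; names
#'   become the legend labels.
#' @return A ggplot object.
#' @method autoplot profile_matrix
#' @export
autoplot.profile_matrix <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "profile_matrix")]
  profs <- c(list(profile = object), extra)
  if (is.null(names(profs)) || any(!nzchar(names(profs)))) {
    names(profs) <- paste0("profile_", seq_along(profs))
  }
  df <- dplyr::bind_rows(lapply(profs, average_profile), .id = "track")
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean_coverage,
                                   colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = paste0("position relative to ", toupper(object$anchor), " (bp)"),
      y = "mean coverage", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Stacked per-class R-loop proportions
#'
#' One bar per gene class split into positive (dark), uncertain-proximity
#' (light) and negative fractions.
#'
#' @param proportions output of [group_proportions()].
#' @return A ggplot object.
#' @export
plot_rloop_proportions <- function(proportions) {
  df <- tidyr::pivot_longer(
    proportions, dplyr::starts_with("prop_"),
    names_to = "status", names_prefix = "prop_", values_to = "proportion"
  )
  df$status <- factor(df$status,
                      levels = c("negative", "uncertain", "positive"))
  ggplot2::ggplot(df, ggplot2::aes(.data$class_label, .data$proportion,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      negative = "grey85", uncertain = "lightsteelblue",
      positive = "steelblue4"
    )) +
    ggplot2::labs(x = NULL, y = "proportion of genes", fill = "R-loop") +
    ggplot2::theme_minimal()
}

#' Boxplot of normalized TSS-window signal by condition
#'
#' @param signal per-gene signal tibble with a `condition` column, as in
#'   the `signal` component of [run_pipeline()] output.
#' @param classes gene classes to show (default all).
#' @return A ggplot object.
#' @export
plot_tss_signal <- function(signal, classes = NULL) {
  if (!is.null(classes)) {
    signal <- dplyr::filter(signal, .data$class_label %in% classes)
  }
  ggplot2::ggplot(signal, ggplot2::aes(.data$class_label,
                                       .data$signal + 1,
                                       fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "normalized TSS signal + 1",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of percent-input qPCR summaries
#'
#' Mean percent input with SD error bars per amplicon and condition.
#'
#' @param summary output of [condition_summary()].
#' @return A ggplot object.
#' @export
plot_percent_input <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$target_id,
                                        .data$mean_percent,
                                        fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent - .data$sd_percent,
                   ymax = .data$mean_percent + .data$sd_percent),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "% of input", fill = NULL) +
    ggplot2::theme_minimal()
}
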