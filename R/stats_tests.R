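#' Wilcoxon rank-sum test (two-sided)
#'
#' Rank-sum statistic `W` = sum of the (mid)ranks of `x` in the pooled
#' sample. The two-sided p-value is computed by exact enumeration of all
#' `choose(n + m, n)` rank assignments when `n + m <= 12` and there are no
#' ties, and by the normal approximation with tie correction and a 0.5
#' continuity correction otherwise.
#'
#' @param x,y numeric samples (each non-empty).
#' @return An `rloopr_htest` object (statistic, p_value, method, stars).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("wilcoxon_rank_sum: both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && n <= 12) {
    subsets <- utils::combn(n, n1)
    sums <- colSums(matrix(as.numeric(subsets), nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu))
    method <- "Wilcoxon rank-sum (exact enumeration)"
  } else {
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / ((n) * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "Wilcoxon rank-sum (normal approximation, tie + continuity correction)"
  }
  new_htest(statistic = w, statistic_name = "W", p_value = p,
            method = method, n = c(n_x = n1, n_y = n2))
}

#' Two-tailed unpaired t-test
#'
#' Pooled-variance (Student) two-sample t statistic by default; Welch's
#' unequal-variance form with `var_equal = FALSE`.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param var_equal pool the variances (default `TRUE`).
#' @return An `rloopr_htest` object (statistic `t`, `df`, p_value, stars).
#' @export
t_test_two_tailed <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("t_test_two_tailed: need at least 2 values per sample",
         call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) {
      stop("zero pooled variance: t statistic undefined", call. = FALSE)
    }
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    if (v1 <= 0 && v2 <= 0) {
      stop("zero variance in both samples: t statistic undefined",
           call. = FALSE)
    }
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mean(x) - mean(y)) / se
  p <- 2 * stats::pt(-abs(t), df)
  new_htest(statistic = t, statistic_name = "t", p_value = p,
            method = if (var_equal) "Two-tailed unpaired t-test (pooled variance)" else
              "Two-tailed unpaired t-test (Welch)",
            df = df, n = c(n_x = n1, n_y = n2))
}

#' Significance stars
#'
#' The figure-legend convention: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @param alpha the three descending thresholds.
#' @return Character vector of annotations.
#' @export
p_stars <- function(p, alpha = c(0.05, 0.01, 0.001)) {
  alpha <- sort(alpha, decreasing = TRUE)
  out <- rep("ns", length(p))
  out[p < alpha[1]] <- "*"
  out[p < alpha[2]] <- "**"
  out[p < alpha[3]] <- "***"
  out
}

new_htest <- function(statistic, statistic_name, p_value, method,
                      df = NULL, n = NULL) {
  structure(
    list(statistic = statistic, statistic_name = statistic_name,
         p_value = p_value, stars = p_stars(p_value), method = method,
         df = df, n = n),
    class = "rloopr_htest"
  )
}

#' @export
print.rloopr_htest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("%s = %.6g", x$statistic_name, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(sprintf(", p = %.4g (%s)\n", x$p_value, x$stars))
  invisible(x)
}

#' @method tidy rloopr_htest
#' @export
tidy.rloopr_htest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    stars = x$stars,
    method = x$method
  )
}

#' @method glance rloopr_htest
#' @export
glance.rloopr_htest <- function(x, ...) tidy(x)
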