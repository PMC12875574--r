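#' Mann-Whitney U test (two-sided)
#'
#' Nonparametric two-group comparison. For combined sample sizes of at
#' most 20 without ties the exact permutation null distribution of U is
#' used (via the exact Wilcoxon distribution, which coincides with full
#' permutation enumeration in the absence of ties); otherwise the normal
#' approximation with tie and continuity correction. The reported U is
#' `min(U_x, U_y)`, the classical tabled convention.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return List with `U`, `U_x`, `U_y`, `p_value` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value  # exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  if (length(unique(comb)) == 1L) {
    # all observations identical: no evidence of any difference
    return(list(U = n1 * n2 / 2, U_x = n1 * n2 / 2, U_y = n1 * n2 / 2,
                p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(comb) > 0L
  exact <- (n1 + n2) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  u_x <- unname(wt$statistic)
  u_y <- n1 * n2 - u_x
  list(U = min(u_x, u_y), U_x = u_x, U_y = u_y,
       p_value = min(wt$p.value, 1),
       method = if (exact) "exact" else "normal approximation")
}

#' Percentage change relative to a reference mean
#'
#' `100 * (reference - other) / reference`: positive values are decreases
#' relative to the reference group, the convention used when reporting
#' age-related declines (e.g. a density drop from 100 to 61.97 is
#' +38.03%).
#'
#' @param mean_reference Reference group mean (nonzero).
#' @param mean_other Comparison group mean.
#' @return Percentage change (positive = decrease).
#' @examples
#' percent_change(10, 5)  # 50
#' @export
percent_change <- function(mean_reference, mean_other) {
  if (mean_reference == 0) {
    stop("percent change is undefined for a zero reference mean",
         call. = FALSE)
  }
  100 * (mean_reference - mean_other) / mean_reference
}

#' Significance stars
#'
#' `****` for p < 0.0001, `*` for p < 0.05, `n.s.` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 0.05, "*", "n.s."))
}

#' Compare connectomics metrics between two cohorts
#'
#' For each requested metric, runs a two-sided Mann-Whitney U test on the
#' per-image values of the two groups and reports means, SDs, the U
#' statistic, p-value, significance at `alpha`, and the percentage change
#' of group B relative to group A. No multiple-testing correction is
#' applied by default (each metric is reported on its own); Holm
#' adjustment is available.
#'
#' @param metrics_a,metrics_b Lists of `connectomics_metrics` (or data
#'   frames with one row per image), at least 2 images per group.
#' @param metric_names Metrics to compare (default: all six).
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A `group_comparison` data frame with one row per metric:
#'   `metric`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `u_statistic`,
#'   `p_value`, `significant`, `stars`, `percent_change`.
#' @export
compare_cohorts <- function(metrics_a, metrics_b, metric_names = NULL,
                            alpha = 0.05,
                            p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  df_a <- metrics_to_df(metrics_a)
  df_b <- metrics_to_df(metrics_b)
  if (nrow(df_a) < 2L || nrow(df_b) < 2L) {
    stop("need at least 2 images per group", call. = FALSE)
  }
  if (is.null(metric_names)) metric_names <- names(df_a)
  missing_m <- setdiff(metric_names, intersect(names(df_a), names(df_b)))
  if (length(missing_m)) {
    stop(sprintf("metric(s) not available in both groups: %s",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(metric_names, function(m) {
    a <- df_a[[m]]; b <- df_b[[m]]
    mw <- mann_whitney_u(a, b)
    pc <- if (mean(a) != 0) percent_change(mean(a), mean(b)) else NA_real_
    data.frame(metric = m, mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               u_statistic = mw$U, p_value = mw$p_value,
               percent_change = pc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < alpha
  out$stars <- significance_stars(out$p_value)
  class(out) <- c("group_comparison", "data.frame")
  out
}

metrics_to_df <- function(metrics) {
  if (is.data.frame(metrics)) return(metrics)
  stopifnot(is.list(metrics))
  do.call(rbind, lapply(metrics, function(m) {
    if (inherits(m, "connectomics_metrics")) as.data.frame(m)
    else as.data.frame(m)
  }))
}
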