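# Velocity-distribution summaries and stage comparisons.
#
# Pooled frame-to-frame velocity vectors are the unit of analysis (not
# per-track means). Bacterial velocity distributions are typically
# non-normal, so stages are compared with the Mann-Whitney U test;
# three goodness-of-fit tests against the normal family justify that
# choice on each data set.

#' Summarize a stage's velocity sample
#'
#' @param velocities numeric vector of individual velocities, um/s.
#' @param label stage label (e.g. "before diauxic shift").
#' @return A `stage_summary`: `label`, `mean_velocity`, `sem`
#'   (sample sd / sqrt(n)), `n_vectors`.
#' @export
summarize_stage <- function(velocities, label = "") {
  if (length(velocities) == 0) stop("empty velocity sample")
  n <- length(velocities)
  structure(list(label = label,
                 mean_velocity = mean(velocities),
                 sem = if (n > 1) stats::sd(velocities) / sqrt(n) else 0,
                 n_vectors = n),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat(sprintf("%s: %.2f +/- %.2f um/s (SEM), n = %d\n",
              if (nzchar(x$label)) x$label else "stage",
              x$mean_velocity, x$sem, x$n_vectors))
  invisible(x)
}

#' Compare two stages by Mann-Whitney U
#'
#' Two-sided rank-sum test. For small samples (combined n <= 20, no
#' ties) the exact null distribution is used; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param v1,v2 non-empty numeric velocity samples.
#' @param labels optional length-2 character vector of stage labels.
#' @return A `stage_comparison`: `labels`, `u_statistic`, `p_value`,
#'   `test`.
#' @export
compare_stages <- function(v1, v2, labels = c("stage 1", "stage 2")) {
  if (length(v1) == 0 || length(v2) == 0)
    stop("both velocity samples must be non-empty")
  ties <- anyDuplicated(c(v1, v2)) > 0
  exact <- (length(v1) + length(v2)) <= 20 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(v1, v2, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(labels = labels,
                 u_statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 test = "mann-whitney-u two-sided"),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: U = %g, p = %.4g (%s)\n", x$labels[1],
              x$labels[2], x$u_statistic, x$p_value, x$test))
  invisible(x)
}

#' Test a velocity sample for normality
#'
#' Runs the Shapiro-Wilk, Anderson-Darling and Cramer-von Mises tests
#' against the composite normal hypothesis (mean and sd estimated from
#' the data). Requires n >= 8: below that the tests are unreliable.
#'
#' @param v numeric vector, length >= 8.
#' @return A named list (`shapiro_wilk`, `anderson_darling`,
#'   `cramer_von_mises`), each a list with `statistic` and `p_value`.
#' @export
normality_tests <- function(v) {
  if (length(v) < 8) stop("normality tests require n >= 8")
  sw <- stats::shapiro.test(v)
  ad <- nortest::ad.test(v)
  cvm <- suppressWarnings(nortest::cvm.test(v))
  list(shapiro_wilk = list(statistic = unname(sw$statistic),
                           p_value = sw$p.value),
       anderson_darling = list(statistic = unname(ad$statistic),
                               p_value = ad$p.value),
       cramer_von_mises = list(statistic = unname(cvm$statistic),
                               p_value = cvm$p.value))
}

#' Histogram of individual velocities
#'
#' Half-open bins `[lo, hi)` of fixed width starting at 0 and covering
#' `max(v)`; a value falling exactly on an edge counts in the upper
#' bin. The default 5 um/s width resolves the typical swimming-speed
#' distributions without emptying most bins.
#'
#' @param v numeric velocities, um/s (>= 0).
#' @param bin_width bin width in um/s (> 0).
#' @return A data frame `bin_lo`, `bin_hi`, `count`; empty input gives
#'   zero rows. `sum(count) == length(v)`.
#' @export
velocity_histogram <- function(v, bin_width = 5) {
  stopifnot(bin_width > 0)
  if (length(v) == 0)
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  stopifnot(all(v >= 0))
  n_bins <- floor(max(v) / bin_width) + 1
  edges <- seq(0, by = bin_width, length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = FALSE)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = as.integer(tabulate(idx, nbins = n_bins)))
}

#' Motile fraction across samples
#'
#' Converts per-sample (motile, total) counts to percentages and
#' reports their unweighted mean and sample standard deviation.
#'
#' @param n_motile,n_total integer vectors of equal length;
#'   `0 <= n_motile <= n_total`, `n_total > 0`.
#' @return A list: `fractions_pct` (per sample), `mean_pct`, `sd_pct`.
#' @export
motile_fraction <- function(n_motile, n_total) {
  stopifnot(length(n_motile) == length(n_total), length(n_total) > 0,
            all(n_total > 0), all(n_motile >= 0),
            all(n_motile <= n_total))
  pct <- 100 * n_motile / n_total
  list(fractions_pct = pct, mean_pct = mean(pct),
       sd_pct = if (length(pct) > 1) stats::sd(pct) else 0)
}
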