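CN_METRICS <- c("pearson", "manhattan", "euclidean", "cosine")

#' Orientation of a similarity metric
#'
#' Pearson correlation and cosine similarity are higher-is-more-similar;
#' Manhattan and Euclidean distance are lower-is-more-similar. The split
#' matters scientifically: the normalized measures (Pearson, cosine) are
#' ploidy agnostic — a whole-genome doubled profile still scores as a
#' perfect match — while the absolute distances are ploidy aware.
#'
#' @param metric One of `"pearson"`, `"manhattan"`, `"euclidean"`,
#'   `"cosine"`.
#' @return `TRUE` if higher scores mean more similar.
#' @export
metric_orientation <- function(metric) {
  metric <- match.arg(metric, CN_METRICS)
  metric %in% c("pearson", "cosine")
}

## pairwise-complete bin values of two profiles on one grid
complete_pairs <- function(a, b) {
  if (!same_grid(a$grid, b$grid))
    stop("profiles are on different bin grids", call. = FALSE)
  ok <- !is.na(a$values) & !is.na(b$values)
  list(x = a$values[ok], y = b$values[ok], n = sum(ok))
}

#' Similarity between two binned copy number profiles
#'
#' Scores a pair of profiles over the bins that are non-missing in both,
#' under one of four metrics: Pearson correlation, Manhattan distance
#' (sum of absolute bin differences), Euclidean distance, or cosine
#' similarity. Missing bins are excluded pairwise; at least two shared
#' bins are required.
#'
#' Pearson on a constant (zero-variance) profile and cosine on an all-zero
#' profile are degenerate and raise an error rather than propagating `NaN`
#' into rankings.
#'
#' @param a,b Two [segments_to_bins()] profiles on the same grid.
#' @param metric Metric name.
#' @return An object of class `cn_similarity`: list with `metric`, `score`,
#'   `n_bins_compared` and `higher_is_better`.
#' @examples
#' grid <- make_bin_grid(c(A = 2e6), 5e5)
#' p <- segments_to_bins(cn_segments("p", "A", 1, 2e6, 2), grid)
#' q <- segments_to_bins(cn_segments("q", c("A", "A"), c(1, 1e6 + 1),
#'                                   c(1e6, 2e6), c(2, 3)), grid)
#' cn_similarity(p, q, "manhattan")$score
#' @export
cn_similarity <- function(a, b, metric = c("pearson", "manhattan",
                                           "euclidean", "cosine")) {
  metric <- match.arg(metric)
  cp <- complete_pairs(a, b)
  if (cp$n < 2L)
    stop("need at least 2 pairwise-complete bins (got ", cp$n, ")",
         call. = FALSE)
  x <- cp$x
  y <- cp$y
  score <- switch(metric,
    pearson = {
      if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("Pearson correlation is undefined for a constant profile ",
             "(zero variance over the compared bins)", call. = FALSE)
      sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    },
    manhattan = sum(abs(x - y)),
    euclidean = sqrt(sum((x - y)^2)),
    cosine = {
      nx <- sqrt(sum(x^2))
      ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0)
        stop("cosine similarity is undefined for an all-zero profile",
             call. = FALSE)
      sum(x * y) / (nx * ny)
    })
  structure(list(metric = metric, score = score, n_bins_compared = cp$n,
                 higher_is_better = metric_orientation(metric)),
            class = "cn_similarity")
}

#' @export
print.cn_similarity <- function(x, ...) {
  cat("<cn_similarity> ", x$metric, " = ", format(x$score, digits = 6),
      " over ", x$n_bins_compared, " bins (",
      if (x$higher_is_better) "higher" else "lower", " = more similar)\n",
      sep = "")
  invisible(x)
}

#' Percentage genome difference between two profiles
#'
#' The fraction (as a percent) of pairwise-complete bins whose copy numbers
#' differ by more than `tolerance` copies. The default tolerance of 0.5
#' copies treats bins as different when they would round to different
#' integer copy number states. The measure is symmetric and lies in
#' \[0, 100\].
#'
#' @param a,b Two profiles on the same grid.
#' @param tolerance Non-negative copy number difference below which bins
#'   count as equal (default 0.5).
#' @return Percent of compared genome bins that differ.
#' @export
pct_genome_difference <- function(a, b, tolerance = 0.5) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("'tolerance' must be a single non-negative number", call. = FALSE)
  cp <- complete_pairs(a, b)
  if (cp$n < 1L)
    stop("no pairwise-complete bins to compare", call. = FALSE)
  100 * sum(abs(cp$x - cp$y) > tolerance) / cp$n
}

#' Empirical p-value of an observed similarity score
#'
#' Given an observed score and a vector of null scores (for instance the
#' query's scores against all other references in a collection), computes
#' the add-one empirical p-value
#' \deqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{null})}
#' with the comparison direction set by the metric's orientation (at least
#' as high for Pearson/cosine, at least as low for Manhattan/Euclidean).
#' Ties with the observed score count as extreme. The result lies in
#' (0, 1] and can never be exactly zero.
#'
#' @param observed A [cn_similarity()] result, or a single numeric score
#'   (in which case `higher_is_better` must be given).
#' @param null_scores Non-empty numeric vector of null scores under the
#'   same metric and orientation.
#' @param higher_is_better Orientation flag; ignored when `observed` is a
#'   `cn_similarity` object.
#' @return Empirical p-value in (0, 1].
#' @examples
#' empirical_pvalue(0.9, c(0.1, 0.2, 0.3), higher_is_better = TRUE)
#' @export
empirical_pvalue <- function(observed, null_scores, higher_is_better = NULL) {
  if (inherits(observed, "cn_similarity")) {
    higher_is_better <- observed$higher_is_better
    observed <- observed$score
  }
  if (is.null(higher_is_better))
    stop("'higher_is_better' is required for a bare numeric score",
         call. = FALSE)
  if (!is.numeric(null_scores) || length(null_scores) == 0L)
    stop("'null_scores' must be a non-empty numeric vector", call. = FALSE)
  extreme <- if (higher_is_better) sum(null_scores >= observed)
             else sum(null_scores <= observed)
  (1 + extreme) / (1 + length(null_scores))
}
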