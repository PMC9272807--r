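#' Rank reference profiles by similarity to a query
#'
#' Scores a query profile against every profile in a reference list under
#' one metric, optionally aligning copy number boundaries pairwise first
#' (see [align_boundaries()]), and returns a ranked match table, best match
#' first. When `with_significance` is set, each reference's score receives
#' an empirical p-value whose null is the query's scores against all the
#' other references ([empirical_pvalue()]). The percentage genome
#' difference to the query is reported for every reference.
#'
#' Ties in score are broken by reference id (lexicographic), making the
#' ranking deterministic.
#'
#' @param query A [segments_to_bins()] profile.
#' @param references Non-empty list of profiles on the query's grid.
#' @param metric Metric name (see [cn_similarity()]).
#' @param with_significance Attach empirical p-values (default `TRUE`;
#'   needs at least 2 references, otherwise `NA`).
#' @param smoothing_window Boundary alignment window in bins passed to
#'   [align_boundaries()]; `0` disables smoothing (default 1).
#' @param tolerance Copy-number tolerance for the percentage genome
#'   difference column (default 0.5).
#' @return A data.frame of class `cn_matchtable` with columns `query`,
#'   `reference`, `metric`, `score`, `rank`, `p_value`, `pct_genome_diff`,
#'   sorted best-first with dense 1-based ranks.
#' @export
rank_matches <- function(query, references,
                         metric = c("pearson", "manhattan", "euclidean",
                                    "cosine"),
                         with_significance = TRUE, smoothing_window = 1,
                         tolerance = 0.5) {
  metric <- match.arg(metric)
  stopifnot(inherits(query, "cn_profile"))
  if (!is.list(references) || length(references) == 0L)
    stop("'references' must be a non-empty list of binned profiles",
         call. = FALSE)
  ids <- vapply(references, function(r) r$sample_id, character(1))
  for (k in seq_along(references)) {
    if (!inherits(references[[k]], "cn_profile"))
      stop("reference ", k, " is not a binned profile", call. = FALSE)
    if (!same_grid(references[[k]]$grid, query$grid))
      stop("reference '", ids[k], "' is on a different bin grid than the ",
           "query", call. = FALSE)
  }
  scores <- numeric(length(references))
  pct <- numeric(length(references))
  for (k in seq_along(references)) {
    pair <- if (smoothing_window > 0)
      align_boundaries(query, references[[k]], smoothing_window)
    else list(a = query, b = references[[k]])
    scores[k] <- cn_similarity(pair$a, pair$b, metric)$score
    pct[k] <- pct_genome_difference(pair$a, pair$b, tolerance)
  }
  higher <- metric_orientation(metric)
  p <- rep(NA_real_, length(references))
  if (isTRUE(with_significance) && length(references) >= 2L) {
    for (k in seq_along(references))
      p[k] <- empirical_pvalue(scores[k], scores[-k],
                               higher_is_better = higher)
  }
  ord <- order(if (higher) -scores else scores, ids)
  out <- data.frame(query = query$sample_id,
                    reference = ids[ord],
                    metric = metric,
                    score = scores[ord],
                    rank = seq_along(ord),
                    p_value = p[ord],
                    pct_genome_diff = pct[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cn_matchtable", "data.frame")
  out
}

#' Best match of a ranked match table
#' @param match A [rank_matches()] table.
#' @return The rank-1 row.
#' @export
top_match <- function(match) {
  stopifnot(inherits(match, "cn_matchtable"))
  match[match$rank == 1L, , drop = FALSE]
}

#' Write a match report CSV
#'
#' Writes the ranked match table as CSV with columns `query`, `reference`,
#' `metric`, `score`, `rank`, `p_value`, `pct_genome_diff`. Leading `#`
#' comment lines echo the configuration used to produce the table, so a
#' report is self-describing; [utils::read.csv()] with `comment.char = "#"`
#' reads it back.
#'
#' @param match A [rank_matches()] table (or several rbind-ed together).
#' @param path Output CSV path.
#' @param config Optional named list echoed in the header.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(match, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    for (nm in names(config))
      writeLines(paste0("# ", nm, "=", format(config[[nm]])), con)
  }
  utils::write.csv(as.data.frame(match), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-bin comparison track of two profiles
#'
#' Builds (and optionally writes as TSV) a per-bin table suitable for
#' genome-browser display: bin coordinates, both profiles' values and a
#' `differs` flag marking bins whose copy numbers differ by more than
#' `tolerance` copies. Bins missing in either profile get `NA` in the flag.
#'
#' @param query,reference Two profiles on one grid.
#' @param tolerance Copy difference threshold (default 0.5).
#' @param path Optional output TSV path.
#' @return The comparison data.frame, invisibly when `path` is given.
#' @export
compare_bins <- function(query, reference, tolerance = 0.5, path = NULL) {
  cp <- complete_pairs(query, reference)  # validates grids
  stopifnot(cp$n >= 1L)
  out <- data.frame(chromosome = query$grid$bins$chrom,
                    start = query$grid$bins$start,
                    end = query$grid$bins$end,
                    query_value = query$values,
                    reference_value = reference$values,
                    differs = abs(query$values - reference$values) > tolerance,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Overlay plot of two binned profiles
#'
#' Draws the query and reference copy number values along the genome with
#' differing bins highlighted, in the style of a profile-overlay figure.
#' Requires ggplot2.
#'
#' @param query,reference Two profiles on one grid.
#' @param tolerance Copy difference threshold for highlighting.
#' @return A ggplot object.
#' @export
plot_profile_overlay <- function(query, reference, tolerance = 0.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_profile_overlay needs the ggplot2 package", call. = FALSE)
  df <- compare_bins(query, reference, tolerance)
  df$bin <- seq_len(nrow(df))
  long <- rbind(
    data.frame(bin = df$bin, chromosome = df$chromosome,
               value = df$query_value, profile = query$sample_id),
    data.frame(bin = df$bin, chromosome = df$chromosome,
               value = df$reference_value, profile = reference$sample_id))
  ggplot2::ggplot(long, ggplot2::aes(x = bin, y = value,
                                     colour = profile)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::geom_point(data = data.frame(bin = df$bin[which(df$differs)]),
                        ggplot2::aes(x = bin), y = -0.25,
                        inherit.aes = FALSE, shape = 15, size = 0.8,
                        colour = "grey40") +
    ggplot2::labs(x = "genome bin", y = "absolute copy number",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
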