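#' Run configuration for the end-to-end workflows
#'
#' Collects and validates the parameters shared by the high-level entry
#' points ([run_match()], [run_signature_cluster()]) and the command-line
#' interface. A bin size below 30 kb triggers a warning: SNP6-derived
#' reference profiles do not support resolution beyond 30 kb.
#'
#' @param genome Named numeric vector of chromosome lengths, or a path to
#'   a UCSC chrom.sizes file, or `NULL` for [hg19_genome()].
#' @param bin_size Bin width in bp (default 500000).
#' @param metric Similarity metric (default `"pearson"`).
#' @param window Boundary smoothing window in bins (default 1).
#' @param tolerance Copy tolerance for percentage genome difference
#'   (default 0.5).
#' @param significance Attach empirical p-values (default `TRUE`).
#' @param seed Integer seed recorded in reports (default 1).
#' @param out Output directory (default `"."`).
#' @return Object of class `cn_config` (a named list).
#' @export
cn_config <- function(genome = NULL, bin_size = 500000,
                      metric = c("pearson", "manhattan", "euclidean",
                                 "cosine"),
                      window = 1, tolerance = 0.5, significance = TRUE,
                      seed = 1, out = ".") {
  metric <- match.arg(metric)
  genome_label <- "hg19"
  if (is.null(genome)) {
    genome <- hg19_genome()
  } else if (is.character(genome) && length(genome) == 1L) {
    if (!file.exists(genome))
      stop("genome file not found: ", genome, call. = FALSE)
    genome_label <- genome
    genome <- read_chrom_sizes(genome)
  } else {
    genome_label <- "custom"
  }
  if (bin_size < 30000)
    warning("bin_size below 30 kb: resolution beyond 30 kb is not ",
            "supported by SNP6-derived reference profiles", call. = FALSE)
  structure(list(genome = genome, genome_label = genome_label,
                 bin_size = bin_size, metric = metric, window = window,
                 tolerance = tolerance, significance = significance,
                 seed = as.integer(seed), out = out),
            class = "cn_config")
}

config_header <- function(config) {
  list(genome = config$genome_label, bin_size = config$bin_size,
       metric = config$metric, window = config$window,
       tolerance = config$tolerance, significance = config$significance,
       seed = config$seed)
}

## load references either from a save_reference() directory or a
## multi-sample segment TSV (binned on the config grid)
load_references_any <- function(path, config) {
  if (dir.exists(path)) return(load_reference(path))
  profiles <- read_segment_table(path)
  if (length(profiles) == 0L)
    stop("empty reference: no profiles in ", path, call. = FALSE)
  grid <- make_bin_grid(config$genome, config$bin_size)
  build_reference(profiles, grid)
}

#' Match one or more query profiles against a reference collection
#'
#' The end-to-end workflow: read the query segment table(s), bin them on
#' the configured grid, align boundaries against each reference, rank the
#' references per query under the configured metric, and write one
#' combined CSV match report (with the full configuration echoed in its
#' header) to `file.path(config$out, "match_report.csv")`. The same
#' configuration and inputs always produce an identical report.
#'
#' @param config A [cn_config()] object.
#' @param query_path Segment table TSV/CSV of the query sample(s).
#' @param reference_path A [save_reference()] directory or a multi-sample
#'   segment TSV.
#' @return The combined match table, invisibly; the report path is in
#'   `attr(, "report")`.
#' @export
run_match <- function(config, query_path, reference_path) {
  stopifnot(inherits(config, "cn_config"))
  queries <- read_segment_table(query_path)
  if (length(queries) == 0L)
    stop("no query profiles in ", query_path, call. = FALSE)
  ref <- load_references_any(reference_path, config)
  grid <- ref$grid
  if (!same_grid(grid, make_bin_grid(config$genome, config$bin_size)))
    message("note: using the reference collection's stored grid (",
            nrow(grid$bins), " bins)")
  tables <- lapply(queries, function(q) {
    qb <- segments_to_bins(q, grid)
    rank_matches(qb, ref$binned, metric = config$metric,
                 with_significance = config$significance,
                 smoothing_window = config$window,
                 tolerance = config$tolerance)
  })
  combined <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(combined) <- NULL
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  report <- file.path(config$out, "match_report.csv")
  write_match_report(combined, report, config = config_header(config))
  class(combined) <- c("cn_matchtable", "data.frame")
  attr(combined, "report") <- report
  invisible(combined)
}

#' Cluster samples by signature exposures and report
#'
#' Reads an exposure matrix, clusters it with seeded k-means, and writes
#' the cluster report, centroid table and top-two-signature scatter
#' export to `config$out` (see [write_cluster_report()]). When `query_id`
#' is given its row is flagged in the report and its cluster returned.
#'
#' @param config A [cn_config()] object.
#' @param exposures_path TSV/CSV exposure matrix path.
#' @param k Number of clusters.
#' @param query_id Optional sample id to locate within the clustering.
#' @return The [cluster_exposures()] assignment, invisibly, with the
#'   query's cluster in `attr(, "query_cluster")` when requested.
#' @export
run_signature_cluster <- function(config, exposures_path, k,
                                  query_id = NULL) {
  stopifnot(inherits(config, "cn_config"))
  exposures <- read_exposures(exposures_path)
  if (!is.null(query_id) && !query_id %in% rownames(exposures))
    stop("query id '", query_id, "' not found in ", exposures_path,
         call. = FALSE)
  assignment <- cluster_exposures(exposures, k, seed = config$seed)
  files <- write_cluster_report(assignment, exposures, config$out,
                                query_id = query_id)
  if (!is.null(query_id))
    attr(assignment, "query_cluster") <-
      unname(assignment$labels[query_id])
  attr(assignment, "files") <- files
  invisible(assignment)
}
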