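#' Read a copy number signature exposure matrix
#'
#' Reads a samples x signatures activity matrix from a delimited file
#' (first column sample id, remaining columns one per signature). Copy
#' number signature exposures quantify how active each mutational process
#' of chromosomal instability is in a sample; each row is a composition
#' summing to 1. Rows whose sum deviates from 1 by at most `1e-3` are
#' renormalized on load; larger deviations are an error. All entries must
#' be non-negative.
#'
#' @param path TSV or CSV path (delimiter sniffed from the header).
#' @return Numeric matrix with sample row names and signature column names.
#' @export
read_exposures <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3L)
    stop("exposure file needs a sample column plus at least 2 signatures",
         call. = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  validate_exposures(m)
}

#' Validate (and renormalize) an exposure matrix
#' @param m Samples x signatures numeric matrix.
#' @return The validated matrix, rows renormalized to sum exactly 1.
#' @export
validate_exposures <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("exposures must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("exposures must be non-negative and finite", call. = FALSE)
  rs <- rowSums(m)
  off <- abs(rs - 1)
  if (any(off > 1e-3)) {
    i <- which(off > 1e-3)[1L]
    stop("exposure row '", rownames(m)[i] %||% i, "' sums to ",
         format(rs[i], digits = 6), ", not 1", call. = FALSE)
  }
  m / rs
}

#' Cosine similarity between two exposure vectors
#'
#' Compares the mutational-process composition of two samples directly:
#' 1 means identical signature mix (up to scale), 0 means disjoint
#' signature activity. For non-negative exposures the value lies in
#' \[0, 1\].
#'
#' @param a,b Numeric exposure vectors of equal length (>= 2), not all
#'   zero.
#' @return Cosine similarity.
#' @examples
#' exposure_cosine(c(0.6, 0.4), c(0.4, 0.6))
#' @export
exposure_cosine <- function(a, b) {
  if (length(a) != length(b))
    stop("exposure vectors differ in length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least 2 signatures", call. = FALSE)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for an all-zero exposure vector",
         call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Cluster samples by signature exposures with seeded k-means
#'
#' Groups samples with similar patterns of chromosomal-instability
#' processes via k-means on their exposure rows (squared-Euclidean
#' objective, `n_restarts` random initializations from `seed`, best
#' objective kept). Results are deterministic given `(seed, n_restarts)`.
#'
#' @param exposures Samples x signatures matrix (rows summing to 1; see
#'   [validate_exposures()]).
#' @param k Number of clusters, `2 <= k <= n_samples`.
#' @param seed Integer random seed (mandatory, for reproducible labels).
#' @param n_restarts Random restarts (default 10).
#' @return Object of class `cn_clusters`: list with `k`, `labels` (named
#'   integer vector in 1..k), `centroids` (k x signatures matrix), `seed`,
#'   and `objective` (total within-cluster sum of squares).
#' @export
cluster_exposures <- function(exposures, k, seed, n_restarts = 10) {
  exposures <- validate_exposures(exposures)
  n <- nrow(exposures)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > n)
    stop("'k' must satisfy 2 <= k <= n_samples (= ", n, ")", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory (single integer)", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  if (k == n) {
    ## exact degenerate fit: every sample its own cluster, objective 0
    labels <- stats::setNames(seq_len(n), rownames(exposures))
    centroids <- exposures
    rownames(centroids) <- NULL
    objective <- 0
  } else {
    km <- stats::kmeans(exposures, centers = as.integer(k),
                        nstart = as.integer(n_restarts), iter.max = 100)
    labels <- stats::setNames(as.integer(km$cluster), rownames(exposures))
    centroids <- km$centers
    objective <- km$tot.withinss
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(k = as.integer(k), labels = labels,
                 centroids = centroids, seed = as.integer(seed),
                 objective = objective),
            class = "cn_clusters")
}

#' @export
print.cn_clusters <- function(x, ...) {
  cat("<cn_clusters> k = ", x$k, ", ", length(x$labels),
      " samples, objective ", format(x$objective, digits = 6),
      " (seed ", x$seed, ")\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Signatures most variable across cluster centroids
#'
#' Ranks signatures by the variance of their centroid values across
#' clusters and returns the top `n` — the standard choice of axes for a
#' two-dimensional scatter of a signature clustering, since these are the
#' signatures that discriminate the clusters. Ties are broken by signature
#' column order.
#'
#' @param assignment A [cluster_exposures()] result.
#' @param n How many signatures to return (default 2).
#' @return Character vector of signature ids, most variable first.
#' @export
top_variable_signatures <- function(assignment, n = 2) {
  stopifnot(inherits(assignment, "cn_clusters"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("'n' must be a single positive count", call. = FALSE)
  cent <- assignment$centroids
  if (n > ncol(cent))
    stop("'n' exceeds the number of signatures (", ncol(cent), ")",
         call. = FALSE)
  v <- apply(cent, 2L, stats::var)
  ord <- order(-v, seq_along(v))
  colnames(cent)[ord][seq_len(n)]
}

#' Assign a query sample to its nearest exposure cluster
#'
#' Places a new sample into an existing clustering by squared-Euclidean
#' distance to the centroids; ties go to the lowest cluster index.
#'
#' @param query_exposures Numeric exposure vector (length = number of
#'   signatures of the clustering).
#' @param assignment A [cluster_exposures()] result.
#' @return Integer cluster index in 1..k.
#' @export
assign_query_to_cluster <- function(query_exposures, assignment) {
  stopifnot(inherits(assignment, "cn_clusters"))
  cent <- assignment$centroids
  if (length(query_exposures) != ncol(cent))
    stop("query has ", length(query_exposures), " signatures but the ",
         "clustering has ", ncol(cent), call. = FALSE)
  d2 <- rowSums(sweep(cent, 2L, as.numeric(query_exposures))^2)
  unname(which.min(d2))  # ties -> lowest index
}

#' Silhouette scan over candidate cluster counts
#'
#' Reports (never decides) the mean silhouette width of seeded k-means
#' clusterings for each candidate k, as guidance for choosing the cluster
#' count. Requires the cluster package.
#'
#' @param exposures Samples x signatures matrix.
#' @param ks Candidate cluster counts (default 2:8).
#' @param seed Integer seed.
#' @param n_restarts Restarts per k (default 10).
#' @return data.frame with columns `k` and `mean_silhouette`.
#' @export
silhouette_scan <- function(exposures, ks = 2:8, seed, n_restarts = 10) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop("silhouette_scan needs the cluster package", call. = FALSE)
  exposures <- validate_exposures(exposures)
  ks <- ks[ks >= 2 & ks < nrow(exposures)]
  d <- stats::dist(exposures)
  res <- lapply(ks, function(k) {
    cl <- cluster_exposures(exposures, k, seed = seed,
                            n_restarts = n_restarts)
    sil <- cluster::silhouette(cl$labels, d)
    data.frame(k = k, mean_silhouette = mean(sil[, "sil_width"]))
  })
  do.call(rbind, res)
}

#' Write signature clustering reports
#'
#' Writes the cluster report CSV (sample, cluster, distance to each
#' centroid, and a `is_query` flag when a query id is given), the centroid
#' table CSV, and a 2-D scatter export (sample and centroid coordinates on
#' the two most variable signatures).
#'
#' @param assignment A [cluster_exposures()] result.
#' @param exposures The matrix that was clustered.
#' @param dir Output directory (created if needed).
#' @param query_id Optional sample id to flag in the report.
#' @param prefix File name prefix (default `"clusters"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cluster_report <- function(assignment, exposures, dir,
                                 query_id = NULL, prefix = "clusters") {
  stopifnot(inherits(assignment, "cn_clusters"))
  exposures <- validate_exposures(exposures)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(query_id) && !query_id %in% rownames(exposures))
    stop("query id '", query_id, "' not found in the exposure matrix",
         call. = FALSE)
  cent <- assignment$centroids
  d2 <- vapply(seq_len(nrow(cent)), function(j)
    rowSums(sweep(exposures, 2L, cent[j, ])^2), numeric(nrow(exposures)))
  colnames(d2) <- paste0("dist_to_cluster_", seq_len(nrow(cent)))
  report <- data.frame(sample = rownames(exposures),
                       cluster = assignment$labels[rownames(exposures)],
                       d2, check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (!is.null(query_id))
    report$is_query <- report$sample == query_id
  files <- c(report = file.path(dir, paste0(prefix, "_report.csv")),
             centroids = file.path(dir, paste0(prefix, "_centroids.csv")),
             scatter = file.path(dir, paste0(prefix, "_scatter.csv")))
  utils::write.csv(report, files[["report"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(cluster = seq_len(nrow(cent)), cent,
                              check.names = FALSE),
                   files[["centroids"]], row.names = FALSE, quote = FALSE)
  top2 <- top_variable_signatures(assignment, 2)
  scatter <- rbind(
    data.frame(id = rownames(exposures), kind = "sample",
               cluster = assignment$labels[rownames(exposures)],
               x = exposures[, top2[1L]], y = exposures[, top2[2L]],
               stringsAsFactors = FALSE),
    data.frame(id = paste0("centroid_", seq_len(nrow(cent))),
               kind = "centroid", cluster = seq_len(nrow(cent)),
               x = cent[, top2[1L]], y = cent[, top2[2L]],
               stringsAsFactors = FALSE))
  names(scatter)[names(scatter) == "x"] <- top2[1L]
  names(scatter)[names(scatter) == "y"] <- top2[2L]
  utils::write.csv(scatter, files[["scatter"]], row.names = FALSE,
                   quote = FALSE)
  invisible(files)
}
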