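#' Build a reference profile collection
#'
#' Packages a list of segment tables into a reference collection against
#' which queries are matched: sample metadata plus binned profiles
#' precomputed on one grid (the expensive rasterization is done once, at
#' build time).
#'
#' @param profiles List of [cn_segments] with unique sample ids.
#' @param grid The [make_bin_grid()] grid to cache binned profiles on.
#' @param metadata Optional data.frame with columns `sample`, `tissue`,
#'   `source`; defaults to unknowns.
#' @return Object of class `cn_reference`: list with `profiles` (named
#'   list of segment tables), `metadata`, `grid`, and `binned` (named list
#'   of [segments_to_bins()] profiles).
#' @export
build_reference <- function(profiles, grid, metadata = NULL) {
  if (inherits(profiles, "cn_segments")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L, inherits(grid, "cn_bingrid"))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample id in reference collection: '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  names(profiles) <- ids
  if (is.null(metadata)) {
    metadata <- data.frame(sample = ids, tissue = "unknown",
                           source = "unknown", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample", "tissue", "source") %in% names(metadata)),
            setequal(metadata$sample, ids))
  metadata <- metadata[match(ids, metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  binned <- lapply(profiles, segments_to_bins, grid = grid)
  structure(list(profiles = profiles, metadata = metadata, grid = grid,
                 binned = binned),
            class = "cn_reference")
}

#' @export
print.cn_reference <- function(x, ...) {
  cat("<cn_reference> ", length(x$profiles), " profiles on ",
      nrow(x$grid$bins), " bins (bin size ",
      format(x$grid$bin_size, big.mark = ","), " bp)\n", sep = "")
  print(table(tissue = x$metadata$tissue))
  invisible(x)
}

#' @export
length.cn_reference <- function(x) length(x$profiles)

#' Save a reference collection to a directory
#'
#' Writes the on-disk interchange form of a collection: `segments.tsv`
#' (multi-sample segment table), `metadata.tsv`, `grid.tsv` (chromosome
#' sizes plus a `#bin_size` header line) and `bins.tsv` (the cached bin
#' matrix). [load_reference()] restores an equal collection.
#'
#' @param ref A [build_reference()] collection.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "cn_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_segment_table(ref$profiles, file.path(dir, "segments.tsv"))
  utils::write.table(ref$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "grid.tsv"), "w")
  writeLines(paste0("#bin_size\t", format(ref$grid$bin_size,
                                          scientific = FALSE)), con)
  utils::write.table(data.frame(chrom = names(ref$grid$genome),
                                size = ref$grid$genome),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  export_bins(ref$binned, file.path(dir, "bins.tsv"))
  invisible(dir)
}

#' Load a reference collection from a directory
#'
#' Restores a collection written by [save_reference()]. The cached bin
#' matrix is recomputed from the segment tables (and must agree with the
#' stored one when present), so a loaded collection is always internally
#' consistent.
#'
#' @param dir Directory written by [save_reference()].
#' @return A `cn_reference` collection.
#' @export
load_reference <- function(dir) {
  seg_path <- file.path(dir, "segments.tsv")
  grid_path <- file.path(dir, "grid.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  for (p in c(seg_path, grid_path, meta_path))
    if (!file.exists(p))
      stop("reference directory is missing ", basename(p), call. = FALSE)
  header <- readLines(grid_path, n = 1L)
  if (!startsWith(header, "#bin_size"))
    stop("grid.tsv lacks the #bin_size header", call. = FALSE)
  bin_size <- as.numeric(strsplit(header, "\t")[[1L]][2L])
  sizes <- utils::read.table(grid_path, sep = "\t", skip = 1L,
                             col.names = c("chrom", "size"),
                             colClasses = c("character", "numeric"))
  genome <- stats::setNames(sizes$size, sizes$chrom)
  grid <- make_bin_grid(genome, bin_size)
  profiles <- read_segment_table(seg_path)
  metadata <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  build_reference(profiles, grid, metadata = metadata)
}
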