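#' Tile a genome into fixed-width bins
#'
#' Builds the fixed-width bin grid onto which segment tables are rasterized
#' so that profiles become comparable fixed-length vectors. Every bin has
#' length `bin_size` except possibly the last bin of each chromosome, which
#' is truncated at the chromosome end. Bins tile each chromosome without
#' gaps or overlaps and are ordered deterministically: chromosomes in the
#' order of `genome`, then by start.
#'
#' The default bin size is 500 kb. Resolutions finer than 30 kb exceed what
#' SNP6-era reference profiles support and trigger a warning.
#'
#' @param genome Named numeric vector of chromosome lengths in bp (e.g.
#'   [hg19_genome()] or [read_chrom_sizes()]).
#' @param bin_size Bin width in bp (default 500000).
#' @return An object of class `cn_bingrid`: list with `genome`, `bin_size`
#'   and `bins` (data.frame `chrom`, `start`, `end`; 0-based half-open).
#' @examples
#' grid <- make_bin_grid(c(A = 1200000), bin_size = 500000)
#' grid$bins
#' @export
make_bin_grid <- function(genome = hg19_genome(), bin_size = 500000) {
  if (!is.numeric(genome) || length(genome) == 0L || is.null(names(genome)))
    stop("'genome' must be a non-empty named numeric vector of chromosome lengths",
         call. = FALSE)
  if (any(genome < 1))
    stop("all chromosome lengths must be >= 1", call. = FALSE)
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("'bin_size' must be a single positive number", call. = FALSE)
  if (bin_size < 30000)
    warning("bin_size below 30 kb: resolution beyond 30 kb is not supported ",
            "by SNP6-derived reference profiles", call. = FALSE)
  names(genome) <- normalize_chrom(names(genome))
  bins <- do.call(rbind, lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(genome = genome, bin_size = bin_size, bins = bins),
            class = "cn_bingrid")
}

#' @export
print.cn_bingrid <- function(x, ...) {
  cat("<cn_bingrid> ", length(x$genome), " chromosomes, bin size ",
      format(x$bin_size, big.mark = ","), " bp, ", nrow(x$bins),
      " bins\n", sep = "")
  invisible(x)
}

#' Number of bins in a grid
#' @param grid A [make_bin_grid()] object.
#' @return Integer bin count.
#' @export
n_bins <- function(grid) {
  stopifnot(inherits(grid, "cn_bingrid"))
  nrow(grid$bins)
}

## two grids are interchangeable iff genome and bin size agree
same_grid <- function(a, b) {
  isTRUE(all.equal(a$genome, b$genome)) && a$bin_size == b$bin_size
}

#' Convert a bin grid to GRanges
#'
#' Interop helper for downstream Bioconductor tooling (genome-browser
#' tracks, overlap queries). Requires GenomicRanges.
#'
#' @param grid A [make_bin_grid()] grid.
#' @return A `GRanges` of the bins (1-based inclusive, as usual there).
#' @export
bins_granges <- function(grid) {
  stopifnot(inherits(grid, "cn_bingrid"))
  if (!requireNamespace("GenomicRanges", quietly = TRUE))
    stop("bins_granges needs the GenomicRanges package", call. = FALSE)
  GenomicRanges::GRanges(
    seqnames = grid$bins$chrom,
    ranges = IRanges::IRanges(start = grid$bins$start + 1,
                              end = grid$bins$end))
}

#' Rasterize a segment table onto a bin grid
#'
#' Converts a piecewise-constant segment table into a binned profile: for
#' each bin, the value is the coverage-length-weighted mean copy number of
#' the segments overlapping that bin. Bins with no overlapping segment are
#' flagged missing (`NA`). A bin lying fully inside one segment takes that
#' segment's copy number exactly, and the construction conserves copy-number
#' mass (sum of value times covered length).
#'
#' @param profile A [cn_segments] object.
#' @param grid A [make_bin_grid()] grid; every chromosome used by `profile`
#'   must exist in `grid$genome` and no segment may extend beyond the
#'   chromosome length.
#' @return An object of class `cn_profile`: list with `sample_id`, `grid`,
#'   `values` (numeric, length [n_bins()]; `NA` = missing) .
#' @examples
#' seg <- cn_segments("S1", "A", start = 1, end = 1200000, copy_number = 2)
#' grid <- make_bin_grid(c(A = 1200000), 500000)
#' segments_to_bins(seg, grid)$values
#' @export
segments_to_bins <- function(profile, grid) {
  stopifnot(inherits(profile, "cn_segments"), inherits(grid, "cn_bingrid"))
  df <- profile$segments
  absent <- setdiff(unique(df$chrom), names(grid$genome))
  if (length(absent))
    stop("chromosome '", absent[1L], "' of sample '", profile$sample_id,
         "' is absent from the bin grid genome", call. = FALSE)
  too_far <- df$end > grid$genome[df$chrom]
  if (any(too_far)) {
    i <- which(too_far)[1L]
    stop("segment ", df$chrom[i], ":", df$start[i] + 1, "-", df$end[i],
         " of sample '", profile$sample_id,
         "' extends beyond the chromosome length (",
         grid$genome[[df$chrom[i]]], " bp)", call. = FALSE)
  }
  values <- rep(NA_real_, nrow(grid$bins))
  bin_chrom <- grid$bins$chrom
  for (ch in unique(df$chrom)) {
    seg <- df[df$chrom == ch, , drop = FALSE]
    at <- which(bin_chrom == ch)
    mass <- cum_overlap(grid$bins$end[at], seg) -
            cum_overlap(grid$bins$start[at], seg)
    cover <- cum_overlap(grid$bins$end[at], seg, coverage = TRUE) -
             cum_overlap(grid$bins$start[at], seg, coverage = TRUE)
    values[at] <- ifelse(cover > 0, mass / cover, NA_real_)
  }
  new_cn_profile(profile$sample_id, grid, values)
}

## cumulative copy-number mass (or covered length) of sorted, disjoint
## segments over [0, t), vectorized in t via findInterval
cum_overlap <- function(t, seg, coverage = FALSE) {
  w <- seg$end - seg$start
  m <- if (coverage) w else seg$copy_number * w
  cum0 <- c(0, cumsum(m))
  i <- findInterval(t, seg$start)
  partial <- numeric(length(t))
  hit <- i >= 1L
  ih <- i[hit]
  frac <- pmax(0, pmin(t[hit], seg$end[ih]) - seg$start[ih])
  partial[hit] <- frac * (if (coverage) 1 else seg$copy_number[ih])
  full <- numeric(length(t))
  full[hit] <- cum0[ih]
  full + partial
}

new_cn_profile <- function(sample_id, grid, values) {
  stopifnot(length(values) == nrow(grid$bins))
  ok <- !is.na(values)
  if (any(!is.finite(values[ok])) || any(values[ok] < 0))
    stop("binned values must be non-negative and finite", call. = FALSE)
  structure(list(sample_id = sample_id, grid = grid,
                 values = as.numeric(values)),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat("<cn_profile> sample '", x$sample_id, "': ", length(x$values),
      " bins (", nm, " missing), mean CN ",
      format(mean(x$values, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method as.data.frame cn_profile
#' @export
as.data.frame.cn_profile <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(chromosome = x$grid$bins$chrom,
             start = x$grid$bins$start,
             end = x$grid$bins$end,
             value = x$values,
             stringsAsFactors = FALSE)
}

#' Export binned profiles to a TSV bin table
#'
#' Writes one column per sample on a shared grid, with `chromosome`,
#' `start`, `end` bin coordinates (0-based half-open).
#'
#' @param profiles A `cn_profile` or list of `cn_profile`s on one grid.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_bins <- function(profiles, path) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  grid <- profiles[[1L]]$grid
  for (p in profiles)
    if (!same_grid(p$grid, grid))
      stop("all profiles must share one bin grid", call. = FALSE)
  out <- grid$bins
  for (p in profiles) out[[p$sample_id]] <- p$values
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
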