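#' Construct a copy number segment table for one sample
#'
#' A segment table is the piecewise-constant representation of one sample's
#' absolute copy number profile: one row per genomic segment with its total
#' copy number. Input coordinates are 1-based inclusive (the ASCAT
#' convention); internally they are converted to 0-based half-open intervals
#' so that adjacent segments abut without gaps.
#'
#' @param sample_id Sample identifier (single string).
#' @param chrom Chromosome labels (normalized: "chr1" and "1" are the same).
#' @param start,end Segment coordinates, 1-based inclusive.
#' @param copy_number Non-negative finite absolute total copy number.
#' @return An object of class `cn_segments`: a list with `sample_id` and a
#'   `segments` data.frame (`chrom`, `start`, `end`, `copy_number`) holding
#'   0-based half-open coordinates, sorted by (karyotype order, start).
#' @seealso [read_segment_table()], [segments_to_bins()]
#' @examples
#' seg <- cn_segments("S1", chrom = c("1", "1"),
#'                    start = c(1, 10000001), end = c(10000000, 20000000),
#'                    copy_number = c(2, 3))
#' seg
#' @export
cn_segments <- function(sample_id, chrom, start, end, copy_number) {
  stopifnot(is.character(sample_id) || is.factor(sample_id),
            length(sample_id) == 1L)
  df <- data.frame(chrom = normalize_chrom(chrom),
                   start = as.numeric(start) - 1,  # to 0-based half-open
                   end = as.numeric(end),
                   copy_number = as.numeric(copy_number),
                   stringsAsFactors = FALSE)
  new_cn_segments(as.character(sample_id), df)
}

## internal constructor: df already 0-based half-open
new_cn_segments <- function(sample_id, df) {
  ## sort by (karyotype chromosome order, start)
  chrom_levels <- unique(df$chrom)
  chrom_levels <- chrom_levels[order_chromosomes(chrom_levels)]
  df <- df[order(match(df$chrom, chrom_levels), df$start), , drop = FALSE]
  rownames(df) <- NULL
  obj <- structure(list(sample_id = sample_id, segments = df),
                   class = "cn_segments")
  validate_segments(obj)
  obj
}

validate_segments <- function(x) {
  df <- x$segments
  if (nrow(df) == 0L)
    stop("segment table for sample '", x$sample_id, "' has no records",
         call. = FALSE)
  if (any(!is.finite(df$copy_number)))
    stop("non-finite copy number in sample '", x$sample_id, "'",
         call. = FALSE)
  if (any(df$copy_number < 0)) {
    i <- which(df$copy_number < 0)[1L]
    stop("negative copy number (", df$copy_number[i], ") in sample '",
         x$sample_id, "' at ", df$chrom[i], ":", df$start[i] + 1, "-",
         df$end[i], call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1L]
    stop("segment with start >= end in sample '", x$sample_id, "' at ",
         df$chrom[i], ":", df$start[i] + 1, "-", df$end[i], call. = FALSE)
  }
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L) {
      bad <- which(sub$start[-1L] < sub$end[-nrow(sub)])
      if (length(bad)) {
        i <- bad[1L]
        stop("overlapping segments in sample '", x$sample_id,
             "' on chromosome ", ch, ": ",
             ch, ":", sub$start[i] + 1, "-", sub$end[i], " overlaps ",
             ch, ":", sub$start[i + 1L] + 1, "-", sub$end[i + 1L],
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.cn_segments <- function(x, ...) {
  df <- x$segments
  cat("<cn_segments> sample '", x$sample_id, "': ", nrow(df),
      " segments on ", length(unique(df$chrom)), " chromosomes\n", sep = "")
  cat("  mean copy number (length-weighted): ",
      format(sum(df$copy_number * (df$end - df$start)) /
             sum(df$end - df$start), digits = 4), "\n", sep = "")
  invisible(x)
}

## default column dialect of the segment-table interchange format
default_dialect <- function() {
  c(chromosome = "chromosome", start = "start", end = "end",
    copy_number = "segVal", sample = "sample")
}

#' Read copy number segment tables from a delimited file
#'
#' Reads one or more absolute copy number profiles from a tab- or
#' comma-delimited file with a header. The default column names are
#' `chromosome`, `start`, `end`, `segVal` and (optionally) `sample`; any of
#' them can be remapped through `dialect`. When a sample column is present
#' the file is split into one segment table per distinct sample id;
#' otherwise the whole file is one sample named after `sample_id`.
#' Coordinates are interpreted as 1-based inclusive.
#'
#' @param path Path to a TSV/CSV file (delimiter sniffed from the header,
#'   or forced with `sep`).
#' @param dialect Named character vector remapping logical column roles
#'   (`chromosome`, `start`, `end`, `copy_number`, `sample`) to the column
#'   names used in the file.
#' @param sample_id Sample name used when the file has no sample column.
#' @param sep Field delimiter; `NULL` (default) sniffs tab vs comma.
#' @return A named list of [cn_segments] objects, one per sample.
#' @export
read_segment_table <- function(path, dialect = NULL, sample_id = NULL,
                               sep = NULL) {
  dia <- default_dialect()
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), names(dia))
    if (length(unknown))
      stop("unknown dialect role(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    dia[names(dialect)] <- dialect
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chromosome", "start", "end", "copy_number")
  for (role in required) {
    if (!dia[[role]] %in% names(tab))
      stop("missing required column '", dia[[role]], "' (", role,
           ") in ", path, call. = FALSE)
  }
  has_sample <- dia[["sample"]] %in% names(tab)
  samples <- if (has_sample) as.character(tab[[dia[["sample"]]]])
             else rep(sample_id %||% "sample_1", nrow(tab))
  out <- lapply(split(seq_len(nrow(tab)), factor(samples, unique(samples))),
                function(idx) {
    cn_segments(sample_id = samples[idx[1L]],
                chrom = tab[[dia[["chromosome"]]]][idx],
                start = tab[[dia[["start"]]]][idx],
                end = tab[[dia[["end"]]]][idx],
                copy_number = tab[[dia[["copy_number"]]]][idx])
  })
  out[unique(samples)]
}

#' Write segment tables to a multi-sample TSV
#'
#' Inverse of [read_segment_table()]: writes one or more profiles to a
#' single tab-separated file with columns `chromosome`, `start`, `end`,
#' `segVal`, `sample` and 1-based inclusive coordinates.
#'
#' @param profiles A `cn_segments` object or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(profiles, path) {
  if (inherits(profiles, "cn_segments")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(chromosome = p$segments$chrom,
               start = p$segments$start + 1,   # back to 1-based inclusive
               end = p$segments$end,
               segVal = p$segments$copy_number,
               sample = p$sample_id,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
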