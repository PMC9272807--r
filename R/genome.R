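#' Chromosome lengths of the hg19 reference genome
#'
#' Returns the chromosome lengths of the human hg19 (GRCh37) assembly in
#' karyotype order. This is the default genome used when binning profiles:
#' hg19 matches the SNP6-era references underlying the large public cell-line
#' copy number collections. The Y chromosome is excluded by default because
#' its coverage in cell lines is unreliable.
#'
#' @param include_x Include chromosome X (default `TRUE`).
#' @param include_y Include chromosome Y (default `FALSE`).
#' @return Named numeric vector of chromosome lengths in bp, names without
#'   the `"chr"` prefix, in karyotype order (1..22, X, Y).
#' @examples
#' g <- hg19_genome()
#' head(g)
#' @export
hg19_genome <- function(include_x = TRUE, include_y = FALSE) {
  lengths <- c(
    `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566,
    X = 155270560, Y = 59373566
  )
  keep <- c(as.character(1:22), if (include_x) "X", if (include_y) "Y")
  lengths[keep]
}

#' Read chromosome lengths from a UCSC chrom.sizes file
#'
#' Parses the two-column (chromosome, length) tab-separated format used by
#' UCSC `chrom.sizes` files. Chromosome labels are normalized (a leading
#' `"chr"` prefix is stripped) and chromosomes are returned in karyotype
#' order: numeric labels first in numeric order, then X, Y, then any other
#' labels in the order encountered.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L)
    stop("chrom.sizes file is empty: ", path, call. = FALSE)
  chrom <- normalize_chrom(tab$chrom)
  if (anyDuplicated(chrom))
    stop("duplicated chromosome in chrom.sizes: ",
         chrom[duplicated(chrom)][1L], call. = FALSE)
  sizes <- stats::setNames(tab$size, chrom)
  sizes[order_chromosomes(chrom)]
}

#' Normalize chromosome labels
#'
#' Accepts labels with or without the `"chr"` prefix ("chr1" and "1" are the
#' same chromosome) and stores them without the prefix.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

## karyotype ordering: 1..22 numerically, then X, Y, then the rest as given
order_chromosomes <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(!is.na(num), num,
                ifelse(chrom == "X", 1e6, ifelse(chrom == "Y", 1e6 + 1, 1e6 + 2)))
  order(key, seq_along(chrom))
}
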