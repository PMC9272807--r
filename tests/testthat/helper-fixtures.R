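# Shared fixtures built in code.

## a binned profile straight from a value vector, one chromosome "A",
## unit bin size 1e5 — handy for hand-computable metric examples
toy_profile <- function(values, sample_id = "toy", bin_size = 1e5) {
  grid <- make_bin_grid(stats::setNames(length(values) * bin_size, "A"),
                        bin_size)
  cnmatch:::new_cn_profile(sample_id, grid, as.numeric(values))
}

## small simulator settings used throughout the suite: 4 x 10 Mb genome,
## 80 bins at 500 kb
small_params <- function(...) {
  sim_params(n_chromosomes = 4, chromosome_length = 1e7, ...)
}

small_grid <- function(bin_size = 5e5) {
  make_bin_grid(sim_genome(small_params()), bin_size)
}

## write a segment-table TSV and return its path
write_seg_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## independent binning oracle via GenomicRanges overlap arithmetic
granges_bin_oracle <- function(profile, grid) {
  df <- profile$segments
  seg_gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, df$end))
  bin_gr <- GenomicRanges::GRanges(
    grid$bins$chrom, IRanges::IRanges(grid$bins$start + 1, grid$bins$end))
  hits <- GenomicRanges::findOverlaps(bin_gr, seg_gr)
  ov <- IRanges::pintersect(bin_gr[S4Vectors::queryHits(hits)],
                            seg_gr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  cn <- df$copy_number[S4Vectors::subjectHits(hits)]
  out <- rep(NA_real_, nrow(grid$bins))
  ms <- rowsum(cbind(w * cn, w), S4Vectors::queryHits(hits))
  out[as.integer(rownames(ms))] <- ms[, 1L] / ms[, 2L]
  out
}

## brute-force metric formulas, the independent oracle route
oracle_metric <- function(x, y, metric) {
  switch(metric,
         pearson = stats::cor(x, y),
         manhattan = sum(abs(x - y)),
         euclidean = sqrt(sum((x - y)^2)),
         cosine = drop(crossprod(x, y)) /
           (sqrt(drop(crossprod(x))) * sqrt(drop(crossprod(y)))))
}
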