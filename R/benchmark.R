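#' Sister-culture partner recovery benchmark
#'
#' Re-enacts, at desk scale with synthetic data, the matched-culture
#' experiment used to validate profile matching: simulate `n_profiles`
#' cell lines, derive one perturbed "sister culture" per line
#' ([perturb_profile()]), and check for every line whether
#' [rank_matches()] places its sister at rank 1 among all sisters (plus
#' optional decoy lines). Recovery is reported per metric.
#'
#' With `ploidy_shift = 2` and decoys present this reproduces the
#' qualitative ploidy-confusion failure mode: the normalized metrics
#' (Pearson, cosine) still recover the doubled sister while the absolute
#' distances (Manhattan, Euclidean) are pulled towards decoys of closer
#' ploidy.
#'
#' @param n_profiles Number of simulated cell lines (default 50).
#' @param params Simulator parameters for the base profiles.
#' @param bin_size Grid bin size in bp (default 500000).
#' @param boundary_jitter Sister breakpoint jitter in bp (default one
#'   bin).
#' @param noise_fraction Fraction of the sister genome with segmental
#'   copy noise (default 0.1).
#' @param noise_magnitude Copy change of noisy segments (default 1).
#' @param ploidy_shift Ploidy multiplier applied to sisters (default 1).
#' @param n_decoys Extra unrelated simulated lines mixed into the
#'   reference set (default 0).
#' @param metrics Metrics to evaluate (default all four).
#' @param smoothing_window Boundary alignment window in bins (default 1).
#' @param seed Integer seed driving the whole experiment.
#' @return data.frame with one row per metric: `metric`, `n_queries`,
#'   `n_recovered`, `recovery_pct`, `n_decoy_top` (queries whose top hit
#'   was a decoy), `decoy_top_pct`.
#' @export
benchmark_recovery <- function(n_profiles = 50, params = sim_params(),
                               bin_size = 500000,
                               boundary_jitter = bin_size,
                               noise_fraction = 0.1, noise_magnitude = 1,
                               ploidy_shift = 1, n_decoys = 0,
                               metrics = c("pearson", "manhattan",
                                           "euclidean", "cosine"),
                               smoothing_window = 1, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  grid <- make_bin_grid(sim_genome(params), bin_size)
  sim <- simulate_collection(n_profiles, params, seed = seed)
  sisters <- lapply(seq_len(n_profiles), function(i)
    perturb_profile(sim$profiles[[i]], boundary_jitter = boundary_jitter,
                    noise_fraction = noise_fraction,
                    noise_magnitude = noise_magnitude,
                    ploidy_shift = ploidy_shift,
                    seed = (seed + 7919 * i) %% 2147483647))
  queries <- lapply(sim$profiles, segments_to_bins, grid = grid)
  refs <- lapply(sisters, segments_to_bins, grid = grid)
  decoy_ids <- character(0)
  if (n_decoys > 0) {
    decoys <- simulate_collection(n_decoys, params,
                                  seed = (seed + 104729) %% 2147483647,
                                  prefix = "DECOY")
    decoy_ids <- names(decoys$profiles)
    refs <- c(refs, lapply(decoys$profiles, segments_to_bins,
                           grid = grid))
  }
  out <- lapply(metrics, function(m) {
    tops <- vapply(seq_len(n_profiles), function(i) {
      mt <- rank_matches(queries[[i]], refs, metric = m,
                         with_significance = FALSE,
                         smoothing_window = smoothing_window)
      top_match(mt)$reference[1L]
    }, character(1))
    partner <- paste0(names(sim$profiles), "_sister")
    data.frame(metric = m, n_queries = n_profiles,
               n_recovered = sum(tops == partner),
               recovery_pct = 100 * mean(tops == partner),
               n_decoy_top = sum(tops %in% decoy_ids),
               decoy_top_pct = 100 * mean(tops %in% decoy_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Calibration of the empirical match p-value
#'
#' Checks that the add-one empirical p-value ([empirical_pvalue()]) is
#' uniform when query and references are exchangeable: in each replicate
#' a fresh query and `n_references` references are simulated
#' independently, the query is scored against all of them, and the first
#' reference's score receives a p-value with the remaining scores as the
#' null. Under exchangeability that p-value is uniform on a discrete
#' grid; the Kolmogorov–Smirnov statistic against the uniform
#' distribution summarizes the calibration.
#'
#' @param n_replicates Number of replicates (default 1000).
#' @param n_references References per replicate (default 24).
#' @param params Simulator parameters (default a compact 4 x 10 Mb
#'   genome for speed).
#' @param bin_size Grid bin size (default 500000).
#' @param metric Metric whose p-value is calibrated (default
#'   `"pearson"`).
#' @param seed Integer seed.
#' @return List with `p_values` (length `n_replicates`) and
#'   `ks_statistic`.
#' @export
calibrate_pvalues <- function(n_replicates = 1000, n_references = 24,
                              params = sim_params(n_chromosomes = 4,
                                                  chromosome_length = 1e7),
                              bin_size = 500000, metric = "pearson",
                              seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  grid <- make_bin_grid(sim_genome(params), bin_size)
  higher <- metric_orientation(metric)
  pvals <- vapply(seq_len(n_replicates), function(r) {
    base <- (seed + 31 * r) %% 2147483647
    q <- segments_to_bins(simulate_profile(params, seed = base, "q"),
                          grid)
    scores <- vapply(seq_len(n_references), function(j) {
      ref <- segments_to_bins(
        simulate_profile(params, seed = (base + 1000003 * j) %% 2147483647,
                         sample_id = "r"), grid)
      cn_similarity(q, ref, metric)$score
    }, numeric(1))
    empirical_pvalue(scores[1L], scores[-1L], higher_is_better = higher)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  list(p_values = pvals, ks_statistic = unname(ks$statistic))
}
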