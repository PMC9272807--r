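#' Parameters for the copy number profile simulator
#'
#' Describes the synthetic genome and the generative process used to
#' emulate absolute copy number profiles: a genome of `n_chromosomes`
#' equal-length chromosomes; per chromosome, a number of segments drawn
#' uniformly from `n_segments` with breakpoints placed uniformly without
#' replacement; integer copy states drawn from `copy_state_weights`
#' (states 0..8, weights peaked at 2 by default to emulate a near-diploid
#' tumour genome with a tail of gains); all values multiplied by
#' `ploidy_scale`.
#'
#' The defaults describe a human-scale genome (22 x 130 Mb, roughly 2.9
#' Gb) with realistic segment counts; smaller genomes are used for quick
#' experiments by overriding `n_chromosomes`/`chromosome_length`.
#'
#' @param n_chromosomes Number of chromosomes (default 22).
#' @param chromosome_length Chromosome length in bp (default 1.3e8).
#' @param n_segments Length-2 range (min, max) of segments per chromosome
#'   (default `c(2, 12)`).
#' @param copy_state_weights Non-negative weights over integer copy states
#'   0..8 (any length >= 2 is accepted; states are `0:(length-1)`).
#' @param ploidy_scale Positive multiplier applied to all copy numbers
#'   (default 1).
#' @return Object of class `cn_sim_params`.
#' @export
sim_params <- function(n_chromosomes = 22, chromosome_length = 1.3e8,
                       n_segments = c(2, 12),
                       copy_state_weights = c(0.01, 0.15, 0.40, 0.20,
                                              0.12, 0.06, 0.03, 0.02,
                                              0.01),
                       ploidy_scale = 1) {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1)
    stop("'n_chromosomes' must be >= 1", call. = FALSE)
  if (!is.numeric(chromosome_length) || chromosome_length < 2)
    stop("'chromosome_length' must be >= 2 bp", call. = FALSE)
  if (length(n_segments) != 2L || any(n_segments < 1) ||
      n_segments[1L] > n_segments[2L])
    stop("'n_segments' must be a valid (min, max) range of counts",
         call. = FALSE)
  if (any(copy_state_weights < 0) || sum(copy_state_weights) <= 0 ||
      length(copy_state_weights) < 2L)
    stop("'copy_state_weights' must be non-negative with positive sum",
         call. = FALSE)
  if (!is.numeric(ploidy_scale) || ploidy_scale <= 0)
    stop("'ploidy_scale' must be positive", call. = FALSE)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.numeric(chromosome_length),
                 n_segments = as.integer(n_segments),
                 copy_state_weights = copy_state_weights /
                   sum(copy_state_weights),
                 ploidy_scale = ploidy_scale),
            class = "cn_sim_params")
}

#' Synthetic genome of a simulation parameter set
#' @param params A [sim_params()] object.
#' @return Named numeric vector of chromosome lengths (`c1`, `c2`, ...).
#' @export
sim_genome <- function(params) {
  stopifnot(inherits(params, "cn_sim_params"))
  stats::setNames(rep(params$chromosome_length, params$n_chromosomes),
                  paste0("c", seq_len(params$n_chromosomes)))
}

#' Simulate one absolute copy number profile
#'
#' Draws a piecewise-constant profile under [sim_params()]: per
#' chromosome, the segment count is uniform over the configured range,
#' internal breakpoints are drawn uniformly without replacement, each
#' segment's integer copy state is drawn from the state distribution, and
#' everything is scaled by `ploidy_scale`. Deterministic given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer random seed (mandatory).
#' @param sample_id Sample name (default `"sim"`).
#' @return A [cn_segments] profile covering every chromosome end to end.
#' @export
simulate_profile <- function(params, seed, sample_id = "sim") {
  stopifnot(inherits(params, "cn_sim_params"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory (single integer)", call. = FALSE)
  set.seed(as.integer(seed))
  states <- seq_along(params$copy_state_weights) - 1
  len <- params$chromosome_length
  chrom <- character(0); st <- numeric(0); en <- numeric(0); cn <- numeric(0)
  for (ci in seq_len(params$n_chromosomes)) {
    k <- sample(params$n_segments[1L]:params$n_segments[2L], 1L)
    k <- min(k, len - 1)  # cannot break more often than there are bases
    ## useHash avoids allocating a length-`len` vector for short chromosomes
    bp <- if (k > 1L) sort(sample.int(len - 1, k - 1L, useHash = TRUE))
          else numeric(0)
    starts <- c(0, bp)
    ends <- c(bp, len)
    vals <- sample(states, k, replace = TRUE,
                   prob = params$copy_state_weights)
    chrom <- c(chrom, rep(paste0("c", ci), k))
    st <- c(st, starts); en <- c(en, ends); cn <- c(cn, vals)
  }
  new_cn_segments(sample_id,
                  data.frame(chrom = chrom, start = st, end = en,
                             copy_number = cn * params$ploidy_scale,
                             stringsAsFactors = FALSE))
}

#' Perturb a profile into a synthetic sister culture
#'
#' Emulates what happens when the same cell line is independently
#' propagated and re-profiled: copy number boundaries jitter by up to
#' `boundary_jitter` bp, a subset of segments covering about
#' `noise_fraction` of the genome changes copy number by
#' `noise_magnitude` copies (random sign, floored at 0), and the whole
#' profile is scaled by `ploidy_shift` (2 emulates a whole-genome-doubled
#' ploidy mis-estimate). Breakpoint displacement is clamped so segments
#' stay valid — clamping is never an error. Deterministic given `seed`.
#'
#' Noisy segments are chosen by permuting the segments and taking a prefix
#' whose cumulative length comes closest to the target genome fraction.
#'
#' @param profile A [cn_segments] profile.
#' @param boundary_jitter Maximum breakpoint displacement in bp
#'   (default 0).
#' @param noise_fraction Fraction of the genome receiving copy number
#'   noise, in \[0, 1\] (default 0).
#' @param noise_magnitude Copy number change applied to noisy segments
#'   (default 1).
#' @param ploidy_shift Positive multiplier on all copy numbers
#'   (default 1).
#' @param seed Integer random seed (mandatory).
#' @param suffix Appended to the sample id (default `"_sister"`).
#' @return A perturbed [cn_segments] profile.
#' @export
perturb_profile <- function(profile, boundary_jitter = 0,
                            noise_fraction = 0, noise_magnitude = 1,
                            ploidy_shift = 1, seed,
                            suffix = "_sister") {
  stopifnot(inherits(profile, "cn_segments"))
  if (!is.numeric(noise_fraction) || noise_fraction < 0 ||
      noise_fraction > 1)
    stop("'noise_fraction' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(ploidy_shift) || ploidy_shift <= 0)
    stop("'ploidy_shift' must be positive", call. = FALSE)
  if (boundary_jitter < 0 || noise_magnitude < 0)
    stop("'boundary_jitter' and 'noise_magnitude' must be >= 0",
         call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory (single integer)", call. = FALSE)
  set.seed(as.integer(seed))
  df <- profile$segments
  ## 1. breakpoint jitter, per chromosome, chromosome ends fixed
  if (boundary_jitter > 0) {
    for (ch in unique(df$chrom)) {
      idx <- which(df$chrom == ch)
      if (length(idx) < 2L) next
      lo <- df$start[idx[1L]]
      hi <- df$end[idx[length(idx)]]
      bp <- df$end[idx[-length(idx)]]
      prop <- round(bp + stats::runif(length(bp), -boundary_jitter,
                                      boundary_jitter))
      ## clamp to keep breakpoints strictly increasing inside (lo, hi)
      for (j in seq_along(prop)) {
        left <- if (j == 1L) lo else prop[j - 1L]
        right <- hi - (length(prop) - j + 1L)
        prop[j] <- min(max(prop[j], left + 1), right)
      }
      df$end[idx[-length(idx)]] <- prop
      df$start[idx[-1L]] <- prop
    }
  }
  ## 2. segmental copy number noise on ~ noise_fraction of the genome
  if (noise_fraction > 0 && noise_magnitude > 0) {
    lens <- df$end - df$start
    target <- noise_fraction * sum(lens)
    ord <- sample.int(nrow(df))
    cum <- cumsum(lens[ord])
    n_take <- sum(cum <= target)
    if (n_take < length(ord)) {
      with_next <- if (n_take == 0L) cum[1L] else cum[n_take + 1L]
      at <- if (n_take == 0L) 0 else cum[n_take]
      if (abs(with_next - target) < abs(at - target))
        n_take <- n_take + 1L
    }
    if (n_take > 0L) {
      hit <- ord[seq_len(n_take)]
      sign <- sample(c(-1, 1), n_take, replace = TRUE)
      df$copy_number[hit] <- pmax(0, df$copy_number[hit] +
                                     sign * noise_magnitude)
    }
  }
  ## 3. ploidy shift
  df$copy_number <- df$copy_number * ploidy_shift
  new_cn_segments(paste0(profile$sample_id, suffix), df)
}

#' Simulate a collection of profiles
#'
#' Convenience wrapper generating `n` independent profiles with ids
#' `prefix` + zero-padded index and (optionally) round-robin tissue
#' labels, from one base seed.
#'
#' @param n Number of profiles.
#' @param params A [sim_params()] object.
#' @param seed Integer base seed; profile i uses `seed * 1000 + i`.
#' @param prefix Sample id prefix (default `"SYN"`).
#' @param tissues Tissue labels cycled over samples (default a small set
#'   of common cancer tissues).
#' @return List with `profiles` (list of [cn_segments]) and `metadata`
#'   (data.frame sample/tissue/source).
#' @export
simulate_collection <- function(n, params = sim_params(), seed,
                                prefix = "SYN",
                                tissues = c("ovary", "pancreas", "lung",
                                            "breast", "colon")) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  ## per-profile seeds derived from the base seed, kept inside integer range
  seeds <- (as.numeric(seed) * 1000 + seq_len(n)) %% 2147483647
  profiles <- lapply(seq_len(n), function(i)
    simulate_profile(params, seed = seeds[i], sample_id = ids[i]))
  names(profiles) <- ids
  metadata <- data.frame(sample = ids,
                         tissue = rep_len(tissues, n),
                         source = "synthetic",
                         stringsAsFactors = FALSE)
  list(profiles = profiles, metadata = metadata)
}

#' The bundled synthetic reference collection
#'
#' Generates the package's stand-in for a real cell-line copy number
#' database: `n` synthetic "cell lines" (default 200) with tissue labels,
#' binned on a shared grid. The collection is generated deterministically
#' from its seed at call time rather than shipped on disk; a user-supplied
#' real database in the same segment-table TSV format can be loaded with
#' [read_segment_table()] + [build_reference()] instead.
#'
#' @param n Collection size (default 200).
#' @param params Simulator parameters (default [sim_params()]).
#' @param bin_size Grid bin size in bp (default 500000).
#' @param seed Integer seed (default 2022).
#' @return A [build_reference()] collection.
#' @export
synthetic_reference <- function(n = 200, params = sim_params(),
                                bin_size = 500000, seed = 2022) {
  sim <- simulate_collection(n, params, seed = seed)
  grid <- make_bin_grid(sim_genome(params), bin_size)
  build_reference(sim$profiles, grid, metadata = sim$metadata)
}
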