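test_that("simulated profiles are valid, deterministic and seed-sensitive", {
  params <- small_params()
  a1 <- simulate_profile(params, seed = 5, "a")
  a2 <- simulate_profile(params, seed = 5, "a")
  expect_identical(a1, a2)
  b <- simulate_profile(params, seed = 6, "a")
  expect_false(identical(a1$segments, b$segments))
  ## profiles tile each chromosome end to end
  for (ch in unique(a1$segments$chrom)) {
    seg <- a1$segments[a1$segments$chrom == ch, ]
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], params$chromosome_length)
    if (nrow(seg) > 1)
      expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
})

test_that("a one-segment chromosome spans it fully; states follow weights", {
  params <- sim_params(n_chromosomes = 1, chromosome_length = 1e6,
                       n_segments = c(1, 1))
  prof <- simulate_profile(params, seed = 3)
  expect_equal(nrow(prof$segments), 1L)
  expect_equal(prof$segments$end - prof$segments$start, 1e6)
  ## degenerate state distribution: all mass on copy state 2
  deg <- sim_params(n_chromosomes = 1, chromosome_length = 1e6,
                    n_segments = c(3, 6),
                    copy_state_weights = c(0, 0, 1))
  draws <- unlist(lapply(1:50, function(i)
    simulate_profile(deg, seed = i)$segments$copy_number))
  expect_true(all(draws == 2))
})

test_that("ploidy_scale multiplies the drawn integer states", {
  base <- sim_params(n_chromosomes = 2, chromosome_length = 1e6)
  scaled <- sim_params(n_chromosomes = 2, chromosome_length = 1e6,
                       ploidy_scale = 2)
  p1 <- simulate_profile(base, seed = 44)
  p2 <- simulate_profile(scaled, seed = 44)
  expect_equal(p2$segments$copy_number, 2 * p1$segments$copy_number)
})

test_that("the identity perturbation returns the profile unchanged", {
  prof <- simulate_profile(small_params(), seed = 8, "p")
  sister <- perturb_profile(prof, boundary_jitter = 0, noise_fraction = 0,
                            ploidy_shift = 1, seed = 9, suffix = "")
  expect_equal(sister$segments, prof$segments)
})

test_that("a pure ploidy shift doubles every copy number", {
  prof <- simulate_profile(small_params(), seed = 8, "p")
  doubled <- perturb_profile(prof, ploidy_shift = 2, seed = 9)
  expect_equal(doubled$segments$copy_number,
               2 * prof$segments$copy_number)
  expect_equal(doubled$segments$start, prof$segments$start)
})

test_that("boundary jitter keeps segments valid and chromosome ends fixed", {
  params <- small_params()
  for (i in 1:10) {
    prof <- simulate_profile(params, seed = 100 + i, "p")
    sister <- perturb_profile(prof, boundary_jitter = 1e6, seed = 200 + i)
    expect_silent(cnmatch:::validate_segments(sister))
    for (ch in unique(sister$segments$chrom)) {
      seg <- sister$segments[sister$segments$chrom == ch, ]
      expect_equal(seg$start[1], 0)
      expect_equal(seg$end[nrow(seg)], params$chromosome_length)
    }
  }
})

test_that("segmental noise covers close to the requested genome fraction", {
  ## 100 equal-length CN-2 segments; measure the fraction actually hit
  prof <- cn_segments("flat", rep("1", 100),
                      start = seq(1, by = 1e5, length.out = 100),
                      end = seq(1e5, by = 1e5, length.out = 100),
                      copy_number = rep(2, 100))
  cover <- vapply(1:100, function(s) {
    pert <- perturb_profile(prof, noise_fraction = 0.5,
                            noise_magnitude = 1, seed = s)
    changed <- pert$segments$copy_number != prof$segments$copy_number
    sum((prof$segments$end - prof$segments$start)[changed]) /
      sum(prof$segments$end - prof$segments$start)
  }, numeric(1))
  expect_true(all(abs(cover - 0.5) <= 0.05))
})

test_that("invalid perturbation fractions are rejected", {
  prof <- simulate_profile(small_params(), seed = 8)
  expect_error(perturb_profile(prof, noise_fraction = 1.5, seed = 1),
               "noise_fraction")
  expect_error(perturb_profile(prof, ploidy_shift = 0, seed = 1),
               "ploidy_shift")
  expect_error(perturb_profile(prof, noise_fraction = 0.1), "seed")
})
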