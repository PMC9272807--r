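test_that("every metric scores a profile against itself as a perfect match", {
  p <- toy_profile(c(2, 2, 3, 3, 1, 4))
  expect_equal(cn_similarity(p, p, "pearson")$score, 1)
  expect_equal(cn_similarity(p, p, "cosine")$score, 1)
  expect_equal(cn_similarity(p, p, "manhattan")$score, 0)
  expect_equal(cn_similarity(p, p, "euclidean")$score, 0)
})

test_that("hand-computed scores match on a one-bin difference", {
  x <- toy_profile(c(2, 2, 3, 3), "x")
  y <- toy_profile(c(2, 2, 2, 3), "y")
  expect_equal(cn_similarity(x, y, "manhattan")$score, 1)
  expect_equal(cn_similarity(x, y, "euclidean")$score, 1)
  expect_equal(cn_similarity(x, y, "pearson")$score,
               cor(c(2, 2, 3, 3), c(2, 2, 2, 3)))
})

test_that("whole-genome doubling fools the absolute distances only", {
  x <- toy_profile(c(2, 2, 3, 3), "x")
  y <- toy_profile(c(4, 4, 6, 6), "y")  # y = 2x
  expect_equal(cn_similarity(x, y, "pearson")$score, 1)
  expect_equal(cn_similarity(x, y, "cosine")$score, 1)
  ## Manhattan sees the ploidy shift: sum|x - 2x| = sum|x| = 10
  expect_equal(cn_similarity(x, y, "manhattan")$score, 10)
})

test_that("all four metrics agree with brute-force formulas and are symmetric", {
  set.seed(7)
  for (i in 1:50) {
    x <- toy_profile(round(runif(20, 0, 8), 3), "x")
    y <- toy_profile(round(runif(20, 0, 8), 3), "y")
    for (m in c("pearson", "manhattan", "euclidean", "cosine")) {
      s <- cn_similarity(x, y, m)$score
      expect_equal(s, oracle_metric(x$values, y$values, m),
                   tolerance = 1e-12)
      expect_equal(cn_similarity(y, x, m)$score, s, tolerance = 1e-12)
    }
    ## L2 <= L1 on every pair
    expect_lte(cn_similarity(x, y, "euclidean")$score,
               cn_similarity(x, y, "manhattan")$score)
  }
})

test_that("scale and shift invariance separate the metric families", {
  set.seed(8)
  v <- sample(0:6, 30, replace = TRUE)
  x <- toy_profile(v, "x")
  for (c_scale in c(0.5, 2, 3.7)) {
    scaled <- toy_profile(c_scale * v + 1, "s")
    expect_equal(cn_similarity(x, scaled, "pearson")$score, 1)
    pure <- toy_profile(c_scale * v, "p")
    expect_equal(cn_similarity(x, pure, "cosine")$score, 1)
    expect_equal(cn_similarity(x, pure, "manhattan")$score,
                 abs(c_scale - 1) * sum(abs(v)))
  }
})

test_that("degenerate inputs raise errors instead of silent NaN", {
  flat <- toy_profile(rep(2, 4), "flat")
  var1 <- toy_profile(c(1, 2, 3, 4), "v")
  zero <- toy_profile(rep(0, 4), "zero")
  expect_error(cn_similarity(flat, var1, "pearson"), "constant profile")
  expect_error(cn_similarity(zero, var1, "cosine"), "all-zero")
  expect_error(cn_similarity(toy_profile(2), toy_profile(3)),
               "at least 2")
})

test_that("missing bins are excluded pairwise", {
  a <- toy_profile(c(2, NA, 3, 5, 1), "a")
  b <- toy_profile(c(2, 4, 3, NA, 2), "b")
  s <- cn_similarity(a, b, "manhattan")
  expect_equal(s$n_bins_compared, 3L)  # bins 1, 3, 5
  expect_equal(s$score, abs(1 - 2))
  expect_equal(pct_genome_difference(a, b), 100 * 1 / 3)
})

test_that("percentage genome difference counts bins beyond tolerance", {
  x <- toy_profile(c(2, 2, 3, 3), "x")
  y <- toy_profile(c(2, 2, 2, 3), "y")
  expect_equal(pct_genome_difference(x, x), 0)
  expect_equal(pct_genome_difference(x, y, 0.5), 25)
  expect_equal(pct_genome_difference(y, x, 0.5), 25)  # symmetric
  near <- toy_profile(c(2.4, 2.4, 3.4, 3.4), "n")
  expect_equal(pct_genome_difference(x, near, 0.5), 0)
  expect_error(pct_genome_difference(x, y, -0.1), "non-negative")
})

test_that("percentage genome difference is monotone in tolerance", {
  set.seed(12)
  x <- toy_profile(runif(50, 0, 6), "x")
  y <- toy_profile(runif(50, 0, 6), "y")
  tols <- c(0, 0.25, 0.5, 1, 2, 8)
  pcts <- vapply(tols, function(t) pct_genome_difference(x, y, t),
                 numeric(1))
  expect_true(all(diff(pcts) <= 0))
  expect_equal(pcts[length(pcts)], 0)  # tolerance beyond the range
})

test_that("empirical p-values follow the add-one counting definition", {
  expect_equal(empirical_pvalue(0.9, c(0.1, 0.2, 0.3),
                                higher_is_better = TRUE), 0.25)
  ## a tie with the most extreme null value counts as extreme
  expect_equal(empirical_pvalue(0.3, c(0.1, 0.2, 0.3),
                                higher_is_better = TRUE), 0.5)
  ## best possible distance against any positive null of size n
  for (n in c(1, 9, 99))
    expect_equal(empirical_pvalue(0, runif(n, 0.1, 5),
                                  higher_is_better = FALSE), 1 / (n + 1))
  expect_error(empirical_pvalue(1, numeric(0), higher_is_better = TRUE),
               "non-empty")
  ## orientation travels with a cn_similarity result
  p <- toy_profile(c(1, 2, 3, 4), "p")
  s <- cn_similarity(p, p, "manhattan")
  expect_equal(empirical_pvalue(s, c(1, 2, 3)), 0.25)
})
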