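## two well-separated exposure groups: group 1 loads on s1, group 2 on s4
two_group_exposures <- function(n_per_group = 10, jitter = 0.01,
                                n_sig = 7, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_group
  m <- matrix(stats::runif(n * n_sig, 0, jitter), n, n_sig)
  m[seq_len(n_per_group), 1] <- m[seq_len(n_per_group), 1] + 1
  m[n_per_group + seq_len(n_per_group), 4] <-
    m[n_per_group + seq_len(n_per_group), 4] + 1
  m <- m / rowSums(m)
  dimnames(m) <- list(sprintf("cell%02d", seq_len(n)),
                      paste0("s", seq_len(n_sig)))
  m
}

test_that("exposure cosine matches the dot-product formula", {
  e <- c(0.5, 0.5, 0, 0, 0, 0, 0)
  expect_equal(exposure_cosine(e, e), 1)
  expect_equal(exposure_cosine(c(1, 0, 0), c(0, 1, 0)), 0)
  ## oracle: 0.48 / 0.52 = 0.923077
  expect_equal(round(exposure_cosine(c(0.6, 0.4), c(0.4, 0.6)), 4), 0.9231)
  expect_error(exposure_cosine(c(1, 0), c(1, 0, 0)), "length")
  expect_error(exposure_cosine(c(0, 0), c(1, 0)), "all-zero")
})

test_that("exposure matrices renormalize small row-sum drift, reject large", {
  m <- matrix(c(0.5, 0.5005, 0.25, 0.7495), 2, 2, byrow = TRUE)
  v <- validate_exposures(m)
  expect_equal(rowSums(v), c(1, 1))
  bad <- matrix(c(0.5, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_error(validate_exposures(bad), "sums to")
  neg <- matrix(c(-0.1, 1.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(validate_exposures(neg), "non-negative")
})

test_that("k-means recovers two well-separated exposure groups exactly", {
  m <- two_group_exposures()
  cl <- cluster_exposures(m, k = 2, seed = 11)
  truth <- rep(1:2, each = 10)
  ## label-permutation-proof agreement with the generating partition
  agreement <- max(mean((cl$labels == truth)),
                   mean((cl$labels == 3 - truth)))
  expect_equal(agreement, 1)
  ## centroids are the means of their members
  for (g in 1:2)
    expect_equal(unname(cl$centroids[g, ]),
                 unname(colMeans(m[cl$labels == g, , drop = FALSE])),
                 tolerance = 1e-10)
  ## centroid rows stay compositional
  expect_equal(unname(rowSums(cl$centroids)), c(1, 1), tolerance = 1e-6)
})

test_that("clustering is deterministic given the seed", {
  m <- two_group_exposures(jitter = 0.3)
  a <- cluster_exposures(m, k = 3, seed = 99, n_restarts = 10)
  b <- cluster_exposures(m, k = 3, seed = 99, n_restarts = 10)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
})

test_that("k = n gives singleton clusters with objective 0; bad k errors", {
  m <- two_group_exposures(n_per_group = 3)
  cl <- cluster_exposures(m, k = 6, seed = 2)
  expect_equal(sort(unname(cl$labels)), 1:6)
  expect_equal(cl$objective, 0)
  expect_error(cluster_exposures(m, k = 1, seed = 2), "k")
  expect_error(cluster_exposures(m, k = 7, seed = 2), "k")
  expect_error(cluster_exposures(m, k = 2), "seed")
})

test_that("top_variable_signatures ranks by centroid variance", {
  ## hand-built assignment: only s2 and s5 vary across centroids
  cent <- matrix(0.2, 2, 5, dimnames = list(NULL, paste0("s", 1:5)))
  cent[, 2] <- c(0.1, 0.5)
  cent[, 5] <- c(0.3, 0.2)
  asg <- structure(list(k = 2L, labels = c(a = 1L, b = 2L),
                        centroids = cent, seed = 1L, objective = 0),
                   class = "cn_clusters")
  expect_equal(top_variable_signatures(asg, 2), c("s2", "s5"))
  ## identical centroids: all variances tie, signature order decides
  flat <- asg
  flat$centroids <- matrix(0.2, 2, 5, dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(top_variable_signatures(flat, 2), c("s1", "s2"))
  ## 3 clusters, s1 spread widest -> ranked first (hand variance check)
  cent3 <- matrix(0.3, 3, 3, dimnames = list(NULL, paste0("s", 1:3)))
  cent3[, 1] <- c(0.1, 0.5, 0.9)
  cent3[, 2] <- c(0.29, 0.30, 0.31)
  asg3 <- structure(list(k = 3L, labels = c(a = 1L, b = 2L, c = 3L),
                         centroids = cent3, seed = 1L, objective = 0),
                    class = "cn_clusters")
  expect_equal(top_variable_signatures(asg3, 1), "s1")
  expect_error(top_variable_signatures(asg3, 0), "positive")
  ## relabeling clusters (permuting centroid rows) changes nothing
  perm <- asg3
  perm$centroids <- cent3[c(3, 1, 2), ]
  expect_equal(top_variable_signatures(perm, 2),
               top_variable_signatures(asg3, 2))
})

test_that("queries land in the nearest cluster, ties to the lowest index", {
  m <- two_group_exposures()
  cl <- cluster_exposures(m, k = 2, seed = 11)
  ## a query equal to a centroid belongs to that cluster
  expect_equal(assign_query_to_cluster(cl$centroids[2, ], cl), 2L)
  ## a sample from inside group 1's hull goes to group 1's cluster
  q <- colMeans(m[1:10, ])
  expect_equal(assign_query_to_cluster(q, cl),
               unname(cl$labels[["cell01"]]))
  ## exact tie -> lowest cluster index
  mid <- (cl$centroids[1, ] + cl$centroids[2, ]) / 2
  expect_equal(assign_query_to_cluster(mid, cl), 1L)
  expect_error(assign_query_to_cluster(c(0.5, 0.5), cl), "signatures")
})

test_that("the silhouette scan reports a width per candidate k", {
  m <- two_group_exposures(jitter = 0.05)
  scan <- silhouette_scan(m, ks = 2:4, seed = 7)
  expect_equal(scan$k, 2:4)
  expect_true(all(scan$mean_silhouette >= -1 & scan$mean_silhouette <= 1))
  ## two real groups: k = 2 should look best
  expect_equal(scan$k[which.max(scan$mean_silhouette)], 2L)
})

test_that("exposure matrices and cluster reports round-trip to disk", {
  m <- two_group_exposures()
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = rownames(m), m, check.names = FALSE),
            path, row.names = FALSE, quote = FALSE)
  back <- read_exposures(path)
  expect_equal(back, m, tolerance = 1e-6)
  cl <- cluster_exposures(back, k = 2, seed = 11)
  dir <- tempfile()
  files <- write_cluster_report(cl, back, dir, query_id = "cell01")
  expect_true(all(file.exists(files)))
  rep <- read.csv(files[["report"]])
  expect_equal(sum(rep$is_query), 1L)
  expect_equal(rep$cluster[rep$sample == "cell01"],
               unname(cl$labels[["cell01"]]))
  scatter <- read.csv(files[["scatter"]])
  expect_equal(sum(scatter$kind == "centroid"), 2L)
  expect_error(write_cluster_report(cl, back, dir, query_id = "nope"),
               "nope")
})
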