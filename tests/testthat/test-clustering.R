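test_that("k-means handles the degenerate and separable cases", {
  set.seed(5)
  H <- matrix(rnorm(40), 20, 2)
  s1 <- kmeans_cluster(H, 1, seed = 1)
  expect_equal(as.vector(s1$centroids), colMeans(H))
  expect_equal(s1$inertia, sum(sweep(H, 2, colMeans(H))^2))
  sn <- kmeans_cluster(H, nrow(H), seed = 1)
  expect_equal(sn$inertia, 0, tolerance = 1e-12)
  blobs <- make_blobs(n_per = 40, sd = 0.5)   # 10 SDs apart
  s2 <- kmeans_cluster(blobs$X, 2, seed = 3)
  expect_equal(adjusted_rand_index(s2$labels, blobs$labels), 1)
  expect_error(kmeans_cluster(H, 21), "between 1 and n")
})

test_that("k-means inertia is non-increasing across Lloyd iterations and
           matches the reference implementation", {
  blobs <- make_blobs(n_per = 50, centers = rbind(c(0, 0), c(4, 0), c(0, 4)),
                      sd = 1, seed = 11)
  sol <- kmeans_cluster(blobs$X, 3, seed = 2)
  expect_true(all(diff(sol$inertia_trace) <= 1e-9))
  ref <- stats::kmeans(blobs$X, centers = 3, nstart = 25,
                       algorithm = "Lloyd", iter.max = 100)
  expect_equal(sol$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("Ward AHC reproduces hand-computable and brute-force merges", {
  H <- matrix(c(0, 1, 10), 3, 1)
  s <- ahc_ward(H, 2)
  expect_equal(s$labels[1], s$labels[2])
  expect_false(s$labels[1] == s$labels[3])
  expect_equal(ahc_ward(H, 3)$n_k, 3L)
  expect_length(unique(ahc_ward(H, 3)$labels), 3)
  # merge heights are non-decreasing (ultrametric monotonicity of Ward)
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  s20 <- ahc_ward(X, 4)
  expect_true(all(diff(s20$merge_history$height) >= -1e-9))
})

test_that("Ward AHC partitions equal the exhaustive oracle on random instances", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    oracle <- oracle_ward_partitions(X)
    for (k in 2:(n - 1)) {
      expect_true(same_partition(ahc_ward(X, k)$labels, oracle[[k]]),
                  label = sprintf("seed %d, n %d, k %d", seed, n, k))
    }
  }
  # one larger instance, a few cut levels
  set.seed(99)
  X <- matrix(rnorm(30 * 3), 30, 3)
  oracle <- oracle_ward_partitions(X)
  for (k in c(2, 3, 5, 8)) {
    expect_true(same_partition(ahc_ward(X, k)$labels, oracle[[k]]))
  }
})

test_that("silhouette matches its definition, bounds and edge cases", {
  H <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(silhouette_score(H, lab), 0.99, tolerance = 0.005)
  expect_error(silhouette_score(H, rep(1, 4)), "single cluster")
  set.seed(13)
  X <- matrix(rnorm(60 * 2), 60, 2)
  lab_r <- sample(rep(1:2, 30))
  s <- silhouette_score(X, lab_r)
  expect_lt(abs(s), 0.1)
  expect_gte(s, -1); expect_lte(s, 1)
  expect_equal(s, oracle_silhouette(X, lab_r))
  # permutation invariance
  perm <- c(2, 1)
  expect_equal(silhouette_score(X, perm[lab_r]), s)
})

test_that("Davies-Bouldin matches the hand-computed value and the oracle", {
  H <- matrix(c(0, 2, 10, 12), 4, 1)
  expect_equal(davies_bouldin(H, c(1, 1, 2, 2)), 0.2)
  # widely separated tight blobs: index near 0
  far <- make_blobs(n_per = 20, centers = rbind(c(0, 0), c(1000, 0)), sd = 0.1)
  expect_lt(davies_bouldin(far$X, far$labels), 0.01)
  set.seed(14)
  X <- matrix(rnorm(25 * 2), 25, 2)
  for (k in 2:4) {
    lab <- kmeans_cluster(X, k, seed = k)$labels
    expect_equal(davies_bouldin(X, lab), oracle_davies_bouldin(X, lab))
    expect_equal(davies_bouldin(X, (lab %% k) + 1),
                 davies_bouldin(X, lab))  # relabeling invariance
  }
  expect_warning(davies_bouldin(rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
                                c(1, 1, 2, 2)), "coincident")
})

test_that("clustering BIC matches the oracle and penalizes useless clusters", {
  set.seed(15)
  X <- matrix(rnorm(30 * 2), 30, 2)
  for (k in 2:4) {
    lab <- kmeans_cluster(X, k, seed = k)$labels
    expect_equal(bic_clustering(X, lab), oracle_bic(X, lab))
  }
  # same fit, more clusters -> penalty dominates
  Xdup <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  lab2 <- rep(1:2, each = 10)
  lab4 <- c(rep(1, 5), rep(2, 5), rep(3, 5), rep(4, 5))
  expect_lt(bic_clustering(Xdup, lab2), bic_clustering(Xdup, lab4))
  blobs <- make_blobs(n_per = 30, sd = 0.5)
  expect_lt(bic_clustering(blobs$X, blobs$labels),
            bic_clustering(blobs$X, rep(1, 60)))
})

test_that("elbow detection finds the bend, with documented tie and fallback", {
  expect_equal(elbow_point(c(10, 4, 3.5, 3.4), k = 2:5), 3)
  expect_warning(k <- elbow_point(c(10, 8, 6, 4), k = 2:5), "no clear elbow")
  expect_equal(k, 3)
  expect_equal(elbow_point(c(9, 3, 2.8), k = 2:4), 3)
  expect_error(elbow_point(c(1, 2), k = 2:3), "at least 3")
})

test_that("cluster-number selection agrees across indices on separable data", {
  blobs <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(12, 0)), sd = 0.6,
                      seed = 16)
  sel <- select_n_clusters(blobs$X, 2:6, seed = 1)
  expect_equal(sel$k_star, 2L)
  expect_equal(unname(sel$votes[c("silhouette", "davies_bouldin")]), c(2L, 2L))
  expect_equal(sort(unique(sel$cvi_table$k)), 2:6)
  expect_setequal(unique(sel$cvi_table$method), c("ahc_ward", "kmeans"))
  expect_true(all(sel$cvi_table$silhouette >= -1 & sel$cvi_table$silhouette <= 1))
  expect_true(all(sel$cvi_table$davies_bouldin >= 0))
})
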