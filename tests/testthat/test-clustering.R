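blobs <- function(centers, n_each, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(stats::rnorm(n_each * ncol(centers), sd = sd),
                 ncol = ncol(centers)), 2, centers[i, ], `+`)))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_each))
}

test_that("five well-separated blobs are recommended by all three scores", {
  ctr <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5), c(5, 5, 5))
  b <- blobs(ctr, 100, sd = 0.1, seed = 5)
  ks <- select_k(b$x, 3:11, seed = 0)
  expect_identical(unname(ks$recommended["silhouette"]), 5L)
  expect_identical(unname(ks$recommended["calinski_harabasz"]), 5L)
  expect_identical(unname(ks$recommended["elbow"]), 5L)
  expect_identical(ks$consensus_k, 5L)
  expect_gte(max(ks$silhouette), 0.8)
})

test_that("two blobs maximize the silhouette at k = 2", {
  b <- blobs(rbind(c(-3, 0), c(3, 0)), 150, sd = 0.3, seed = 6)
  ks <- select_k(b$x, 2:6, seed = 0)
  expect_true(all(ks$silhouette[1] > ks$silhouette[-1]))
})

test_that("k_range outside [2, n-1] is rejected", {
  set.seed(7)
  x <- matrix(stats::rnorm(20), ncol = 2)
  expect_error(select_k(x, 3:11, seed = 0), "k_range")
})

test_that("k-means recovers ground truth and is deterministic", {
  b <- blobs(rbind(c(-5, 0), c(5, 0)), 100, sd = 0.5, seed = 8)
  cm <- fit_kmeans(b$x, 2, seed = 0)
  expect_equal(cm$labels, b$truth)   # relabeled by ascending PC1
  cm2 <- fit_kmeans(b$x, 2, seed = 0)
  expect_identical(cm$labels, cm2$labels)
  expect_identical(cm$centroids, cm2$centroids)
  expect_true(all(diff(cm$centroids[, 1]) > 0))
})

test_that("restarted k-means matches the best of many random starts", {
  set.seed(9)
  x <- matrix(stats::rnorm(60 * 2), ncol = 2)
  cm <- fit_kmeans(x, 4, seed = 0, n_init = 10)
  best <- Inf
  for (i in 1:1000) {
    km <- suppressWarnings(
      stats::kmeans(x, centers = x[sample.int(60, 4), ], iter.max = 100,
                    algorithm = "Lloyd"))
    best <- min(best, km$tot.withinss)
  }
  expect_lte(cm$inertia, best * (1 + 1e-9))
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rep(c(0, 1), each = 10), ncol = 2)
  expect_error(fit_kmeans(x, 5, seed = 0), "distinct")
  expect_error(fit_kmeans(matrix(stats::rnorm(8), ncol = 2), 1, seed = 0),
               "at least 2")
})

test_that("cluster labels are invariant to row permutation", {
  b <- blobs(rbind(c(0, 0), c(4, 0), c(0, 4)), 60, sd = 0.2, seed = 10)
  cm <- fit_kmeans(b$x, 3, seed = 0)
  set.seed(11)
  perm <- sample.int(nrow(b$x))
  cmp <- fit_kmeans(b$x[perm, ], 3, seed = 0)
  expect_identical(cmp$labels, cm$labels[perm])
})

test_that("cluster profiles aggregate sizes and moments correctly", {
  b <- blobs(rbind(c(0, 0, 0), c(6, 0, 0)), 80, sd = 0.3, seed = 12)
  colnames(b$x) <- paste0("PC", 1:3)
  cm <- fit_kmeans(b$x, 2, seed = 0)
  feats <- data.frame(L = stats::rnorm(160) + b$truth, S = stats::runif(160))
  prof <- profile_clusters(cm, features = feats, scores = b$x)
  expect_equal(sum(prof$n[prof$variable == "PC1"]), 160)
  # per-cluster mean equals direct aggregation
  m1 <- prof$mean[prof$cluster == 1 & prof$variable == "L"]
  expect_equal(m1, mean(feats$L[cm$labels == 1]))
  expect_error(profile_clusters(cm, features = feats[1:10, ]), "mismatch")
})

test_that("KDE shift maps conserve mass and detect translation", {
  set.seed(13)
  s <- cbind(stats::rnorm(1000), stats::rnorm(1000))
  lab <- rep(1L, 1000)
  grp <- rep(c("control", "learner"), each = 500)

  null_map <- kde_shift(s, lab, grp, 1, group_order = c("control", "learner"))
  expect_lt(sqrt(sum(null_map$shift^2)), 0.1)
  for (g in names(null_map$kde)) {
    kd <- null_map$kde[[g]]
    mass <- sum(kd$z) * diff(kd$x[1:2]) * diff(kd$y[1:2])
    expect_equal(mass, 1, tolerance = 1e-6)
  }

  s2 <- s
  s2[grp == "learner", 1] <- s2[grp == "learner", 1] + 1
  shifted <- kde_shift(s2, lab, grp, 1, group_order = c("control", "learner"))
  expect_equal(unname(shifted$shift), c(1, 0), tolerance = 0.1)

  tiny <- kde_shift
  expect_error(kde_shift(s[1:11, ], rep(1L, 11),
                         c("a", rep("b", 10)), 1), "fewer than")
})

test_that("five-family spine populations are recovered end to end", {
  pop <- recovery_population(n_per_family = 40L, seed = 11)
  ft <- population_features(pop)
  pruned <- correlation_prune(ft)
  std <- standardize(pruned)
  pca <- fit_pca(std$data)
  cm <- fit_kmeans(pca$scores, 5, seed = 0)
  ari <- mclust::adjustedRandIndex(cm$labels, ft$family)
  expect_gte(ari, 0.8)
})
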