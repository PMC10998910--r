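# builds a 10-feature table with the redundancy structure seen in spine
# data: AD tracks L, V and HV track S, MC and GC track 1/L
synthetic_feature_table <- function(n = 400, seed = 21) {
  set.seed(seed)
  L <- stats::rlnorm(n, 0.5, 0.4)
  S <- stats::rlnorm(n, 2, 0.5)
  data.frame(
    L = L,
    AD = L * (1 + stats::rnorm(n, 0, 0.01)),
    S = S,
    V = 0.12 * S * (1 + stats::rnorm(n, 0, 0.02)),
    HV = 0.15 * S * (1 + stats::rnorm(n, 0, 0.02)),
    HR = stats::rlnorm(n, -0.6, 0.3),
    CVD = stats::runif(n, 0.2, 0.5),
    OA = stats::runif(n, 0.4, 1.2),
    MC = 3 - 0.8 * L + stats::rnorm(n, 0, 0.03),
    GC = 5 - 0.4 * S + stats::rnorm(n, 0, 0.05))
}

test_that("correlation pruning reproduces the retained five-feature set", {
  tab <- synthetic_feature_table()
  pruned <- correlation_prune(tab)
  kept <- intersect(feature_priority_default, names(pruned))
  expect_setequal(kept, c("L", "S", "HR", "CVD", "OA"))
  expect_true(all(c("AD", "V", "HV") %in% attr(pruned, "dropped")))
  expect_gte(attr(pruned, "correlations")["L", "AD"], 0.9)
})

test_that("a duplicated column is dropped, the original kept", {
  set.seed(2)
  tab <- data.frame(L = stats::rnorm(50))
  tab$AD <- tab$L
  tab$CVD <- stats::rnorm(50)
  pruned <- correlation_prune(tab)
  expect_named(pruned, c("L", "CVD"))
})

test_that("independent columns survive pruning", {
  set.seed(3)
  tab <- as.data.frame(matrix(stats::rnorm(1000 * 5), ncol = 5))
  names(tab) <- c("L", "S", "HR", "CVD", "OA")
  pruned <- correlation_prune(tab)
  expect_identical(length(attr(pruned, "dropped")), 0L)
})

test_that("pruning rejects constant columns and is order-stable", {
  tab <- synthetic_feature_table(n = 200)
  bad <- tab; bad$CVD <- 1
  expect_error(correlation_prune(bad), "CVD")

  set.seed(8)
  perm <- sample.int(nrow(tab))
  kept1 <- names(correlation_prune(tab))
  kept2 <- names(correlation_prune(tab[perm, ]))
  expect_identical(kept1, kept2)
})

test_that("standardization gives mean 0, population sd 1, reusable params", {
  tab <- data.frame(L = c(1, 3), S = c(0, 10))
  out <- standardize(tab)
  expect_equal(out$data$L, c(-1, 1))

  set.seed(4)
  tab2 <- as.data.frame(matrix(stats::rnorm(600), ncol = 3))
  names(tab2) <- c("L", "S", "HR")
  out2 <- standardize(tab2)
  z <- as.matrix(out2$data)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_equal(unname(sqrt(colMeans(sweep(z, 2, colMeans(z))^2))),
               rep(1, 3), tolerance = 1e-10)

  again <- standardize(tab2, params = out2$params)
  expect_equal(again$data, out2$data)

  const <- data.frame(L = rep(2, 5), S = 1:5)
  expect_error(standardize(const), "zero-variance")
})

test_that("PCA captures planar data exactly and keeps orthogonality", {
  set.seed(6)
  basis <- qr.Q(qr(matrix(stats::rnorm(25), 5)))[, 1:2]
  x <- matrix(stats::rnorm(400), ncol = 2) %*% t(basis)
  df <- as.data.frame(x)
  names(df) <- c("L", "S", "HR", "CVD", "OA")
  model <- fit_pca(df, n_components = 5)
  expect_equal(sum(model$explained_variance_ratio[1:2]), 1,
               tolerance = 1e-9)
  # reconstruction from all components
  recon <- model$scores %*% model$loadings
  recon <- sweep(recon, 2, -model$center)
  expect_equal(unname(recon), unname(x), tolerance = 1e-9)
})

test_that("isotropic Gaussian data spreads variance evenly", {
  set.seed(10)
  df <- as.data.frame(matrix(stats::rnorm(50000), ncol = 5))
  names(df) <- c("L", "S", "HR", "CVD", "OA")
  model <- fit_pca(standardize(df)$data, n_components = 5)
  expect_equal(unname(model$explained_variance_ratio), rep(0.2, 5),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("PCA is deterministic under row permutation (fixed signs)", {
  tab <- synthetic_feature_table(n = 300)
  std <- standardize(correlation_prune(tab))$data
  m1 <- fit_pca(std)
  set.seed(12)
  perm <- sample.int(nrow(std))
  m2 <- fit_pca(std[perm, ])
  expect_equal(m2$loadings, m1$loadings, tolerance = 1e-9)
  expect_equal(m2$scores[order(perm), ], m1$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(fit_pca(std, n_components = 10), "exceeds")
})

test_that("explained variance ratios are non-increasing and sum to 1", {
  tab <- synthetic_feature_table(n = 250, seed = 33)
  std <- standardize(correlation_prune(tab))$data
  m <- fit_pca(std, n_components = length(feature_columns(std)))
  evr <- m$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_equal(sum(evr), 1, tolerance = 1e-9)
  expect_true(all(evr >= 0 & evr <= 1))
})
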