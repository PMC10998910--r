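#' K-means in principal-component space
#'
#' Lloyd's algorithm with k-means++ seeding and `n_init` restarts; the run
#' with the lowest within-cluster sum of squares is kept. Cluster labels
#' are then relabeled by ascending centroid PC1 (first column), which makes
#' cluster identities deterministic and invariant to row permutation.
#'
#' @param scores numeric matrix of PC scores (rows = spines).
#' @param k number of clusters (`>= 2`, `< nrow(scores)`).
#' @param seed RNG seed controlling the restarts.
#' @param n_init number of k-means++ restarts.
#' @return list of class `cluster_model`: `k`, `centroids` (k x d, ordered
#'   by PC1), `labels` (1..k per row), `inertia`, `seed`, `n_init`.
#' @export
fit_kmeans <- function(scores, k, seed = 0L, n_init = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 2L) stop("k must be at least 2")
  if (n <= k) stop("need more points than clusters")
  if (nrow(unique(scores)) < k)
    stop("fewer than k distinct points")
  set.seed(as.integer(seed))
  best <- NULL
  for (rep in seq_len(n_init)) {
    centers <- kmeanspp_centers(scores, k)
    km <- tryCatch(
      stats::kmeans(scores, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        stats::kmeans(scores, centers = centers, iter.max = 200L,
                      algorithm = "Lloyd")))
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for all restarts")
  ord <- order(best$centers[, 1])
  relab <- match(best$cluster, ord)
  structure(list(k = as.integer(k),
                 centroids = best$centers[ord, , drop = FALSE],
                 labels = relab,
                 inertia = best$tot.withinss,
                 seed = as.integer(seed), n_init = as.integer(n_init)),
            class = "cluster_model")
}

# k-means++ seeding: first center uniform, then points drawn with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0)
      idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = probs)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: k = %d, inertia = %.4g>\n", x$k, x$inertia))
  print(round(x$centroids, 3))
  invisible(x)
}

#' Select the number of clusters
#'
#' Fits k-means for each candidate `k` and records the inertia (elbow
#' curve), the mean silhouette width and the Calinski-Harabasz score. The
#' recommendation per score is the silhouette argmax, the Calinski-Harabasz
#' argmax, and the elbow knee (the `k` whose inertia lies farthest from the
#' chord joining the first and last points of the curve); the consensus is
#' the majority, with ties resolved in favor of the silhouette winner.
#'
#' @param scores PC-score matrix.
#' @param k_range candidate cluster counts (default 3:11).
#' @param seed,n_init passed to [fit_kmeans()].
#' @return list of class `k_selection_report`.
#' @export
select_k <- function(scores, k_range = 3:11, seed = 0L, n_init = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within [2, n-1]")
  inertia <- sil <- ch <- numeric(length(k_range))
  dmat <- stats::dist(scores)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cm <- fit_kmeans(scores, k, seed = seed, n_init = n_init)
    inertia[i] <- cm$inertia
    sil[i] <- mean(cluster::silhouette(cm$labels, dmat)[, "sil_width"])
    ch[i] <- calinski_harabasz(scores, cm$labels)
  }
  rec <- c(silhouette = k_range[which.max(sil)],
           calinski_harabasz = k_range[which.max(ch)],
           elbow = k_range[elbow_knee(k_range, inertia)])
  tab <- sort(table(rec), decreasing = TRUE)
  consensus <- if (length(k_range) == 1L) k_range else {
    if (tab[1] > 1L) as.integer(names(tab)[1]) else rec[["silhouette"]]
  }
  structure(list(k_range = k_range, inertia = inertia, silhouette = sil,
                 calinski_harabasz = ch, recommended = rec,
                 consensus_k = as.integer(consensus)),
            class = "k_selection_report")
}

calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  gmean <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (c in unique(labels)) {
    xc <- x[labels == c, , drop = FALSE]
    cm <- colMeans(xc)
    ssb <- ssb + nrow(xc) * sum((cm - gmean)^2)
    ssw <- ssw + sum(sweep(xc, 2, cm)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# index of the point with maximum perpendicular distance to the chord
# joining the first and last points of the inertia curve
elbow_knee <- function(k_range, inertia) {
  p1 <- c(k_range[1], inertia[1])
  p2 <- c(k_range[length(k_range)], inertia[length(inertia)])
  v <- p2 - p1
  v <- v / sqrt(sum(v^2))
  d <- vapply(seq_along(k_range), function(i) {
    w <- c(k_range[i], inertia[i]) - p1
    abs(w[1] * v[2] - w[2] * v[1])
  }, 0)
  which.max(d)
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat("<k_selection_report>\n")
  print(data.frame(k = x$k_range, inertia = signif(x$inertia, 4),
                   silhouette = round(x$silhouette, 3),
                   calinski_harabasz = round(x$calinski_harabasz, 1)))
  cat(sprintf("  recommended: silhouette=%d, CH=%d, elbow=%d -> consensus %d\n",
              x$recommended[["silhouette"]],
              x$recommended[["calinski_harabasz"]],
              x$recommended[["elbow"]], x$consensus_k))
  invisible(x)
}

#' Per-cluster profiles
#'
#' Size and mean +/- SD of every principal component and every raw feature
#' for each cluster, the table used to attach a morphological reading
#' (stubby, mushroom, thin, ...) to each cluster.
#'
#' @param model a `cluster_model`.
#' @param features data.frame of raw features aligned with the model rows.
#' @param scores PC-score matrix aligned with the model rows.
#' @return data.frame with one row per (cluster, variable) giving n, mean
#'   and sd.
#' @export
profile_clusters <- function(model, features = NULL, scores = NULL) {
  labels <- model$labels
  vars <- list()
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != length(labels)) stop("row mismatch: scores vs labels")
    for (j in seq_len(ncol(scores)))
      vars[[colnames(scores)[j] %||% paste0("PC", j)]] <- scores[, j]
  }
  if (!is.null(features)) {
    if (nrow(features) != length(labels)) stop("row mismatch: features vs labels")
    for (nm in feature_columns(features)) vars[[nm]] <- features[[nm]]
  }
  if (length(vars) == 0L) stop("provide scores and/or features")
  out <- list()
  for (c in sort(unique(labels))) {
    sel <- labels == c
    for (nm in names(vars)) {
      out[[length(out) + 1L]] <- data.frame(
        cluster = c, n = sum(sel), variable = nm,
        mean = mean(vars[[nm]][sel]), sd = stats::sd(vars[[nm]][sel]))
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kernel-density shift map of one cluster between two groups
#'
#' For the members of one cluster, estimates a 2D Gaussian kernel density
#' over (PC1, PC2) separately per experimental group (Scott's bandwidth,
#' 100 x 100 grid over the pooled data range extended by three bandwidths)
#' and summarizes the morphological drift as the displacement of the
#' group centroids.
#'
#' @param scores PC-score matrix (first two columns used).
#' @param labels cluster labels aligned with `scores`.
#' @param groups group id per row (exactly two distinct values after
#'   subsetting, compared in the order given by `group_order`).
#' @param cluster_id the cluster to map.
#' @param group_order optional length-2 vector: reference group first; the
#'   shift vector is `centroid(second) - centroid(first)`.
#' @param gridsize grid points per axis.
#' @param min_n minimum members per group in the cluster.
#' @return list of class `shift_map`: per-group KDE grids (normalized to
#'   total mass 1 over the grid), centroids, and `shift`.
#' @export
kde_shift <- function(scores, labels, groups, cluster_id,
                      group_order = NULL, gridsize = 100L, min_n = 10L) {
  scores <- as.matrix(scores)
  sel <- labels == cluster_id
  if (!any(sel)) stop("empty cluster: ", cluster_id)
  xy <- scores[sel, 1:2, drop = FALSE]
  g <- as.character(groups[sel])
  glev <- if (is.null(group_order)) sort(unique(g)) else as.character(group_order)
  if (length(glev) != 2L) stop("exactly two groups are required")
  ns <- table(factor(g, levels = glev))
  if (any(ns < min_n))
    stop("fewer than ", min_n, " spines in cluster ", cluster_id,
         " for group(s): ", paste(glev[ns < min_n], collapse = ", "))
  # Scott bandwidth per axis on the pooled members; kde2d's h is 4x the
  # kernel sd, so scale accordingly
  scott <- function(v, n) stats::sd(v) * n^(-1 / 6)
  grids <- list(); cents <- list()
  bw_ref <- c(scott(xy[, 1], nrow(xy)), scott(xy[, 2], nrow(xy)))
  lims <- c(min(xy[, 1]) - 3 * bw_ref[1], max(xy[, 1]) + 3 * bw_ref[1],
            min(xy[, 2]) - 3 * bw_ref[2], max(xy[, 2]) + 3 * bw_ref[2])
  for (gg in glev) {
    m <- xy[g == gg, , drop = FALSE]
    h <- 4 * c(scott(m[, 1], nrow(m)), scott(m[, 2], nrow(m)))
    kd <- MASS::kde2d(m[, 1], m[, 2], h = h, n = gridsize, lims = lims)
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    kd$z <- kd$z / (sum(kd$z) * cell)   # unit mass over the grid
    grids[[gg]] <- kd
    cents[[gg]] <- colMeans(m)
  }
  structure(list(cluster = cluster_id, groups = glev, kde = grids,
                 centroids = cents,
                 shift = cents[[glev[2]]] - cents[[glev[1]]]),
            class = "shift_map")
}
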