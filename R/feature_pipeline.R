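#' Canonical feature names and pruning priority
#'
#' The ten descriptors in priority order for correlation pruning: widely
#' used descriptors are preferred, so Length is kept over Average Distance
#' and Surface over Volume and Hull Volume when they are near-duplicates.
#' With this order and threshold 0.9 on spine data the retained set is
#' Length, Surface, Hull Ratio, CVD and Open Angle.
#'
#' @export
feature_priority_default <- c("L", "S", "HR", "CVD", "OA",
                              "AD", "V", "HV", "MC", "GC")

feature_columns <- function(df, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_priority_default, names(df))
  if (length(features) == 0L) stop("no feature columns found")
  features
}

#' Drop highly correlated features
#'
#' Computes the Pearson correlation matrix of the feature columns and,
#' within any set of features pairwise correlated at `|r| >= threshold`,
#' keeps only the highest-priority one: features are visited in priority
#' order and a feature is dropped if it correlates at or above the
#' threshold with any feature already kept.
#'
#' @param df data.frame containing feature columns (metadata columns are
#'   passed through untouched).
#' @param threshold absolute Pearson correlation at or above which two
#'   features are considered redundant.
#' @param priority ordered character vector of feature names.
#' @return `df` with redundant feature columns removed; the correlation
#'   matrix and the dropped set are attached as attributes
#'   `correlations` and `dropped`.
#' @export
correlation_prune <- function(df, threshold = 0.9,
                              priority = feature_priority_default) {
  feats <- intersect(priority, names(df))
  if (length(feats) < 1L) stop("no feature columns found")
  x <- as.matrix(df[, feats, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(feats[sds == 0], collapse = ", "))
  cm <- stats::cor(x)
  kept <- character(0)
  for (f in feats) {
    if (length(kept) == 0L || all(abs(cm[f, kept]) < threshold))
      kept <- c(kept, f)
  }
  out <- df[, c(setdiff(names(df), feats), kept), drop = FALSE]
  attr(out, "correlations") <- cm
  attr(out, "dropped") <- setdiff(feats, kept)
  out
}

#' Standardize feature columns
#'
#' Centers each feature column to mean 0 and scales it to population
#' standard deviation 1 (divide-by-n), storing the per-column parameters
#' for reuse on new data.
#'
#' @param df data.frame with feature columns.
#' @param features feature column names; defaults to the known descriptor
#'   columns present.
#' @param params optional previously fitted `scaler_params`, applied as-is.
#' @return list with `data` (standardized data.frame) and `params`
#'   (`scaler_params`: per-column `mean` and `sd`).
#' @export
standardize <- function(df, features = NULL, params = NULL) {
  features <- feature_columns(df, features)
  x <- as.matrix(df[, features, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (is.null(params)) {
    mu <- colMeans(x)
    sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))   # population sd
    if (any(sdev == 0))
      stop("zero-variance column(s): ",
           paste(features[sdev == 0], collapse = ", "))
    params <- structure(list(features = features, mean = mu, sd = sdev),
                        class = "scaler_params")
  }
  z <- sweep(sweep(x, 2, params$mean), 2, params$sd, `/`)
  out <- df
  out[, features] <- z
  list(data = out, params = params)
}

#' Principal component analysis of standardized features
#'
#' Fits the principal axes of the (already standardized) feature matrix
#' and projects every spine onto the leading components. The sign of each
#' component is fixed by making its largest-magnitude loading positive, so
#' results are reproducible across runs and row orderings.
#'
#' @param df standardized data.frame (see [standardize()]).
#' @param n_components number of components to keep (default 3).
#' @param features feature column names.
#' @return list of class `pca_model` with `loadings` (components x
#'   features), `explained_variance_ratio`, `n_components`, `features`,
#'   and `scores` (spines x components, columns `PC1..PCk`).
#' @export
fit_pca <- function(df, n_components = 3L, features = NULL) {
  features <- feature_columns(df, features)
  x <- as.matrix(df[, features, drop = FALSE])
  if (n_components > length(features))
    stop("n_components exceeds the number of features")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(x, 2, pc$center) %*% rot[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(loadings = t(rot[, seq_len(n_components), drop = FALSE]),
                 explained_variance_ratio = evr[seq_len(n_components)],
                 explained_variance_ratio_full = evr,
                 n_components = as.integer(n_components),
                 features = features,
                 center = pc$center,
                 scores = scores),
            class = "pca_model")
}

#' Project new standardized data onto a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param df standardized data.frame with the model's feature columns.
#' @return scores matrix (rows x components).
#' @export
pca_transform <- function(model, df) {
  x <- as.matrix(df[, model$features, drop = FALSE])
  scores <- sweep(x, 2, model$center) %*% t(model$loadings)
  colnames(scores) <- paste0("PC", seq_len(model$n_components))
  scores
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components on %s>\n", x$n_components,
              paste(x$features, collapse = ", ")))
  cat(sprintf("  explained variance: %s (total %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", "),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}
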