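#' Pipeline configuration
#'
#' Bundles all settings of an end-to-end run. Input is either an existing
#' feature table (`feature_csv` or `features`), a directory of pre-cut
#' spine meshes (`mesh_dir`, with an optional metadata CSV), or a synthetic
#' population request (`simulate`).
#'
#' @param out_dir output directory (created if missing).
#' @param features data.frame of spine features with metadata columns, or
#'   `NULL`.
#' @param feature_csv path to a feature CSV, or `NULL`.
#' @param mesh_dir directory of PLY/OBJ/STL spine meshes, or `NULL`.
#' @param mesh_metadata optional CSV path with one row per mesh file
#'   (columns `file`, `group`, `mouse_id`, `cell_id`).
#' @param simulate `NULL`, or a list with `n_per_family`, `regimes` (3 or
#'   5) and optionally `groups` (named list: group label -> multiplicative
#'   size shift applied to that group's spines).
#' @param threshold correlation-pruning threshold.
#' @param priority feature priority order for pruning.
#' @param n_components PCA components (0 disables PCA: clustering runs on
#'   the standardized features, the robustness variant).
#' @param k fixed cluster count, or `NULL` to select via `k_range`.
#' @param k_range candidate cluster counts when `k` is `NULL`.
#' @param grouping grouping factor for the ICC (`"mouse"` or `"cell"`).
#' @param seed seed recorded in every output and used for all stochastic
#'   stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, features = NULL, feature_csv = NULL,
                            mesh_dir = NULL, mesh_metadata = NULL,
                            simulate = NULL, threshold = 0.9,
                            priority = feature_priority_default,
                            n_components = 3L, k = NULL, k_range = 3:11,
                            grouping = c("mouse", "cell"), seed = 0L) {
  grouping <- match.arg(grouping)
  if (is.null(features) && is.null(feature_csv) && is.null(mesh_dir) &&
      is.null(simulate))
    stop("config needs one of: features, feature_csv, mesh_dir, simulate")
  if (!is.null(feature_csv) && !file.exists(feature_csv))
    stop("validation error: feature_csv does not exist: ", feature_csv)
  if (!is.null(mesh_dir) && !dir.exists(mesh_dir))
    stop("validation error: mesh_dir does not exist: ", mesh_dir)
  structure(list(out_dir = out_dir, features = features,
                 feature_csv = feature_csv, mesh_dir = mesh_dir,
                 mesh_metadata = mesh_metadata, simulate = simulate,
                 threshold = threshold, priority = priority,
                 n_components = as.integer(n_components), k = k,
                 k_range = k_range, grouping = grouping,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the spine morphometry pipeline
#'
#' Executes the requested stages in order: obtain features (measure meshes,
#' load a CSV, or simulate a population), correlation-prune, standardize,
#' PCA, cluster (with cluster-number selection when `k` is not fixed),
#' profile clusters, and, when at least two groups are present, compute the
#' group statistics (per-feature t/d, per-cluster Agresti-Caffo, ICC).
#' All artifacts are written under `config$out_dir` together with a run
#' manifest carrying the seed and the config hash; re-running the same
#' config reproduces identical outputs.
#'
#' @param config a [pipeline_config].
#' @return the run manifest (list), invisibly; artifacts on disk:
#'   `features.csv`, `clusters.csv`, `model.json`, `report.json`,
#'   `report.txt`, `config.json`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "features"
  res <- tryCatch({
    feats <- pipeline_features(config)

    stage <- "prune"
    pruned <- correlation_prune(feats, threshold = config$threshold,
                                priority = config$priority)

    stage <- "standardize"
    std <- standardize(pruned)

    stage <- "pca"
    if (config$n_components > 0L) {
      pca <- fit_pca(std$data, n_components = config$n_components)
      scores <- pca$scores
    } else {
      pca <- NULL
      scores <- as.matrix(std$data[, feature_columns(std$data), drop = FALSE])
      colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    }

    stage <- "cluster"
    ksel <- NULL
    k <- config$k
    if (is.null(k)) {
      ksel <- select_k(scores, k_range = config$k_range, seed = config$seed)
      k <- ksel$consensus_k
    }
    cm <- fit_kmeans(scores, k, seed = config$seed)
    profile <- profile_clusters(cm, features = pruned, scores = scores)

    stage <- "stats"
    stats_out <- pipeline_stats(feats, pruned, cm, config)

    list(features = feats, pruned = pruned, scaler = std$params, pca = pca,
         scores = scores, k_selection = ksel, cluster_model = cm,
         profile = profile, stats = stats_out)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  write_pipeline_outputs(res, config)
}

pipeline_features <- function(config) {
  if (!is.null(config$features)) return(config$features)
  if (!is.null(config$feature_csv))
    return(utils::read.csv(config$feature_csv, stringsAsFactors = FALSE))
  if (!is.null(config$mesh_dir)) {
    files <- list.files(config$mesh_dir, "\\.(ply|obj|stl)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) stop("no mesh files in ", config$mesh_dir)
    meshes <- lapply(files, function(f) repair_mesh(load_mesh(f))$mesh)
    md <- data.frame(spine_id = seq_along(files), file = basename(files))
    if (!is.null(config$mesh_metadata)) {
      extra <- utils::read.csv(config$mesh_metadata, stringsAsFactors = FALSE)
      md <- merge(md, extra, by = "file", all.x = TRUE, sort = FALSE)
    }
    return(feature_table(meshes, md))
  }
  sim <- config$simulate
  regimes <- spine_family_regimes(sim$regimes %||% 3)
  groups <- sim$groups %||% list(control = 1)
  out <- list()
  for (gi in seq_along(groups)) {
    shift <- groups[[gi]]
    fams <- lapply(regimes, function(p)
      spine_params(p$family, head_radius = p$head_radius * shift,
                   neck_radius = p$neck_radius * shift,
                   neck_length = p$neck_length * shift,
                   mesh_resolution = p$mesh_resolution))
    pop <- make_population(n_per_family = sim$n_per_family %||% 50L,
                           families = fams, seed = config$seed + gi - 1L)
    out[[gi]] <- population_features(pop, group = names(groups)[gi])
  }
  do.call(rbind, out)
}

pipeline_stats <- function(feats, pruned, cm, config) {
  groups <- unique(as.character(feats$group %||% "all"))
  out <- list()
  if (length(groups) == 2L) {
    ga <- feats$group == groups[1]
    gb <- feats$group == groups[2]
    out$feature_tests <- compare_features(pruned[ga, , drop = FALSE],
                                          pruned[gb, , drop = FALSE])
    out$proportion_tests <- compare_cluster_distributions(
      cm$labels[ga], cm$labels[gb], cm$k)
    out$group_order <- groups
  }
  gid <- switch(config$grouping, mouse = feats$mouse_id, cell = feats$cell_id)
  if (!is.null(gid) && length(unique(gid)) >= 2L) {
    vcol <- intersect(c("V", "S", "L"), names(feats))[1]
    if (!is.na(vcol))
      out$icc <- tryCatch(icc_oneway(feats[[vcol]], gid),
                          error = function(e) NULL)
  }
  out
}

write_pipeline_outputs <- function(res, config) {
  od <- config$out_dir
  cfg_json <- file.path(od, "config.json")
  cfg <- config
  cfg$features <- if (is.null(config$features)) NULL else "<inline>"
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))

  utils::write.csv(res$features, file.path(od, "features.csv"),
                   row.names = FALSE)
  clustered <- res$pruned
  clustered$cluster <- res$cluster_model$labels
  for (j in seq_len(ncol(res$scores)))
    clustered[[colnames(res$scores)[j]]] <- round(res$scores[, j], 10)
  utils::write.csv(clustered, file.path(od, "clusters.csv"),
                   row.names = FALSE)

  model <- list(config_hash = cfg_hash, seed = config$seed,
                k = res$cluster_model$k,
                centroids = res$cluster_model$centroids,
                inertia = res$cluster_model$inertia,
                scaler = res$scaler[c("features", "mean", "sd")],
                pca = if (!is.null(res$pca))
                  res$pca[c("loadings", "explained_variance_ratio",
                            "features", "center")],
                k_selection = if (!is.null(res$k_selection))
                  res$k_selection[c("k_range", "inertia", "silhouette",
                                    "calinski_harabasz", "consensus_k")])
  jsonlite::write_json(model, file.path(od, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  report <- write_report(res, od, cfg_hash = cfg_hash, seed = config$seed)
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   n_spines = nrow(res$features),
                   files = c("features.csv", "clusters.csv", "model.json",
                             "report.json", "report.txt", "config.json"))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(results = res, report = report)))
}

#' Write the human-readable and JSON run report
#'
#' Five sections: group densities, per-feature tests, cluster profile,
#' per-cluster proportion tests, and k-selection scores; sections whose
#' inputs are absent are marked missing rather than dropped.
#'
#' @param res pipeline results (as assembled by [run_pipeline()]); a list
#'   that may contain `stats$densities`, `stats$feature_tests`, `profile`,
#'   `stats$proportion_tests`, `k_selection`.
#' @param out_dir directory for `report.json` and `report.txt`.
#' @param cfg_hash,seed provenance fields embedded in the report.
#' @return the report list, invisibly.
#' @export
write_report <- function(res, out_dir, cfg_hash = NA_character_, seed = NA) {
  missing_marker <- "section not computed in this run"
  sec <- function(x) if (is.null(x)) missing_marker else x
  report <- list(
    provenance = list(config_hash = cfg_hash, seed = seed),
    densities = sec(res$stats$densities),
    feature_tests = sec(res$stats$feature_tests),
    cluster_profile = sec(res$profile),
    proportion_tests = sec(res$stats$proportion_tests),
    k_selection = sec(if (!is.null(res$k_selection))
      res$k_selection[c("k_range", "silhouette", "calinski_harabasz",
                        "inertia", "consensus_k")]),
    icc = sec(if (!is.null(res$stats$icc)) unclass(res$stats$icc)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)

  txt <- c("spine morphometry run report",
           sprintf("config: %s  seed: %s", cfg_hash, seed), "")
  fmt_sec <- function(title, x) {
    c(sprintf("== %s ==", title),
      if (is.character(x) && length(x) == 1L) paste(" ", x)
      else utils::capture.output(print(x)), "")
  }
  txt <- c(txt,
           fmt_sec("group densities", report$densities),
           fmt_sec("feature tests", report$feature_tests),
           fmt_sec("cluster profile", report$cluster_profile),
           fmt_sec("cluster proportion tests", report$proportion_tests),
           fmt_sec("k selection", report$k_selection))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
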