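#' Spine density
#'
#' @param spine_count number of spines on a dendritic segment.
#' @param dendrite_length segment length in um.
#' @return density in spines/um.
#' @export
spine_density <- function(spine_count, dendrite_length) {
  if (any(dendrite_length <= 0)) stop("dendrite_length must be positive")
  spine_count / dendrite_length
}

#' Per-group density summary
#'
#' Aggregates per-cell densities into the group mean +/- SD with cell and
#' mouse counts, the form in which spine densities are reported.
#'
#' @param df data.frame with columns `group`, `mouse_id`, `spine_count`,
#'   `dendrite_length` (one row per cell).
#' @return data.frame per group: `mean_density`, `sd_density`, `n_cells`,
#'   `n_mice`.
#' @export
density_summary <- function(df) {
  dens <- spine_density(df$spine_count, df$dendrite_length)
  out <- lapply(split(seq_len(nrow(df)), df$group), function(ix)
    data.frame(group = df$group[ix[1]],
               mean_density = mean(dens[ix]),
               sd_density = stats::sd(dens[ix]),
               n_cells = length(ix),
               n_mice = length(unique(df$mouse_id[ix]))))
  rownames_reset(do.call(rbind, out))
}

rownames_reset <- function(df) { rownames(df) <- NULL; df }

#' Unpaired two-sample Student t-test
#'
#' Classical pooled-variance t-test, two-sided.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @return list with `t`, `df`, `p`.
#' @export
ttest_unpaired <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2L,
                                        p = 1))
    stop("degenerate input: zero variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Cohen's d effect size
#'
#' Standardized mean difference with the (n-1)-weighted pooled standard
#' deviation. The interpretation bands follow the convention that an
#' effect below 0.01 is very small and below 0.20 small.
#'
#' @param a,b numeric samples.
#' @return list with `cohens_d` and `interpretation`.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs n >= 2")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled SD: effect size undefined")
  d <- (mean(a) - mean(b)) / sp
  band <- cut(abs(d), c(-Inf, 0.01, 0.20, 0.50, 0.80, Inf),
              labels = c("very small", "small", "medium", "large",
                         "very large"), right = FALSE)
  list(cohens_d = d, interpretation = as.character(band))
}

#' Agresti-Caffo two-proportion test
#'
#' Adjusted Wald comparison of two independent proportions: one success
#' and one failure are added to each group (`p~ = (x+1)/(n+2)`), the
#' difference of adjusted proportions is tested with a normal z statistic,
#' and the companion 95% interval is `diff +/- 1.96 se`.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list of class `prop_test_result`: `p_tilde_1`, `p_tilde_2`,
#'   `diff`, `se`, `z`, `p_two_sided`, `ci95`.
#' @export
agresti_caffo <- function(x1, n1, x2, n2) {
  if (any(c(x1, x2) < 0) || x1 > n1 || x2 > n2 || n1 < 1 || n2 < 1)
    stop("invalid counts")
  p1 <- (x1 + 1) / (n1 + 2)
  p2 <- (x2 + 1) / (n2 + 2)
  se <- sqrt(p1 * (1 - p1) / (n1 + 2) + p2 * (1 - p2) / (n2 + 2))
  if (se == 0) stop("degenerate input: zero standard error")
  z <- (p1 - p2) / se
  structure(list(p_tilde_1 = p1, p_tilde_2 = p2, diff = p1 - p2, se = se,
                 z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
                 ci95 = c(p1 - p2 - 1.96 * se, p1 - p2 + 1.96 * se)),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("Agresti-Caffo: diff = %.4f (95%% CI %.4f..%.4f), z = %.3f, p = %.4g\n",
              x$diff, x$ci95[1], x$ci95[2], x$z, x$p_two_sided))
  invisible(x)
}

#' Compare cluster distributions between two groups
#'
#' One Agresti-Caffo test per cluster on the per-group membership counts.
#' Raw per-cluster p-values are reported by default (no multiplicity
#' correction); Holm adjustment can be requested.
#'
#' @param labels_a,labels_b cluster labels (integers in `1..k`) of the two
#'   groups.
#' @param k number of clusters.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per cluster: counts, percentages,
#'   adjusted difference, z and p.
#' @export
compare_cluster_distributions <- function(labels_a, labels_b, k,
                                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  na <- length(labels_a); nb <- length(labels_b)
  if (na == 0L || nb == 0L) stop("empty group")
  if (any(!labels_a %in% seq_len(k)) || any(!labels_b %in% seq_len(k)))
    stop("labels must be integers in 1..k")
  ca <- tabulate(labels_a, k)
  cb <- tabulate(labels_b, k)
  rows <- lapply(seq_len(k), function(c) {
    t <- agresti_caffo(ca[c], na, cb[c], nb)
    data.frame(cluster = c, count_a = ca[c], count_b = cb[c],
               pct_a = 100 * ca[c] / na, pct_b = 100 * cb[c] / nb,
               diff = t$diff, z = t$z, p = t$p_two_sided)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' From the one-way ANOVA decomposition with grouping factor `group_ids`
#' (typically the animal): `ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW)`,
#' where `k0` is the balanced-equivalent group size
#' `(N - sum(n_i^2)/N) / (a - 1)`. Used to quantify how much of the
#' variance in a spine- or cell-level measurement is attributable to the
#' grouping, i.e. the degree of pseudo-replication.
#'
#' @param values numeric measurements.
#' @param group_ids grouping identifiers aligned with `values`.
#' @return list of class `icc_result`: `icc`, `ms_between`, `ms_within`,
#'   `n_groups`, `k0`.
#' @export
icc_oneway <- function(values, group_ids) {
  g <- factor(group_ids)
  a <- nlevels(g)
  if (a < 2L) stop("need at least 2 groups")
  ni <- as.vector(table(g))
  if (max(ni) < 2L) stop("need at least one group with 2+ observations")
  N <- length(values)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[g])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  structure(list(icc = icc, ms_between = msb, ms_within = msw,
                 n_groups = a, k0 = k0),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1) = %.4f  (%d groups, k0 = %.2f)\n",
              x$icc, x$n_groups, x$k0))
  invisible(x)
}

#' Per-feature group comparison
#'
#' Unpaired pooled-variance t-test plus Cohen's d for every feature column
#' shared by the two data frames.
#'
#' @param df_a,df_b data.frames with feature columns.
#' @param features feature names (default: the known descriptors present
#'   in both).
#' @return data.frame: feature, group means, t, p, d, interpretation.
#' @export
compare_features <- function(df_a, df_b, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_columns(df_a), feature_columns(df_b))
  rows <- lapply(features, function(f) {
    tt <- ttest_unpaired(df_a[[f]], df_b[[f]])
    es <- cohens_d(df_a[[f]], df_b[[f]])
    data.frame(feature = f, mean_a = mean(df_a[[f]]), mean_b = mean(df_b[[f]]),
               t = tt$t, p = tt$p, cohens_d = es$cohens_d,
               effect = es$interpretation)
  })
  do.call(rbind, rows)
}
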