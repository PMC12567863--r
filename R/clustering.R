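#' Feature screening before clustering
#'
#' Two removal rules, applied to a users x features table: (1) for every
#' pair with absolute Pearson correlation at or above `corr_threshold`, drop
#' the member with the lower one-way ANOVA F-statistic against provisional
#' cluster labels (K-means, k = 3, on all standardized features); (2) drop
#' low-F features -- those strictly below the bottom `f_drop_quantile` of
#' the remaining F-scores (inverse-ECDF quantile, so equally informative
#' features are never split by a tie) or whose ANOVA p-value exceeds
#' `f_p_threshold` (features carrying no evidence of group structure at
#' all). Deterministic given `seed`.
#'
#' @param features Tibble with `user_id` and numeric feature columns.
#' @param corr_threshold Absolute-correlation cut (default 0.90).
#' @param f_drop_quantile Bottom-quantile F cut (default 0.1).
#' @param f_p_threshold ANOVA p-value above which a feature is considered
#'   uninformative (default 0.05).
#' @param seed Seed for the provisional K-means (default 42).
#' @return Character vector of retained feature names.
#' @export
select_features <- function(features, corr_threshold = 0.90,
                            f_drop_quantile = 0.1, f_p_threshold = 0.05,
                            seed = 42L) {
  x <- as.matrix(features[setdiff(names(features), "user_id")])
  if (ncol(x) < 2) abort("select_features: need >= 2 features")
  if (nrow(x) < 3) abort("select_features: need >= 3 samples")
  xs <- scale(x)
  xs[, apply(x, 2, sd) == 0] <- 0
  prov <- fit_kmeans(xs, k = 3, seed = seed)$labels
  prov2 <- fit_kmeans(xs, k = 2, seed = seed)$labels
  f_score <- function(v, lab) {
    if (sd(v) == 0) return(c(0, 1))
    tab <- summary(aov(v ~ factor(lab)))[[1]]
    c(tab[["F value"]][1], tab[["Pr(>F)"]][1])
  }
  ft <- apply(x, 2, f_score, lab = prov)
  fs <- ft[1, ]
  # a k-means partition is fit on these same columns, so it can carve a
  # pure-noise axis and lend it a significant F; require group signal under
  # both a k=2 and the k=3 provisional partition before trusting a feature
  ps <- pmax(ft[2, ], apply(x, 2, function(v) f_score(v, prov2)[2]))
  keep <- colnames(x)
  cm <- abs(stats::cor(x))
  pairs <- which(cm >= corr_threshold & upper.tri(cm), arr.ind = TRUE)
  # drop lower-F member of each highly correlated pair
  for (r in seq_len(nrow(pairs))) {
    a <- colnames(x)[pairs[r, 1]]; b <- colnames(x)[pairs[r, 2]]
    if (!(a %in% keep && b %in% keep)) next
    keep <- setdiff(keep, if (fs[a] < fs[b]) a else b)
  }
  # inverse-ECDF quantile: only features strictly below the bottom decile
  # fall, so ties (equally informative features) are never broken spuriously
  cut <- quantile(fs[keep], f_drop_quantile, type = 1)
  # Holm-adjusted p-values: the provisional labels were fit on these same
  # features, so unadjusted tests are anti-conservative for noise channels
  padj <- stats::p.adjust(ps[keep], method = "holm")
  keep <- keep[!(fs[keep] < cut | padj > f_p_threshold)]
  if (!length(keep)) abort("select_features: all features dropped")
  keep
}

#' PCA retaining a target fraction of variance
#'
#' Standardizes columns and keeps the smallest number of principal
#' components whose cumulative explained-variance ratio reaches the target.
#'
#' @param features Tibble with `user_id` and numeric columns, or a matrix.
#' @param variance_target Fraction in (0, 1]; default 0.85.
#' @return A `sleeprec_pca` list: `rotation`, `center`, `scale`,
#'   `ev_ratio`, `m` (components kept), `scores` (n x m matrix).
#' @export
fit_pca <- function(features, variance_target = 0.85) {
  if (variance_target <= 0 || variance_target > 1)
    abort("fit_pca: variance_target must be in (0, 1]")
  x <- if (is.data.frame(features))
    as.matrix(features[setdiff(names(features), "user_id")]) else as.matrix(features)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  m <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  structure(list(rotation = p$rotation[, seq_len(m), drop = FALSE],
                 center = p$center, scale = p$scale,
                 ev_ratio = ev, m = m,
                 scores = p$x[, seq_len(m), drop = FALSE]),
            class = "sleeprec_pca")
}

# k-means++ seeding (greedy D^2 sampling)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' K-means with k-means++ restarts
#'
#' `n_init` k-means++ seedings, each refined by Lloyd iterations
#' ([stats::kmeans()]); the lowest-inertia solution wins. Deterministic for
#' a fixed `seed`.
#'
#' @param x Numeric matrix (e.g. PCA scores).
#' @param k Number of clusters (`k <= nrow(x)`).
#' @param n_init Restarts (default 50).
#' @param max_iter Lloyd iteration cap (default 500).
#' @param seed Random state (default 42).
#' @return List: `labels` (integer, 0-based to match the 0/1/2 cluster
#'   naming convention), `centers`, `inertia`.
#' @export
fit_kmeans <- function(x, k, n_init = 50, max_iter = 500, seed = 42L) {
  x <- as.matrix(x)
  if (k > nrow(x)) abort("fit_kmeans: k exceeds the number of samples")
  withr::with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      cen <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = cen, iter.max = max_iter, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(labels = best$cluster - 1L, centers = best$centers,
         inertia = best$tot.withinss)
  })
}

#' Mean silhouette score
#'
#' For each point, `a` is its mean distance to its own cluster's other
#' members and `b` the smallest mean distance to another cluster; the score
#' is the mean of `(b - a) / max(a, b)` (singleton clusters contribute 0).
#' Euclidean distances.
#'
#' @param x Numeric matrix of points.
#' @param labels Cluster labels (any type; >= 2 distinct values).
#' @return Scalar in `[-1, 1]`.
#' @seealso [silhouette_widths()] for the per-point values.
#' @export
silhouette_score <- function(x, labels) {
  mean(silhouette_widths(x, labels))
}

#' Per-point silhouette widths
#'
#' @inheritParams silhouette_score
#' @return Numeric vector of per-point widths.
#' @export
silhouette_widths <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2)
    abort("silhouette: need >= 2 clusters")
  d <- as.matrix(dist(x))
  vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Cluster users: screening, PCA, silhouette-selected K-means
#'
#' The full refinement pipeline: [select_features()] removes redundant and
#' uninformative columns, [fit_pca()] reduces to the components explaining
#' at least `variance_target` of the variance, and K-means is fitted for
#' each `k` in `k_range`, keeping the `k` with the highest silhouette score
#' in PCA space (ties resolved toward smaller `k`). Users whose silhouette
#' width falls below `ambiguous_threshold` are flagged as lacking a clear
#' cluster match; they keep their label but are marked excluded from cluster
#' profiling.
#'
#' @param features Users x features tibble (`user_id` + numeric columns).
#' @param k_range Candidate cluster counts, within 2..6.
#' @param variance_target PCA explained-variance target (default 0.85).
#' @param corr_threshold,f_drop_quantile Passed to [select_features()].
#' @param ambiguous_threshold Per-user silhouette width below which a user
#'   is flagged ambiguous (default 0.1).
#' @param seed Random state (default 42).
#' @return A `sleeprec_cluster_model`: retained feature names, the PCA
#'   basis, `k`, centroids, a per-user `labels` tibble (with silhouette
#'   widths and the ambiguity flag) and the per-k silhouette curve.
#' @export
cluster_users <- function(features, k_range = 2:6, variance_target = 0.85,
                          corr_threshold = 0.90, f_drop_quantile = 0.1,
                          ambiguous_threshold = 0.1, seed = 42L) {
  if (any(k_range < 2 | k_range > 6))
    abort("cluster_users: k_range must lie within 2..6")
  retained <- select_features(features, corr_threshold = corr_threshold,
                              f_drop_quantile = f_drop_quantile, seed = seed)
  pca <- fit_pca(features[c("user_id", retained)], variance_target)
  fits <- lapply(k_range, function(k) fit_kmeans(pca$scores, k, seed = seed))
  sil <- vapply(fits, function(f) silhouette_score(pca$scores, f$labels),
                numeric(1))
  best <- which(sil == max(sil))[1]  # ties -> smaller k (k_range ascending)
  fit <- fits[[best]]
  widths <- silhouette_widths(pca$scores, fit$labels)
  structure(list(
    retained = retained,
    pca = pca,
    k = k_range[best],
    centers = fit$centers,
    inertia = fit$inertia,
    labels = tibble::tibble(user_id = features$user_id,
                            cluster = fit$labels,
                            silhouette = widths,
                            ambiguous = widths < ambiguous_threshold),
    silhouette_by_k = tibble::tibble(k = k_range, silhouette = sil),
    seed = seed),
    class = "sleeprec_cluster_model")
}

#' @export
print.sleeprec_cluster_model <- function(x, ...) {
  cat(sprintf("<sleeprec_cluster_model> k = %d, silhouette = %.3f, %d/%d features, %d PCs\n",
              x$k, x$silhouette_by_k$silhouette[x$silhouette_by_k$k == x$k],
              length(x$retained),
              length(x$pca$center), x$pca$m))
  cat(sprintf("users: %d (%d ambiguous, silhouette < 0.1)\n",
              nrow(x$labels), sum(x$labels$ambiguous)))
  invisible(x)
}

#' Profile clusters on the users with a clear match
#'
#' Summarises each cluster (count, mean quality, mean features) over the
#' non-ambiguous users only, reproducing the exclusion mechanism whereby
#' users without a clear cluster match do not enter the profile table.
#'
#' @param model A `sleeprec_cluster_model`.
#' @param features The user feature table used to fit it.
#' @param quality Tibble from [user_quality()].
#' @return Tibble, one row per cluster.
#' @export
cluster_profiles <- function(model, features, quality) {
  lab <- model$labels[!model$labels$ambiguous, ]
  df <- dplyr::inner_join(lab, quality, by = "user_id")
  df <- dplyr::inner_join(df, features, by = "user_id")
  dplyr::summarise(dplyr::group_by(df, .data$cluster),
                   n_users = dplyr::n(),
                   avg_sleep_quality = mean(.data$quality_raw),
                   dplyr::across(dplyr::where(is.numeric) &
                                   !dplyr::any_of(c("cluster", "silhouette",
                                                    "quality_raw", "quality_score",
                                                    "n_nights")),
                                 mean),
                   .groups = "drop")
}

#' Persist / restore a cluster model as JSON
#'
#' @param model A `sleeprec_cluster_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(retained = model$retained,
              rotation = model$pca$rotation,
              center = model$pca$center, scale = model$pca$scale,
              ev_ratio = model$pca$ev_ratio, m = model$pca$m,
              k = model$k, centers = model$centers,
              labels = model$labels,
              silhouette_by_k = model$silhouette_by_k)
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
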