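# three well-separated planted blobs in feature space
blob_features <- function(n_per = 20, d = 5, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * d), 3, d) * sep
  x <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[g, ], "+")))
  tibble::tibble(user_id = sprintf("u%03d", seq_len(3 * n_per)),
                 !!!setNames(as.data.frame(x), paste0("f", seq_len(d))))
}

# two equally informative features built on orthogonal group contrasts, so
# they separate the groups without correlating with each other
contrast_features <- function(n_per = 30, sep = 6, seed = 1) {
  set.seed(seed)
  g <- rep(1:3, each = n_per)
  tibble::tibble(user_id = sprintf("u%03d", seq_along(g)),
                 f1 = sep * c(-1, 1, 0)[g] + rnorm(length(g)),
                 f2 = sep / sqrt(3) * c(1, 1, -2)[g] + rnorm(length(g)))
}

test_that("identical columns collapse to one; informative features survive", {
  f <- contrast_features()
  f$f3 <- f$f1                       # exact duplicate, r = 1
  kept <- select_features(f)
  expect_equal(sum(c("f1", "f3") %in% kept), 1)
  expect_true("f2" %in% kept)
  expect_error(select_features(f[1:2, ]), ">= 3 samples")
  expect_error(select_features(f["user_id"]), ">= 2")
})

test_that("noise features score lower F than group-separated ones", {
  f <- contrast_features()
  set.seed(2)
  f$noise <- rnorm(nrow(f))
  labels <- rep(1:3, each = 30)
  f_oracle <- function(v) summary(aov(v ~ factor(labels)))[[1]][["F value"]][1]
  expect_gt(f_oracle(f$f1), f_oracle(f$noise))
  # uncorrelated, comparably informative features are all retained
  expect_setequal(select_features(contrast_features(seed = 3)), c("f1", "f2"))
})

test_that("PCA keeps the smallest component count reaching the target", {
  # rank-2 data embedded in 5-D
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  x <- matrix(rnorm(200), 100, 2) %*% t(basis)
  expect_equal(fit_pca(x, 0.85)$m, 2)
  # isotropic 4-D: each PC explains ~25%, so 0.85 needs all 4
  iso <- matrix(rnorm(4 * 5000), ncol = 4)
  expect_equal(fit_pca(iso, 0.85)$m, 4)
  expect_error(fit_pca(iso, 1.5), "variance_target")
})

test_that("discarded eigenvalue mass equals reconstruction error", {
  set.seed(5)
  x <- matrix(rnorm(300), 60, 5) %*% diag(c(3, 2, 1, 0.5, 0.2))
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  m <- 2
  xs <- scale(x)
  recon <- p$x[, 1:m] %*% t(p$rotation[, 1:m])
  err <- sum((xs - recon)^2) / (nrow(x) - 1)
  expect_equal(err, sum(p$sdev[(m + 1):5]^2), tolerance = 1e-10)
})

test_that("kmeans finds the exhaustive-best 2-partition of 8 points", {
  set.seed(6)
  x <- matrix(rnorm(16), 8, 2)
  fit <- fit_kmeans(x, 2)
  inertia_of <- function(assign) {
    sum(sapply(unique(assign), function(g) {
      pts <- x[assign == g, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }))
  }
  # enumerate all 2^8 assignments with both clusters non-empty
  best <- min(sapply(1:(2^8 - 2), function(code) {
    assign <- as.integer(intToBits(code))[1:8]
    if (length(unique(assign)) < 2) Inf else inertia_of(assign)
  }))
  expect_equal(fit$inertia, best, tolerance = 1e-8)
})

test_that("kmeans is deterministic per seed and splits separated pairs", {
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 10, 0.1), 5))
  a <- fit_kmeans(x, 2, seed = 42)
  b <- fit_kmeans(x, 2, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_equal(length(unique(a$labels[1:5])), 1)
  expect_equal(length(unique(a$labels[6:10])), 1)
  expect_false(a$labels[1] == a$labels[6])
  expect_error(fit_kmeans(x, 20), "k exceeds")
})

test_that("silhouette matches a hand computation and the cluster package", {
  # 6 hand-placed points, 2 clusters
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 10), c(10, 11), c(11, 10))
  lab <- c(0, 0, 0, 1, 1, 1)
  d <- as.matrix(dist(pts))
  hand <- mean(sapply(1:6, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(6) != i])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }))
  expect_equal(silhouette_score(pts, lab), hand)
  expect_gt(silhouette_score(pts, lab), 0.9)
  skip_if_not_installed("cluster")
  cl <- mean(cluster::silhouette(lab + 1, dist(pts))[, 3])
  expect_equal(silhouette_score(pts, lab), cl)
  expect_error(silhouette_score(pts, rep(1, 6)), ">= 2 clusters")
})

test_that("random labels on isotropic data give silhouette near zero", {
  set.seed(7)
  x <- matrix(rnorm(1000), 500, 2)
  lab <- sample(0:1, 500, TRUE)
  expect_lt(abs(silhouette_score(x, lab)), 0.1)
})

test_that("silhouette-driven selection recovers the planted k", {
  f3 <- blob_features(n_per = 25, sep = 6, seed = 8)
  m3 <- cluster_users(f3)
  expect_equal(m3$k, 3)
  set.seed(9)
  f2 <- tibble::tibble(
    user_id = sprintf("u%03d", 1:60),
    f1 = c(rnorm(30, 0), rnorm(30, 12)),
    f2 = c(rnorm(30, 0), rnorm(30, -9)),
    f3 = rnorm(60))
  expect_equal(cluster_users(f2)$k, 2)
})

test_that("silhouette ties resolve toward the smaller k", {
  sil <- c(0.5, 0.5, 0.3)
  expect_equal(c(2, 3, 4)[which(sil == max(sil))[1]], 2)
  # and through the public interface: perfectly symmetric 4-corner data has
  # k = 2 <= k = 4, so a tie or near-tie must never pick the larger k over
  # an equal smaller one
  corners <- rbind(matrix(rnorm(40, 0, 0.05), 20),
                   sweep(matrix(rnorm(40, 0, 0.05), 20), 2, c(0, 8), "+"),
                   sweep(matrix(rnorm(40, 0, 0.05), 20), 2, c(8, 0), "+"),
                   sweep(matrix(rnorm(40, 0, 0.05), 20), 2, c(8, 8), "+"))
  f <- tibble::tibble(user_id = sprintf("u%02d", 1:80),
                      a = corners[, 1], b = corners[, 2], c = rnorm(80))
  m <- cluster_users(f)
  best <- max(m$silhouette_by_k$silhouette)
  ties <- m$silhouette_by_k$k[m$silhouette_by_k$silhouette == best]
  expect_equal(m$k, min(ties))
})

test_that("planted cohort structure is recovered with high ARI", {
  skip_if_not_installed("mclust")
  pop <- separated_population(n_users = 120, n_nights = 28, seed = 10)
  feats <- user_feature_table(pop$nights)
  model <- cluster_users(feats)
  expect_equal(model$k, 3)
  truth <- pop$truth$users$group[match(model$labels$user_id,
                                       pop$truth$users$user_id)]
  ari <- mclust::adjustedRandIndex(model$labels$cluster, truth)
  expect_gte(ari, 0.8)
})

test_that("refinement does not hurt silhouette relative to raw features", {
  pop <- separated_population(n_users = 90, n_nights = 21, seed = 11)
  feats <- user_feature_table(pop$nights)
  model <- cluster_users(feats)
  raw <- as.matrix(feats[-1])
  raw_fit <- fit_kmeans(scale(raw), model$k)
  raw_sil <- silhouette_score(scale(raw), raw_fit$labels)
  refined_sil <- glance(model)$silhouette
  expect_gte(refined_sil, raw_sil)
})

test_that("kmeans inertia never increases across Lloyd iterations", {
  set.seed(12)
  x <- matrix(rnorm(400), 200, 2)
  cen <- x[sample(200, 3), ]
  prev <- Inf
  for (it in 1:10) {
    km <- suppressWarnings(kmeans(x, centers = cen, iter.max = 1,
                                  algorithm = "Lloyd"))
    expect_lte(km$tot.withinss, prev + 1e-9)
    prev <- km$tot.withinss
    cen <- km$centers
  }
})

test_that("cluster profiles exclude ambiguous users", {
  pop <- separated_population(seed = 13)
  feats <- user_feature_table(pop$nights)
  model <- cluster_users(feats)
  prof <- cluster_profiles(model, feats, user_quality(pop$nights))
  expect_equal(sum(prof$n_users),
               sum(!model$labels$ambiguous))
  expect_true(all(diff(prof$cluster) > 0) || nrow(prof) == 1)
})

test_that("cluster model JSON round trip preserves the labeling", {
  pop <- separated_population(n_users = 45, n_nights = 14, seed = 14)
  model <- cluster_users(user_feature_table(pop$nights))
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(model, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$k, model$k)
  expect_equal(back$labels$cluster, model$labels$cluster)
  expect_equal(back$centers, model$centers, ignore_attr = TRUE,
               tolerance = 1e-12)
})
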