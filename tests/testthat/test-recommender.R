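test_that("cosine similarity matches hand computations and is symmetric", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_equal(cosine_sim(c(3, 2, 1), c(1, 2, 3)), 10 / 14)
  expect_warning(s <- cosine_sim(c(0, 0), c(1, 2)), "zero vector")
  expect_equal(s, 0)
  expect_error(cosine_sim(c(1, 2), c(1, 2, 3)), "equal length")
})

simple_users <- function() {
  feats <- tibble::tibble(user_id = c("a", "b", "c", "d", "e"),
                          f1 = c(1, 1.1, 0.9, 4, 4.2),
                          f2 = c(2, 2.1, 1.8, 0.5, 0.4))
  labels <- tibble::tibble(user_id = feats$user_id,
                           cluster = c(0L, 0L, 0L, 1L, 1L))
  quality <- tibble::tibble(user_id = feats$user_id,
                            quality_raw = c(3.0, 4.0, 4.5, 2.0, 5.0))
  list(feats = feats, labels = labels, quality = quality)
}

test_that("cbsur picks the most similar higher-quality same-cluster user", {
  s <- simple_users()
  ref <- cbsur("a", s$feats, s$labels, s$quality)
  expect_true(ref$user_id %in% c("b", "c"))       # same cluster, better sleep
  # brute-force argmax over the eligible pool
  x <- as.matrix(s$feats[-1])
  sims <- sapply(2:3, function(i) cosine_sim(x[1, ], x[i, ]))
  expect_equal(ref$user_id, c("b", "c")[which.max(sims)])
  # top-quality user in a cluster has no reference
  expect_null(cbsur("c", s$feats, s$labels, s$quality))
  # one eligible candidate -> that candidate
  expect_equal(cbsur("d", s$feats, s$labels, s$quality)$user_id, "e")
  # unclustered user falls back to the global pool with a warning
  lab2 <- s$labels; lab2$cluster[1] <- NA
  expect_warning(ref2 <- cbsur("a", s$feats, lab2, s$quality), "no cluster")
  expect_false(is.null(ref2))
})

test_that("cbsur never crosses clusters nor returns lower quality", {
  pop <- separated_population(n_users = 60, n_nights = 14, seed = 21)
  feats <- user_feature_table(pop$nights)
  model <- cluster_users(feats)
  quality <- user_quality(pop$nights)
  for (u in head(feats$user_id, 15)) {
    ref <- cbsur(u, feats, model$labels, quality)
    if (is.null(ref)) next
    expect_equal(model$labels$cluster[model$labels$user_id == ref$user_id],
                 model$labels$cluster[model$labels$user_id == u])
    expect_gt(ref$quality_raw,
              quality$quality_raw[quality$user_id == u])
  }
})

test_that("pfra_predict is the similarity-weighted neighbor mean", {
  nbrs <- tibble::tibble(user_id = "u", neighbor_id = c("v1", "v2"),
                         sim = c(0.5, 0.5))
  r <- tibble::tibble(user_id = c("v1", "v2"), item_id = "i1",
                      rating = c(4, 2))
  expect_equal(pfra_predict(r, nbrs, "u", "i1")$pred, 3)
  one <- pfra_predict(r[1, ], nbrs[1, ], "u", "i1")
  expect_equal(one$pred, 4)
  nb3 <- tibble::tibble(user_id = "u", neighbor_id = c("v1", "v2", "v3"),
                        sim = c(0.9, 0.3, 0.1))
  r3 <- tibble::tibble(user_id = c("v1", "v2", "v3"), item_id = "i1",
                       rating = c(5, 3, 1))
  expect_equal(pfra_predict(r3, nb3, "u", "i1")$pred,
               (0.9 * 5 + 0.3 * 3 + 0.1 * 1) / 1.3)
  # no neighbor rated the item -> item-mean fallback, flagged
  r_other <- tibble::tibble(user_id = "w", item_id = "i1", rating = 2)
  out <- pfra_predict(r_other, nbrs, "u", "i1")
  expect_true(out$fallback)
  expect_equal(out$pred, 2)
})

test_that("pfra_predict stays within neighbor rating bounds and shifts with c", {
  set.seed(22)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    nbrs <- tibble::tibble(user_id = "u",
                           neighbor_id = paste0("v", seq_len(k)),
                           sim = runif(k))
    r <- tibble::tibble(user_id = paste0("v", seq_len(k)), item_id = "i",
                        rating = runif(k, 1, 5))
    p <- pfra_predict(r, nbrs, "u", "i")$pred
    expect_gte(p, min(r$rating))
    expect_lte(p, max(r$rating))
    r2 <- r; r2$rating <- r$rating + 0.7
    expect_equal(pfra_predict(r2, nbrs, "u", "i")$pred, p + 0.7)
  }
})

test_that("pfra_topk orders by prediction with item-id tie break", {
  nbrs <- tibble::tibble(user_id = "u", neighbor_id = "v", sim = 1)
  cat6 <- tibble::tibble(item_id = sprintf("i%02d", 1:6))
  # all neighbor ratings equal -> ties -> ascending item id
  r_tie <- tibble::tibble(user_id = "v", item_id = cat6$item_id, rating = 3)
  top <- pfra_topk(r_tie, nbrs, "u", cat6, k_items = 6)
  expect_equal(top$item_id, sort(cat6$item_id))
  # a dominant item ranks first; full ordering matches an exhaustive sort
  r6 <- tibble::tibble(user_id = "v", item_id = cat6$item_id,
                       rating = c(2, 5, 3, 1, 4, 2.5))
  top6 <- pfra_topk(r6, nbrs, "u", cat6, k_items = 6)
  expect_equal(top6$item_id[1], "i02")
  expect_equal(top6$item_id, r6$item_id[order(-r6$rating, r6$item_id)])
  # user who rated everything gets an empty list with a notice
  r_all <- tibble::tibble(user_id = "u", item_id = cat6$item_id, rating = 3)
  expect_message(empty <- pfra_topk(r_all, nbrs, "u", cat6), "rated every")
  expect_equal(nrow(empty), 0)
})

test_that("neighborhoods are cluster-restricted, positive, sorted, and exclude self", {
  pop <- separated_population(n_users = 45, n_nights = 14, seed = 23)
  feats <- user_feature_table(pop$nights)
  model <- cluster_users(feats)
  nbrs <- neighborhoods(feats, model$labels, k = 5)
  expect_true(all(nbrs$sim > 0))
  expect_true(all(nbrs$user_id != nbrs$neighbor_id))
  for (u in unique(nbrs$user_id)) {
    s <- nbrs$sim[nbrs$user_id == u]
    expect_true(all(diff(s) <= 0))
    expect_lte(length(s), 5)
    cu <- model$labels$cluster[model$labels$user_id == u]
    nbc <- model$labels$cluster[match(nbrs$neighbor_id[nbrs$user_id == u],
                                      model$labels$user_id)]
    cluster_size <- sum(model$labels$cluster == cu) - 1
    if (cluster_size >= 5) expect_true(all(nbc == cu))
  }
})

test_that("pfra beats random ranking on planted low-rank preferences", {
  gains <- vapply(1:3, function(s) {
    pop <- generate_population(cohort_spec(n_users = 60, n_nights = 14,
                                           seed = 100 + s))
    ratings <- generate_ratings(pop, noise_sd = 0.5)
    feats <- user_feature_table(pop$nights)
    model <- cluster_users(feats)
    nbrs <- neighborhoods(feats, model$labels, k = 10)
    util <- sleeprec:::latent_utilities(pop$truth$users, item_catalog())
    rownames(util) <- pop$users$user_id
    colnames(util) <- item_catalog()$item_id
    users <- sample(pop$users$user_id, 25)
    per_user <- function(rank_fun) {
      mean_ap(lapply(users, function(u) {
        # hide this user's own ratings entirely; rank all items
        r_others <- ratings[ratings$user_id != u, ]
        items <- sort(item_catalog()$item_id)
        ranked <- rank_fun(u, r_others, items)
        rel <- util[u, ranked] >= quantile(util[u, ], 0.75)
        as.numeric(rel)[1:5]
      }))
    }
    pfra_rank <- function(u, r, items) {
      preds <- vapply(items, function(i)
        pfra_predict(r, nbrs, u, i)$pred, numeric(1))
      items[order(-preds, items)]
    }
    set.seed(s)
    random_rank <- function(u, r, items) sample(items)
    as.numeric(per_user(pfra_rank)) - as.numeric(per_user(random_rank))
  }, numeric(1))
  expect_gte(mean(gains), 0.15)
})

test_that("recommendations render with context-specific triggers", {
  cat <- item_catalog()
  bed <- cat[cat$template == "bedtime_shift_earlier", ]
  out <- render_recommendation(bed, list(sleep_debt = 120))
  expect_equal(out$param, -30)
  expect_equal(out$trigger, "sleep_debt")
  expect_match(out$text, "30 min earlier")
  walk <- cat[cat$template == "afternoon_walk", ]
  out2 <- render_recommendation(walk, list(steps = 3000))
  expect_equal(out2$param, 20)
  expect_match(out2$text, "20-min afternoon walk")
  # no trigger active -> generic phrasing, defaults kept
  out3 <- render_recommendation(walk, list(steps = 12000))
  expect_equal(out3$trigger, "none")
  out4 <- render_recommendation(cat[cat$template == "caffeine_cutoff", ],
                                list())
  expect_equal(out4$trigger, "none")
  expect_equal(out4$param, 840)
})
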