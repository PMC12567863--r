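#' Cluster-based similar-user reference (CBSUR)
#'
#' Within the target user's cluster, candidates are the other users whose
#' aggregated sleep-quality score exceeds the target's; the candidate with
#' the highest cosine similarity of user-level feature vectors is returned
#' as the reference profile. If the target is unclustered, the candidate
#' pool falls back to all users (with a warning). Returns `NULL` when no
#' candidate sleeps better than the target.
#'
#' @param user Target user id.
#' @param features User-level feature tibble (`user_id` + numeric columns).
#' @param labels Tibble `user_id`, `cluster` (e.g. `model$labels`).
#' @param quality Tibble from [user_quality()] (`quality_raw` is compared).
#' @return One-row tibble `user_id`, `similarity`, `quality_raw`, or `NULL`.
#' @export
cbsur <- function(user, features, labels, quality) {
  if (!user %in% features$user_id) abort("cbsur: unknown user")
  lab <- labels$cluster[match(user, labels$user_id)]
  if (length(lab) == 0 || is.na(lab)) {
    warn("cbsur: user has no cluster label; falling back to the global pool")
    pool <- setdiff(features$user_id, user)
  } else {
    pool <- setdiff(labels$user_id[!is.na(labels$cluster) &
                                     labels$cluster == lab], user)
  }
  qu <- quality$quality_raw[match(user, quality$user_id)]
  qv <- quality$quality_raw[match(pool, quality$user_id)]
  pool <- pool[!is.na(qv) & qv > qu]
  if (!length(pool)) return(NULL)
  x <- as.matrix(features[setdiff(names(features), "user_id")])
  rownames(x) <- features$user_id
  sims <- as.numeric(cosine_sim(x[user, , drop = FALSE], x[pool, , drop = FALSE]))
  best <- which.max(sims)
  tibble::tibble(user_id = pool[best], similarity = sims[best],
                 quality_raw = qv[!is.na(qv) & qv > qu][best])
}

#' Top-K user neighborhoods for collaborative re-ranking
#'
#' Cosine similarities between user-level feature vectors, restricted to the
#' target's cluster (falling back to the global pool when the cluster has
#' fewer than `k` other members, or when `restrict_cluster = FALSE`).
#' Negative similarities are excluded so predictions stay convex
#' combinations of neighbor ratings.
#'
#' @param features User-level feature tibble.
#' @param labels Tibble `user_id`, `cluster`, or `NULL` for no restriction.
#' @param k Neighborhood size (default 10).
#' @param restrict_cluster Restrict neighbors to the user's cluster.
#' @return Tibble `user_id`, `neighbor_id`, `sim`, sorted by descending
#'   similarity within user.
#' @export
neighborhoods <- function(features, labels = NULL, k = 10,
                          restrict_cluster = !is.null(labels)) {
  ids <- features$user_id
  x <- as.matrix(features[setdiff(names(features), "user_id")])
  sims <- suppressWarnings(cosine_sim(x, x))
  purrr::map_dfr(seq_along(ids), function(i) {
    pool <- setdiff(seq_along(ids), i)
    if (restrict_cluster && !is.null(labels)) {
      li <- labels$cluster[match(ids[i], labels$user_id)]
      inclust <- pool[labels$cluster[match(ids[pool], labels$user_id)] %in% li]
      if (length(inclust) >= k) pool <- inclust
    }
    s <- sims[i, pool]
    pool <- pool[s > 0]
    s <- s[s > 0]
    ord <- order(s, decreasing = TRUE)
    take <- head(ord, k)
    tibble::tibble(user_id = ids[i], neighbor_id = ids[pool[take]],
                   sim = s[take])
  })
}

#' Predict one rating by similarity-weighted neighbor averaging (PFRA)
#'
#' The feedback re-ranking estimate: the similarity-weighted mean of the
#' ratings that the target's top-K neighbors gave the item,
#' `sum(sim * r) / sum(sim)` over neighbors that rated it. When no neighbor
#' rated the item (or the similarity mass is zero) the item's global mean
#' rating is returned with `fallback = TRUE`.
#'
#' @param ratings Long tibble `user_id`, `item_id`, `rating` (deduplicated
#'   to one row per pair; see [generate_ratings()]).
#' @param nbrs Neighborhood tibble from [neighborhoods()].
#' @param user,item Target pair.
#' @return One-row tibble `user_id`, `item_id`, `pred`, `n_neighbors`,
#'   `fallback`.
#' @export
pfra_predict <- function(ratings, nbrs, user, item) {
  nb <- nbrs[nbrs$user_id == user, ]
  r <- ratings[ratings$item_id == item, ]
  nb <- dplyr::inner_join(nb, r, by = c("neighbor_id" = "user_id"))
  if (nrow(nb) == 0 || sum(nb$sim) == 0) {
    fallback <- mean(r$rating)
    return(tibble::tibble(user_id = user, item_id = item,
                          pred = fallback, n_neighbors = 0L, fallback = TRUE))
  }
  tibble::tibble(user_id = user, item_id = item,
                 pred = sum(nb$sim * nb$rating) / sum(nb$sim),
                 n_neighbors = nrow(nb), fallback = FALSE)
}

#' Top-K personalized list by PFRA predictions
#'
#' Predicts every catalog item the user has not rated and returns the top
#' `k_items` by predicted rating, ties broken by ascending item id.
#'
#' @param ratings Long ratings tibble.
#' @param nbrs Neighborhood tibble from [neighborhoods()].
#' @param user Target user id.
#' @param catalog Item catalog (needs `item_id`).
#' @param k_items List length (default 5); shorter if fewer unrated items.
#' @return Tibble `user_id`, `item_id`, `pred`, `rank`; zero rows (with a
#'   message) if the user rated everything.
#' @export
pfra_topk <- function(ratings, nbrs, user, catalog = item_catalog(),
                      k_items = 5) {
  rated <- ratings$item_id[ratings$user_id == user]
  cand <- setdiff(catalog$item_id, rated)
  if (!length(cand)) {
    message("pfra_topk: user has rated every catalog item")
    return(tibble::tibble(user_id = character(), item_id = character(),
                          pred = numeric(), rank = integer()))
  }
  preds <- purrr::map_dfr(cand, ~ pfra_predict(ratings, nbrs, user, .x))
  preds <- preds[order(-preds$pred, preds$item_id), ]
  preds <- head(preds, k_items)
  preds$rank <- seq_len(nrow(preds))
  preds[c("user_id", "item_id", "pred", "rank")]
}

#' Render a catalog item as contextual guidance
#'
#' Turns a template item into a guidance record conditioned on the user's
#' current context: a positive sleep debt triggers the 30-minutes-earlier
#' bedtime advice, a step count under `steps_threshold` the 20-minute
#' afternoon walk, a high stress index relaxation guidance, and elevated
#' night light/noise an environment adjustment; otherwise the generic
#' template phrasing with default parameters is used.
#'
#' @param item One catalog row (tibble).
#' @param context List/row with any of `sleep_debt`, `steps`,
#'   `stress_index`, `light_mean`, `noise_mean`.
#' @param steps_threshold Daily step target (default 8000).
#' @param stress_threshold High-stress cut (default 70).
#' @param light_threshold,noise_threshold Night environment cuts.
#' @return One-row tibble `item_id`, `category`, `param`, `trigger`, `text`.
#' @export
render_recommendation <- function(item, context = list(),
                                  steps_threshold = 8000,
                                  stress_threshold = 70,
                                  light_threshold = 20,
                                  noise_threshold = 38) {
  if (!item$item_id %in% item_catalog()$item_id &&
      is.null(item$template))
    abort("render_recommendation: item not in catalog")
  g <- function(f) context[[f]] %||% NA_real_
  trigger <- "none"
  param <- item$param
  text <- switch(item$template,
    bedtime_shift_earlier = {
      if (!is.na(g("sleep_debt")) && g("sleep_debt") > 0) {
        trigger <- "sleep_debt"; param <- -30
        "Cumulative sleep debt detected: go to bed 30 min earlier than usual."
      } else "Consider an earlier bedtime to lengthen your sleep opportunity."
    },
    afternoon_walk = {
      if (!is.na(g("steps")) && g("steps") < steps_threshold) {
        trigger <- "low_steps"; param <- 20
        "Daily step count below target: take a 20-min afternoon walk."
      } else "A regular afternoon walk supports deeper sleep."
    },
    relaxation_breathing = {
      if (!is.na(g("stress_index")) && g("stress_index") > stress_threshold) {
        trigger <- "high_stress"
        "Stress index elevated: practice a 10-min relaxation breathing routine before bed."
      } else "A short breathing routine before bed can ease sleep onset."
    },
    reduce_evening_light = {
      if (!is.na(g("light_mean")) && g("light_mean") > light_threshold) {
        trigger <- "night_light"
        "Bedroom light remains elevated at night: darken the room before sleep."
      } else "Dim the lights in the hour before bedtime."
    },
    reduce_bedroom_noise = {
      if (!is.na(g("noise_mean")) && g("noise_mean") > noise_threshold) {
        trigger <- "night_noise"
        "Night-time noise is elevated: reduce noise exposure in the bedroom."
      } else "Keep the bedroom quiet during the sleep window."
    },
    sprintf("Follow the '%s' plan (parameter %g).", item$template, item$param)
  )
  tibble::tibble(item_id = item$item_id, category = item$category,
                 param = param, trigger = trigger, text = text)
}
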