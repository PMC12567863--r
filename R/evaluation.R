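#' Precision at cutoff k
#'
#' Fraction of the top `k` ranked items that are relevant.
#'
#' @param relevance Binary (0/1 or logical) relevance flags in rank order.
#' @param k Cutoff, `1 <= k <= length(relevance)`.
#' @return Value in `[0, 1]`.
#' @export
precision_at_k <- function(relevance, k) {
  relevance <- as.numeric(relevance)
  if (k < 1 || k > length(relevance))
    abort("precision_at_k: k must be within the list length")
  sum(relevance[seq_len(k)]) / k
}

#' Average precision of a ranked list
#'
#' Mean of the precision values at the ranks holding relevant items:
#' `AP = (1/R) * sum_k P@k * rel_k`. A list with no relevant item has an
#' undefined AP; it is returned as 0 with attribute `no_relevant = TRUE`
#' so callers can exclude it from averaging.
#'
#' @param relevance Binary relevance flags in rank order.
#' @return Value in `[0, 1]`.
#' @export
average_precision <- function(relevance) {
  relevance <- as.numeric(relevance)
  rel_pos <- which(relevance == 1)
  if (!length(rel_pos)) {
    return(structure(0, no_relevant = TRUE))
  }
  mean(vapply(rel_pos, function(k) precision_at_k(relevance, k), numeric(1)))
}

#' Mean average precision over users
#'
#' Unweighted mean of per-user APs. Lists with no relevant item are
#' excluded from the average (and counted in the `n_excluded` attribute).
#'
#' @param relevance_lists List of per-user binary relevance vectors.
#' @return mAP in `[0, 1]`.
#' @export
mean_ap <- function(relevance_lists) {
  aps <- lapply(relevance_lists, average_precision)
  keep <- !vapply(aps, function(a) isTRUE(attr(a, "no_relevant")), logical(1))
  if (!any(keep)) abort("mean_ap: no user has a relevant item")
  structure(mean(unlist(aps[keep])), n_excluded = sum(!keep))
}

#' F1 score
#'
#' Harmonic mean of precision and recall; defined as 0 when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return Value in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (any(c(precision, recall) < 0 | c(precision, recall) > 1))
    abort("f1_score: precision and recall must be in [0, 1]")
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Grouped train/validation/test split by user
#'
#' Users (not nights) are partitioned 70/10/20 by default, so no user's
#' nights leak across splits; within each user nights stay in chronological
#' order. Counts are exact to rounding (largest-remainder).
#'
#' @param user_ids Character vector of user ids.
#' @param fractions Length-3 non-negative fractions summing to 1.
#' @param seed Assignment seed.
#' @return List of character vectors: `train`, `val`, `test`.
#' @export
grouped_split <- function(user_ids, fractions = c(0.7, 0.1, 0.2), seed = 0L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    abort("grouped_split: fractions must be length 3 and sum to 1")
  n <- length(user_ids)
  if (n < 10) abort("grouped_split: need at least 10 users")
  base <- floor(fractions * n)
  rem <- n - sum(base)
  frac <- fractions * n - base
  add <- order(frac, decreasing = TRUE)[seq_len(rem)]
  base[add] <- base[add] + 1
  withr::with_seed(seed, {
    shuffled <- sample(user_ids)
    list(train = shuffled[seq_len(base[1])],
         val = shuffled[base[1] + seq_len(base[2])],
         test = shuffled[base[1] + base[2] + seq_len(base[3])])
  })
}

# per-user ranking evaluation on held-out ratings: given a ranked item
# vector and the user's held-out ratings, compute AP / precision / recall /
# F1 at cutoff k with relevance = rating >= threshold
rank_metrics_for_user <- function(ranked_items, heldout, k = 5,
                                  rel_threshold = 4) {
  rel_items <- heldout$item_id[heldout$rating >= rel_threshold]
  flags <- as.numeric(ranked_items %in% rel_items)
  kk <- min(k, length(ranked_items))
  ap <- average_precision(flags[seq_len(kk)])
  if (!length(rel_items))
    return(tibble::tibble(ap = NA_real_, precision = NA_real_,
                          recall = NA_real_, f1 = NA_real_))
  p <- precision_at_k(flags, kk)
  r <- sum(flags[seq_len(kk)]) / length(rel_items)
  tibble::tibble(ap = as.numeric(ap), precision = p, recall = r,
                 f1 = f1_score(p, r))
}

# content-based score: cosine similarity between each item's attributes and
# the centroid of the user's liked (visible rating >= threshold) items
cbf_scores <- function(visible, user, catalog, items, rel_threshold = 4) {
  A <- as.matrix(catalog[c("attr1", "attr2", "attr3")])
  rownames(A) <- catalog$item_id
  liked <- visible$item_id[visible$user_id == user &
                             visible$rating >= rel_threshold]
  if (!length(liked)) {
    rated <- visible[visible$user_id == user, ]
    liked <- rated$item_id[which.max(rated$rating)]
  }
  centroid <- colMeans(A[liked, , drop = FALSE])
  as.numeric(suppressWarnings(cosine_sim(A[items, , drop = FALSE],
                                         matrix(centroid, 1))))
}

#' Run the ablation / baseline comparison experiment
#'
#' On a synthetic cohort, evaluates five configurations over several seeds:
#' `full` (MLP relevance scores fused with PFRA predictions), `no_pfra`
#' (MLP scores alone), `cf` (neighbor-based prediction without cluster
#' restriction), `cbf` (item-attribute similarity to the user's liked-item
#' centroid) and `cf_cbf` (equal-weight fusion of the last two). For each
#' seed, users are split 70/10/20; for each test user half their rated
#' items are hidden and the configurations rank them; mAP and F1 at the
#' cutoff are averaged over test users, then reported as mean and SD over
#' seeds.
#'
#' @param spec A [cohort_spec()]; the cohort is regenerated per seed offset.
#' @param seeds Experiment seeds (default `c(0, 1, 2)`).
#' @param models Which configurations to run.
#' @param k_items Evaluation cutoff (default 5).
#' @param alpha Fusion weight for `full`: either a fixed value or
#'   `"validate"` (default) to pick the weight from `alpha_grid` by mAP on
#'   held-out validation-user ratings.
#' @param alpha_grid Candidate fusion weights for validation tuning.
#' @param k_neighbors Neighborhood size (default 10).
#' @param net Network spec for the MLP configurations.
#' @param config Train config for the MLP configurations.
#' @param catalog Item catalog.
#' @return A `sleeprec_eval_report`: `by_seed` tibble (seed x model
#'   metrics) and `summary` tibble (model, mAP/F1 mean and SD).
#' @export
run_experiment <- function(spec, seeds = c(0L, 1L, 2L),
                           models = c("full", "no_pfra", "cf", "cbf",
                                      "cf_cbf"),
                           k_items = 5, alpha = "validate",
                           alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                           k_neighbors = 10,
                           net = network_spec(), config = train_config(),
                           catalog = item_catalog()) {
  known <- c("full", "no_pfra", "cf", "cbf", "cf_cbf")
  bad <- setdiff(models, known)
  if (length(bad))
    abort(sprintf("run_experiment: unknown model(s): %s",
                  paste(bad, collapse = ", ")))
  needs_mlp <- any(c("full", "no_pfra") %in% models)
  rows <- list()
  for (sd_i in seeds) {
    sp <- cohort_spec(spec$n_users, spec$n_nights, spec$cluster_mixture,
                      spec$group_params, spec$missingness,
                      seed = spec$seed + 1000L * sd_i)
    pop <- inject_missingness(generate_population(sp))
    ratings <- generate_ratings(pop, catalog)
    cleaned <- clean_cohort(pop$nights)
    nights <- cleaned$nights
    users <- pop$users[pop$users$user_id %in% nights$user_id, ]
    split <- grouped_split(users$user_id, seed = sd_i)
    ufeat <- user_feature_table(nights)
    model <- cluster_users(ufeat)
    # hide half of each validation and test user's ratings: validation
    # holdouts tune the fusion weight, test holdouts are ground truth
    eval_pool <- c(split$val, split$test)
    heldout <- withr::with_seed(sd_i + 17L, {
      dplyr::group_modify(
        dplyr::group_by(ratings[ratings$user_id %in% eval_pool, ],
                        .data$user_id),
        function(df, key) {
          df[sample.int(nrow(df), ceiling(nrow(df) / 2)), ]
        })
    })
    heldout <- dplyr::ungroup(heldout)
    visible <- dplyr::anti_join(ratings, heldout,
                                by = c("user_id", "item_id"))
    nbrs_clustered <- neighborhoods(ufeat, model$labels, k = k_neighbors)
    nbrs_global <- neighborhoods(ufeat, labels = NULL, k = k_neighbors,
                                 restrict_cluster = FALSE)
    ranker <- NULL
    if (needs_mlp) {
      stats <- feature_stats(nights, users, train_users = split$train)
      fm <- build_feature_matrix(nights, users, stats)
      fat <- fatigue_targets(nights)
      fm_fat <- fat[match(paste(fm$user_id, fm$night),
                          paste(fat$user_id, fat$night)), "fatigue_z"][[1]]
      tr_rows <- fm$user_id %in% split$train
      va_rows <- fm$user_id %in% split$val
      pairs_tr <- build_pairs(fm[tr_rows, ], visible, catalog,
                              fm_fat[tr_rows], seed = sd_i)
      pairs_va <- build_pairs(fm[va_rows, ], visible, catalog,
                              fm_fat[va_rows], seed = sd_i + 1L)
      ranker <- suppressWarnings(
        train_ranker(pairs_tr, pairs_va, net, config, seed = sd_i))
      mlp_x <- dplyr::summarise(dplyr::group_by(fm, .data$user_id),
                                dplyr::across(dplyr::all_of(feature_schema()),
                                              mean), .groups = "drop")
    }
    # per-user candidate scores: the hidden ratings (ground truth) plus the
    # user's never-rated items (scored but counted non-relevant), so the
    # cutoff actually truncates the list
    user_scores <- function(u) {
      hu <- heldout[heldout$user_id == u, ]
      never <- setdiff(catalog$item_id,
                       ratings$item_id[ratings$user_id == u])
      items <- sort(union(hu$item_id, never))
      sc <- list(items = items, hu = hu)
      sc$pfra <- vapply(items, function(i)
        pfra_predict(visible, nbrs_clustered, u, i)$pred, numeric(1))
      sc$cf <- vapply(items, function(i)
        pfra_predict(visible, nbrs_global, u, i)$pred, numeric(1))
      sc$cbf <- cbf_scores(visible, u, catalog, items)
      if (needs_mlp) {
        xr <- as.matrix(mlp_x[mlp_x$user_id == u, feature_schema()])
        sc$mlp <- as.numeric(score_items(ranker, xr, items))
      }
      sc
    }
    metrics_of <- function(sc, s_vec, mo) {
      ranked <- sc$items[order(-s_vec, sc$items)]
      dplyr::mutate(rank_metrics_for_user(ranked, sc$hu, k = k_items),
                    model = mo)
    }
    alpha_used <- if (identical(alpha, "validate")) 0.5 else alpha
    if (needs_mlp && "full" %in% models && identical(alpha, "validate")) {
      val_sc <- lapply(intersect(split$val, unique(heldout$user_id)),
                       user_scores)
      if (length(val_sc)) {
        val_map <- vapply(alpha_grid, function(a) {
          aps <- vapply(val_sc, function(sc)
            metrics_of(sc, suppressWarnings(
              fuse_scores(sc$mlp, sc$pfra, a)), "full")$ap, numeric(1))
          mean(aps, na.rm = TRUE)
        }, numeric(1))
        if (any(is.finite(val_map)))
          alpha_used <- alpha_grid[which.max(val_map)]
      }
    }
    test_users <- intersect(split$test, unique(heldout$user_id))
    per_user <- purrr::map_dfr(test_users, function(u) {
      sc <- user_scores(u)
      scores <- list()
      if (needs_mlp) {
        scores$no_pfra <- sc$mlp
        scores$full <- suppressWarnings(
          fuse_scores(sc$mlp, sc$pfra, alpha_used))
      }
      scores$cf <- sc$cf
      scores$cbf <- sc$cbf
      scores$cf_cbf <- suppressWarnings(fuse_scores(sc$cbf, sc$cf, 0.5))
      purrr::map_dfr(intersect(models, names(scores)), function(mo)
        dplyr::mutate(metrics_of(sc, scores[[mo]], mo), user_id = u))
    })
    agg <- dplyr::summarise(dplyr::group_by(per_user, .data$model),
                            map = mean(.data$ap, na.rm = TRUE),
                            f1 = mean(.data$f1, na.rm = TRUE),
                            n_users = sum(!is.na(.data$ap)),
                            .groups = "drop")
    agg$seed <- sd_i
    agg$alpha <- alpha_used
    rows[[length(rows) + 1]] <- agg
  }
  by_seed <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(dplyr::group_by(by_seed, .data$model),
                              map_mean = mean(.data$map),
                              map_sd = sd(.data$map),
                              f1_mean = mean(.data$f1),
                              f1_sd = sd(.data$f1), .groups = "drop")
  structure(list(by_seed = by_seed, summary = summary,
                 seeds = seeds, k_items = k_items, alpha = alpha),
            class = "sleeprec_eval_report")
}

#' @export
print.sleeprec_eval_report <- function(x, ...) {
  cat(sprintf("<sleeprec_eval_report> %d seed(s), cutoff %d\n",
              length(x$seeds), x$k_items))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Next-day fatigue regression targets
#'
#' Per-user z-scored fatigue index of the following night (last night falls
#' back to the current value), the auxiliary head's target.
#'
#' @param nights Cleaned night tibble.
#' @return Tibble `user_id`, `night`, `fatigue_z`.
#' @export
fatigue_targets <- function(nights) {
  out <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(nights, .data$user_id, .data$night),
                    .data$user_id),
    fatigue_next = dplyr::lead(.data$fatigue_index,
                               default = dplyr::last(.data$fatigue_index)),
    fatigue_z = {
      s <- sd(.data$fatigue_next)
      (.data$fatigue_next - mean(.data$fatigue_next)) / ifelse(s > 0, s, 1)
    })
  dplyr::ungroup(out)[c("user_id", "night", "fatigue_z")]
}
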