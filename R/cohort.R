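#' Specify a synthetic lifelog cohort
#'
#' Defines the statistical conditions under which a cohort of wearable +
#' AI-bed users is simulated: how many users and nights, the mixture over
#' latent lifestyle groups, group-conditional distributions for activity,
#' heart rate, HRV-proxy stress/fatigue, sleep outcomes and subjective sleep
#' quality, and missingness rates.
#'
#' The three default groups mirror the lifestyle profiles the clustering
#' stage is expected to recover: moderate stress with irregular activity,
#' high stress with low activity, and low stress with high activity (the
#' last with the highest mean sleep quality). The default mixture weights
#' the groups 10:4:37.
#'
#' @param n_users Number of users (>= 2).
#' @param n_nights Nights per user; default 84 (~12 weeks).
#' @param cluster_mixture Proportions over latent groups; must sum to 1.
#' @param group_params Tibble of per-group distribution parameters, one row
#'   per group; see [default_group_params()].
#' @param missingness List with rates in `[0,1]`: `gap_rate` (probability a
#'   night carries a short, sub-30-minute gap in one wearable channel),
#'   `night_drop_rate` (probability a whole night's wearable+bed signals are
#'   lost), `unknown_rate` (probability a categorical entry is missing).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return A `sleeprec_cohort_spec` list.
#' @examples
#' spec <- cohort_spec(n_users = 10, n_nights = 14, seed = 1)
#' pop <- generate_population(spec)
#' @export
cohort_spec <- function(n_users = 100,
                        n_nights = 84,
                        cluster_mixture = c(10, 4, 37) / 51,
                        group_params = default_group_params(),
                        missingness = list(gap_rate = 0.01,
                                           night_drop_rate = 0.009,
                                           unknown_rate = 0.005),
                        seed = 1L) {
  if (n_users < 2) abort("cohort_spec: n_users must be >= 2")
  if (n_nights < 1) abort("cohort_spec: n_nights must be >= 1")
  if (length(cluster_mixture) != nrow(group_params))
    abort("cohort_spec: cluster_mixture length must match group_params rows")
  if (any(cluster_mixture < 0) || abs(sum(cluster_mixture) - 1) > 1e-8)
    abort("cohort_spec: cluster_mixture must be non-negative and sum to 1")
  disp <- unlist(group_params[grepl("_sd$|_sigma$", names(group_params))])
  if (any(disp <= 0)) abort("cohort_spec: all dispersions must be > 0")
  for (r in c("gap_rate", "night_drop_rate", "unknown_rate")) {
    if (is.null(missingness[[r]]) || missingness[[r]] < 0 || missingness[[r]] > 1)
      abort(sprintf("cohort_spec: missingness$%s must be in [0,1]", r))
  }
  structure(list(n_users = as.integer(n_users),
                 n_nights = as.integer(n_nights),
                 cluster_mixture = cluster_mixture,
                 group_params = group_params,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "sleeprec_cohort_spec")
}

#' Default per-group generative parameters
#'
#' One row per latent lifestyle group. Steps are Poisson-lognormal
#' (overdispersed counts; `steps_log_mu`/`steps_log_sigma` parameterize the
#' lognormal rate); continuous physiology is Gaussian truncated at physical
#' bounds. `pref1..pref3` are the group's latent item-preference coordinates
#' that drive rating utilities (low-rank user x item structure).
#'
#' @return A tibble with one row per group.
#' @export
default_group_params <- function() {
  tibble::tibble(
    group = c("moderate_stress_irregular", "high_stress_low_activity",
              "low_stress_high_activity"),
    steps_log_mu = log(c(7000, 2500, 11000)),
    steps_log_sigma = c(0.70, 0.25, 0.20),
    hr_mu = c(68, 78, 60), hr_sd = c(4, 4, 3),
    stress_mu = c(55, 82, 30), stress_sd = c(8, 7, 7),
    fatigue_mu = c(55, 75, 38), fatigue_sd = c(8, 8, 8),
    quality_mu = c(3.9, 2.8, 4.4), quality_sd = c(0.6, 0.7, 0.4),
    tst_mu = c(410, 370, 450), tst_sd = c(45, 40, 30),
    bedtime_mu = c(1410, 1500, 1380), bedtime_sd = c(90, 40, 20),
    light_mu = c(25, 10, 6), noise_mu = c(38, 36, 27),
    resp_mu = c(14.5, 15.5, 13.5),
    pref1 = c(1.5, -0.5, 0.2),
    pref2 = c(-0.3, 1.6, 0.1),
    pref3 = c(0.3, 0.2, 1.2)
  )
}

#' Generate a synthetic cohort with planted group structure
#'
#' Draws users from the group mixture, then per-night wearable aggregates,
#' bed-derived features, environment summaries, sleep outcomes and a nightly
#' 1-5 subjective sleep rating from group-conditional distributions.
#' Subjective quality is positively coupled to low stress and high activity
#' within every group, so the planted groups order as their `quality_mu`.
#'
#' The returned object also carries the latent truth (group labels, latent
#' preference vectors, per-night true respiration rates and missingness
#' injections). Truth is never consumed by the analysis pipeline; it exists
#' for parameter-recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return A `sleeprec_population`: list with `users` (one row per user),
#'   `nights` (one row per user-night), `truth` (latent state), `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "sleeprec_cohort_spec"))
  gp <- spec$group_params
  withr::with_seed(spec$seed, {
    g <- sample.int(nrow(gp), spec$n_users, replace = TRUE,
                    prob = spec$cluster_mixture)
    users <- tibble::tibble(
      user_id = sprintf("u%03d", seq_len(spec$n_users)),
      age = round(runif(spec$n_users, 20, 55)),
      sex = sample(c("female", "male"), spec$n_users, replace = TRUE,
                   prob = c(0.52, 0.48))
    )
    truth_users <- tibble::tibble(
      user_id = users$user_id,
      group = gp$group[g],
      pref1 = gp$pref1[g] + rnorm(spec$n_users, 0, 0.15),
      pref2 = gp$pref2[g] + rnorm(spec$n_users, 0, 0.15),
      pref3 = gp$pref3[g] + rnorm(spec$n_users, 0, 0.15),
      offset = rnorm(spec$n_users, 0, 0.25)
    )
    # between-user heterogeneity within groups: independent per-user random
    # effects on each channel, so user-level summaries are not collinear
    # copies of the group label
    re <- tibble::tibble(
      steps_log = rnorm(spec$n_users, 0, 0.20),
      stress = rnorm(spec$n_users, 0, 8),
      fatigue = rnorm(spec$n_users, 0, 8),
      hr = rnorm(spec$n_users, 0, 3.5),
      light = rnorm(spec$n_users, 0, 5),
      noise = rnorm(spec$n_users, 0, 3),
      temp = rnorm(spec$n_users, 0, 0.7),
      humidity = rnorm(spec$n_users, 0, 4),
      bedtime = rnorm(spec$n_users, 0, 15),
      tst = rnorm(spec$n_users, 0, 25)
    )
    nights <- purrr::map_dfr(seq_len(spec$n_users), function(u) {
      p <- gp[g[u], ]
      nn <- spec$n_nights
      steps <- rpois(nn, exp(rnorm(nn, p$steps_log_mu + re$steps_log[u],
                                   p$steps_log_sigma)))
      stress <- clip(rnorm(nn, p$stress_mu + re$stress[u], p$stress_sd), 0, 100)
      fatigue <- clip(rnorm(nn, p$fatigue_mu + re$fatigue[u], p$fatigue_sd),
                      0, 100)
      hr_mean <- clip(rnorm(nn, p$hr_mu + re$hr[u], p$hr_sd), 40, 120)
      hr_sd_n <- clip(rnorm(nn, 6, 1.2), 1, 20)
      tst <- clip(p$tst_mu + re$tst[u] - 0.6 * (stress - p$stress_mu) +
                    rnorm(nn, 0, p$tst_sd), 180, 600)
      sol <- rgamma(nn, shape = 2, scale = (4 + 0.15 * stress) / 2)
      waso <- rgamma(nn, shape = 2, scale = (3 + 0.25 * stress) / 2)
      tib <- tst + sol + waso
      bedtime <- (rnorm(nn, p$bedtime_mu + re$bedtime[u], p$bedtime_sd)) %% 1440
      resp_hz_true <- clip(rnorm(nn, p$resp_mu / 60, 0.02), 0.13, 0.45)
      ptrans <- rpois(nn, pmax(1, 8 + 0.15 * (stress - 50)))
      latent_quality <- p$quality_mu -
        0.02 * (stress - p$stress_mu) +
        0.4 * (log(pmax(steps, 1)) - p$steps_log_mu) +
        rnorm(nn, 0, p$quality_sd / 2)
      tibble::tibble(
        user_id = users$user_id[u],
        night = seq_len(nn),
        steps = steps,
        active_minutes = clip(steps / 120 + rnorm(nn, 0, 4), 0, 600),
        mobility = abs(rnorm(nn, 2 + steps / 4000, 0.8)),
        hr_mean = hr_mean,
        hr_sd = hr_sd_n,
        hr_resting = hr_mean - abs(rnorm(nn, 8, 2)),
        hr_max = hr_mean + abs(rnorm(nn, 45, 8)),
        stress_index = stress,
        fatigue_index = fatigue,
        stress_peak = clip(stress + abs(rnorm(nn, 10, 4)), 0, 100),
        fatigue_peak = clip(fatigue + abs(rnorm(nn, 8, 4)), 0, 100),
        temp_mean = rnorm(nn, 21.5 + re$temp[u], 1),
        light_mean = abs(rnorm(nn, p$light_mu + re$light[u], 4)),
        noise_mean = clip(rnorm(nn, p$noise_mu + re$noise[u], 3), 15, 80),
        humidity_mean = clip(rnorm(nn, 45 + re$humidity[u], 5), 10, 90),
        resp_rate = 60 * resp_hz_true + rnorm(nn, 0, 0.4),
        posture_transitions = ptrans,
        micro_movement_index = abs(rnorm(nn, 0.8 + 0.01 * (stress - 50), 0.2)),
        pressure_entropy = clip(rnorm(nn, 2.4 + 0.02 * ptrans, 0.25), 0.1, 4),
        bedtime_min = bedtime,
        time_in_bed = tib,
        tst = tst,
        sol = sol,
        waso = waso,
        sleep_efficiency = tst / tib,
        midsleep_min = (bedtime + sol + (tst + waso) / 2) %% 1440,
        rating = as.integer(clip(round(latent_quality), 1, 5)),
        context_label = sample(c("workday", "offday"), nn, TRUE, c(5 / 7, 2 / 7)),
        resp_hz_true = resp_hz_true
      )
    })
    truth_nights <- nights[c("user_id", "night", "resp_hz_true")]
    nights$resp_hz_true <- NULL
    structure(list(users = users,
                   nights = nights,
                   truth = list(users = truth_users,
                                nights = truth_nights,
                                injections = tibble::tibble(
                                  user_id = character(), night = integer(),
                                  kind = character(), column = character(),
                                  minutes = numeric())),
                   spec = spec),
              class = "sleeprec_population")
  })
}

#' @export
print.sleeprec_population <- function(x, ...) {
  cat(sprintf("<sleeprec_population> %d users x %d nights (%d night rows)\n",
              nrow(x$users), x$spec$n_nights, nrow(x$nights)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$truth$users$group)),
                               table(x$truth$users$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Inject missingness into a synthetic cohort
#'
#' Applies, at the rates in the population's spec (or `missingness` override):
#' short gaps (a missing value in one continuous wearable channel for one
#' night, with a recorded gap duration strictly under 30 minutes), whole-night
#' wearable+bed signal loss, and unknown categorical entries. Every injection
#' is logged in the latent truth so cleaning can be audited against it.
#'
#' @param pop A `sleeprec_population`.
#' @param missingness Optional rate list overriding `pop$spec$missingness`.
#' @return The population with modified `nights` and an updated
#'   `truth$injections` log.
#' @export
inject_missingness <- function(pop, missingness = NULL) {
  stopifnot(inherits(pop, "sleeprec_population"))
  rates <- missingness %||% pop$spec$missingness
  gap_cols <- c("hr_mean", "steps", "stress_index", "fatigue_index")
  signal_cols <- setdiff(names(pop$nights),
                         c("user_id", "night", "context_label", "rating"))
  nights <- pop$nights
  n <- nrow(nights)
  withr::with_seed(pop$spec$seed + 1L, {
    inj <- list()
    drop_idx <- which(runif(n) < rates$night_drop_rate)
    if (length(drop_idx)) {
      nights[drop_idx, signal_cols] <- NA_real_
      inj$drop <- tibble::tibble(user_id = nights$user_id[drop_idx],
                                 night = nights$night[drop_idx],
                                 kind = "night_drop", column = "all",
                                 minutes = NA_real_)
    }
    gap_idx <- setdiff(which(runif(n) < rates$gap_rate), drop_idx)
    if (length(gap_idx)) {
      cols <- sample(gap_cols, length(gap_idx), replace = TRUE)
      mins <- runif(length(gap_idx), 5, 29.5)
      for (j in seq_along(gap_idx)) nights[gap_idx[j], cols[j]] <- NA_real_
      inj$gap <- tibble::tibble(user_id = nights$user_id[gap_idx],
                                night = nights$night[gap_idx],
                                kind = "gap", column = cols, minutes = mins)
    }
    unk_idx <- which(runif(n) < rates$unknown_rate)
    if (length(unk_idx)) {
      nights$context_label[unk_idx] <- NA_character_
      inj$unk <- tibble::tibble(user_id = nights$user_id[unk_idx],
                                night = nights$night[unk_idx],
                                kind = "unknown_category",
                                column = "context_label", minutes = NA_real_)
    }
    pop$nights <- nights
    pop$truth$injections <- dplyr::bind_rows(pop$truth$injections,
                                             dplyr::bind_rows(unname(inj)))
  })
  pop
}

#' Catalog of recommendable sleep/lifestyle items
#'
#' Twelve parameterized guidance templates in the two catalog categories:
#' sleep-schedule adjustment and lifestyle/activity optimization. Each item
#' carries a 3-dimensional attribute vector in the same latent space as the
#' generator's group preference vectors, giving ratings a learnable low-rank
#' structure.
#'
#' @return A tibble with `item_id`, `category`, `template`, `param`
#'   (template parameter, e.g. minutes), and attributes `attr1..attr3`.
#' @export
item_catalog <- function() {
  tibble::tibble(
    item_id = sprintf("i%02d", 1:12),
    category = c(rep("sleep_schedule_adjustment", 6),
                 rep("lifestyle_activity_optimization", 6)),
    template = c("bedtime_shift_earlier", "bedtime_shift_later",
                 "fixed_wake_time", "regular_bedtime_window",
                 "target_sleep_duration", "wind_down_routine",
                 "afternoon_walk", "morning_exercise",
                 "relaxation_breathing", "reduce_evening_light",
                 "reduce_bedroom_noise", "caffeine_cutoff"),
    param = c(-30, 15, 0, 30, 480, 30, 20, 25, 10, 0, 0, 840),
    attr1 = c(1.2, -0.8, 1.0, 1.4, 0.5, 0.3, 0.1, 0.2, -0.2, 0.1, 0.0, 0.4),
    attr2 = c(0.3, -0.2, 0.1, 0.2, 0.4, 0.9, 1.1, 0.8, 1.3, 0.7, 0.9, 0.5),
    attr3 = c(0.2, 0.1, 0.4, 0.3, 0.6, 0.2, 0.8, 1.0, 0.1, 0.5, 0.4, 0.3)
  )
}

# latent utility of each catalog item for each user, on the 1..5 scale
latent_utilities <- function(truth_users, catalog) {
  P <- as.matrix(truth_users[c("pref1", "pref2", "pref3")])
  A <- t(as.matrix(catalog[c("attr1", "attr2", "attr3")]))
  u <- P %*% A + truth_users$offset
  s <- stats::sd(u)
  # degenerate spread: utilities are taken as already on the rating scale
  if (!is.finite(s) || s < 1e-12) return(u)
  3 + 1.1 * (u - mean(u)) / s
}

#' Generate feedback ratings over the item catalog
#'
#' Each user rates a random subset of catalog items; each rated item gets one
#' integer 1-5 rating per sampled night, `clip(round(utility + noise), 1, 5)`,
#' and the nightly ratings are aggregated to one value per (user, item) by
#' their mean before the rating matrix is built.
#'
#' @param pop A `sleeprec_population` (its latent truth drives utilities).
#' @param catalog Item catalog tibble; see [item_catalog()].
#' @param noise_sd Gaussian noise added to the latent utility per nightly
#'   rating (default 0.5).
#' @param items_per_user How many items each user rates (default 8); the
#'   sparsity pattern is a parameter because no canonical pattern exists.
#' @param nights_per_item Nightly ratings aggregated per (user, item).
#' @return A tibble `user_id`, `item_id`, `rating` (mean of nightly integer
#'   ratings, in `[1, 5]`), `n_nights`.
#' @export
generate_ratings <- function(pop, catalog = item_catalog(), noise_sd = 0.5,
                             items_per_user = 8, nights_per_item = 3) {
  stopifnot(inherits(pop, "sleeprec_population"))
  if (nrow(catalog) == 0) abort("generate_ratings: catalog must be non-empty")
  items_per_user <- min(items_per_user, nrow(catalog))
  util <- latent_utilities(pop$truth$users, catalog)
  withr::with_seed(pop$spec$seed + 2L, {
    purrr::map_dfr(seq_len(nrow(pop$users)), function(u) {
      idx <- sample.int(nrow(catalog), items_per_user)
      purrr::map_dfr(idx, function(i) {
        r <- as.integer(clip(round(util[u, i] + rnorm(nights_per_item, 0, noise_sd)),
                             1, 5))
        tibble::tibble(user_id = pop$users$user_id[u],
                       item_id = catalog$item_id[i],
                       rating = mean(r), n_nights = nights_per_item)
      })
    })
  })
}

#' Cast long ratings to a users x items matrix
#'
#' @param ratings Long tibble with `user_id`, `item_id`, `rating`.
#' @return Numeric matrix (rows = users, cols = items) with NA where unrated.
#' @export
rating_matrix <- function(ratings) {
  wide <- tidyr::pivot_wider(ratings[c("user_id", "item_id", "rating")],
                             names_from = "item_id", values_from = "rating")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$user_id
  m[, order(colnames(m)), drop = FALSE]
}

#' Write a population to delimited tables
#'
#' Emits `users.csv`, `nights.csv`, `ratings.csv` (if given) and
#' `truth.json` under `dir`.
#'
#' @param pop A `sleeprec_population`.
#' @param dir Output directory (created if needed).
#' @param ratings Optional ratings tibble to include.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(pop, dir, ratings = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pop$users, file.path(dir, "users.csv"), row.names = FALSE)
  utils::write.csv(pop$nights, file.path(dir, "nights.csv"), row.names = FALSE)
  if (!is.null(ratings))
    utils::write.csv(ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  jsonlite::write_json(pop$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(dir)
}
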