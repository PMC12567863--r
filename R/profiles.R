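WEARABLE_COLS <- c("steps", "active_minutes", "mobility", "hr_mean", "hr_sd",
                   "hr_resting", "hr_max", "stress_index", "fatigue_index",
                   "stress_peak", "fatigue_peak")
BED_COLS <- c("resp_rate", "posture_transitions", "micro_movement_index",
              "pressure_entropy")

#' Clean a cohort's night table
#'
#' Applies the preprocessing rules in order: nights whose wearable or bed
#' signals are entirely missing are removed; short gaps (a missing value in
#' one continuous channel, representing a sub-30-minute within-day gap) are
#' imputed with the mean of the flanking valid nights of the same user;
#' missing categorical entries are coded `"unknown"`. Users left with no
#' nights are excluded with a warning.
#'
#' @param nights Night-level tibble (as in a `sleeprec_population`).
#' @return List: `nights` (cleaned tibble), `removed` (tibble of dropped
#'   user-nights), `imputed` (tibble of imputed cells), `excluded_users`.
#' @export
clean_cohort <- function(nights) {
  sig_cols <- intersect(c(WEARABLE_COLS, BED_COLS), names(nights))
  wear <- intersect(WEARABLE_COLS, names(nights))
  bed <- intersect(BED_COLS, names(nights))
  all_missing <- function(cols) {
    if (!length(cols)) return(rep(FALSE, nrow(nights)))
    rowSums(!is.na(as.matrix(nights[cols]))) == 0
  }
  drop <- all_missing(wear) | all_missing(bed)
  removed <- nights[drop, c("user_id", "night")]
  kept <- nights[!drop, , drop = FALSE]
  imputed <- list()
  kept <- dplyr::group_modify(dplyr::group_by(kept, .data$user_id), function(df, key) {
    df <- df[order(df$night), , drop = FALSE]
    for (cl in sig_cols) {
      miss <- which(is.na(df[[cl]]))
      for (i in miss) {
        lo <- df[[cl]][seq_len(i - 1)]
        hi <- df[[cl]][-seq_len(i)]
        neigh <- c(tail(lo[!is.na(lo)], 1), head(hi[!is.na(hi)], 1))
        if (length(neigh)) {
          imputed[[length(imputed) + 1]] <<- tibble::tibble(
            user_id = key$user_id, night = df$night[i], column = cl,
            value = mean(neigh))
          df[[cl]][i] <- mean(neigh)
        }
      }
    }
    df
  })
  kept <- dplyr::ungroup(kept)
  if ("context_label" %in% names(kept))
    kept$context_label[is.na(kept$context_label)] <- "unknown"
  if ("sleep_efficiency" %in% names(kept) && "tst" %in% names(kept))
    kept$sleep_efficiency <- kept$tst / kept$time_in_bed
  lost <- setdiff(unique(nights$user_id), unique(kept$user_id))
  if (length(lost))
    warn(sprintf("clean_cohort: user(s) lost all nights and were excluded: %s",
                 paste(lost, collapse = ", ")))
  list(nights = kept,
       removed = removed,
       imputed = dplyr::bind_rows(imputed),
       excluded_users = lost)
}

#' Nightly sleep metrics from sleep/wake annotations
#'
#' Computes, per annotated night: time in bed (final wake minus bed entry),
#' SOL (sleep onset minus bed entry), WASO (summed awakening minutes between
#' onset and final wake), TST (onset-to-wake span minus WASO) and sleep
#' efficiency (TST / time in bed).
#'
#' @param annotations Tibble with `user_id`, `night`, `bed_entry`,
#'   `sleep_onset`, `final_wake` (minutes on a common clock).
#' @param awakenings Tibble with `user_id`, `night`, `duration` (minutes),
#'   one row per awakening; may be empty.
#' @return Tibble with `user_id`, `night`, `time_in_bed`, `tst`, `sol`,
#'   `waso`, `sleep_efficiency`.
#' @export
sleep_metrics <- function(annotations,
                          awakenings = tibble::tibble(user_id = character(),
                                                      night = integer(),
                                                      duration = numeric())) {
  if (any(annotations$sleep_onset < annotations$bed_entry))
    abort("sleep_metrics: sleep onset before bed entry")
  if (any(annotations$final_wake < annotations$sleep_onset))
    abort("sleep_metrics: final wake before sleep onset")
  w <- dplyr::summarise(dplyr::group_by(awakenings, .data$user_id, .data$night),
                        waso = sum(.data$duration), .groups = "drop")
  out <- dplyr::left_join(annotations, w, by = c("user_id", "night"))
  out$waso[is.na(out$waso)] <- 0
  out$time_in_bed <- out$final_wake - out$bed_entry
  out$sol <- out$sleep_onset - out$bed_entry
  out$tst <- (out$final_wake - out$sleep_onset) - out$waso
  out$sleep_efficiency <- out$tst / out$time_in_bed
  out[c("user_id", "night", "time_in_bed", "tst", "sol", "waso",
        "sleep_efficiency")]
}

#' Categorize users' activity patterns
#'
#' Cohort-relative labels: `low` = lowest quartile of mean daily steps,
#' `high` = highest quartile, `irregular` = day-to-day step coefficient of
#' variation above the cohort's 75th percentile (precedence over low/high),
#' remainder `typical`.
#'
#' @param nights Cleaned night tibble with `user_id` and `steps`.
#' @param min_days Minimum step days per user (default 7).
#' @return Tibble `user_id`, `steps_mean`, `steps_cv`, `activity_category`.
#' @export
categorize_activity <- function(nights, min_days = 7) {
  per <- dplyr::summarise(dplyr::group_by(nights, .data$user_id),
                          n_days = sum(!is.na(.data$steps)),
                          steps_mean = mean(.data$steps, na.rm = TRUE),
                          steps_cv = sd(.data$steps, na.rm = TRUE) /
                            mean(.data$steps, na.rm = TRUE),
                          .groups = "drop")
  if (any(per$n_days == 0)) abort("categorize_activity: user with empty step history")
  if (any(per$n_days < min_days))
    abort(sprintf("categorize_activity: need >= %d step days per user", min_days))
  q <- quantile(per$steps_mean, c(0.25, 0.75))
  cv75 <- quantile(per$steps_cv, 0.75)
  cat <- rep("typical", nrow(per))
  cat[per$steps_mean <= q[1]] <- "low"
  cat[per$steps_mean >= q[2]] <- "high"
  cat[per$steps_cv > cv75] <- "irregular"
  per$activity_category <- cat
  per[c("user_id", "steps_mean", "steps_cv", "activity_category")]
}

#' Cumulative sleep debt
#'
#' `debt_t = max(0, debt_{t-1} + baseline - TST_t)`: the running non-negative
#' shortfall of nightly sleep against a baseline requirement.
#'
#' @param tst Numeric vector of nightly total sleep times (minutes), in
#'   chronological order.
#' @param baseline_min Baseline nightly requirement (default 480).
#' @return Numeric vector of the same length: debt after each night.
#' @export
sleep_debt <- function(tst, baseline_min = 480) {
  if (baseline_min <= 0) abort("sleep_debt: baseline must be > 0")
  debt <- numeric(length(tst))
  d <- 0
  for (t in seq_along(tst)) {
    d <- max(0, d + baseline_min - tst[t])
    debt[t] <- d
  }
  debt
}

# the fixed 68-component schema: 4 lagged signals x 8 stats = 32,
# 12 current-night wearable aggregates, 4 bed + 4 bed 7-night means,
# 4 environment means, sleep debt, 4 circadian, age, 2 sex, 4 activity
LAG_SIGNALS <- c("steps", "hr_mean", "stress_index", "fatigue_index")
LAG_STATS <- c("lag1", "mean3", "sd3", "mean7", "sd7", "mean14", "sd14",
               "slope7")
CURRENT_COLS <- c(WEARABLE_COLS, "prior_rating")

#' Names of the 68 feature-vector components
#'
#' @return Character vector of length 68, in schema order.
#' @export
feature_schema <- function() {
  c(as.vector(outer(LAG_SIGNALS, LAG_STATS, paste, sep = "_")),
    CURRENT_COLS,
    BED_COLS, paste0(BED_COLS, "_mean7"),
    c("temp_mean", "light_mean", "noise_mean", "humidity_mean"),
    "sleep_debt",
    c("bedtime_sin", "bedtime_cos", "midsleep_sin", "midsleep_cos"),
    "age", c("sex_female", "sex_male"),
    paste0("activity_", c("low", "high", "irregular", "typical")))
}

# raw (pre-normalization) feature table, one row per user-night
raw_feature_table <- function(nights, users, activity, baseline_min = 480) {
  nights <- dplyr::arrange(nights, .data$user_id, .data$night)
  per_user <- dplyr::group_by(nights, .data$user_id)
  lagged <- dplyr::ungroup(dplyr::mutate(
    per_user,
    dplyr::across(dplyr::all_of(LAG_SIGNALS),
                  list(lag1 = ~ dplyr::lag(.x, default = dplyr::first(.x)),
                       mean3 = ~ roll_mean(.x, 3), sd3 = ~ roll_sd(.x, 3),
                       mean7 = ~ roll_mean(.x, 7), sd7 = ~ roll_sd(.x, 7),
                       mean14 = ~ roll_mean(.x, 14), sd14 = ~ roll_sd(.x, 14),
                       slope7 = ~ roll_slope(.x, 7)),
                  .names = "{.col}_{.fn}"),
    dplyr::across(dplyr::all_of(BED_COLS), ~ roll_mean(.x, 7),
                  .names = "{.col}_mean7"),
    prior_rating = {
      pr <- dplyr::lag(.data$rating)
      um <- mean(.data$rating, na.rm = TRUE)
      ifelse(is.na(pr), um, pr)
    },
    sleep_debt = sleep_debt(.data$tst, baseline_min),
    bedtime_sin = sin(2 * pi * .data$bedtime_min / 1440),
    bedtime_cos = cos(2 * pi * .data$bedtime_min / 1440),
    midsleep_sin = sin(2 * pi * .data$midsleep_min / 1440),
    midsleep_cos = cos(2 * pi * .data$midsleep_min / 1440)))
  out <- dplyr::left_join(lagged, users[c("user_id", "age", "sex")], by = "user_id")
  out <- dplyr::left_join(out, activity[c("user_id", "activity_category")],
                          by = "user_id")
  bad_sex <- setdiff(unique(out$sex), c("female", "male"))
  if (length(bad_sex))
    abort(sprintf("build_feature_matrix: unknown sex category: %s",
                  paste(bad_sex, collapse = ", ")))
  bad_act <- setdiff(unique(out$activity_category),
                     c("low", "high", "irregular", "typical"))
  if (length(bad_act))
    abort(sprintf("build_feature_matrix: unknown activity category: %s",
                  paste(bad_act, collapse = ", ")))
  out$sex_female <- as.numeric(out$sex == "female")
  out$sex_male <- as.numeric(out$sex == "male")
  for (a in c("low", "high", "irregular", "typical"))
    out[[paste0("activity_", a)]] <- as.numeric(out$activity_category == a)
  out
}

# schema components that are z-scored (continuous; not one-hot / circular)
normalized_components <- function() {
  setdiff(feature_schema(),
          c("bedtime_sin", "bedtime_cos", "midsleep_sin", "midsleep_cos",
            "sex_female", "sex_male",
            paste0("activity_", c("low", "high", "irregular", "typical"))))
}

#' Compute normalization statistics on training users
#'
#' Means and standard deviations of the continuous schema components,
#' computed on the given (training) users only, so test-set features are
#' scored with training statistics and no information leaks across the
#' grouped split.
#'
#' @param nights,users Cleaned cohort tables.
#' @param train_users Character vector of training user ids.
#' @param baseline_min Sleep-debt baseline.
#' @return A `sleeprec_feature_stats` list with `mean`, `sd` per component.
#' @export
feature_stats <- function(nights, users, train_users = users$user_id,
                          baseline_min = 480) {
  act <- categorize_activity(nights)
  raw <- raw_feature_table(nights[nights$user_id %in% train_users, ],
                           users[users$user_id %in% train_users, ],
                           act, baseline_min)
  comps <- normalized_components()
  mu <- vapply(comps, function(cl) mean(raw[[cl]], na.rm = TRUE), numeric(1))
  sg <- vapply(comps, function(cl) sd(raw[[cl]], na.rm = TRUE), numeric(1))
  sg[!is.finite(sg) | sg == 0] <- 1
  structure(list(mean = mu, sd = sg, activity = act,
                 baseline_min = baseline_min),
            class = "sleeprec_feature_stats")
}

#' Build the 68-component user-night feature matrix
#'
#' The deterministic per-user-night vector that feeds both the similarity
#' computations and the MLP ranker: 32 lagged activity/physiology statistics
#' (4 signals x lag-1 value, trailing 3/7/14-night means and SDs, 7-night
#' trend slope), 12 current-night wearable aggregates (including prior-night
#' rating, user mean when absent), the 4 bed features plus their 7-night
#' means, 4 environment means, cumulative sleep debt, circadian sine/cosine
#' encodings of bedtime and midsleep, age, and one-hot sex and activity
#' categories. Continuous components are z-scored on training statistics.
#'
#' @param nights,users Cleaned cohort tables.
#' @param stats A `sleeprec_feature_stats` from [feature_stats()] (computed
#'   on training users).
#' @return Tibble: `user_id`, `night`, then the 68 schema columns, all
#'   finite.
#' @export
build_feature_matrix <- function(nights, users, stats) {
  stopifnot(inherits(stats, "sleeprec_feature_stats"))
  raw <- raw_feature_table(nights, users, stats$activity, stats$baseline_min)
  comps <- feature_schema()
  out <- raw[c("user_id", "night", comps)]
  for (cl in normalized_components())
    out[[cl]] <- (out[[cl]] - stats$mean[[cl]]) / stats$sd[[cl]]
  m <- as.matrix(out[comps])
  if (any(!is.finite(m)))
    abort("build_feature_matrix: non-finite components after preprocessing")
  out
}

#' Per-user profile summaries
#'
#' Aggregates nightly records to one row per user: mean feature vector
#' components used for similarity, and the normalized quality score (mean of
#' per-user z-scored nightly ratings -- by construction centred near 0; the
#' cross-user ordering is carried by `quality_raw`, the plain mean rating,
#' which is what quality comparisons use).
#'
#' @param nights Cleaned night tibble with `rating`.
#' @return Tibble `user_id`, `quality_raw`, `quality_score`, `n_nights`.
#' @export
user_quality <- function(nights) {
  dplyr::summarise(
    dplyr::group_by(nights, .data$user_id),
    quality_raw = mean(.data$rating, na.rm = TRUE),
    quality_score = mean(scale(.data$rating)[, 1], na.rm = TRUE),
    n_nights = dplyr::n(), .groups = "drop")
}

#' User-level feature table for clustering and similarity
#'
#' Per-user summaries of the pre-/post-sleep indicators used by the
#' clustering stage (activity, heart rate, HRV-proxy stress/fatigue, bed
#' environment). Sleep outcomes are deliberately excluded: they are treated
#' as outcome measures, not clustering inputs.
#'
#' @param nights Cleaned night tibble.
#' @return Tibble with `user_id` and one column per summary feature.
#' @export
user_feature_table <- function(nights) {
  dplyr::summarise(
    dplyr::group_by(nights, .data$user_id),
    steps_mean = mean(.data$steps, na.rm = TRUE),
    steps_cv = sd(.data$steps, na.rm = TRUE) / mean(.data$steps, na.rm = TRUE),
    active_mean = mean(.data$active_minutes, na.rm = TRUE),
    mobility_mean = mean(.data$mobility, na.rm = TRUE),
    hr_mean = mean(.data$hr_mean, na.rm = TRUE),
    hr_sd_mean = mean(.data$hr_sd, na.rm = TRUE),
    stress_mean = mean(.data$stress_index, na.rm = TRUE),
    fatigue_mean = mean(.data$fatigue_index, na.rm = TRUE),
    light_mean = mean(.data$light_mean, na.rm = TRUE),
    noise_mean = mean(.data$noise_mean, na.rm = TRUE),
    temp_mean = mean(.data$temp_mean, na.rm = TRUE),
    humidity_mean = mean(.data$humidity_mean, na.rm = TRUE),
    .groups = "drop")
}
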