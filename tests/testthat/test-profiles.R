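test_that("cleaning is a no-op on complete cohorts", {
  pop <- tiny_population()
  out <- clean_cohort(pop$nights)
  expect_equal(out$nights, pop$nights)
  expect_equal(nrow(out$removed), 0)
  expect_equal(nrow(out$imputed), 0)
})

test_that("short gaps are imputed from flanking valid nights", {
  pop <- tiny_population()
  nights <- pop$nights
  i <- which(nights$user_id == "u001" & nights$night == 5)
  nights$hr_mean[i] <- NA
  out <- clean_cohort(nights)
  flank <- mean(nights$hr_mean[nights$user_id == "u001" &
                                 nights$night %in% c(4, 6)])
  expect_equal(out$nights$hr_mean[out$nights$user_id == "u001" &
                                    out$nights$night == 5], flank)
  expect_equal(out$imputed$column, "hr_mean")
})

test_that("whole-night drops are removed and match the injection log", {
  pop <- generate_population(cohort_spec(n_users = 100, n_nights = 84,
                                         seed = 33))
  inj <- inject_missingness(pop, list(gap_rate = 0, night_drop_rate = 0.009,
                                      unknown_rate = 0))
  out <- clean_cohort(inj$nights)
  log <- inj$truth$injections[inj$truth$injections$kind == "night_drop", ]
  expect_equal(nrow(out$removed), nrow(log))
  expect_setequal(paste(out$removed$user_id, out$removed$night),
                  paste(log$user_id, log$night))
})

test_that("unknown categorical entries are coded unknown", {
  pop <- tiny_population()
  inj <- inject_missingness(pop, list(gap_rate = 0, night_drop_rate = 0,
                                      unknown_rate = 0.2))
  out <- clean_cohort(inj$nights)
  expect_false(anyNA(out$nights$context_label))
  expect_gt(sum(out$nights$context_label == "unknown"), 0)
})

test_that("cleaning never imputes across users or long runs of missingness", {
  pop <- tiny_population(n_users = 3)
  nights <- pop$nights
  # first night of u002 missing: only the following night can flank it
  i <- which(nights$user_id == "u002" & nights$night == 1)
  nights$steps[i] <- NA
  out <- clean_cohort(nights)
  expect_equal(out$nights$steps[out$nights$user_id == "u002" &
                                  out$nights$night == 1],
               nights$steps[nights$user_id == "u002" & nights$night == 2])
})

test_that("sleep metrics follow their defining arithmetic", {
  ann <- tibble::tibble(user_id = "u1", night = 1:3,
                        bed_entry = c(0, 0, 10),
                        sleep_onset = c(20, 0, 30),
                        final_wake = c(480, 480, 500))
  wak <- tibble::tibble(user_id = "u1", night = c(1, 1, 1, 3),
                        duration = c(5, 10, 5, 40))
  m <- sleep_metrics(ann, wak)
  expect_equal(m$waso, c(20, 0, 40))
  expect_equal(m$sol, c(20, 0, 20))
  expect_equal(m$tst, c(440, 480, 430))
  expect_equal(m$time_in_bed, c(480, 480, 490))
  # in bed 480 asleep 420 -> efficiency 0.875
  ann2 <- tibble::tibble(user_id = "u1", night = 1, bed_entry = 0,
                         sleep_onset = 30, final_wake = 480)
  wak2 <- tibble::tibble(user_id = "u1", night = 1, duration = 30)
  expect_equal(sleep_metrics(ann2, wak2)$sleep_efficiency, 420 / 480)
  bad <- tibble::tibble(user_id = "u1", night = 1, bed_entry = 100,
                        sleep_onset = 50, final_wake = 480)
  expect_error(sleep_metrics(bad), "onset before bed entry")
})

test_that("activity categories follow cohort quartiles with irregular precedence", {
  set.seed(41)
  nights <- purrr::map_dfr(1:100, function(u) {
    mu <- 2000 + 100 * u           # distinct means, u100 highest
    tibble::tibble(user_id = sprintf("u%03d", u), night = 1:14,
                   steps = round(pmax(rnorm(14, mu, mu * 0.05), 0)))
  })
  act <- categorize_activity(nights)
  expect_equal(sum(act$steps_mean <= quantile(act$steps_mean, 0.25)), 25)
  expect_setequal(unique(act$activity_category),
                  c("low", "high", "irregular", "typical"))
  # highest-mean, low-CV user is "high" unless flagged irregular
  top <- act[which.max(act$steps_mean), ]
  expect_true(top$activity_category %in% c("high", "irregular"))
  expect_equal(sum(act$activity_category == "irregular"),
               sum(act$steps_cv > quantile(act$steps_cv, 0.75)))
  expect_error(categorize_activity(nights[nights$night <= 3, ]), ">= 7")
})

test_that("constant-steps users at the cohort median are typical", {
  nights <- purrr::map_dfr(1:20, function(u) {
    tibble::tibble(user_id = sprintf("u%02d", u), night = 1:7,
                   steps = 4000 + 100 * u)
  })
  nights$steps[nights$user_id == "u10"] <- 5000  # mid-range, zero CV
  act <- categorize_activity(nights)
  expect_equal(act$activity_category[act$user_id == "u10"], "typical")
})

test_that("sleep debt accumulates shortfall and never goes negative", {
  expect_equal(sleep_debt(rep(480, 5)), rep(0, 5))
  expect_equal(sleep_debt(rep(420, 3))[3], 180)
  # brute-force recursion oracle on random input
  set.seed(42)
  tst <- runif(50, 300, 600)
  oracle <- Reduce(function(d, t) max(0, d + 480 - t), tst, accumulate = TRUE,
                   init = 0)[-1]
  expect_equal(sleep_debt(tst), oracle)
  expect_error(sleep_debt(rep(400, 3), baseline_min = 0), "> 0")
})

test_that("sleep debt is monotone non-increasing in TST", {
  set.seed(43)
  tst <- runif(20, 300, 600)
  d1 <- sleep_debt(tst)
  tst2 <- tst; tst2[7] <- tst2[7] + 60
  expect_true(all(sleep_debt(tst2) <= d1))
})

test_that("feature matrix has exactly 68 finite schema components", {
  pop <- tiny_population(n_users = 8, n_nights = 16)
  stats <- feature_stats(pop$nights, pop$users)
  fm <- build_feature_matrix(pop$nights, pop$users, stats)
  expect_length(feature_schema(), 68)
  expect_equal(setdiff(names(fm), c("user_id", "night")), feature_schema())
  expect_true(all(is.finite(as.matrix(fm[feature_schema()]))))
  # one-hot blocks each sum to one
  expect_true(all(fm$sex_female + fm$sex_male == 1))
  act <- fm[paste0("activity_", c("low", "high", "irregular", "typical"))]
  expect_true(all(rowSums(act) == 1))
})

test_that("circadian encoding places midnight at (0, 1)", {
  pop <- tiny_population(n_users = 4, n_nights = 8)
  pop$nights$bedtime_min <- 0
  stats <- feature_stats(pop$nights, pop$users)
  fm <- build_feature_matrix(pop$nights, pop$users, stats)
  expect_equal(unique(fm$bedtime_sin), 0)
  expect_equal(unique(fm$bedtime_cos), 1)
})

test_that("normalization uses training statistics only (no leakage)", {
  pop <- tiny_population(n_users = 12, n_nights = 20)
  train <- sprintf("u%03d", 1:8)
  stats <- feature_stats(pop$nights, pop$users, train_users = train)
  fm <- build_feature_matrix(pop$nights, pop$users, stats)
  tr <- fm[fm$user_id %in% train, ]
  # continuous components are ~N(0,1) on training rows
  expect_lt(abs(mean(tr$stress_index)), 0.05)
  expect_equal(sd(tr$stress_index), 1, tolerance = 0.05)
  # a feature equal to the training mean maps to z = 0
  expect_equal((stats$mean[["stress_index"]] - stats$mean[["stress_index"]]) /
                 stats$sd[["stress_index"]], 0)
  # test rows are scored with the same statistics, so their mean may differ
  te <- fm[!fm$user_id %in% train, ]
  expect_false(isTRUE(all.equal(mean(te$steps_mean7), 0, tolerance = 1e-3)))
})

test_that("prior-night rating falls back to the user mean when absent", {
  pop <- tiny_population(n_users = 4, n_nights = 10)
  stats <- feature_stats(pop$nights, pop$users)
  raw <- sleeprec:::raw_feature_table(pop$nights, pop$users, stats$activity,
                                      480)
  u1 <- raw[raw$user_id == "u001", ]
  expect_equal(u1$prior_rating[1],
               mean(pop$nights$rating[pop$nights$user_id == "u001"]))
  expect_equal(u1$prior_rating[2],
               pop$nights$rating[pop$nights$user_id == "u001"][1])
})

test_that("quality summaries order users by mean rating", {
  pop <- tiny_population(n_users = 10, n_nights = 20)
  q <- user_quality(pop$nights)
  direct <- tapply(pop$nights$rating, pop$nights$user_id, mean)
  expect_equal(q$quality_raw, as.numeric(direct[q$user_id]))
})
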