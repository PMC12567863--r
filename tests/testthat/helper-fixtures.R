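# small deterministic fixtures shared across test files

tiny_spec <- function(n_users = 12, n_nights = 14, seed = 11L, ...) {
  cohort_spec(n_users = n_users, n_nights = n_nights, seed = seed, ...)
}

tiny_population <- function(...) generate_population(tiny_spec(...))

# cohort with well-separated planted groups for recovery tests
separated_population <- function(n_users = 90, n_nights = 21, seed = 5L) {
  generate_population(cohort_spec(n_users = n_users, n_nights = n_nights,
                                  cluster_mixture = c(1, 1, 1) / 3,
                                  seed = seed))
}
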