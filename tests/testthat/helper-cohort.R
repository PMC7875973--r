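## shared small cohorts, built once per test run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

## small but non-trivial cohort used across unit tests
tiny_cohort <- function() {
  cached_cohort("tiny", sim_config(
    n_subjects = 30, n_total = 120, n_cortex = 100, t_per_run = 65,
    n_runs = 2, n_parcels = 6, seed = 42
  ))
}

## a preprocessed scan with pure iid rows (for feature oracles)
noise_scan <- function(n_total = 40, t = 60, seed = 1, id = "s1") {
  X <- with_seed_test(seed, matrix(rnorm(n_total * t), n_total, t))
  X <- X - rowMeans(X)
  X <- X / sqrt(rowMeans(X^2))
  rest_scan(id, X, t, preprocessed = TRUE)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
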