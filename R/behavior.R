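#' Fisher z transformation
#'
#' Variance-stabilizing `atanh` transform of a correlation. Inputs at or
#' beyond `|r| = 1` are clipped to `1 - 1e-7` in magnitude with a warning.
#'
#' @param r correlation(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clipped before Fisher z transform")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Correlate prediction scores with behavior
#'
#' Pearson correlation between Fisher-z transformed per-subject prediction
#' scores and behavioral task accuracy, over subjects present in both tables.
#'
#' @param scores tibble with columns `subject_id`, `r` (one model/contrast
#'   slice of a [score_table()]).
#' @param behavior tibble with columns `subject_id`, `accuracy`.
#' @return scalar correlation.
#' @export
behavior_correlation <- function(scores, behavior) {
  merged <- dplyr::inner_join(
    dplyr::select(scores, "subject_id", "r"),
    dplyr::select(behavior, "subject_id", "accuracy"),
    by = "subject_id"
  )
  merged <- merged[stats::complete.cases(merged), ]
  if (nrow(merged) < 3) {
    stop("fewer than 3 matched subjects between scores and behavior",
         call. = FALSE)
  }
  cor(fisher_z(merged$r), merged$accuracy)
}

#' Multi-split behavioral benchmark
#'
#' Repeats the full fit/score/correlate pipeline over `n_splits` seeded
#' train/test permutations of the cohort, compares each model's per-split
#' behavioral correlations to the group-mean baseline's via the corrected
#' resampled t-test, and returns one row per model. All models share the
#' identical split sequence (required for the paired comparison).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param model_specs character vector of model names (see
#'   [fit_model_spec()]); `"group-mean"` is added automatically as the
#'   reference.
#' @param contrast contrast (and its linked behavior score) to analyze.
#' @param n_splits number of train/test permutations (default 20).
#' @param n_train,n_test split sizes; default an even split.
#' @param seed master seed.
#' @return list with `summary` (tibble: model, mean_r, sd_r, t, p vs the
#'   group-mean baseline) and `per_split` (tibble: model, split, r).
#' @export
multi_split_behavior_benchmark <- function(cohort, model_specs,
                                           contrast = names(cohort$maps)[1],
                                           n_splits = 20, n_train = NULL,
                                           n_test = NULL, seed = 1) {
  specs <- union(model_specs, "group-mean")
  beh <- dplyr::filter(cohort$behavior, .data$contrast_id == contrast)
  feats <- lapply(setNames(specs, specs), function(m) extract_features(cohort, m))
  rows <- purrr::map_dfr(seq_len(n_splits), function(sp) {
    split <- split_cohort(cohort, n_train, n_test,
                          seed = seed_for(seed, paste0("split", sp)))
    purrr::map_dfr(specs, function(m) {
      res <- fit_and_score(cohort, feats[[m]], m, split, contrast)
      tibble::tibble(
        model = m, split = sp,
        r = behavior_correlation(res, beh)
      )
    })
  })
  n1 <- if (is.null(n_train)) floor(length(cohort$subject_ids) / 2) else n_train
  n2 <- if (is.null(n_test)) length(cohort$subject_ids) - n1 else n_test
  base <- dplyr::filter(rows, .data$model == "group-mean")$r
  summary <- purrr::map_dfr(specs, function(m) {
    rs <- dplyr::filter(rows, .data$model == m)$r
    zs <- fisher_z(rs) - fisher_z(base)
    tt <- if (m == "group-mean") {
      list(t = 0, p = 0.5)
    } else corrected_resampled_ttest(zs, n1, n2)
    tibble::tibble(model = m, mean_r = mean(rs), sd_r = sd(rs),
                   t_vs_baseline = tt$t, p_vs_baseline = tt$p)
  })
  list(summary = summary, per_split = rows)
}
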