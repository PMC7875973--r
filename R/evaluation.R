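#' Pearson prediction score
#'
#' Standard Pearson correlation between a predicted and an observed
#' activation map across the cortical vertices. Invariant under affine maps
#' with positive slope of either argument.
#'
#' @param pred,truth [activation_map()]s or numeric vectors of equal length.
#' @return a correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   side has zero variance.
#' @export
pearson_score <- function(pred, truth) {
  p <- if (inherits(pred, "activation_map")) pred$values else as.numeric(pred)
  y <- if (inherits(truth, "activation_map")) truth$values else as.numeric(truth)
  stopifnot(length(p) == length(y))
  if (sd(p) < 1e-15 || sd(y) < 1e-15) {
    warning("zero-variance map; Pearson score undefined, recording NA")
    return(NA_real_)
  }
  cor(p, y)
}

#' Per-vertex predictive R-squared
#'
#' For each vertex `j`, `R2_j = 1 - sum_i (y_ij - yhat_ij)^2 /
#' sum_i (y_ij - ybar_j)^2`, with `ybar_j` the *test-subject* mean at that
#' vertex. Negative values are preserved: they mean the test mean out-predicts
#' the model there. Vertices with zero test variance are masked and counted.
#' The per-vertex test-target variance is retained as the aggregation weight.
#'
#' @param preds,truths numeric `n_test x n_cortex` matrices (rows are
#'   subjects), or lists of [activation_map()]s.
#' @return object of class `"r2_map"`: fields `r2`, `weight`, `mask`
#'   (TRUE where defined), `n_test`, `n_masked`.
#' @export
predictive_r2 <- function(preds, truths) {
  if (is.list(preds)) preds <- maps_matrix(preds)
  if (is.list(truths)) truths <- maps_matrix(truths)
  stopifnot(all(dim(preds) == dim(truths)), nrow(truths) >= 2)
  n <- nrow(truths)
  sse <- colSums((truths - preds)^2)
  centered <- sweep(truths, 2, colMeans(truths))
  sst <- colSums(centered^2)
  mask <- sst > 1e-24
  r2 <- rep(NA_real_, ncol(truths))
  r2[mask] <- 1 - sse[mask] / sst[mask]
  structure(
    list(
      r2 = r2,
      weight = sst / (n - 1),   # test-target variance per vertex
      mask = mask,
      n_test = n,
      n_masked = sum(!mask)
    ),
    class = "r2_map"
  )
}

#' @export
print.r2_map <- function(x, ...) {
  cat(sprintf(
    "<r2_map> %d vertices (%d masked), n_test = %d, weighted mean R^2 = %.4f\n",
    length(x$r2), x$n_masked, x$n_test, weighted_mean_r2(x)
  ))
  invisible(x)
}

#' Variance-weighted cortical mean R-squared
#'
#' Aggregates an [predictive_r2()] map into one number per model/contrast:
#' each unmasked vertex's R-squared weighted by the variance of the test
#' targets at that vertex.
#'
#' @param r2map an `"r2_map"`.
#' @return scalar weighted mean.
#' @export
weighted_mean_r2 <- function(r2map) {
  stopifnot(inherits(r2map, "r2_map"))
  m <- r2map$mask
  if (!any(m)) stop("all vertices are masked; weighted mean undefined",
                    call. = FALSE)
  sum(r2map$weight[m] * r2map$r2[m]) / sum(r2map$weight[m])
}

#' @describeIn tidiers-restpred tidy a per-vertex R-squared map
#' @method tidy r2_map
#' @export
tidy.r2_map <- function(x, ...) {
  tibble::tibble(
    vertex = seq_along(x$r2),
    r2 = x$r2,
    weight = x$weight,
    masked = !x$mask
  )
}

#' Tidiers and plots for restpred result objects
#'
#' broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods.
#'
#' @param x a fitted or evaluated restpred object.
#' @param object same as `x`, for `autoplot`.
#' @param ... unused.
#' @name tidiers-restpred
NULL

#' @describeIn tidiers-restpred one-row summary of an R-squared map
#' @method glance r2_map
#' @export
glance.r2_map <- function(x, ...) {
  tibble::tibble(
    n_vertices = length(x$r2),
    n_masked = x$n_masked,
    n_test = x$n_test,
    weighted_mean_r2 = weighted_mean_r2(x),
    median_r2 = median(x$r2, na.rm = TRUE),
    frac_positive = mean(x$r2 > 0, na.rm = TRUE)
  )
}

#' @describeIn tidiers-restpred per-vertex tidy view of a fitted model
#' @method tidy vertexwise_model
#' @export
tidy.vertexwise_model <- function(x, ...) {
  tibble::tibble(
    vertex = seq_along(x$intercepts),
    lambda = x$lambdas,
    intercept = x$intercepts,
    weight_norm = sqrt(rowSums(x$weights^2))
  )
}

#' @describeIn tidiers-restpred one-row summary of a fitted model
#' @method glance vertexwise_model
#' @export
glance.vertexwise_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    feature_kind = x$feature_kind,
    n_vertices = nrow(x$weights),
    n_features = ncol(x$weights),
    median_lambda = median(x$lambdas),
    median_weight_norm = median(sqrt(rowSums(x$weights^2)))
  )
}

#' @describeIn tidiers-restpred histogram of per-vertex R-squared with the
#'   weighted cortical mean marked
#' @method autoplot r2_map
#' @export
autoplot.r2_map <- function(object, ...) {
  df <- tidy(object)
  wm <- weighted_mean_r2(object)
  ggplot2::ggplot(df[!df$masked, ], ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = wm, linetype = 2) +
    ggplot2::labs(
      x = expression(R^2), y = "vertices",
      title = sprintf("Per-vertex predictive R² (weighted mean %.3f)", wm)
    )
}

#' Score predictions over a test cohort
#'
#' Produces a long tibble of per-subject Pearson scores -- one row per
#' (model, contrast, subject) -- ready for piping into significance tests or
#' plots.
#'
#' @param preds named list: `preds[[model]][[contrast]]` is a list of
#'   predicted [activation_map()]s over test subjects.
#' @param truths `truths[[contrast]]` is the matching list of observed maps.
#' @return tibble with columns model, contrast, subject_id, r.
#' @export
score_table <- function(preds, truths) {
  purrr::map_dfr(names(preds), function(model) {
    purrr::map_dfr(names(preds[[model]]), function(contrast) {
      pm <- preds[[model]][[contrast]]
      tm <- truths[[contrast]]
      tibble::tibble(
        model = model,
        contrast = contrast,
        subject_id = vapply(tm, function(m) m$subject_id, character(1)),
        r = vapply(seq_along(pm),
                   function(i) pearson_score(pm[[i]], tm[[i]]), numeric(1))
      )
    })
  })
}

#' Paired sign-flip permutation test
#'
#' One-sided test that model scores exceed baseline scores: the observed
#' statistic is the paired t over the per-subject differences, the null is
#' built by seeded random sign-flips of those differences, and
#' `p = (1 + #[t_perm >= t_obs]) / (1 + n_perm)`. Bonferroni correction is
#' applied across the contrast-battery comparisons.
#'
#' @param model_scores,baseline_scores equal-length numeric vectors
#'   (per-subject Pearson scores).
#' @param n_perm number of sign-flip draws (default 5000).
#' @param n_comparisons Bonferroni family size (default 47, the task
#'   contrast battery).
#' @param seed RNG seed.
#' @return list with `p_raw`, `p_bonferroni`, `t_obs`, `n_perm`.
#' @export
paired_permutation_test <- function(model_scores, baseline_scores,
                                    n_perm = 5000, n_comparisons = 47,
                                    seed = 1) {
  d <- model_scores - baseline_scores
  n <- length(d)
  stopifnot(n >= 3, length(baseline_scores) == n)
  if (all(abs(d) < 1e-15)) {
    return(list(p_raw = 1, p_bonferroni = 1, t_obs = 0, n_perm = n_perm))
  }
  tstat <- function(x) mean(x) / (sd(x) / sqrt(n))
  t_obs <- tstat(d)
  signs <- with_seed(seed,
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n))
  D <- signs * rep(d, each = n_perm)
  mu <- rowMeans(D)
  s2 <- (rowSums(D^2) - n * mu^2) / (n - 1)
  t_perm <- mu / sqrt(s2 / n)
  p_raw <- (1 + sum(t_perm >= t_obs)) / (1 + n_perm)
  list(
    p_raw = p_raw,
    p_bonferroni = min(1, n_comparisons * p_raw),
    t_obs = t_obs,
    n_perm = n_perm
  )
}

#' Corrected resampled t-test
#'
#' t-test over `k` repeated train/test splits with the variance inflation
#' `(1/k + n_test/n_train)` that accounts for the overlap between resampled
#' splits; one-sided p from the t distribution with `k - 1` df.
#'
#' @param per_split_diffs length-`k` vector of per-split score differences
#'   (model minus baseline).
#' @param n_train,n_test split sizes.
#' @return list with `t`, `p` (one-sided, H1: mean difference > 0), `df`, and
#'   a `degenerate` flag for zero-variance differences (t becomes signed
#'   infinity, p exactly 0/1/0.5).
#' @export
corrected_resampled_ttest <- function(per_split_diffs, n_train, n_test) {
  k <- length(per_split_diffs)
  stopifnot(k >= 2)
  dbar <- mean(per_split_diffs)
  s2 <- var(per_split_diffs)
  if (s2 < 1e-24) {
    t <- if (dbar > 0) Inf else if (dbar < 0) -Inf else 0
    p <- if (dbar > 0) 0 else if (dbar < 0) 1 else 0.5
    return(list(t = t, p = p, df = k - 1, degenerate = TRUE))
  }
  t <- dbar / sqrt((1 / k + n_test / n_train) * s2)
  list(t = t, p = pt(t, df = k - 1, lower.tail = FALSE), df = k - 1,
       degenerate = FALSE)
}

#' Learning curve over training-set size
#'
#' Refits a model on nested training subsets of increasing size (smaller
#' subsets are contained in larger ones, reducing Monte-Carlo variance) with
#' a fixed test set, and records mean Pearson score and weighted mean
#' R-squared at each size.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param model_spec a model name understood by [fit_model_spec()] (e.g.
#'   `"mmp-rr"`, `"group-mean"`).
#' @param train_sizes integer sizes (each `>= 3`).
#' @param split a [cohort_split()]: the train pool to draw subsets from and
#'   the fixed test set.
#' @param contrast contrast to evaluate (default the first).
#' @param seed seed controlling the nesting order.
#' @return tibble: n_train, mean_r, weighted_r2, model, contrast.
#' @export
learning_curve <- function(cohort, model_spec, train_sizes, split,
                           contrast = names(cohort$maps)[1], seed = 1) {
  if (any(train_sizes < 3)) stop("train sizes must be >= 3", call. = FALSE)
  if (any(train_sizes > length(split$train_ids))) {
    stop("train sizes exceed the available train pool", call. = FALSE)
  }
  pool <- with_seed(seed, sample(split$train_ids))
  feats <- extract_features(cohort, model_spec)
  purrr::map_dfr(sort(train_sizes), function(s) {
    sub <- cohort_split(pool[seq_len(s)], split$test_ids, seed = split$seed)
    res <- fit_and_score(cohort, feats, model_spec, sub, contrast)
    tibble::tibble(
      n_train = s, mean_r = mean(res$r, na.rm = TRUE),
      se_r = sd(res$r, na.rm = TRUE) / sqrt(sum(is.finite(res$r))),
      weighted_r2 = attr(res, "weighted_r2"),
      model = model_spec, contrast = contrast
    )
  })
}
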