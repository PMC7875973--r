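## Model registry and the one-command benchmark pipeline.
##
## Model names follow the battery convention:
##   group-mean, group-zstat      group-level baselines
##   anat-rr                      per-vertex ridge on 6 anatomical maps
##   mmp-rr / mmp-ols / mmp-parcelrr   parcel-mean connectome + per-vertex
##                                ridge / OLS / parcel-shared-lambda ridge
##   mmp-rr-dr                    dual-regression subject maps + ridge
##   mmp-rr-pcr                   PCR semi-partial connectome + ridge
##   grp-rr                       Gaussian random projection + ridge
##   gica-rest-rr / gica-task-rr  group-ICA maps (from rest / task runs) + ridge
##   af / af-mod                  activity flow, unfitted / 2-parameter OLS

MODEL_SPECS <- c(
  "group-mean", "group-zstat", "anat-rr",
  "mmp-rr", "mmp-ols", "mmp-parcelrr", "mmp-rr-dr", "mmp-rr-pcr",
  "grp-rr", "gica-rest-rr", "gica-task-rr", "af", "af-mod"
)

#' Precompute split-independent features for a model
#'
#' Preprocesses the cohort's rest scans and computes whatever per-subject
#' features the named model needs that do not depend on the train/test split
#' (parcel-mean, dual-regression, PCR and random-projection connectomes).
#' Split-dependent features (group-ICA maps, activity-flow templates) are
#' computed inside [fit_and_score()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param spec model name (see [fit_model_spec()]).
#' @param opts named list of extractor options: `grp_f` (random-projection
#'   features, default 379), `n_components` (group ICA, default 80),
#'   `pcr_n_pcs` (default 64 at synthetic scale), `pcr_radius_mm`
#'   (default 10), `seed`.
#' @return an opaque feature bundle consumed by [fit_and_score()].
#' @export
extract_features <- function(cohort, spec, opts = list()) {
  spec <- match.arg(spec, MODEL_SPECS)
  o <- utils::modifyList(
    list(grp_f = 379, n_components = 80, pcr_n_pcs = 64,
         pcr_radius_mm = 10, seed = 1),
    opts
  )
  geom <- cohort$geometry
  out <- list(spec = spec, opts = o, pp = NULL, connectomes = NULL)
  if (spec %in% c("group-mean", "group-zstat", "anat-rr")) return(out)

  pp <- lapply(cohort$scans, preprocess_rest)
  names(pp) <- cohort$subject_ids
  out$pp <- pp
  cn <- switch(spec,
    "mmp-rr" = , "mmp-ols" = , "mmp-parcelrr" = {
      A <- parcel_projection(cohort$parcellation)
      lapply(pp, function(s) normalize_features(semi_dense_connectome(s, A)))
    },
    "grp-rr" = {
      A <- gaussian_random_projection(geom$n_total, f = o$grp_f, seed = o$seed)
      lapply(pp, function(s) normalize_features(semi_dense_connectome(s, A)))
    },
    "mmp-rr-dr" = {
      A <- parcel_projection(cohort$parcellation)
      lapply(pp, function(s) normalize_features(dual_regression_features(s, A)))
    },
    "mmp-rr-pcr" = {
      lapply(pp, function(s) {
        normalize_features(pcr_semipartial_connectome(
          s, cohort$parcellation, geom,
          n_pcs = o$pcr_n_pcs, mask_radius_mm = o$pcr_radius_mm, seed = o$seed
        ))
      })
    },
    NULL
  )
  if (!is.null(cn)) names(cn) <- cohort$subject_ids
  out$connectomes <- cn
  out
}

#' Fit one model on a split and score the test subjects
#'
#' Computes split-dependent features where needed (group-ICA maps from the
#' training scans or task runs, activity-flow templates from the training
#' maps), fits the model named by `spec` on the training subjects, predicts
#' every test subject's activation map, and scores predictions.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param feats result of [extract_features()] for the same model.
#' @param spec model name.
#' @param split a [cohort_split()].
#' @param contrast contrast id to predict.
#' @return tibble with columns `subject_id`, `r` (one row per test subject)
#'   and attributes `weighted_r2`, `r2_map` (the [predictive_r2()] object),
#'   `model` (the fitted object), and `predictions`.
#' @export
fit_and_score <- function(cohort, feats, spec, split, contrast) {
  spec <- match.arg(spec, MODEL_SPECS)
  stopifnot(identical(feats$spec, spec))
  geom <- cohort$geometry
  o <- feats$opts
  maps <- cohort$maps[[contrast]]
  if (is.null(maps)) stop(sprintf("unknown contrast '%s'", contrast), call. = FALSE)
  names(maps) <- vapply(maps, function(m) m$subject_id, character(1))
  train <- split$train_ids
  test <- split$test_ids
  names(cohort$anatomical) <- cohort$subject_ids

  cn <- feats$connectomes
  if (spec %in% c("gica-rest-rr", "gica-task-rr")) {
    if (spec == "gica-rest-rr") {
      A <- group_ica(feats$pp[train], n_components = o$n_components,
                     seed = o$seed)
    } else {
      if (is.null(cohort$task_series)) {
        stop("cohort carries no task series; regenerate with task_series = TRUE",
             call. = FALSE)
      }
      others <- setdiff(names(cohort$task_series), contrast)
      idx <- match(train, cohort$subject_ids)
      concat <- lapply(idx, function(i) {
        runs <- lapply(others, function(cc) cohort$task_series[[cc]][[i]])
        preprocess_rest(rest_scan(
          cohort$subject_ids[i],
          do.call(cbind, lapply(runs, function(r) r$data)),
          run_boundaries = vapply(runs, function(r) ncol(r$data), integer(1))
        ))
      })
      A <- group_ica(concat, n_components = o$n_components, seed = o$seed)
    }
    cn <- lapply(feats$pp, function(s) {
      normalize_features(semi_dense_connectome(s, A))
    })
    names(cn) <- cohort$subject_ids
  }
  if (spec %in% c("af", "af-mod")) {
    template <- colMeans(maps_matrix(maps[train]))
    cn <- lapply(feats$pp, function(s) activity_flow_features(s, template, geom))
    names(cn) <- cohort$subject_ids
    if (spec == "af-mod") cn <- lapply(cn, normalize_features)
  }

  model <- switch(spec,
    "group-mean" = group_mean(maps[train]),
    "group-zstat" = group_zstat(maps[train]),
    "af" = activity_flow_model(),
    "anat-rr" = fit_anatomical_rr(cohort$anatomical[train], maps[train]),
    "af-mod" = fit_vertexwise(cn[train], maps[train], geom, method = "af_mod"),
    "mmp-ols" = fit_vertexwise(cn[train], maps[train], geom, method = "ols"),
    "mmp-parcelrr" = fit_parcel_rr(cn[train], maps[train], geom,
                                   cohort$parcellation),
    ## all remaining specs are per-vertex GCV ridge on their features
    fit_vertexwise(cn[train], maps[train], geom, method = "rr")
  )

  preds <- lapply(test, function(id) {
    if (inherits(model, "baseline_model") && model$kind != "af") {
      predict(model, subject_id = id, contrast_id = contrast)
    } else if (spec == "anat-rr") {
      predict(model, cohort$anatomical[[id]], subject_id = id,
              contrast_id = contrast)
    } else {
      predict(model, cn[[id]], geom = geom, contrast_id = contrast)
    }
  })
  truths <- maps[test]
  scores <- tibble::tibble(
    subject_id = test,
    r = vapply(seq_along(test),
               function(i) pearson_score(preds[[i]], truths[[i]]), numeric(1))
  )
  r2 <- predictive_r2(preds, truths)
  attr(scores, "weighted_r2") <- weighted_mean_r2(r2)
  attr(scores, "r2_map") <- r2
  attr(scores, "model") <- model
  attr(scores, "predictions") <- preds
  scores
}

#' Fit one model of the battery
#'
#' Convenience wrapper returning the fitted model object itself (rather than
#' test scores): extracts features, fits on the split's training subjects.
#'
#' @inheritParams fit_and_score
#' @param opts extractor options, see [extract_features()].
#' @return the fitted model (a [vertexwise_model()] or baseline model).
#' @export
fit_model_spec <- function(cohort, spec, split, contrast, opts = list()) {
  feats <- extract_features(cohort, spec, opts)
  res <- fit_and_score(cohort, feats, spec, split, contrast)
  attr(res, "model")
}

#' Benchmark configuration
#'
#' Validates and resolves a benchmark configuration (defaults filled in,
#' unknown keys rejected). Recognized top-level keys: `cohort` (arguments to
#' [sim_config()]), `models` (character vector from the battery), `split`
#' (`n_train`, `n_test`, `seed`), `evaluation` (`n_perm`, `contrasts`),
#' `learning_curve` (`sizes`, `model` or `NULL`), `features` (extractor
#' options), `out_dir`, `seed`.
#'
#' @param config named list (e.g. parsed from YAML).
#' @return resolved configuration list of class `"bench_config"`.
#' @export
bench_config <- function(config = list()) {
  defaults <- list(
    cohort = list(),
    models = c("group-mean", "group-zstat", "mmp-rr"),
    split = list(n_train = NULL, n_test = NULL, seed = 1),
    evaluation = list(n_perm = 5000, contrasts = NULL),
    learning_curve = NULL,
    features = list(),
    out_dir = "restpred-benchmark",
    seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$models, MODEL_SPECS)
  if (length(bad)) {
    stop(sprintf("unknown model name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  unknown_cohort <- setdiff(names(cfg$cohort), names(formals(sim_config)))
  if (length(unknown_cohort)) {
    stop(sprintf("unknown cohort key(s): %s",
                 paste(unknown_cohort, collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "bench_config")
}

#' Run the full benchmark pipeline
#'
#' Simulates (or reuses) a cohort, fits every configured model on a shared
#' train/test split, scores all test subjects per contrast, tests each model
#' against the group-mean baseline with the paired sign-flip permutation
#' test, optionally computes a learning curve, and writes all products to the
#' output directory: `scores.tsv`, `r2_summary.tsv`, `significance.tsv`,
#' `curves.tsv`, `resolved_config.yaml`, `log.txt`. Fully deterministic given
#' the configuration.
#'
#' @param config a [bench_config()] (or plain list coerced through it).
#' @param cohort optionally, a pre-built [simulate_cohort()] result.
#' @return (invisibly) list with `scores`, `r2_summary`, `significance`,
#'   `curves`, `out_dir`, `cohort`.
#' @export
run_benchmark <- function(config = list(), cohort = NULL) {
  cfg <- if (inherits(config, "bench_config")) config else bench_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  note("stage simulate: seed %d", cfg$seed)
  if (is.null(cohort)) {
    sim_args <- utils::modifyList(list(seed = seed_for(cfg$seed, "cohort")),
                                  cfg$cohort)
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
  }
  contrasts <- cfg$evaluation$contrasts
  if (is.null(contrasts)) contrasts <- names(cohort$maps)
  split <- split_cohort(cohort, cfg$split$n_train, cfg$split$n_test,
                        seed = seed_for(cfg$seed, "split"))
  note("split: %d train / %d test subjects",
       length(split$train_ids), length(split$test_ids))

  fopts <- utils::modifyList(list(seed = seed_for(cfg$seed, "features")),
                             cfg$features)
  scores_list <- list()
  r2_rows <- list()
  for (m in cfg$models) {
    note("stage fit: model %s", m)
    feats <- extract_features(cohort, m, fopts)
    for (cc in contrasts) {
      res <- fit_and_score(cohort, feats, m, split, cc)
      scores_list[[paste(m, cc)]] <- dplyr::mutate(
        res, model = m, contrast = cc, .before = 1
      )
      lam <- attr(res, "model")$lambdas
      r2_rows[[paste(m, cc)]] <- tibble::tibble(
        model = m, contrast = cc,
        mean_r = mean(res$r, na.rm = TRUE),
        sd_r = sd(res$r),
        weighted_r2 = attr(res, "weighted_r2"),
        median_lambda = if (is.null(lam)) NA_real_ else median(lam)
      )
    }
  }
  scores <- dplyr::bind_rows(scores_list)
  r2_summary <- dplyr::bind_rows(r2_rows)

  note("stage significance: %d permutations vs group-mean",
       cfg$evaluation$n_perm)
  significance <- NULL
  if ("group-mean" %in% cfg$models) {
    significance <- purrr::map_dfr(
      setdiff(cfg$models, "group-mean"),
      function(m) purrr::map_dfr(contrasts, function(cc) {
        ms <- dplyr::filter(scores, .data$model == m, .data$contrast == cc)$r
        bs <- dplyr::filter(scores, .data$model == "group-mean",
                            .data$contrast == cc)$r
        pt <- paired_permutation_test(
          ms, bs, n_perm = cfg$evaluation$n_perm,
          n_comparisons = length(contrasts),
          seed = seed_for(cfg$seed, paste0("perm_", m, "_", cc))
        )
        tibble::tibble(model = m, contrast = cc, t = pt$t_obs,
                       p_raw = pt$p_raw, p_bonferroni = pt$p_bonferroni)
      })
    )
  }

  curves <- NULL
  if (!is.null(cfg$learning_curve)) {
    lc <- cfg$learning_curve
    note("stage learning_curve: model %s", lc$model)
    curves <- learning_curve(cohort, lc$model, lc$sizes, split,
                             contrast = contrasts[1],
                             seed = seed_for(cfg$seed, "curve"))
  }

  note("stage write: %s", cfg$out_dir)
  write_tsv <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(scores, "scores.tsv")
  write_tsv(r2_summary, "r2_summary.tsv")
  write_tsv(significance, "significance.tsv")
  write_tsv(curves, "curves.tsv")
  resolved <- unclass(cfg)
  resolved$config_hash <- seed_for(0, paste(deparse(resolved), collapse = ""))
  yaml::write_yaml(resolved, file.path(cfg$out_dir, "resolved_config.yaml"))
  writeLines(log_lines, log_path)

  invisible(list(scores = scores, r2_summary = r2_summary,
                 significance = significance, curves = curves,
                 out_dir = cfg$out_dir, cohort = cohort))
}

#' Heat-map of a benchmark score table
#'
#' @param scores long score tibble (model, contrast, subject_id, r) as
#'   produced by [run_benchmark()] or [score_table()].
#' @return a ggplot: models x contrasts tile plot of mean Pearson score, rows
#'   ordered by subject-wise mean across contrasts.
#' @export
plot_score_matrix <- function(scores) {
  summ <- scores |>
    dplyr::group_by(.data$model, .data$contrast) |>
    dplyr::summarise(mean_r = mean(.data$r, na.rm = TRUE), .groups = "drop")
  ord <- summ |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(m = mean(.data$mean_r), .groups = "drop") |>
    dplyr::arrange(.data$m)
  summ$model <- factor(summ$model, levels = ord$model)
  ggplot2::ggplot(summ, ggplot2::aes(.data$contrast, .data$model,
                                     fill = .data$mean_r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean r",
                  title = "Mean test-subject Pearson score")
}

#' Learning-curve plot
#'
#' @param curves tibble from [learning_curve()] (possibly row-bound over
#'   models).
#' @return a ggplot of mean Pearson score against training-set size.
#' @export
plot_learning_curve <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$n_train, .data$mean_r,
                                       color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training subjects", y = "mean Pearson r",
                  title = "Learning curve")
}
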