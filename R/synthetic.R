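#' Synthetic cohort configuration
#'
#' Defines the study conditions of a fully self-contained synthetic
#' grayordinate cohort with planted ground truth. Rest series mix
#' subject-specific latent spatial networks with temporally autocorrelated
#' time courses; task maps share the same subject-specific components with a
#' spatially heterogeneous signal-to-noise profile (stereotyped
#' "primary-sensory" vertices vs variable "association" vertices); behavior
#' scores are coupled to each subject's planted rest-task alignment.
#'
#' @param n_subjects cohort size (default 120, supporting a 60/60 split).
#' @param n_total,n_cortex grayordinate and cortical vertex counts.
#' @param t_per_run frames per rest run (before discarding).
#' @param n_runs rest runs per subject.
#' @param n_latent number of latent spatial networks.
#' @param n_modes number of shared spatial deviation modes carrying
#'   inter-subject variation (subject deviations are random loadings on this
#'   fixed basis).
#' @param n_parcels regions in the synthetic parcellation.
#' @param subject_dev_sd SD of subject-specific deviations of the latent
#'   maps, on the scale of the (unit-SD) group maps.
#' @param snr_profile per-cortical-vertex ratio of predictable-signal SD to
#'   task-noise SD. Default: 0.15 on the "primary-sensory" half of the
#'   cortex, 1.0 on the "association" half: explainable fractions of about
#'   0.02 and 0.5 of inter-subject task-map variance, an idealization of the
#'   stereotyped-sensory vs variable-association contrast.
#' @param noise_sd_profile per-cortical-vertex task-noise SD (default 1
#'   everywhere); the predictable-signal SD at a vertex is
#'   `snr_profile * noise_sd_profile`, so the SNR ratio -- and the oracle
#'   ceiling -- are unchanged by this profile.
#' @param behavior_coupling correlation strength in `[0, 1]` between each
#'   subject's rest-task alignment and their behavioral accuracy.
#' @param subject_scale_sd log-SD of the per-subject amplitude applied to the
#'   deviation maps; this amplitude (on the log scale) is the planted
#'   rest-task alignment scalar.
#' @param rest_noise_sd SD of the i.i.d. rest measurement noise.
#' @param ar_coef AR(1) coefficient of the latent time courses (BOLD-like
#'   temporal smoothness).
#' @param group_amplitude scale of the shared group activation pattern in the
#'   task maps (z-map-like units).
#' @param contrasts character vector of contrast names.
#' @param task_series also generate per-contrast task time series (used by
#'   task-derived group ICA)? Default `FALSE`.
#' @param task_t_per_run frames per task run when `task_series = TRUE`.
#' @param seed integer master seed; every source of randomness derives from
#'   it.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 120, n_total = 600, n_cortex = 500,
                       t_per_run = 405, n_runs = 2, n_latent = 8, n_modes = 3,
                       n_parcels = 12,
                       subject_dev_sd = 0.5, snr_profile = NULL,
                       noise_sd_profile = NULL,
                       behavior_coupling = 0.6, subject_scale_sd = 0.2,
                       rest_noise_sd = 1, ar_coef = 0.5,
                       group_amplitude = 3,
                       contrasts = c("nback", "math_story", "relational"),
                       task_series = FALSE, task_t_per_run = 125,
                       seed = 1) {
  if (is.null(snr_profile)) {
    half <- floor(n_cortex / 2)
    snr_profile <- c(rep(0.15, half), rep(1, n_cortex - half))
  }
  if (is.null(noise_sd_profile)) noise_sd_profile <- rep(1, n_cortex)
  stopifnot(
    length(noise_sd_profile) == n_cortex, all(noise_sd_profile > 0),
    n_subjects > 0, n_total >= n_cortex, n_cortex >= 3, t_per_run > 0,
    n_runs > 0, n_latent > 0, n_modes > 0, n_parcels > 0,
    n_parcels <= n_total, subject_dev_sd >= 0,
    length(snr_profile) == n_cortex,
    behavior_coupling >= 0, behavior_coupling <= 1
  )
  if (all(snr_profile == 0)) {
    stop("snr_profile must not be identically zero", call. = FALSE)
  }
  structure(
    list(
      n_subjects = n_subjects, n_total = n_total, n_cortex = n_cortex,
      t_per_run = t_per_run, n_runs = n_runs, n_latent = n_latent,
      n_modes = n_modes, n_parcels = n_parcels,
      subject_dev_sd = subject_dev_sd, snr_profile = snr_profile,
      noise_sd_profile = noise_sd_profile,
      behavior_coupling = behavior_coupling,
      subject_scale_sd = subject_scale_sd,
      rest_noise_sd = rest_noise_sd, ar_coef = ar_coef,
      group_amplitude = group_amplitude, contrasts = contrasts,
      task_series = task_series, task_t_per_run = task_t_per_run,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Seeded spatially contiguous parcellation
#'
#' Assigns every grayordinate to its nearest of `K` seeded centroid
#' grayordinates (Euclidean metric), producing nonempty, spatially compact
#' regions -- a synthetic stand-in for an expert multimodal parcellation.
#'
#' @param geom a [geometry()] with coordinates.
#' @param K number of regions (`K <= n_total`).
#' @param seed seed for the centroid draw.
#' @return a [parcellation()].
#' @export
make_parcellation <- function(geom, K, seed = 1) {
  if (K > geom$n_total) stop("K must not exceed n_total", call. = FALSE)
  centroids <- with_seed(seed, sample.int(geom$n_total, K))
  D <- grayordinate_distances_euclidean(geom, centroids)
  parcellation(max.col(-D, ties.method = "first"), K = K)
}

## Euclidean-only distance from every grayordinate to a set of points
grayordinate_distances_euclidean <- function(geom, to) {
  P <- geom$coordinates
  Q <- geom$coordinates[to, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  sqrt(pmax(d2, 0))
}

## Gaussian spatial smoother over the grayordinate axis (rows normalized)
smoothing_operator <- function(geom, bandwidth_mm) {
  D <- grayordinate_distances(geom)
  S <- exp(-D^2 / (2 * bandwidth_mm^2))
  S / rowSums(S)
}

## smooth standardized random fields: n_fields x n_total, each mean 0 sd 1
smooth_fields <- function(n_fields, Sm, seed) {
  raw <- with_seed(seed, matrix(rnorm(n_fields * nrow(Sm)), n_fields))
  F <- tcrossprod(raw, Sm)
  F <- F - rowMeans(F)
  F / apply(F, 1, sd)
}

ar1_series <- function(n_series, t, coef, seed) {
  innov <- with_seed(seed, matrix(rnorm(n_series * t), n_series, t))
  out <- innov * sqrt(1 - coef^2)
  out[, 1] <- innov[, 1]
  for (k in 2:t) out[, k] <- coef * out[, k - 1] + out[, k]
  out
}

#' Simulate a synthetic cohort
#'
#' Generates geometry, a parcellation, per-subject raw rest scans
#' (`X_i = t(M_i) T_i + E_i` with `M_i = group_maps + subject_deviations_i`),
#' per-contrast task activation maps sharing the subject-specific components
#' under the configured SNR profile, 6 anatomical feature maps per subject,
#' behavior scores coupled to the planted rest-task alignment, and the full
#' ground truth. Bit-reproducible from the configuration alone.
#'
#' @param config a [sim_config()].
#' @return a list of class `"synthetic_cohort"` with elements `geometry`,
#'   `parcellation`, `scans` (raw [rest_scan()]s), `maps` (list by contrast of
#'   lists of [activation_map()]s), `anatomical` (list of `n_cortex x 6`
#'   matrices), `behavior` (tibble: subject_id, contrast_id, accuracy),
#'   `task_series` (optional, list by contrast of raw [rest_scan()]s),
#'   `subject_ids`, `config`, and `ground_truth` (group maps, per-subject
#'   deviations, task loadings, noise SD map, planted alignment, noiseless
#'   signal maps, and the per-vertex oracle R-squared ceiling
#'   `snr^2 / (snr^2 + 1)`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  geom <- make_geometry(cf$n_total, cf$n_cortex)
  parc <- make_parcellation(geom, K = cf$n_parcels,
                            seed = seed_for(cf$seed, "parcellation"))
  Sm <- smoothing_operator(geom, bandwidth_mm = 30)
  subject_ids <- sprintf("sub-%03d", seq_len(cf$n_subjects))

  group_maps <- smooth_fields(cf$n_latent, Sm, seed_for(cf$seed, "group_maps"))
  ## subject amplitude: log-normal; its log is the planted rest-task alignment
  log_a <- with_seed(seed_for(cf$seed, "amplitude"),
                     rnorm(cf$n_subjects, sd = cf$subject_scale_sd))
  a <- exp(log_a)
  ## subject deviations live on a fixed low-dimensional basis of smooth
  ## "deviation modes": individual functional topography varies along a few
  ## shared spatial dimensions, with i.i.d. subject loadings
  modes <- lapply(seq_len(cf$n_modes), function(m) {
    smooth_fields(cf$n_latent, Sm, seed_for(cf$seed, paste0("mode", m)))
  })
  loadings_dev <- with_seed(seed_for(cf$seed, "dev_loadings"),
                            matrix(rnorm(cf$n_subjects * cf$n_modes),
                                   cf$n_subjects, cf$n_modes) / sqrt(cf$n_modes))
  deviations <- lapply(seq_len(cf$n_subjects), function(i) {
    D <- matrix(0, cf$n_latent, cf$n_total)
    for (m in seq_len(cf$n_modes)) D <- D + loadings_dev[i, m] * modes[[m]]
    cf$subject_dev_sd * a[i] * D
  })

  t_gen <- cf$t_per_run * cf$n_runs
  scans <- lapply(seq_len(cf$n_subjects), function(i) {
    M <- group_maps + deviations[[i]]
    TC <- ar1_series(cf$n_latent, t_gen, cf$ar_coef,
                     seed_for(cf$seed, paste0("tc", i)))
    E <- with_seed(seed_for(cf$seed, paste0("noise", i)),
                   matrix(rnorm(cf$n_total * t_gen, sd = cf$rest_noise_sd),
                          cf$n_total, t_gen))
    rest_scan(subject_ids[i], crossprod(M, TC) + E,
              run_boundaries = rep(cf$t_per_run, cf$n_runs))
  })

  ## task maps: per contrast, the subject-specific signal is the loading-
  ## weighted latent map, standardized per vertex across subjects and scaled
  ## by the SNR profile; task noise has unit SD
  ctx <- geom$cortex_index
  loadings <- lapply(seq_along(cf$contrasts), function(c) {
    v <- with_seed(seed_for(cf$seed, paste0("loadings", c)), rnorm(cf$n_latent))
    v / sqrt(sum(v^2))
  })
  names(loadings) <- cf$contrasts
  maps <- list()
  signal_maps <- list()
  for (cname in cf$contrasts) {
    tau <- loadings[[cname]]
    base <- as.numeric(crossprod(group_maps[, ctx, drop = FALSE], tau))
    sig <- do.call(rbind, lapply(deviations, function(Dv) {
      as.numeric(crossprod(Dv[, ctx, drop = FALSE], tau))
    }))
    mu <- colMeans(sig)
    sdv <- apply(sig, 2, sd)
    z <- sweep(sig, 2, mu)
    z <- sweep(z, 2, ifelse(sdv < 1e-12, 1, sdv), `/`)
    noiseless <- cf$group_amplitude * matrix(base, cf$n_subjects, cf$n_cortex,
                                             byrow = TRUE) +
      sweep(z, 2, cf$snr_profile * cf$noise_sd_profile, `*`)
    eps <- with_seed(seed_for(cf$seed, paste0("taskeps_", cname)),
                     matrix(rnorm(cf$n_subjects * cf$n_cortex),
                            cf$n_subjects, cf$n_cortex))
    Y <- noiseless + sweep(eps, 2, cf$noise_sd_profile, `*`)
    maps[[cname]] <- lapply(seq_len(cf$n_subjects), function(i) {
      activation_map(subject_ids[i], cname, Y[i, ])
    })
    signal_maps[[cname]] <- noiseless
  }

  ## anatomical stand-ins: 6 smooth group fields correlated with the SNR
  ## profile at strength 0.3, plus small smooth subject-specific variation
  snr_std <- (cf$snr_profile - mean(cf$snr_profile)) / sd(cf$snr_profile)
  anat_group <- smooth_fields(6, Sm, seed_for(cf$seed, "anat_group"))[, ctx, drop = FALSE]
  anat_group <- 0.3 * matrix(snr_std, 6, cf$n_cortex, byrow = TRUE) +
    sqrt(1 - 0.3^2) * anat_group
  anatomical <- lapply(seq_len(cf$n_subjects), function(i) {
    pert <- smooth_fields(6, Sm, seed_for(cf$seed, paste0("anat", i)))[, ctx, drop = FALSE]
    t(anat_group + 0.5 * pert)
  })

  ## behavior: coupling to the standardized planted alignment
  alignment <- (log_a - mean(log_a)) / sd(log_a)
  behavior <- dplyr::bind_rows(lapply(cf$contrasts, function(cname) {
    eta <- with_seed(seed_for(cf$seed, paste0("behavior_", cname)),
                     rnorm(cf$n_subjects))
    tibble::tibble(
      subject_id = subject_ids,
      contrast_id = cname,
      accuracy = cf$behavior_coupling * alignment +
        sqrt(1 - cf$behavior_coupling^2) * eta
    )
  }))

  task_series <- NULL
  if (isTRUE(cf$task_series)) {
    task_series <- lapply(cf$contrasts, function(cname) {
      gain <- 0.5 + abs(loadings[[cname]])
      lapply(seq_len(cf$n_subjects), function(i) {
        M <- group_maps + deviations[[i]]
        TC <- gain * ar1_series(cf$n_latent, cf$task_t_per_run, cf$ar_coef,
                                seed_for(cf$seed, paste0("ttc_", cname, "_", i)))
        E <- with_seed(seed_for(cf$seed, paste0("tnoise_", cname, "_", i)),
                       matrix(rnorm(cf$n_total * cf$task_t_per_run,
                                    sd = cf$rest_noise_sd),
                              cf$n_total, cf$task_t_per_run))
        rest_scan(subject_ids[i], crossprod(M, TC) + E,
                  run_boundaries = cf$task_t_per_run)
      })
    })
    names(task_series) <- cf$contrasts
  }

  structure(
    list(
      geometry = geom, parcellation = parc, scans = scans, maps = maps,
      anatomical = anatomical, behavior = behavior,
      task_series = task_series, subject_ids = subject_ids, config = cf,
      ground_truth = list(
        group_maps = group_maps,
        subject_deviations = deviations,
        task_loadings = loadings,
        noise_sd_map = cf$noise_sd_profile,
        snr_profile = cf$snr_profile,
        oracle_ceiling = cf$snr_profile^2 / (cf$snr_profile^2 + 1),
        alignment = alignment,
        signal_maps = signal_maps
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d grayordinates (%d cortical), %d contrasts, seed %d\n",
    length(x$scans), x$geometry$n_total, x$geometry$n_cortex,
    length(x$maps), x$config$seed
  ))
  invisible(x)
}

#' Default train/test split of a synthetic cohort
#'
#' Seeded random partition into train and test halves (or the given sizes).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param n_train,n_test subset sizes; default an even split.
#' @param seed split seed.
#' @return a [cohort_split()].
#' @export
split_cohort <- function(cohort, n_train = NULL, n_test = NULL, seed = 1) {
  ids <- cohort$subject_ids
  if (is.null(n_train)) n_train <- floor(length(ids) / 2)
  if (is.null(n_test)) n_test <- length(ids) - n_train
  stopifnot(n_train + n_test <= length(ids))
  perm <- with_seed(seed, sample(ids))
  cohort_split(perm[seq_len(n_train)],
               perm[n_train + seq_len(n_test)], seed = seed)
}
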