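#' Semi-dense connectome container
#'
#' An `f x n_total` feature-by-grayordinate matrix for one subject, produced
#' by projecting the subject's rest covariance: `G = t(A) X t(X)`.
#'
#' @param subject_id subject identifier.
#' @param G numeric `f x n_total` matrix.
#' @param feature_kind label of the extraction scheme (e.g. `"parcel_mean"`).
#' @param normalized has [normalize_features()] been applied?
#' @param degenerate count of feature rows zeroed during normalization.
#' @return object of class `"connectome"`.
#' @export
connectome <- function(subject_id, G, feature_kind, normalized = FALSE,
                       degenerate = 0L) {
  G <- as.matrix(G)
  if (!all(is.finite(G))) stop("connectome values must be finite", call. = FALSE)
  structure(
    list(
      subject_id = as.character(subject_id),
      G = G,
      feature_kind = as.character(feature_kind),
      normalized = isTRUE(normalized),
      degenerate = as.integer(degenerate)
    ),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> subject %s: %d features x %d grayordinates [%s%s]\n",
    x$subject_id, nrow(x$G), ncol(x$G), x$feature_kind,
    if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

#' Projection matrix wrapper
#'
#' @param A numeric `n_total x f` matrix; no column may be all-zero.
#' @param kind one of `"parcel_mean"`, `"gaussian_random"`, `"group_ica"`,
#'   `"activation_template"`.
#' @param seed seed used where the construction is stochastic.
#' @return object of class `"projection_matrix"`.
#' @export
projection_matrix <- function(A, kind, seed = NA_integer_) {
  A <- as.matrix(A)
  if (ncol(A) < 1) stop("projection must have at least one column", call. = FALSE)
  if (any(colSums(abs(A)) == 0)) {
    stop("projection matrix has an all-zero column", call. = FALSE)
  }
  structure(list(A = A, kind = kind, seed = seed), class = "projection_matrix")
}

#' Parcel-mean projection
#'
#' Column `k` takes value `1/|region k|` on region-`k` grayordinates and 0
#' elsewhere, so `t(A) %*% x` is the vector of region means of `x`. The number
#' of features equals the number of regions (379 for the standard
#' multimodal cortical + subcortical parcellation).
#'
#' @param parc a [parcellation()].
#' @return a [projection_matrix()] with `f = parc$K`.
#' @export
parcel_projection <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  n <- length(parc$labels)
  sizes <- tabulate(parc$labels, nbins = parc$K)
  A <- matrix(0, n, parc$K)
  assigned <- parc$labels > 0
  A[cbind(which(assigned), parc$labels[assigned])] <-
    1 / sizes[parc$labels[assigned]]
  projection_matrix(A, kind = "parcel_mean")
}

#' Gaussian random projection
#'
#' Entries i.i.d. `N(0, 1/f)`, the distance-preserving random alternative to
#' an expert parcellation; `f = 379` mirrors the parcel-mean configuration.
#'
#' @param n_total grayordinate count.
#' @param f number of projection features.
#' @param seed RNG seed (the draw is deterministic given the seed).
#' @return a [projection_matrix()].
#' @export
gaussian_random_projection <- function(n_total, f = 379, seed = 1) {
  stopifnot(f >= 1)
  A <- with_seed(seed, matrix(rnorm(n_total * f, sd = sqrt(1 / f)), n_total, f))
  projection_matrix(A, kind = "gaussian_random", seed = seed)
}

#' Semi-dense connectome extraction
#'
#' The core covariance feature map: `G = t(A) X t(X)`, an `f x n_total`
#' matrix of (unnormalized) covariances between the `f` projected time series
#' and every grayordinate's time series. The scan must be preprocessed --
#' feature scales are otherwise silently wrong.
#'
#' @param scan a preprocessed [rest_scan()].
#' @param proj a [projection_matrix()] (or bare `n_total x f` matrix).
#' @param feature_kind label stored on the result; defaults to the
#'   projection's kind.
#' @return an unnormalized [connectome()].
#' @export
semi_dense_connectome <- function(scan, proj, feature_kind = NULL) {
  stopifnot(inherits(scan, "rest_scan"))
  if (!scan$preprocessed) {
    stop("scan must be preprocessed before feature extraction", call. = FALSE)
  }
  A <- if (inherits(proj, "projection_matrix")) proj$A else as.matrix(proj)
  if (nrow(A) != nrow(scan$data)) {
    stop("projection rows must match the grayordinate axis", call. = FALSE)
  }
  if (is.null(feature_kind)) {
    feature_kind <- if (inherits(proj, "projection_matrix")) proj$kind else "custom"
  }
  ## t(A) (X t(X)) ordered as (t(A) X) t(X): f x t then f x v
  G <- tcrossprod(crossprod(A, scan$data), scan$data)
  connectome(scan$subject_id, G, feature_kind = feature_kind)
}

#' Normalize connectome features
#'
#' Each of the `f` feature rows is demeaned across grayordinates and scaled to
#' unit Euclidean norm. Degenerate (constant) rows are zeroed and counted.
#' Idempotent.
#'
#' @param cn a [connectome()].
#' @return the normalized [connectome()].
#' @export
normalize_features <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  G <- cn$G - rowMeans(cn$G)
  nrm <- sqrt(rowSums(G^2))
  degenerate <- nrm < 1e-12
  nrm[degenerate] <- 1
  G <- G / nrm
  G[degenerate, ] <- 0
  connectome(cn$subject_id, G, cn$feature_kind, normalized = TRUE,
             degenerate = sum(degenerate))
}

#' Group ICA spatial maps
#'
#' Derives `n_components` group-level spatial sources from a training set of
#' scans: per-subject PCA reduction in the time dimension, temporal
#' concatenation of the reduced data, group-level PCA, then FastICA rotation
#' of the whitened group components into independent spatial maps. The
#' returned projection's columns are the group maps on the grayordinate axis.
#'
#' @param train_scans list of preprocessed [rest_scan()]s (at least 2).
#' @param n_components number of subject- and group-level components
#'   (default 80).
#' @param seed seed controlling the ICA initialization.
#' @return a [projection_matrix()] of kind `"group_ica"` with
#'   `f = n_components`.
#' @export
group_ica <- function(train_scans, n_components = 80, seed = 1) {
  if (length(train_scans) < 2) stop("group ICA needs at least 2 scans", call. = FALSE)
  reduced <- lapply(train_scans, function(scan) {
    stopifnot(inherits(scan, "rest_scan"))
    X <- scan$data
    k <- min(n_components, ncol(X) - 1, nrow(X))
    ## subject-level reduction: top temporal PCs of X (v x t) -> v x k scores
    s <- svd(X, nu = k, nv = 0)
    s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  })
  Y <- do.call(cbind, reduced)              # v x (sum k_i)
  k <- min(n_components, ncol(Y), nrow(Y))
  g <- svd(Y, nu = k, nv = 0)
  ## whitened spatial components: zero mean, identity covariance across
  ## grayordinates (required by the FastICA fixed point)
  Z <- t(g$u[, seq_len(k), drop = FALSE]) * sqrt(nrow(Y))
  Z <- Z - rowMeans(Z)
  e <- eigen(tcrossprod(Z) / ncol(Z), symmetric = TRUE)
  Z <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
    crossprod(e$vectors, Z)
  ica <- fast_ica(Z, seed = seed)
  projection_matrix(t(ica$S), kind = "group_ica", seed = seed)
}

#' Dual-regression subject features
#'
#' The standard two-stage procedure: (1) the group spatial maps are regressed
#' onto each time frame, yielding subject-specific component time courses;
#' (2) those time courses are regressed onto the full data, yielding
#' subject-specific spatial maps, which form the feature rows.
#'
#' @param scan a preprocessed [rest_scan()].
#' @param group_maps a [projection_matrix()] (columns = group spatial maps).
#' @return a [connectome()] of kind `"dual_regression"`, shape
#'   `f x n_total`.
#' @export
dual_regression_features <- function(scan, group_maps) {
  stopifnot(inherits(scan, "rest_scan"))
  if (!scan$preprocessed) {
    stop("scan must be preprocessed before feature extraction", call. = FALSE)
  }
  A <- if (inherits(group_maps, "projection_matrix")) group_maps$A else as.matrix(group_maps)
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    stop("group-map matrix is rank deficient", call. = FALSE)
  }
  ## stage 1: per-frame LS of maps -> f x t subject time courses
  TC <- qr.coef(qa, scan$data)
  ## stage 2: per-grayordinate LS of time courses -> spatial maps (v x f)
  S <- t(qr.coef(qr(t(TC)), t(scan$data)))
  connectome(scan$subject_id, t(S), feature_kind = "dual_regression")
}

#' PCR semi-partial connectome
#'
#' For each parcel `k`, all grayordinates within `mask_radius_mm` of any of
#' the parcel's cortical vertices -- plus the parcel's own members -- are
#' excluded; principal components of the remaining (masked) data are computed
#' by randomized SVD; the parcel's mean time series is regressed (OLS) on the
#' PC time courses; and the coefficients are back-projected through the PC
#' loadings onto the full grayordinate axis. Excluded grayordinates receive
#' exactly 0. Row `k` of the result is that semi-partial coefficient map.
#'
#' @param scan a preprocessed [rest_scan()].
#' @param parc a [parcellation()].
#' @param geom a [geometry()] with coordinates (cortical distances geodesic,
#'   subcortical Euclidean).
#' @param n_pcs number of principal components (default 512; truncated with a
#'   warning when it exceeds the usable rank).
#' @param mask_radius_mm exclusion radius around each parcel (default 10).
#' @param seed seed for the randomized SVD sketches.
#' @return a [connectome()] of kind `"pcr_semipartial"`, shape `K x n_total`.
#' @export
pcr_semipartial_connectome <- function(scan, parc, geom, n_pcs = 512,
                                       mask_radius_mm = 10, seed = 1) {
  stopifnot(inherits(scan, "rest_scan"), inherits(parc, "parcellation"))
  if (!scan$preprocessed) {
    stop("scan must be preprocessed before feature extraction", call. = FALSE)
  }
  X <- scan$data
  n <- nrow(X)
  cortical <- is_cortical(geom)
  G <- matrix(0, parc$K, n)
  warned <- FALSE
  for (k in seq_len(parc$K)) {
    members <- which(parc$labels == k)
    ring <- vertex_neighborhood(geom, members[cortical[members]], mask_radius_mm)
    excl <- union(members, ring)
    keep <- setdiff(seq_len(n), excl)
    if (length(keep) == 0) {
      stop(sprintf("exclusion set of region %d covers all grayordinates", k),
           call. = FALSE)
    }
    y <- colMeans(X[members, , drop = FALSE])
    Xm <- X[keep, , drop = FALSE]
    r <- min(n_pcs, dim(Xm))
    if (r < n_pcs && !warned) {
      warning(sprintf(
        "n_pcs = %d exceeds the usable rank; truncated to %d", n_pcs, r
      ))
      warned <- TRUE
    }
    s <- randomized_svd(Xm, k = r, seed = seed_for(seed, paste0("pcr", k)))
    pos <- s$d > max(s$d[1], 0) * 1e-10
    U <- s$u[, pos, drop = FALSE]
    d <- s$d[pos]
    V <- s$v[, pos, drop = FALSE]        # t x r PC time courses (orthonormal)
    beta <- crossprod(V, y)              # OLS on orthonormal PC time courses
    G[k, keep] <- as.numeric(U %*% (beta / d))
  }
  connectome(scan$subject_id, G, feature_kind = "pcr_semipartial")
}

#' Activity-flow feature
#'
#' A single covariance feature per subject: the projection template is a
#' group-mean cortical activation map (zero on subcortical positions), so the
#' feature row is the functional-connectivity-weighted flow of mean task
#' activity into every grayordinate.
#'
#' @param scan a preprocessed [rest_scan()].
#' @param template numeric vector of length `n_cortex` (group-mean activation)
#'   or an [activation_map()].
#' @param geom a [geometry()].
#' @return a [connectome()] of kind `"activity_flow"` with a single feature
#'   row.
#' @export
activity_flow_features <- function(scan, template, geom) {
  if (inherits(template, "activation_map")) template <- template$values
  if (length(template) != geom$n_cortex) {
    stop("template length must equal the cortical vertex count", call. = FALSE)
  }
  A <- numeric(geom$n_total)
  A[geom$cortex_index] <- template
  out <- semi_dense_connectome(scan, matrix(A, ncol = 1),
                               feature_kind = "activity_flow")
  out
}
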