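#' Ridge regression with generalized cross-validation
#'
#' Fits ridge regression of a centered target on a design matrix, selecting
#' the penalty from a grid by generalized cross-validation:
#' `GCV(lambda) = n * ||(I - H_lambda) y||^2 / tr(I - H_lambda)^2`, with
#' `H_lambda` the hat matrix of the full affine model -- the unpenalized
#' intercept contributes one degree of freedom, so
#' `tr(I - H_lambda) = n - 1 - sum(d^2 / (d^2 + lambda))`. Counting the
#' intercept keeps the criterion well-behaved on wide designs (`f >= n`),
#' where the plain trace otherwise collapses toward interpolation. The whole
#' path is evaluated through a single SVD of the design. Ties in the GCV
#' curve are broken toward the largest tied `lambda` (more shrinkage under
#' flat profiles).
#'
#' @param design numeric `n x f` matrix.
#' @param target numeric length-`n` response; centered internally (the train
#'   mean becomes the intercept).
#' @param lambda_grid positive penalties to search; default 30 log-spaced
#'   values spanning `[1e-3, 1e6]` times the mean squared singular value of
#'   the design.
#' @return list with `lambda` (selected penalty), `weights` (length `f`),
#'   `intercept`, `gcv` (the GCV curve over the grid), `lambda_grid`, and
#'   `degenerate` (`TRUE` when the target was constant: zero weights, maximum
#'   penalty).
#' @export
gcv_ridge <- function(design, target, lambda_grid = NULL) {
  design <- as.matrix(design)
  n <- nrow(design)
  f <- ncol(design)
  stopifnot(n >= 2, length(target) == n)
  intercept <- mean(target)
  y <- target - intercept
  s <- svd(design)
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(mean(s$d^2))
  }
  if (length(lambda_grid) == 0) stop("lambda grid is empty", call. = FALSE)
  lambda_grid <- sort(lambda_grid)
  if (sum(y^2) < 1e-24) {
    return(list(
      lambda = max(lambda_grid), weights = numeric(f), intercept = intercept,
      gcv = rep(NA_real_, length(lambda_grid)), lambda_grid = lambda_grid,
      degenerate = TRUE
    ))
  }
  d2 <- s$d^2
  cy <- as.numeric(crossprod(s$u, y))
  base <- max(sum(y^2) - sum(cy^2), 0)
  gcv <- vapply(lambda_grid, function(lam) {
    shrink <- if (lam == 0) as.numeric(d2 > 0) else d2 / (d2 + lam)
    rss <- base + sum((1 - shrink)^2 * cy^2)
    df <- 1 + sum(shrink)   # intercept counts one degree of freedom
    if (n - df < 1e-10) return(Inf)
    n * rss / (n - df)^2
  }, numeric(1))
  best <- min(gcv)
  ## largest lambda whose GCV ties the minimum (relative tolerance)
  idx <- max(which(gcv <= best * (1 + 1e-10)))
  lam <- lambda_grid[idx]
  list(
    lambda = lam,
    weights = ridge_weights(s, cy, lam, f),
    intercept = intercept,
    gcv = gcv, lambda_grid = lambda_grid,
    degenerate = FALSE
  )
}

## solve the ridge problem at a fixed lambda from a precomputed SVD;
## lambda = 0 gives the minimum-norm least-squares solution
ridge_weights <- function(s, cy, lam, f) {
  d <- s$d
  if (lam == 0) {
    pos <- d > max(d[1], 0) * 1e-10
    coefs <- ifelse(pos, cy / d, 0)
  } else {
    coefs <- cy * d / (d^2 + lam)
  }
  as.numeric(s$v %*% coefs)[seq_len(f)]
}

default_lambda_grid <- function(scale) {
  if (!is.finite(scale) || scale <= 0) scale <- 1
  exp(seq(log(1e-3), log(1e6), length.out = 30)) * scale
}

#' Vertex-wise encoding model
#'
#' Container for a battery of independently fitted per-vertex linear models:
#' weights, intercepts, selected penalties, and the per-vertex feature
#' standardization constants needed at prediction time.
#'
#' @param weights `n_cortex x f` weight matrix (on the standardized feature
#'   scale).
#' @param intercepts length-`n_cortex` intercepts (train target means).
#' @param lambdas length-`n_cortex` selected penalties (0 for OLS fits).
#' @param feature_kind feature scheme the model was trained on.
#' @param feature_mean,feature_sd `n_cortex x f` train standardization
#'   constants.
#' @param method one of `"rr"`, `"ols"`, `"af_mod"`, `"parcel_rr"`,
#'   `"anatomical_rr"`.
#' @return object of class `"vertexwise_model"`.
#' @export
vertexwise_model <- function(weights, intercepts, lambdas, feature_kind,
                             feature_mean, feature_sd, method) {
  stopifnot(
    nrow(weights) == length(intercepts),
    length(lambdas) == length(intercepts),
    all(is.finite(weights)), all(lambdas >= 0), all(is.finite(lambdas))
  )
  structure(
    list(
      weights = weights, intercepts = intercepts, lambdas = lambdas,
      feature_kind = feature_kind,
      feature_mean = feature_mean, feature_sd = feature_sd,
      method = method
    ),
    class = "vertexwise_model"
  )
}

#' @export
print.vertexwise_model <- function(x, ...) {
  cat(sprintf(
    "<vertexwise_model> %s on %s features: %d vertices x %d features, median lambda %.3g\n",
    x$method, x$feature_kind, nrow(x$weights), ncol(x$weights),
    median(x$lambdas)
  ))
  invisible(x)
}

## shared fitting core over a f x n_cortex x n design array
fit_vertexwise_core <- function(arr, targets, method, lambda_grid,
                                feature_kind, parcel_of = NULL) {
  f <- dim(arr)[1]; n_cortex <- dim(arr)[2]; n <- dim(arr)[3]
  stopifnot(nrow(targets) == n, ncol(targets) == n_cortex, n >= 3)
  W <- matrix(0, n_cortex, f)
  intercepts <- numeric(n_cortex)
  lambdas <- numeric(n_cortex)
  MU <- matrix(0, n_cortex, f)
  SD <- matrix(1, n_cortex, f)

  ## n x f design at vertex j (robust to f == 1 dimension dropping)
  design_at <- function(j) t(matrix(arr[, j, ], nrow = f))

  standardize <- function(D) {
    mu <- colMeans(D)
    sdv <- apply(D, 2, sd)
    keep <- sdv > 1e-12
    Ds <- sweep(D[, keep, drop = FALSE], 2, mu[keep]) /
      rep(sdv[keep], each = nrow(D))
    list(D = Ds, mu = mu, sd = ifelse(keep, sdv, 1), keep = keep)
  }

  if (identical(method, "parcel_rr")) {
    stopifnot(!is.null(parcel_of))
    for (k in sort(unique(parcel_of))) {
      vs <- which(parcel_of == k)
      svds <- vector("list", length(vs))
      prep <- vector("list", length(vs))
      scale_acc <- 0
      for (ii in seq_along(vs)) {
        j <- vs[ii]
        st <- standardize(design_at(j))
        sv <- svd(st$D)
        prep[[ii]] <- st
        svds[[ii]] <- sv
        scale_acc <- scale_acc + mean(sv$d^2)
      }
      grid <- if (is.null(lambda_grid)) {
        default_lambda_grid(scale_acc / length(vs))
      } else sort(lambda_grid)
      total <- numeric(length(grid))
      curves <- vector("list", length(vs))
      for (ii in seq_along(vs)) {
        j <- vs[ii]
        y <- targets[, j] - mean(targets[, j])
        sv <- svds[[ii]]
        cy <- as.numeric(crossprod(sv$u, y))
        base <- max(sum(y^2) - sum(cy^2), 0)
        d2 <- sv$d^2
        curves[[ii]] <- vapply(grid, function(lam) {
          shrink <- d2 / (d2 + lam)
          rss <- base + sum((1 - shrink)^2 * cy^2)
          df <- 1 + sum(shrink)   # intercept counts one degree of freedom
          if (nrow(targets) - df < 1e-10) return(Inf)
          nrow(targets) * rss / (nrow(targets) - df)^2
        }, numeric(1))
        total <- total + curves[[ii]]
      }
      best <- min(total)
      lam <- grid[max(which(total <= best * (1 + 1e-10)))]
      for (ii in seq_along(vs)) {
        j <- vs[ii]
        st <- prep[[ii]]
        y <- targets[, j]
        cy <- as.numeric(crossprod(svds[[ii]]$u, y - mean(y)))
        wk <- ridge_weights(svds[[ii]], cy, lam, sum(st$keep))
        W[j, st$keep] <- wk
        intercepts[j] <- mean(y)
        lambdas[j] <- lam
        MU[j, ] <- st$mu
        SD[j, ] <- st$sd
      }
    }
  } else {
    for (j in seq_len(n_cortex)) {
      st <- standardize(design_at(j))
      y <- targets[, j]
      if (ncol(st$D) == 0) {
        intercepts[j] <- mean(y)
        lambdas[j] <- 0
        next
      }
      fit <- switch(method,
        rr = gcv_ridge(st$D, y, lambda_grid),
        ols = ,
        af_mod = {
          sv <- svd(st$D)
          cy <- as.numeric(crossprod(sv$u, y - mean(y)))
          list(lambda = 0, intercept = mean(y),
               weights = ridge_weights(sv, cy, 0, ncol(st$D)))
        },
        stop(sprintf("unknown method '%s'", method), call. = FALSE)
      )
      W[j, st$keep] <- fit$weights
      intercepts[j] <- fit$intercept
      lambdas[j] <- fit$lambda
      MU[j, ] <- st$mu
      SD[j, ] <- st$sd
    }
  }
  vertexwise_model(W, intercepts, lambdas, feature_kind, MU, SD, method)
}

## stack connectomes into an f x n_cortex x n design array over the
## cortical columns
connectome_design_array <- function(connectomes, geom) {
  f <- nrow(connectomes[[1]]$G)
  kinds <- vapply(connectomes, function(x) x$feature_kind, character(1))
  fs <- vapply(connectomes, function(x) nrow(x$G), integer(1))
  if (length(unique(kinds)) != 1 || length(unique(fs)) != 1) {
    stop("all connectomes must share feature_kind and feature count",
         call. = FALSE)
  }
  ccols <- geom$cortex_index
  arr <- array(0, c(f, geom$n_cortex, length(connectomes)))
  for (i in seq_along(connectomes)) {
    arr[, , i] <- connectomes[[i]]$G[, ccols, drop = FALSE]
  }
  arr
}

maps_matrix <- function(maps) {
  do.call(rbind, lapply(maps, function(m) {
    if (inherits(m, "activation_map")) m$values else as.numeric(m)
  }))
}

#' Fit vertex-wise encoding models
#'
#' Fits an independent linear model at every cortical vertex: the design at
#' vertex `j` is the `n x f` matrix of the training subjects' connectome
#' features at that grayordinate, standardized columnwise by train
#' statistics. `method = "rr"` selects each vertex's ridge penalty by GCV;
#' `"ols"` fixes the penalty at 0 (minimum-norm solution when
#' under-determined); `"af_mod"` is the two-parameter slope + intercept OLS
#' used with single-feature activity-flow connectomes.
#'
#' @param connectomes list of training [connectome()]s (same kind and `f`).
#' @param maps list of training [activation_map()]s, same order.
#' @param geom the [geometry()].
#' @param method `"rr"`, `"ols"` or `"af_mod"`.
#' @param lambda_grid optional shared penalty grid; default is per-vertex,
#'   scaled by the design's mean squared singular value.
#' @return a [vertexwise_model()].
#' @export
fit_vertexwise <- function(connectomes, maps, geom,
                           method = c("rr", "ols", "af_mod"),
                           lambda_grid = NULL) {
  method <- match.arg(method)
  arr <- connectome_design_array(connectomes, geom)
  if (method == "af_mod" && dim(arr)[1] != 1) {
    stop("af_mod expects single-feature (activity flow) connectomes",
         call. = FALSE)
  }
  fit_vertexwise_core(arr, maps_matrix(maps), method, lambda_grid,
                      connectomes[[1]]$feature_kind)
}

#' Parcel-wise ridge regression
#'
#' The comparison model isolating the effect of per-vertex penalties: one
#' ridge penalty is shared by all vertices of a parcel, selected by
#' minimizing the sum of the member vertices' GCV scores; weights are then
#' solved per vertex at the shared penalty.
#'
#' @inheritParams fit_vertexwise
#' @param parc a [parcellation()]; only its cortical labels are used.
#' @return a [vertexwise_model()] with `method = "parcel_rr"`.
#' @export
fit_parcel_rr <- function(connectomes, maps, geom, parc, lambda_grid = NULL) {
  arr <- connectome_design_array(connectomes, geom)
  parcel_of <- parc$labels[geom$cortex_index]
  if (any(parcel_of == 0)) {
    stop("every cortical vertex must carry a parcel label", call. = FALSE)
  }
  fit_vertexwise_core(arr, maps_matrix(maps), "parcel_rr", lambda_grid,
                      connectomes[[1]]$feature_kind, parcel_of = parcel_of)
}

#' Anatomical ridge baseline
#'
#' Per-vertex GCV ridge on 6 anatomical feature maps (myelin, sulcal depth,
#' curvature, thickness, and two mean-EPI stand-ins): the design at vertex
#' `j` is each training subject's anatomical values at that vertex.
#'
#' @param anatomical list (one per subject) of `n_cortex x 6` matrices.
#' @param maps training [activation_map()]s.
#' @param lambda_grid optional penalty grid.
#' @return a [vertexwise_model()] with `method = "anatomical_rr"`.
#' @export
fit_anatomical_rr <- function(anatomical, maps, lambda_grid = NULL) {
  f <- ncol(anatomical[[1]])
  if (f != 6) stop("anatomical baseline expects exactly 6 feature maps",
                   call. = FALSE)
  n_cortex <- nrow(anatomical[[1]])
  arr <- array(0, c(f, n_cortex, length(anatomical)))
  for (i in seq_along(anatomical)) arr[, , i] <- t(anatomical[[i]])
  fit_vertexwise_core(arr, maps_matrix(maps), "rr", lambda_grid, "anatomical")
}

#' Group-level baseline models
#'
#' `group_mean()` predicts every test subject's map as the average of the
#' training maps. `group_zstat()` converts the per-vertex one-sample t
#' statistic of the training maps (against zero, `n - 1` df) into a z value
#' by exact matching of upper-tail probabilities; degenerate vertices
#' (zero variance) are set to 0 and counted.
#'
#' @param train_maps list of training [activation_map()]s.
#' @return object of class `"baseline_model"`.
#' @export
group_mean <- function(train_maps) {
  Y <- maps_matrix(train_maps)
  structure(
    list(kind = "group_mean", map = colMeans(Y), degenerate = 0L),
    class = "baseline_model"
  )
}

#' @rdname group_mean
#' @export
group_zstat <- function(train_maps) {
  Y <- maps_matrix(train_maps)
  n <- nrow(Y)
  stopifnot(n >= 2)
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, sd)
  degenerate <- sdv < 1e-12
  tstat <- ifelse(degenerate, 0, mu / (sdv / sqrt(n)))
  ## exact tail matching, stable in the extreme tails via log probabilities
  z <- qnorm(pt(tstat, df = n - 1, log.p = TRUE), log.p = TRUE)
  z[degenerate | !is.finite(z)] <- 0
  structure(
    list(kind = "group_zstat", map = z, degenerate = sum(degenerate)),
    class = "baseline_model"
  )
}

#' Unfitted activity-flow model
#'
#' Returns the raw single activity-flow feature row on the cortex as the
#' prediction, with no data-driven fitting. Its Pearson score is invariant to
#' affine rescaling of the template; on the predictive R-squared scale it is
#' expected to be strongly negative.
#'
#' @return object of class `"baseline_model"` with kind `"af"`.
#' @export
activity_flow_model <- function() {
  structure(list(kind = "af", map = NULL, degenerate = 0L),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s\n", x$kind))
  invisible(x)
}

#' Predict an activation map
#'
#' For vertex-wise models, applies each vertex's stored standardization and
#' weights to the subject's features at that vertex. Group baselines ignore
#' `newdata`; the unfitted activity-flow model returns the raw feature row.
#'
#' @param object a [vertexwise_model()] or baseline model.
#' @param newdata a [connectome()] for connectome-trained models, or an
#'   `n_cortex x f` matrix (anatomical models); ignored by group baselines.
#' @param geom the [geometry()] (needed to index cortical columns of a
#'   connectome).
#' @param subject_id,contrast_id identifiers stamped on the returned map.
#' @param ... unused.
#' @return an [activation_map()].
#' @export
predict.vertexwise_model <- function(object, newdata, geom = NULL,
                                     subject_id = NULL, contrast_id = "", ...) {
  if (inherits(newdata, "connectome")) {
    if (!identical(newdata$feature_kind, object$feature_kind)) {
      stop(sprintf(
        "connectome feature kind '%s' does not match model's '%s'",
        newdata$feature_kind, object$feature_kind
      ), call. = FALSE)
    }
    stopifnot(!is.null(geom))
    Ft <- newdata$G[, geom$cortex_index, drop = FALSE]  # f x n_cortex
    if (is.null(subject_id)) subject_id <- newdata$subject_id
  } else {
    Ft <- t(as.matrix(newdata))                          # f x n_cortex
    if (is.null(subject_id)) subject_id <- "subject"
  }
  Z <- (Ft - t(object$feature_mean)) / t(object$feature_sd)
  pred <- object$intercepts + colSums(t(object$weights) * Z)
  activation_map(subject_id, contrast_id, pred)
}

#' @rdname predict.vertexwise_model
#' @export
predict.baseline_model <- function(object, newdata = NULL, geom = NULL,
                                   subject_id = "subject", contrast_id = "",
                                   ...) {
  if (object$kind == "af") {
    stopifnot(inherits(newdata, "connectome"))
    if (!identical(newdata$feature_kind, "activity_flow")) {
      stop("the unfitted AF model requires activity_flow features",
           call. = FALSE)
    }
    stopifnot(!is.null(geom))
    return(activation_map(newdata$subject_id, contrast_id,
                          newdata$G[1, geom$cortex_index]))
  }
  activation_map(subject_id, contrast_id, object$map)
}
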