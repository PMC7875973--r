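dense_gcv <- function(X, y, lam) {
  ## oracle: explicit hat matrix of the affine ridge model (unpenalized
  ## intercept via the constant-vector projector, centered design columns)
  n <- nrow(X)
  yc <- y - mean(y)
  H <- X %*% solve(crossprod(X) + lam * diag(ncol(X)), t(X))
  P1 <- matrix(1 / n, n, n)
  rss <- sum(((diag(n) - H) %*% yc)^2)
  n * rss / (n - 1 - sum(diag(H)))^2
}

test_that("SVD-path GCV matches the dense hat-matrix oracle", {
  for (s in 1:20) {
    set.seed(s)
    X <- scale(matrix(rnorm(50 * 20), 50, 20), scale = FALSE)
    y <- rnorm(50)
    fit <- gcv_ridge(X, y)
    for (i in c(1, 8, 15, 30)) {
      lam <- fit$lambda_grid[i]
      expect_equal(fit$gcv[i], dense_gcv(X, y, lam), tolerance = 1e-8)
      ## closed-form ridge weights
      wd <- solve(crossprod(X) + lam * diag(20), crossprod(X, y - mean(y)))
      sv <- svd(X)
      cy <- as.numeric(crossprod(sv$u, y - mean(y)))
      expect_equal(restpred:::ridge_weights(sv, cy, lam, 20),
                   as.numeric(wd), tolerance = 1e-8)
    }
  }
})

test_that("the zero-penalty limit reproduces OLS", {
  set.seed(2)
  X <- scale(matrix(rnorm(50 * 8), 50, 8), scale = FALSE)
  y <- rnorm(50)
  fit <- gcv_ridge(X, y, lambda_grid = 0)
  ols <- lm(y ~ X)
  expect_equal(fit$weights, unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("a flat GCV profile resolves to the largest penalty", {
  ## design whose centered columns are an orthonormal basis of the centered
  ## observation space: GCV is constant over lambda, so the tie rule applies
  set.seed(3)
  n <- 12
  U <- qr.Q(qr(scale(matrix(rnorm(n * (n - 1)), n), scale = FALSE)))
  y <- rnorm(n)
  fit <- gcv_ridge(U, y)
  expect_lt(diff(range(fit$gcv)) / fit$gcv[1], 1e-8)
  expect_equal(fit$lambda, max(fit$lambda_grid))
})

test_that("constant targets are flagged degenerate with zero weights", {
  fit <- gcv_ridge(matrix(rnorm(20), 10, 2), rep(4, 10))
  expect_true(fit$degenerate)
  expect_equal(fit$weights, c(0, 0))
  expect_equal(fit$lambda, max(fit$lambda_grid))
  expect_equal(fit$intercept, 4)
})

test_that("ridge shrinkage is monotone in the penalty", {
  set.seed(5)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  sv <- svd(X)
  cy <- as.numeric(crossprod(sv$u, y - mean(y)))
  grid <- 10^seq(-3, 5, length.out = 25)
  norms <- vapply(grid, function(l) {
    sqrt(sum(restpred:::ridge_weights(sv, cy, l, 10)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

## a small realizable fitting problem shared by several tests
make_fit_problem <- function(n = 40, f = 5, n_cortex = 30, seed = 1,
                             noise = 0) {
  set.seed(seed)
  geom <- geometry(n_cortex, n_cortex)
  w <- matrix(rnorm(f * n_cortex), f, n_cortex)
  cns <- vector("list", n); maps <- vector("list", n)
  for (i in seq_len(n)) {
    G <- matrix(rnorm(f * n_cortex), f, n_cortex)
    y <- colSums(G * w) + 2 + noise * rnorm(n_cortex)
    cns[[i]] <- connectome(sprintf("s%02d", i), G, "custom")
    maps[[i]] <- activation_map(sprintf("s%02d", i), "c", y)
  }
  list(geom = geom, cns = cns, maps = maps, w = w)
}

test_that("vertex-wise fits recover realizable targets", {
  pb <- make_fit_problem()
  m <- fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "rr")
  ## held-out realizable subject
  G <- matrix(rnorm(5 * 30), 5, 30)
  truth <- colSums(G * pb$w) + 2
  pred <- predict(m, connectome("t", G, "custom"), geom = pb$geom)
  expect_gt(cor(pred$values, truth), 0.999)
})

test_that("vertices are fitted independently", {
  pb <- make_fit_problem(n = 20, f = 3, n_cortex = 12, noise = 0.5)
  m <- fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "rr")
  ## permuting the vertex axis permutes the fit identically
  perm <- sample(12)
  cns_p <- lapply(pb$cns, function(c) {
    connectome(c$subject_id, c$G[, perm], "custom")
  })
  maps_p <- lapply(pb$maps, function(mm) {
    activation_map(mm$subject_id, "c", mm$values[perm])
  })
  mp <- fit_vertexwise(cns_p, maps_p, pb$geom, method = "rr")
  expect_identical(mp$weights, m$weights[perm, ])
  expect_identical(mp$lambdas, m$lambdas[perm])
  ## deleting vertices leaves the remaining fits bit-identical
  keep <- c(2, 5, 9)
  gk <- geometry(3, 3)
  cns_k <- lapply(pb$cns, function(c) {
    connectome(c$subject_id, c$G[, keep], "custom")
  })
  maps_k <- lapply(pb$maps, function(mm) {
    activation_map(mm$subject_id, "c", mm$values[keep])
  })
  mk <- fit_vertexwise(cns_k, maps_k, gk, method = "rr")
  expect_identical(mk$weights, m$weights[keep, ])
  expect_identical(mk$lambdas, m$lambdas[keep])
})

test_that("noisier vertices receive stronger regularization", {
  ## identical signal, noise SD 0.1 vs 2.0 in two vertex groups
  wins <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 30; f <- 4; nc <- 20
    geom <- geometry(nc, nc)
    w <- matrix(rnorm(f * nc), f, nc)
    noise_sd <- rep(c(0.1, 2), each = nc / 2)
    cns <- vector("list", n); maps <- vector("list", n)
    for (i in seq_len(n)) {
      G <- matrix(rnorm(f * nc), f, nc)
      y <- colSums(G * w) + noise_sd * rnorm(nc)
      cns[[i]] <- connectome(sprintf("s%02d", i), G, "custom")
      maps[[i]] <- activation_map(sprintf("s%02d", i), "c", y)
    }
    m <- fit_vertexwise(cns, maps, geom, method = "rr")
    wins <- wins +
      (median(m$lambdas[11:20]) > median(m$lambdas[1:10]))
  }
  expect_gte(wins, 19)
})

test_that("OLS and af_mod methods fix the penalty at zero", {
  pb <- make_fit_problem(n = 25, f = 3, n_cortex = 10, noise = 0.2)
  mo <- fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "ols")
  expect_true(all(mo$lambdas == 0))
  ## af_mod wants a single feature
  expect_error(fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "af_mod"),
               "single-feature")
  cns1 <- lapply(pb$cns, function(c) {
    connectome(c$subject_id, c$G[1, , drop = FALSE], "activity_flow")
  })
  m1 <- fit_vertexwise(cns1, pb$maps, pb$geom, method = "af_mod")
  expect_equal(ncol(m1$weights), 1L)
  ## the two-parameter fit equals lm slope/intercept at a vertex
  j <- 4
  x <- vapply(cns1, function(c) c$G[1, j], numeric(1))
  y <- vapply(pb$maps, function(mm) mm$values[j], numeric(1))
  lmfit <- lm(y ~ scale(x))
  expect_equal(m1$weights[j, 1], unname(coef(lmfit)[2]), tolerance = 1e-6)
  expect_equal(m1$intercepts[j], unname(coef(lmfit)[1]), tolerance = 1e-8)
})

test_that("a single-parcel parcellation shares one penalty cortex-wide", {
  pb <- make_fit_problem(n = 25, f = 3, n_cortex = 10, noise = 0.5)
  parc <- parcellation(rep(1, 10), K = 1)
  mp <- fit_parcel_rr(pb$cns, pb$maps, pb$geom, parc)
  expect_equal(length(unique(mp$lambdas)), 1L)
  expect_equal(mp$method, "parcel_rr")
})

test_that("homogeneous parcels make parcel and vertex penalties agree", {
  ## same noise everywhere: shared-lambda and per-vertex predictions differ
  ## by less than 0.01 mean r over seeds
  diffs <- vapply(1:5, function(s) {
    pb <- make_fit_problem(n = 40, f = 4, n_cortex = 20, seed = 200 + s,
                           noise = 1)
    parc <- parcellation(rep(1:4, each = 5), K = 4)
    mv <- fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "rr")
    mp <- fit_parcel_rr(pb$cns, pb$maps, pb$geom, parc)
    set.seed(999 + s)
    rs <- vapply(1:10, function(i) {
      G <- matrix(rnorm(4 * 20), 4, 20)
      truth <- colSums(G * pb$w) + 2 + rnorm(20)
      cn <- connectome("t", G, "custom")
      cor(predict(mv, cn, geom = pb$geom)$values, truth) -
        cor(predict(mp, cn, geom = pb$geom)$values, truth)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.01)
})

test_that("group baselines compute means and exact t-to-z statistics", {
  maps <- list(activation_map("a", "c", c(1, 3)),
               activation_map("b", "c", c(3, 5)))
  gm <- group_mean(maps)
  expect_equal(predict(gm)$values, c(2, 4))
  ## scalar z oracle at a vertex with values 1, 2, 3
  m3 <- list(activation_map("a", "c", c(1, 0)),
             activation_map("b", "c", c(2, 0)),
             activation_map("c", "c", c(3, 0)))
  gz <- group_zstat(m3)
  t_oracle <- 2 / (1 / sqrt(3))
  expect_equal(t_oracle, 3.4641, tolerance = 1e-4)
  expect_equal(gz$map[1], qnorm(pt(t_oracle, df = 2)), tolerance = 1e-10)
  expect_equal(gz$map[1], 1.7855, tolerance = 1e-3)
  ## all-zero vertex: z = 0 and counted degenerate
  expect_equal(gz$map[2], 0)
  expect_equal(gz$degenerate, 1L)
  ## sign symmetry
  m3n <- lapply(m3, function(x) activation_map(x$subject_id, "c", -x$values))
  expect_equal(group_zstat(m3n)$map[1], -gz$map[1])
})

test_that("anatomical ridge needs 6 maps and fits linear mixes", {
  set.seed(8)
  n <- 30; nc <- 25
  anat <- lapply(1:n, function(i) matrix(rnorm(nc * 6), nc, 6))
  expect_error(fit_anatomical_rr(lapply(anat, function(a) a[, 1:5]),
                                 list()), "6")
  mix <- rnorm(6)
  maps <- lapply(1:n, function(i) {
    activation_map(sprintf("s%d", i), "c", as.numeric(anat[[i]] %*% mix))
  })
  m <- fit_anatomical_rr(anat, maps)
  newa <- matrix(rnorm(nc * 6), nc, 6)
  pred <- predict(m, newa)
  expect_gt(cor(pred$values, as.numeric(newa %*% mix)), 0.99)
  ## uncorrelated anatomy explains nothing out of sample
  r2s <- vapply(1:3, function(s) {
    set.seed(400 + s)
    mapsn <- lapply(1:n, function(i) {
      activation_map(sprintf("s%d", i), "c", rnorm(nc))
    })
    mn <- fit_anatomical_rr(anat[1:20], mapsn[1:20])
    preds <- lapply(21:30, function(i) predict(mn, anat[[i]]))
    weighted_mean_r2(predictive_r2(preds, mapsn[21:30]))
  }, numeric(1))
  expect_lte(mean(r2s), 0.02)
})

test_that("prediction respects standardization, kinds, and degenerate cases", {
  pb <- make_fit_problem(n = 20, f = 3, n_cortex = 8, noise = 0.3)
  m <- fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "rr")
  ## zero weights predict the intercepts
  m0 <- m; m0$weights[] <- 0
  pred <- predict(m0, pb$cns[[1]], geom = pb$geom)
  expect_equal(pred$values, m$intercepts)
  ## kind mismatch
  bad <- connectome("x", pb$cns[[1]]$G, "other_kind")
  expect_error(predict(m, bad, geom = pb$geom), "feature kind")
  ## unfitted AF predictions are r-invariant to template rescaling
  geom <- make_geometry(30, 25)
  sc <- noise_scan(30, 80, seed = 12)
  tpl <- rnorm(25)
  truth <- rnorm(25)
  af <- activity_flow_model()
  p1 <- predict(af, activity_flow_features(sc, tpl, geom), geom = geom)
  p2 <- predict(af, activity_flow_features(sc, 3 * tpl, geom), geom = geom)
  expect_equal(pearson_score(p1, truth), pearson_score(p2, truth),
               tolerance = 1e-10)
})

test_that("tidy and glance summarize fitted models", {
  pb <- make_fit_problem(n = 15, f = 3, n_cortex = 6, noise = 0.3)
  m <- fit_vertexwise(pb$cns, pb$maps, pb$geom, method = "rr")
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_named(td, c("vertex", "lambda", "intercept", "weight_norm"))
  gl <- glance(m)
  expect_equal(gl$n_features, 3L)
  expect_equal(gl$method, "rr")
})
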