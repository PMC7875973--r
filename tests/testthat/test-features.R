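test_that("parcel projection averages region activity", {
  p <- parcellation(c(1, 1, 2), K = 2)
  A <- parcel_projection(p)$A
  expect_equal(A, cbind(c(0.5, 0.5, 0), c(0, 0, 1)))
  expect_equal(as.numeric(crossprod(A, c(2, 4, 6))), c(3, 6))
  ## column sums are 1 for any parcellation
  p2 <- tiny_cohort()$parcellation
  A2 <- parcel_projection(p2)$A
  expect_equal(unname(colSums(A2)), rep(1, p2$K))
})

test_that("Gaussian random projections have the prescribed scale", {
  A <- gaussian_random_projection(400, f = 300, seed = 1)$A
  expect_equal(var(as.numeric(A)), 1 / 300, tolerance = 0.05)
  expect_identical(A, gaussian_random_projection(400, 300, seed = 1)$A)
  ## norm preservation in expectation: E||t(A) x||^2 = ||x||^2
  x <- with_seed_test(2, rnorm(150))
  vals <- vapply(1:200, function(s) {
    sum(crossprod(gaussian_random_projection(150, 40, seed = s)$A, x)^2)
  }, numeric(1))
  expect_equal(mean(vals), sum(x^2), tolerance = 0.05)
})

test_that("semi-dense connectome implements the projected covariance", {
  sc <- noise_scan(30, 40, seed = 3)
  ## identity projection gives the raw (unnormalized) covariance
  g_id <- semi_dense_connectome(sc, diag(30))
  expect_equal(g_id$G, tcrossprod(sc$data), tolerance = 1e-12)
  ## hand-checked 3 x 4 orthogonal-row case, one-hot projection
  X <- rbind(c(2, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 1, 1))
  scx <- rest_scan("h", X, 4, preprocessed = TRUE)
  G <- semi_dense_connectome(scx, matrix(c(1, 0, 0), ncol = 1))$G
  expect_equal(as.numeric(G), c(4, 0, 0))
  ## bilinearity: scaling X by c scales G by c^2
  sc2 <- rest_scan("c", 3 * sc$data, ncol(sc$data), preprocessed = TRUE)
  expect_equal(semi_dense_connectome(sc2, diag(30))$G, 9 * g_id$G,
               tolerance = 1e-12)
  ## column-stacking projections row-stacks features, exactly
  A1 <- matrix(rnorm(30 * 2), 30); A2 <- matrix(rnorm(30 * 3), 30)
  both <- semi_dense_connectome(sc, cbind(A1, A2))$G
  expect_identical(both,
                   rbind(semi_dense_connectome(sc, A1)$G,
                         semi_dense_connectome(sc, A2)$G))
  ## raw scans are rejected
  expect_error(semi_dense_connectome(rest_scan("r", X, 4), diag(3)),
               "preprocessed")
})

test_that("parcel-mean connectome rows equal brute-force covariances", {
  co <- tiny_cohort()
  sc <- preprocess_rest(co$scans[[1]])
  A <- parcel_projection(co$parcellation)
  G <- semi_dense_connectome(sc, A)$G
  for (k in c(1, co$parcellation$K)) {
    mean_ts <- colMeans(sc$data[co$parcellation$labels == k, , drop = FALSE])
    brute <- as.numeric(sc$data %*% mean_ts)
    expect_equal(unname(G[k, ]), brute, tolerance = 1e-8)
  }
})

test_that("feature normalization gives zero-mean unit-norm rows, idempotently", {
  cn <- connectome("s", rbind(c(1, 2, 3), c(5, 5, 5)), "custom")
  out <- normalize_features(cn)
  expect_equal(out$G[1, ], c(-1 / sqrt(2), 0, 1 / sqrt(2)))
  expect_equal(out$G[2, ], c(0, 0, 0))
  expect_equal(out$degenerate, 1L)
  expect_true(out$normalized)
  again <- normalize_features(out)
  expect_equal(again$G, out$G, tolerance = 1e-12)
  ## generic rows: |mean| and norm within 1e-10
  cn2 <- normalize_features(connectome("t", matrix(rnorm(40), 4), "custom"))
  expect_true(all(abs(rowMeans(cn2$G)) < 1e-10))
  expect_true(all(abs(sqrt(rowSums(cn2$G^2)) - 1) < 1e-10))
})

test_that("group ICA recovers planted super-Gaussian spatial sources", {
  set.seed(11)
  v <- 400; t <- 120; k <- 3
  S <- matrix(rt(k * v, df = 3), k, v)
  scans <- lapply(1:4, function(i) {
    TC <- matrix(rnorm(k * t), k, t)
    X <- t(S) %*% TC + matrix(rnorm(v * t, sd = 0.2), v, t)
    rest_scan(paste0("s", i), X - rowMeans(X), t, preprocessed = TRUE)
  })
  A <- group_ica(scans, n_components = 3, seed = 2)
  cc <- abs(cor(A$A, t(S)))
  ## each recovered column matches one distinct source
  expect_true(all(apply(cc, 1, max) > 0.95))
  expect_equal(sort(apply(cc, 1, which.max)), 1:3)
  ## subject order does not change the recovered subspace
  A2 <- group_ica(rev(scans), n_components = 3, seed = 2)
  angles <- acos(pmin(svd(crossprod(qr.Q(qr(A$A)), qr.Q(qr(A2$A))))$d, 1))
  expect_true(all(angles < 1e-3))
  expect_error(group_ica(scans[1]), "at least 2")
  ## battery default component count
  expect_equal(formals(group_ica)$n_components, 80)
})

test_that("dual regression recovers planted time courses and maps", {
  set.seed(4)
  v <- 300; t <- 400; f <- 4
  maps <- qr.Q(qr(matrix(rnorm(v * f), v, f)))
  TC <- matrix(rnorm(f * t), f, t)
  ## noiseless: stage-1 time courses are exact, so features reproduce maps
  sc0 <- rest_scan("a", maps %*% TC, t, preprocessed = TRUE)
  dr0 <- dual_regression_features(sc0, maps)
  expect_lt(max(abs(t(dr0$G) - maps)), 1e-8)
  ## noisy: subject-specific maps recovered at t = 400, SD 0.5 noise
  subj_maps <- maps + 0.1 * matrix(rnorm(v * f), v, f)
  X <- subj_maps %*% TC + matrix(rnorm(v * t, sd = 0.5), v, t)
  dr <- dual_regression_features(rest_scan("b", X, t, preprocessed = TRUE), maps)
  expect_true(all(abs(diag(cor(t(dr$G), subj_maps))) > 0.9))
  ## f = 1 reduces to the univariate regression slope map
  m1 <- maps[, 1, drop = FALSE]
  sc1 <- rest_scan("c", X, t, preprocessed = TRUE)
  dr1 <- dual_regression_features(sc1, m1)
  tc1 <- as.numeric(crossprod(m1, X)) / sum(m1^2)
  slope <- as.numeric(X %*% tc1) / sum(tc1^2)
  expect_equal(as.numeric(dr1$G), slope, tolerance = 1e-8)
  ## rank-deficient group maps are rejected
  expect_error(dual_regression_features(sc1, cbind(m1, m1)), "rank")
})

test_that("PCR semi-partial features honor the exclusion mask", {
  set.seed(7)
  geom <- make_geometry(80, 60)
  t <- 50
  for (s in 1:3) {
    parc <- make_parcellation(geom, 5, seed = s)
    X <- matrix(rnorm(80 * t), 80, t)
    sc <- rest_scan("s", X - rowMeans(X), t, preprocessed = TRUE)
    cn <- suppressWarnings(
      pcr_semipartial_connectome(sc, parc, geom, n_pcs = 40, seed = s)
    )
    ctx <- logical(80); ctx[geom$cortex_index] <- TRUE
    for (k in seq_len(parc$K)) {
      members <- which(parc$labels == k)
      excl <- union(members,
                    vertex_neighborhood(geom, members[ctx[members]], 10))
      expect_true(all(cn$G[k, excl] == 0))
      expect_gt(sum(cn$G[k, -excl] != 0), 0)
    }
  }
})

test_that("PCR back-projection reproduces the OLS fit at full rank", {
  set.seed(9)
  geom <- make_geometry(80, 60)
  parc <- make_parcellation(geom, 6, seed = 2)
  t <- 50
  X <- matrix(rnorm(80 * t), 80, t)
  ## a remote vertex carrying the region-1 mean exactly
  m1 <- which(parc$labels == 1)
  ctx <- logical(80); ctx[geom$cortex_index] <- TRUE
  excl1 <- union(m1, vertex_neighborhood(geom, m1[ctx[m1]], 10))
  far <- setdiff(seq_len(80), excl1)[1]
  X[far, ] <- colMeans(X[m1, , drop = FALSE])
  sc <- rest_scan("s", X - rowMeans(X), t, preprocessed = TRUE)
  expect_warning(
    cn <- pcr_semipartial_connectome(sc, parc, geom, n_pcs = 60, seed = 1),
    "truncated"
  )
  expect_equal(which.max(abs(cn$G[1, ])), far)
  ## residual equals the dense OLS residual of the region mean on the
  ## masked data's column space
  y <- colMeans(sc$data[m1, , drop = FALSE])
  keep <- setdiff(seq_len(80), excl1)
  fitted <- as.numeric(crossprod(sc$data[keep, , drop = FALSE], cn$G[1, keep]))
  ols <- lm.fit(t(sc$data[keep, , drop = FALSE]), y)
  expect_lt(max(abs((y - fitted) - ols$residuals)), 1e-6)
})

test_that("activity-flow features are template-weighted covariance flows", {
  geom <- make_geometry(40, 30)
  sc <- noise_scan(40, 5000, seed = 5)
  ## zero template -> zero feature row
  z <- activity_flow_features(sc, rep(0, 30), geom)
  expect_true(all(z$G == 0))
  expect_equal(nrow(z$G), 1L)
  ## one-hot template approximates the covariance row of that vertex
  tpl <- c(1, rep(0, 29))
  af <- activity_flow_features(sc, tpl, geom)
  covrow <- as.numeric(sc$data %*% sc$data[1, ]) / ncol(sc$data)
  expect_equal(as.numeric(af$G) / ncol(sc$data), covrow, tolerance = 1e-10)
  expect_error(activity_flow_features(sc, rep(1, 7), geom), "cortical")
})

test_that("randomized SVD matches the dense SVD on well-conditioned input", {
  set.seed(3)
  A <- matrix(rnorm(60 * 40), 60, 40) %*% diag(c(10:1, rep(0.01, 30)))
  rs <- randomized_svd(A, k = 10, seed = 1)
  ds <- svd(A)
  expect_equal(rs$d, ds$d[1:10], tolerance = 1e-6)
  expect_equal(abs(diag(crossprod(rs$u, ds$u[, 1:10]))), rep(1, 10),
               tolerance = 1e-5)
})
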