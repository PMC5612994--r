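# GLM beta recovery, CompCor components, z-scoring, condition filtering.

test_that("estimate_betas recovers generating betas from noiseless series", {
  d <- generate_design(design_spec(n_runs = 3), seed = 5)
  g <- volume_grid(c(4, 4, 3))
  sig <- signal_spec(seed = 7, smooth_fwhm_vox = 0)
  b <- generate_betas(d, sig, g)
  ts <- generate_timeseries(d, b)
  est <- estimate_betas(ts, d, b$mask, g)
  expect_lt(max(abs(est$betas - b$betas)), 1e-8)
  expect_equal(est$conditions, b$conditions)
})

test_that("pure-noise series give betas centered on zero", {
  d <- generate_design(design_spec(n_runs = 4), seed = 6)
  g <- volume_grid(c(5, 5, 4))
  b <- generate_betas(d, signal_spec(seed = 8, smooth_fwhm_vox = 0), g)
  b$betas[] <- 0
  ts <- generate_timeseries(d, b, noise_sd = 1, seed = 11)
  est <- estimate_betas(ts, d, b$mask, g)
  # pooled t-test across runs x conditions x 100 voxels
  vals <- as.numeric(est$betas[, , 1:100])
  expect_gt(stats::t.test(vals)$p.value, 0.01)
})

test_that("nuisance regressors orthogonal to the design leave betas unchanged", {
  d <- generate_design(design_spec(n_runs = 2), seed = 7)
  g <- volume_grid(c(3, 3, 2))
  b <- generate_betas(d, signal_spec(seed = 9, smooth_fwhm_vox = 0), g)
  ts <- generate_timeseries(d, b, noise_sd = 0.5, seed = 12)
  n_tp <- dim(ts$series)[2]
  est_plain <- estimate_betas(ts, d, b$mask, g)
  # orthogonalize random regressors against the condition design + intercept
  nuisance <- lapply(b$runs, function(ri) {
    dr <- d[d$run == ri, ]
    X <- cbind(facegeom:::build_design_matrix(dr, b$conditions$condition, n_tp), 1)
    set.seed(100 + ri)
    N <- matrix(rnorm(n_tp * 2), n_tp, 2)
    N - X %*% qr.coef(qr(X), N)
  })
  est_nui <- estimate_betas(ts, d, b$mask, g, nuisance = nuisance)
  expect_equal(est_nui$betas, est_plain$betas, tolerance = 1e-10)
  # a duplicated condition regressor is flagged as rank deficiency
  dup <- lapply(b$runs, function(ri) {
    dr <- d[d$run == ri, ]
    facegeom:::build_design_matrix(dr, b$conditions$condition[1], n_tp)
  })
  expect_error(estimate_betas(ts, d, b$mask, g, nuisance = dup),
               "rank deficient")
})

test_that("compcor components match the eigendecomposition oracle", {
  set.seed(13)
  n_tp <- 80; nv <- 30
  resid <- matrix(rnorm(n_tp * nv), n_tp, nv)
  comp <- compcor_components(resid, n_components = 5)
  expect_equal(dim(comp), c(n_tp, 5))
  # unit variance, mutually orthogonal
  expect_equal(unname(apply(comp, 2, sd)), rep(1, 5), tolerance = 1e-10)
  g <- crossprod(scale(comp, scale = FALSE))
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # independent eigensolver oracle: projections on top eigenvectors
  centered <- scale(resid, scale = FALSE)
  eig <- eigen(stats::cov(centered), symmetric = TRUE)
  for (k in 1:5) {
    proj <- as.numeric(centered %*% eig$vectors[, k])
    expect_equal(abs(cor(proj, comp[, k])), 1, tolerance = 1e-8)
    expect_equal(stats::var(proj), eig$values[k], tolerance = 1e-8)
  }

  # rank-1 residuals: first component recovers the time course
  ct <- sin(seq_len(n_tp) / 5)
  r1 <- outer(ct, rnorm(nv))
  c1 <- compcor_components(r1, n_components = 1)
  expect_equal(abs(cor(c1[, 1], ct)), 1, tolerance = 1e-10)

  expect_error(compcor_components(r1, n_components = 5), "rank")
  expect_error(compcor_components(matrix(rnorm(40), 10, 4)), "at least")

  # confound removal: components orthogonal to the confound
  conf <- matrix(rnorm(n_tp), n_tp, 1)
  cc <- compcor_components(resid + conf %*% matrix(5, 1, nv), conf, 3)
  expect_lt(max(abs(cor(conf, cc))), 1e-6)
})

test_that("estimation is equivariant/invariant to voxel order", {
  set.seed(14)
  resid <- matrix(rnorm(60 * 12), 60, 12)
  perm <- sample(12)
  c1 <- compcor_components(resid, n_components = 3)
  c2 <- compcor_components(resid[, perm], n_components = 3)
  for (k in 1:3) expect_equal(abs(cor(c1[, k], c2[, k])), 1, tolerance = 1e-8)

  d <- generate_design(design_spec(n_runs = 2), seed = 15)
  g <- volume_grid(c(3, 3, 2))
  b <- generate_betas(d, signal_spec(seed = 16, smooth_fwhm_vox = 0), g)
  ts <- generate_timeseries(d, b, noise_sd = 0.3, seed = 17)
  vperm <- sample(dim(ts$series)[3])
  ts2 <- ts
  ts2$series <- ts$series[, , vperm, drop = FALSE]
  est1 <- estimate_betas(ts, d, b$mask, g)
  est2 <- estimate_betas(ts2, d, b$mask, g)
  expect_equal(est2$betas, est1$betas[, , vperm, drop = FALSE])
})

test_that("zscore_within_run standardizes per run and voxel", {
  d <- generate_design(design_spec(n_runs = 3), seed = 8)
  b <- generate_betas(d, signal_spec(seed = 10), volume_grid(c(4, 4, 3)))
  z <- zscore_within_run(b)
  for (ri in 1:3) {
    m <- z$betas[ri, , ]
    expect_lt(max(abs(colMeans(m))), 1e-12)
    expect_lt(max(abs(sqrt(colMeans(sweep(m, 2, colMeans(m))^2)) - 1)), 1e-12)
  }
  # idempotence
  expect_equal(zscore_within_run(z)$betas, z$betas, tolerance = 1e-10)
  # closed form for two conditions: (a, b) -> (-1, +1) by sign of (a - b)
  g1 <- volume_grid(c(1, 1, 1))
  two <- beta_pattern_set(array(c(2, 7), c(1, 2, 1)), 1,
                          data.frame(condition = c("A", "B"),
                                     identity = c("A", "B"),
                                     familiarity = c("familiar", "unfamiliar")),
                          g1, full_brain_mask(g1))
  expect_equal(as.numeric(zscore_within_run(two)$betas), c(-1, 1))
  # sample-SD option
  expect_equal(as.numeric(zscore_within_run(two, "sample")$betas),
               c(-1, 1) / sqrt(2))
  # constant voxels map to zero with a warning
  const <- two
  const$betas[] <- 3
  expect_warning(zc <- zscore_within_run(const), "constant")
  expect_true(all(zc$betas == 0))
  one <- beta_pattern_set(array(1, c(1, 1, 1)), 1,
                          data.frame(condition = "A", identity = "A",
                                     familiarity = "familiar"),
                          g1, full_brain_mask(g1))
  expect_error(zscore_within_run(one), "at least 2 conditions")
})

test_that("filter_conditions keeps exactly the 8 identity conditions", {
  d <- generate_design(design_spec(n_runs = 2), seed = 9)
  b <- generate_betas(d, signal_spec(seed = 11), volume_grid(c(3, 3, 2)))
  expect_equal(nrow(b$conditions), 9)
  f <- filter_conditions(b)
  expect_equal(nrow(f$conditions), 8)
  expect_false("self" %in% f$conditions$familiarity)
  # idempotent; input already lacking self passes through unchanged
  expect_equal(filter_conditions(f)$betas, f$betas)
  # the pipeline order is filter first, then z-score: features are
  # standardized over the 8 retained conditions, not all 9
  p <- prepare_features(b)
  expect_equal(p$betas, zscore_within_run(filter_conditions(b))$betas)
  expect_false(isTRUE(all.equal(p$betas,
                                filter_conditions(zscore_within_run(b))$betas)))
})
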