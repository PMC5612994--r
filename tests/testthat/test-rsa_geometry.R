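# Cross-validated RDMs, inter-ROI geometry, MDS, RV, system contrast.

test_that("fisher_average is the tanh-mean-atanh closed form", {
  expect_equal(fisher_average(c(0.4, 0.4)), 0.4)
  expect_equal(fisher_average(c(0.5, -0.5)), 0)
  expect_equal(fisher_average(c(0.3, 0.8)),
               tanh((atanh(0.3) + atanh(0.8)) / 2))
  expect_error(fisher_average(numeric(0)), "empty")
  expect_error(fisher_average(1.2), "\\[-1, 1\\]")
  expect_warning(v <- fisher_average(c(1, 0)), "clipped")
  expect_lt(v, 1)
})

test_that("crossvalidated_rdm averages all split-half partitions", {
  expect_length(run_partitions(1:11), 462)
  expect_length(run_partitions(1:4), 3) # even n: complements deduplicated
  expect_length(run_partitions(1:3), 3)

  # 3-run hand oracle with explicit partitions and Fisher-z averaging
  fx <- make_signal_betas(seed = 61, n_runs = 3, dims = c(4, 4, 3))
  b <- fx$prepared
  vox <- 1:10
  got <- crossvalidated_rdm(b, vox)
  expect_equal(attr(got, "n_partitions"), 3L)
  parts <- list(list(a = c(1, 2), b = 3), list(a = c(1, 3), b = 2),
                list(a = c(2, 3), b = 1))
  zs <- 0
  for (p in parts) {
    ma <- apply(b$betas[p$a, , vox, drop = FALSE], c(2, 3), mean)
    mb <- apply(b$betas[p$b, , vox, drop = FALSE], c(2, 3), mean)
    zs <- zs + atanh(cor(t(ma), t(mb)))
  }
  zm <- zs / 3
  oracle <- tanh((zm + t(zm)) / 2)
  expect_equal(unclass(got), oracle, ignore_attr = TRUE)
  expect_equal(unclass(got), t(unclass(got))) # exactly symmetric

  # noiseless run-stable patterns: diagonal reliability at its ceiling
  fx0 <- make_signal_betas(seed = 62, n_runs = 4, dims = c(4, 4, 3),
                           familiarity_amp = 0, identity_amp = 2,
                           noise_sd = 1e-9)
  suppressWarnings(r0 <- crossvalidated_rdm(fx0$prepared, fx0$region))
  expect_true(all(diag(unclass(r0)) > 0.999))

  expect_error(crossvalidated_rdm(b, c(1, 10000)), "outside")
})

test_that("within-subject inter-ROI distances match the direct formula", {
  r1 <- random_rdm(8, 1); r2 <- random_rdm(8, 2); r3 <- random_rdm(8, 3)
  geom <- inter_roi_distances(list(list(r1, r2, r3)),
                              systems = c("EV", "extended", "extended"))
  # direct correlation-distance oracle (diagonal included)
  v <- function(m) m[upper.tri(m, diag = TRUE)]
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ms <- list(r1, r2, r3)
    expect_equal(geom$D[pair[1], pair[2]],
                 1 - cor(v(unclass(ms[[pair[1]]])), v(unclass(ms[[pair[2]]]))),
                 tolerance = 1e-10)
  }
  expect_equal(unname(diag(geom$D)), rep(0, 3))

  # identical RDMs -> distance 0; negated RDM -> distance 2
  same <- inter_roi_distances(list(list(r1, r1)), systems = c("EV", "EV"))
  expect_lt(same$D[1, 2], 1e-5)
  neg <- structure(-unclass(r1), class = c("rdm", "matrix"), roi = "neg")
  opp <- inter_roi_distances(list(list(r1, neg)), systems = c("EV", "EV"))
  expect_gt(opp$D[1, 2], 2 - 1e-5)

  const <- structure(matrix(0.3, 8, 8), class = c("rdm", "matrix"), roi = "flat")
  expect_error(inter_roi_distances(list(list(r1, const))), "flat")
})

test_that("between-subject geometry implements the reliability-normalized index", {
  # 11 subjects -> 55 subject pairs
  set.seed(63)
  rdms <- lapply(1:11, function(s)
    lapply(1:3, function(k) {
      m <- unclass(random_rdm(8, k)) + matrix(rnorm(64, 0, 0.1), 8)
      structure((m + t(m)) / 2, class = c("rdm", "matrix"),
                roi = paste0("roi", k))
    }))
  geom <- between_subject_geometry(rdms, systems = c("EV", "extended", "EV"))
  expect_length(geom$r_by_unit, 55)
  expect_equal(unname(diag(geom$D)), rep(0, 3), tolerance = 1e-10)
  expect_equal(geom$D, t(geom$D), tolerance = 1e-12)
  # direct Eq arithmetic: D = 1 - r_ab / sqrt(r_a * r_b)
  expect_equal(geom$D[1, 2],
               1 - geom$r_pair[1, 2] /
                 sqrt(geom$r_reliability[[1]] * geom$r_reliability[[2]]),
               tolerance = 1e-12)

  # identical subjects: reliability 1 and D(a, a) = 0
  same <- suppressWarnings(
    between_subject_geometry(rep(list(rdms[[1]]), 3),
                             systems = c("EV", "extended", "EV")))
  expect_true(all(same$r_reliability > 0.999))
  expect_equal(unname(diag(same$D)), rep(0, 3), tolerance = 1e-6)

  # anti-correlated RDMs across subjects: reliability <= 0 is an error
  flip <- rdms[1:2]
  flip[[2]] <- lapply(flip[[1]], function(m)
    structure(-unclass(m), class = c("rdm", "matrix"), roi = attr(m, "roi")))
  expect_error(between_subject_geometry(flip), "non-positive|reliability")
  expect_error(between_subject_geometry(rdms[1]), "at least 2")
})

test_that("classical MDS recovers planted configurations", {
  set.seed(64)
  pts <- matrix(rnorm(15), 5, 3)
  D <- as.matrix(dist(pts))
  emb <- classical_mds(D, k = 3)
  expect_lt(procrustes_rms(pts, emb), 1e-8)
  # agrees with the independent cmdscale implementation up to axis signs
  ref <- stats::cmdscale(D, k = 3)
  for (j in 1:3)
    expect_true(max(abs(emb[, j] - ref[, j])) < 1e-8 ||
                  max(abs(emb[, j] + ref[, j])) < 1e-8)
  # Euclidean input: no sizeable negative eigenvalues
  expect_true(all(attr(emb, "eigenvalues") > -1e-10 * max(D^2)))

  # two points at distance d embed at +/- d/2
  D2 <- matrix(c(0, 3, 3, 0), 2)
  e2 <- classical_mds(D2, k = 1)
  expect_equal(sort(as.numeric(e2)), c(-1.5, 1.5))

  expect_error(classical_mds(D2, k = 2), "positive eigenvalues")
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
})

test_that("rv_coefficient is the double-centered trace formula", {
  set.seed(65)
  A <- crossprod(matrix(rnorm(36), 6))
  B <- crossprod(matrix(rnorm(36), 6))
  expect_equal(rv_coefficient(A, A), 1)
  # direct trace-formula oracle
  J <- diag(6) - matrix(1 / 6, 6, 6)
  Ac <- J %*% A %*% J; Bc <- J %*% B %*% J
  expect_equal(rv_coefficient(A, B),
               sum(Ac * Bc) / sqrt(sum(Ac^2) * sum(Bc^2)))
  expect_error(rv_coefficient(A, matrix(0, 6, 6)), "zero matrix")
  expect_error(rv_coefficient(A, B[1:5, 1:5]), "shape")
})

test_that("the system contrast model reduces to OLS and shifts correctly", {
  set.seed(66)
  n_unit <- 6; n_pair <- 45
  C <- rbinom(n_pair, 1, 0.25)
  E <- ifelse(C == 1, 0, rbinom(n_pair, 1, 0.25))
  df <- data.frame(unit = rep(1:n_unit, each = n_pair),
                   C = rep(C, n_unit), E = rep(E, n_unit))
  df$r <- 0.2 + 0.05 * df$C + 0.1 * df$E + rnorm(nrow(df), 0, 0.03)
  fit <- lme_system_contrast(df, n_bootstrap = 50, seed = 1)
  ols <- coef(lm(r ~ C + E, data = df))
  expect_equal(fit$estimates$estimate, unname(ols), tolerance = 1e-6)
  # translation equivariance: +c shifts beta0 only
  df2 <- df; df2$r <- df$r + 0.07
  fit2 <- lme_system_contrast(df2, n_bootstrap = 50, seed = 1)
  expect_equal(fit2$estimates$estimate[1], fit$estimates$estimate[1] + 0.07,
               tolerance = 1e-6)
  expect_equal(fit2$estimates$estimate[2:3], fit$estimates$estimate[2:3],
               tolerance = 1e-6)

  bad <- df; bad$E[bad$C == 1] <- 1
  expect_error(lme_system_contrast(bad), "both")
  expect_error(lme_system_contrast(df[df$unit == 1, ]), "2 units")
})
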