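# Linear C-SVM behavior, decoding analyses, searchlight maps.

test_that("train_predict handles separable, degenerate and invalid input", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60) + 4, 20, 3), matrix(rnorm(60), 20, 3))
  y <- rep(c("fam", "unf"), each = 20)
  Xte <- rbind(matrix(rnorm(30) + 4, 10, 3), matrix(rnorm(30), 10, 3))
  yte <- rep(c("fam", "unf"), each = 10)
  fit <- train_predict(X, y, Xte, yte)
  expect_equal(fit$accuracy, 1)

  # duplicating every training sample leaves predictions unchanged
  fit2 <- train_predict(rbind(X, X), c(y, y), Xte, yte)
  expect_equal(fit2$predicted, fit$predicted)

  # shared train/test feature scaling leaves predictions unchanged
  fit3 <- train_predict(X * 7, y, Xte * 7, yte)
  expect_equal(fit3$predicted, fit$predicted)

  # all-constant features: chance accuracy with a warning
  expect_warning(
    degen <- train_predict(matrix(1, 10, 2), rep(c("a", "b"), 5),
                           matrix(1, 4, 2), c("a", "a", "b", "b")),
    "constant")
  expect_equal(degen$accuracy, 0.5)

  expect_error(train_predict(X, rep("fam", 40), Xte), "2 classes")
  expect_error(train_predict(X, y, Xte, rep("zzz", 20)), "absent")

  # 4-way one-vs-one reduction on separable clusters
  mu <- rbind(c(8, 0), c(0, 8), c(-8, 0), c(0, -8))
  X4 <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(24), 12, 2), 2, mu[k, ], "+")))
  y4 <- rep(letters[1:4], each = 12)
  te4 <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(8), 4, 2), 2, mu[k, ], "+")))
  expect_equal(train_predict(X4, y4, te4, rep(letters[1:4], each = 4))$accuracy, 1)
})

test_that("shuffled labels on random features decode at chance", {
  set.seed(32)
  accs <- replicate(60, {
    X <- matrix(rnorm(24 * 5), 24, 5)
    # balanced shuffled labels in both halves: accuracy has expectation 0.5
    y_tr <- sample(rep(c("a", "b"), 8))
    y_te <- sample(rep(c("a", "b"), 4))
    train_predict(X[1:16, ], y_tr, X[17:24, ], y_te)$accuracy
  })
  ci <- stats::t.test(accs, mu = 0.5)$conf.int
  expect_gt(ci[2], 0.5)
  expect_lt(ci[1], 0.55)
})

test_that("familiarity decoding finds planted signal and respects schemes", {
  fx <- make_signal_betas(seed = 41, familiarity_amp = 2, identity_amp = 1,
                          noise_sd = 0.8)
  sp <- l2io_16()
  acc <- familiarity_decoding(fx$prepared, sp, voxels = fx$region)
  expect_gt(acc, 0.9)

  wrong <- leave_one_run_out_splits(1:11, fx$prepared$conditions$condition)
  bad <- sp
  bad[[1]]$scheme <- "loro" # mixed schemes must be rejected
  expect_error(familiarity_decoding(fx$prepared, bad), "scheme")
  # a permuted labeling scores near chance on strong familiarity signal
  perm <- enumerate_familiarity_permutations(
    fx$prepared$conditions$identity, paste0("F", 1:4))[[20]]
  sp_perm <- leave_two_identities_out_splits(
    names(perm)[perm == "familiar"], names(perm)[perm == "unfamiliar"], 1:11)
  acc_perm <- familiarity_decoding(fx$prepared, sp_perm, labeling = perm,
                                   voxels = fx$region)
  expect_lt(acc_perm, acc - 0.2)
})

test_that("identity decoding is class-pure and finds planted signal", {
  fx <- make_signal_betas(seed = 42, familiarity_amp = 0, identity_amp = 3,
                          noise_sd = 0.5)
  b <- fx$prepared
  fam_idx <- which(b$conditions$familiarity == "familiar")
  bf <- b
  bf$betas <- b$betas[, fam_idx, , drop = FALSE]
  bf$conditions <- b$conditions[fam_idx, ]
  sp <- leave_one_run_out_splits(b$runs, bf$conditions$condition)
  acc <- identity_decoding(bf, sp, voxels = fx$region)
  expect_gt(acc, 0.9)
  expect_error(identity_decoding(b, sp), "single familiarity class")

  # pure noise decodes at 4-way chance
  set.seed(43)
  accs <- vapply(1:8, function(s) {
    fx0 <- make_signal_betas(seed = 100 + s, familiarity_amp = 0,
                             identity_amp = 0, noise_sd = 1,
                             n_runs = 6, dims = c(5, 5, 4))
    b0 <- fx0$prepared
    idx <- which(b0$conditions$familiarity == "familiar")
    bs <- b0
    bs$betas <- b0$betas[, idx, , drop = FALSE]
    bs$conditions <- b0$conditions[idx, ]
    identity_decoding(bs, leave_one_run_out_splits(bs$runs,
                                                   bs$conditions$condition))
  }, numeric(1))
  ci <- stats::t.test(accs, mu = 0.25)$conf.int
  expect_true(ci[1] <= 0.25 && 0.25 <= ci[2] + 0.1)
})

test_that("searchlight maps localize signal and reduce to direct decoding", {
  fx <- make_signal_betas(seed = 44, familiarity_amp = 2, identity_amp = 1,
                          noise_sd = 1)
  b <- fx$prepared
  map <- searchlight_map(b, "familiarity", radius_vox = 1.5)
  expect_s3_class(map, "accuracy_map")
  expect_true(all(map$values >= 0 & map$values <= 1))
  expect_equal(map$chance, 0.5)
  # mean accuracy inside the planted region exceeds outside
  expect_gt(mean(map$values[fx$region]), mean(map$values[-fx$region]) + 0.1)

  # single-voxel center mask at radius 0 equals direct decoding on that voxel
  g <- b$grid
  center_lin <- b$mask$voxels[fx$region[1]]
  one <- array(FALSE, g$dims)
  one[center_lin] <- TRUE
  m1 <- searchlight_map(b, "familiarity", radius_vox = 0,
                        mask = brain_mask(g, one))
  direct <- familiarity_decoding(b, l2io_16(), voxels = fx$region[1])
  expect_equal(unname(m1$values), direct)

  # shared feature scaling upstream of z-scoring leaves the map unchanged
  raw2 <- fx$betas
  raw2$betas <- raw2$betas * 5
  m2 <- searchlight_map(prepare_features(raw2), "familiarity", radius_vox = 0,
                        mask = brain_mask(g, one))
  expect_equal(m2$values, m1$values, tolerance = 1e-6)
})

test_that("veridical decoding exceeds the exhaustive permutation null", {
  # with a strong planted familiarity component, the veridical labeling must
  # reach at least the 97.5th percentile of the 35-permutation null (each
  # labeling analyzed with splits balanced w.r.t. its own classes)
  fx <- make_signal_betas(seed = 46, familiarity_amp = 3, identity_amp = 1,
                          noise_sd = 1)
  b <- fx$prepared
  perms <- enumerate_familiarity_permutations(
    b$conditions$identity,
    familiar = b$conditions$identity[b$conditions$familiarity == "familiar"])
  accs <- vapply(perms, function(p) {
    sp <- leave_two_identities_out_splits(
      names(p)[p == "familiar"], names(p)[p == "unfamiliar"], b$runs)
    familiarity_decoding(b, sp, labeling = p, voxels = fx$region)
  }, numeric(1))
  expect_gte(accs[1], quantile(accs, 0.975))
  expect_gt(accs[1], 0.9)
})

test_that("null searchlight maps have the scheme-specific shape", {
  fx <- make_signal_betas(seed = 45, n_runs = 4, dims = c(4, 4, 3),
                          familiarity_amp = 0.5, identity_amp = 0.5)
  b <- fx$prepared
  nm <- searchlight_null_maps(b, "familiarity", radius_vox = 1)
  expect_equal(dim(nm), c(length(b$mask$voxels), 35L))
  expect_equal(attr(nm, "chance"), 0.5)
  # first column is the veridical labeling: equals the observed map
  obs <- searchlight_map(b, "familiarity", radius_vox = 1)
  expect_equal(nm[, 1], unname(obs$values))
  ni <- searchlight_null_maps(b, "identity", radius_vox = 1, n_perms = 4,
                              seed = 9)
  expect_equal(dim(ni), c(length(b$mask$voxels), 4L))
  expect_identical(ni, searchlight_null_maps(b, "identity", radius_vox = 1,
                                             n_perms = 4, seed = 9))
})
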