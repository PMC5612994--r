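# Linear classification of beta patterns and searchlight mapping.
#
# The classifier is a linear C-SVM (L1 hinge loss) trained by dual coordinate
# descent in compiled code, with one-vs-one voting for the 4-way identity
# analyses. The C parameter is scaled by the mean Euclidean norm of the
# training vectors (c = c_base / mean norm), reproducing the behavior of the
# toolkit default this analysis style assumes.

#' Classifier specification
#' @param c_base base regularization constant (> 0, default 1); the effective
#'   C is `c_base / mean(||x_train||)`.
#' @export
classifier_spec <- function(c_base = 1) {
  if (!is.finite(c_base) || c_base <= 0) stop("c_base must be > 0")
  structure(list(kind = "linear-csvm", c_base = c_base), class = "classifier_spec")
}

#' Train a linear C-SVM and predict test labels
#'
#' @param train_x,test_x numeric feature matrices (samples x features).
#' @param train_y training labels (factor, character or integer); every class
#'   must have at least one training sample.
#' @param test_y optional test labels; if given, accuracy is returned.
#' @param spec a [classifier_spec()].
#' @return list with `predicted` (labels) and `accuracy` (or `NA` without
#'   `test_y`). Degenerate all-constant training features yield chance-level
#'   expected accuracy with a warning.
#' @export
train_predict <- function(train_x, train_y, test_x, test_y = NULL,
                          spec = classifier_spec()) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) stop("feature dimensions do not match")
  lev <- sort(unique(as.character(train_y)))
  if (length(lev) < 2) stop("training data must contain at least 2 classes")
  if (!is.null(test_y) && !all(as.character(test_y) %in% lev))
    stop("a test class is absent from training")
  if (all(apply(train_x, 2, function(v) max(v) - min(v)) < 1e-12)) {
    warning("all training features are constant; returning chance-level accuracy")
    predicted <- rep(lev[1], nrow(test_x))
    acc <- if (is.null(test_y)) NA_real_ else 1 / length(lev)
    return(list(predicted = predicted, accuracy = acc))
  }
  y_int <- match(as.character(train_y), lev)
  pred_int <- .svm_train_predict_cpp(train_x, as.integer(y_int), test_x,
                                     spec$c_base)
  predicted <- lev[pred_int]
  acc <- if (is.null(test_y)) NA_real_
         else mean(predicted == as.character(test_y))
  list(predicted = predicted, accuracy = acc)
}

# One row per (run, condition) sample, aligned with as_feature_matrix().
sample_index <- function(betas) {
  g <- expand.grid(ci = seq_len(nrow(betas$conditions)),
                   ri = seq_along(betas$runs), KEEP.OUT.ATTRS = FALSE)
  data.frame(row = seq_len(nrow(g)),
             run = betas$runs[g$ri],
             condition = betas$conditions$condition[g$ci],
             identity = betas$conditions$identity[g$ci],
             familiarity = betas$conditions$familiarity[g$ci],
             stringsAsFactors = FALSE)
}

#' Flatten a beta set into a samples x voxels feature matrix
#'
#' Rows are (run, condition) samples in the order of [sample_index()]'s
#' internal table.
#' @param betas a [beta_pattern_set()].
#' @export
as_feature_matrix <- function(betas) {
  d <- dim(betas$betas)
  m <- matrix(aperm(betas$betas, c(2, 1, 3)), d[1] * d[2], d[3])
  m
}

# Map split keys to sample rows; errors if any key is missing.
resolve_split_rows <- function(split, samples) {
  find_rows <- function(k) {
    idx <- samples$row[paste(samples$run, samples$condition) %in%
                         paste(k$run, k$condition)]
    idx
  }
  list(train = find_rows(split$train), test = find_rows(split$test))
}

check_scheme <- function(splits, schemes) {
  found <- unique(vapply(splits, function(s) s$scheme %||% "", ""))
  if (length(found) != 1 || !found %in% schemes)
    stop(sprintf("splits carry the wrong scheme label (expected %s)",
                 paste(sQuote(schemes), collapse = " or ")))
}

#' Identity-independent familiarity decoding
#'
#' Mean leave-two-identities-out test accuracy for classifying familiar vs
#' unfamiliar faces. With the default veridical labeling this is the observed
#' statistic; passing one element of
#' [enumerate_familiarity_permutations()] computes a permutation statistic.
#'
#' @param betas a [beta_pattern_set()] with the 8 familiar + unfamiliar
#'   conditions (use [prepare_features()] first).
#' @param splits splits from [leave_two_identities_out_splits()]; splits from
#'   [leave_one_run_out_splits()] are also accepted for the (less controlled)
#'   run-wise familiarity analysis used to demonstrate the identity confound.
#' @param spec a [classifier_spec()].
#' @param labeling optional named vector mapping identity to class.
#' @param voxels optional indices into the masked voxels to restrict features.
#' @return mean accuracy across splits (chance 0.5).
#' @export
familiarity_decoding <- function(betas, splits, spec = classifier_spec(),
                                 labeling = NULL, voxels = NULL) {
  check_scheme(splits, c("l2io", "loro"))
  samples <- sample_index(betas)
  if (nrow(betas$conditions) != 8)
    warning("expected 8 conditions (4 familiar + 4 unfamiliar)")
  X <- as_feature_matrix(betas)
  if (!is.null(voxels)) X <- X[, voxels, drop = FALSE]
  labels <- if (is.null(labeling)) samples$familiarity
            else unname(labeling[samples$identity])
  accs <- vapply(splits, function(sp) {
    rows <- resolve_split_rows(sp, samples)
    train_predict(X[rows$train, , drop = FALSE], labels[rows$train],
                  X[rows$test, , drop = FALSE], labels[rows$test], spec)$accuracy
  }, numeric(1))
  mean(accs)
}

#' Identity decoding within one familiarity class
#'
#' 4-way classification of identities using leave-one-run-out
#' cross-validation. Must be called separately for the familiar and the
#' unfamiliar conditions; the caller averages the two results (see
#' [searchlight_map()], which does this for maps).
#'
#' @param betas a [beta_pattern_set()] whose conditions all share one
#'   familiarity class.
#' @param splits splits from [leave_one_run_out_splits()].
#' @param spec a [classifier_spec()].
#' @param relabeling optional data.frame (`run`, `condition`, `new_label`)
#'   from [identity_permutations_within_run()].
#' @param voxels optional masked-voxel indices to restrict features.
#' @return mean accuracy across splits (chance 0.25 for 4 identities).
#' @export
identity_decoding <- function(betas, splits, spec = classifier_spec(),
                              relabeling = NULL, voxels = NULL) {
  check_scheme(splits, "loro")
  if (length(unique(betas$conditions$familiarity)) != 1)
    stop("identity decoding must be run within a single familiarity class")
  samples <- sample_index(betas)
  X <- as_feature_matrix(betas)
  if (!is.null(voxels)) X <- X[, voxels, drop = FALSE]
  labels <- samples$identity
  if (!is.null(relabeling)) {
    m <- match(paste(samples$run, samples$condition),
               paste(relabeling$run, relabeling$condition))
    labels <- relabeling$new_label[m]
  }
  accs <- vapply(splits, function(sp) {
    rows <- resolve_split_rows(sp, samples)
    train_predict(X[rows$train, , drop = FALSE], labels[rows$train],
                  X[rows$test, , drop = FALSE], labels[rows$test], spec)$accuracy
  }, numeric(1))
  mean(accs)
}

# --- searchlight ------------------------------------------------------------

accuracy_map <- function(values, grid, mask, chance, analysis, radius_vox) {
  structure(list(values = values, grid = grid, mask = mask, chance = chance,
                 analysis = analysis, radius_vox = radius_vox),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat(sprintf("accuracy_map (%s): %d voxels, chance %.2f, mean %.3f\n",
              x$analysis, length(x$values), x$chance, mean(x$values)))
  invisible(x)
}

#' Embed an accuracy/z map in a 3D volume (NA outside the mask)
#' @param map an `accuracy_map` or `z_map`.
#' @export
as_volume <- function(map) {
  vol <- array(NA_real_, map$grid$dims)
  vol[map$mask$voxels] <- map$values
  vol
}

# Neighborhood column indices (into the masked feature columns) for every
# center of `centers_mask`, using the feature mask's voxels.
build_neighborhoods <- function(feature_mask, centers_mask, radius_vox) {
  dims <- feature_mask$grid$dims
  pos_of_linear <- rep(NA_integer_, prod(dims))
  pos_of_linear[feature_mask$voxels] <- seq_along(feature_mask$voxels)
  off <- sphere_offsets(radius_vox)
  centers <- linear_to_ijk(dims, centers_mask$voxels)
  lapply(seq_len(nrow(centers)), function(i) {
    cand <- sweep(off, 2, centers[i, ], "+")
    keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
            cand[, 2] >= 1 & cand[, 2] <= dims[2] &
            cand[, 3] >= 1 & cand[, 3] <= dims[3]
    nb <- pos_of_linear[ijk_to_linear(dims, cand[keep, , drop = FALSE])]
    nb <- nb[!is.na(nb)]
    if (length(nb) == 0)
      stop("searchlight neighborhood is empty; center outside the feature mask")
    as.integer(nb)
  })
}

# Shared engine behind searchlight_map and searchlight_null_maps. `labelings`:
# for familiarity, a list of identity->class maps (NULL = veridical); for
# identity, a list of within-run relabelings (NULL = veridical). Returns a
# voxels x n_labelings accuracy matrix.
searchlight_engine <- function(betas, analysis, radius_vox, spec, centers_mask,
                               labelings) {
  samples <- sample_index(betas)
  X <- as_feature_matrix(betas)
  nbhd <- build_neighborhoods(betas$mask, centers_mask, radius_vox)
  if (analysis == "familiarity") {
    fams <- unique(betas$conditions$familiarity)
    if (!setequal(fams, c("familiar", "unfamiliar")))
      stop("familiarity searchlight needs familiar + unfamiliar conditions only")
    if (is.null(labelings)) {
      labelings <- list(setNames(betas$conditions$familiarity,
                                 betas$conditions$identity))
    }
    # the leave-two-identities-out scheme follows the labeling: a permuted
    # labeling is analyzed with splits balanced w.r.t. its own classes, so
    # every permutation is treated exactly like the veridical analysis
    lab_mat <- vapply(labelings, function(lb)
      match(unname(lb[samples$identity]), c("familiar", "unfamiliar")),
      integer(nrow(samples)))
    splits_by_labeling <- lapply(labelings, function(lb) {
      splits <- leave_two_identities_out_splits(
        names(lb)[lb == "familiar"], names(lb)[lb == "unfamiliar"],
        runs = betas$runs)
      lapply(splits, function(sp) {
        r <- resolve_split_rows(sp, samples)
        list(train = r$train, test = r$test)
      })
    })
    acc <- .searchlight_accuracy_cpp(X, nbhd, lab_mat, splits_by_labeling,
                                     spec$c_base)
    return(acc)
  }
  # identity analysis: run per familiarity class and average the maps
  acc <- NULL
  for (cls in c("familiar", "unfamiliar")) {
    ci <- which(betas$conditions$familiarity == cls)
    if (length(ci) < 2) stop("identity searchlight needs both familiarity classes")
    sub_rows <- samples$row[samples$familiarity == cls]
    sub_samples <- samples[sub_rows, ]
    conds <- betas$conditions$condition[ci]
    splits <- leave_one_run_out_splits(betas$runs, conds)
    rows <- lapply(splits, function(sp) {
      r <- list(
        train = match(paste(sp$train$run, sp$train$condition),
                      paste(sub_samples$run, sub_samples$condition)),
        test = match(paste(sp$test$run, sp$test$condition),
                     paste(sub_samples$run, sub_samples$condition)))
      r
    })
    if (is.null(labelings)) {
      lab_mat <- matrix(match(sub_samples$identity, conds), ncol = 1)
    } else {
      lab_mat <- vapply(labelings[[cls]], function(rl) {
        m <- match(paste(sub_samples$run, sub_samples$condition),
                   paste(rl$run, rl$condition))
        match(rl$new_label[m], conds)
      }, integer(nrow(sub_samples)))
    }
    rows_by_labeling <- rep(list(rows), ncol(lab_mat))
    a <- .searchlight_accuracy_cpp(X[sub_samples$row, , drop = FALSE], nbhd,
                                   lab_mat, rows_by_labeling, spec$c_base)
    acc <- if (is.null(acc)) a else (acc + a) / 2
  }
  acc
}

#' Searchlight accuracy map
#'
#' Moves a spherical neighborhood over every in-mask voxel, runs the
#' designated decoding analysis on the sphere's voxels and stores the mean
#' cross-validated accuracy at the center. For the identity analysis the
#' familiar-only and unfamiliar-only maps are computed and averaged.
#'
#' @param betas a prepared [beta_pattern_set()] (see [prepare_features()]).
#' @param analysis `"familiarity"` (leave-two-identities-out, chance 0.5) or
#'   `"identity"` (leave-one-run-out 4-way, chance 0.25).
#' @param radius_vox searchlight radius in voxel units (default 5, i.e. 10 mm
#'   at 2 mm resolution).
#' @param spec a [classifier_spec()].
#' @param mask optional center mask (must be a subset of the beta mask);
#'   default all beta-mask voxels.
#' @return an `accuracy_map`.
#' @export
searchlight_map <- function(betas, analysis = c("familiarity", "identity"),
                            radius_vox = 5, spec = classifier_spec(),
                            mask = NULL) {
  analysis <- match.arg(analysis)
  centers_mask <- if (is.null(mask)) betas$mask else mask
  if (!all(centers_mask$voxels %in% betas$mask$voxels))
    stop("center mask must be a subset of the beta mask")
  acc <- searchlight_engine(betas, analysis, radius_vox, spec, centers_mask,
                            labelings = NULL)
  accuracy_map(acc[, 1], betas$grid, centers_mask,
               chance = if (analysis == "familiarity") 0.5 else 0.25,
               analysis = analysis, radius_vox = radius_vox)
}

#' Permutation null searchlight maps for one subject
#'
#' For the familiarity analysis the null set is the exhaustive list of
#' balanced familiarity relabelings (35 for 8 identities, including the
#' veridical class). For the identity analysis it is `n_perms` random
#' within-run identity relabelings applied to each familiarity class.
#'
#' @param betas a prepared [beta_pattern_set()].
#' @param analysis `"familiarity"` or `"identity"`.
#' @param radius_vox searchlight radius in voxel units.
#' @param spec a [classifier_spec()].
#' @param mask optional center mask.
#' @param n_perms identity-analysis permutation count (default 20).
#' @param seed seed for the identity relabelings.
#' @return voxels x n_permutations accuracy matrix (attribute `chance`).
#' @export
searchlight_null_maps <- function(betas, analysis = c("familiarity", "identity"),
                                  radius_vox = 5, spec = classifier_spec(),
                                  mask = NULL, n_perms = 20, seed = 1L) {
  analysis <- match.arg(analysis)
  centers_mask <- if (is.null(mask)) betas$mask else mask
  if (analysis == "familiarity") {
    labelings <- enumerate_familiarity_permutations(
      betas$conditions$identity,
      familiar = betas$conditions$identity[betas$conditions$familiarity == "familiar"])
  } else {
    labelings <- list(
      familiar = identity_permutations_within_run(
        betas$conditions$condition[betas$conditions$familiarity == "familiar"],
        betas$runs, n_perms, seed = derive_seed(seed, 1)),
      unfamiliar = identity_permutations_within_run(
        betas$conditions$condition[betas$conditions$familiarity == "unfamiliar"],
        betas$runs, n_perms, seed = derive_seed(seed, 2)))
  }
  acc <- searchlight_engine(betas, analysis, radius_vox, spec, centers_mask,
                            labelings)
  attr(acc, "chance") <- if (analysis == "familiarity") 0.5 else 0.25
  acc
}
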