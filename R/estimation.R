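# Run-wise GLM beta estimation, CompCor-style noise components, within-run
# z-scoring and condition filtering.

#' Estimate condition betas from run-wise time series
#'
#' Per-run ordinary least squares of each voxel's time series on the condition
#' regressors (trial boxcars convolved with the HRF) plus optional nuisance
#' columns and an intercept. Only the condition betas are returned.
#'
#' @param timeseries runs x timepoints x voxels array, or the list returned by
#'   [generate_timeseries()].
#' @param design trial table from [generate_design()].
#' @param mask a [brain_mask()] matching the voxel axis.
#' @param grid a [volume_grid()].
#' @param nuisance optional list (one per run) of timepoints x k nuisance
#'   regressor matrices.
#' @param tr_s,hrf,fixation_s,trial_spacing_s timing parameters; must match
#'   the generating model (defaults mirror [generate_timeseries()]).
#' @return a [beta_pattern_set()].
#' @export
estimate_betas <- function(timeseries, design, mask, grid, nuisance = NULL,
                           tr_s = 2, hrf = canonical_hrf, fixation_s = 10,
                           trial_spacing_s = 6) {
  if (is.list(timeseries) && !is.null(timeseries$series)) {
    tr_s <- timeseries$tr_s
    fixation_s <- timeseries$fixation_s
    trial_spacing_s <- timeseries$trial_spacing_s
    timeseries <- timeseries$series
  }
  runs <- sort(unique(design$run))
  if (dim(timeseries)[1] != length(runs)) stop("run count mismatch")
  n_tp <- dim(timeseries)[2]
  nv <- dim(timeseries)[3]
  normal <- design[design$trial_type == "normal", ]
  ids <- unique(normal$identity)
  fam <- setNames(normal$familiarity[match(ids, normal$identity)], ids)
  betas <- array(0, c(length(runs), length(ids), nv))
  for (ri in seq_along(runs)) {
    dr <- design[design$run == runs[ri], ]
    X <- build_design_matrix(dr, ids, n_tp, tr_s, hrf, trial_spacing_s, fixation_s)
    Xfull <- cbind(X, intercept = 1)
    if (!is.null(nuisance)) {
      N <- as.matrix(nuisance[[ri]])
      if (nrow(N) != n_tp) stop("nuisance regressors have wrong length")
      colnames(N) <- paste0("nuisance", seq_len(ncol(N)))
      Xfull <- cbind(Xfull, N)
    }
    qr_x <- qr(Xfull)
    if (qr_x$rank < ncol(Xfull)) {
      bad <- colnames(Xfull)[qr_x$pivot[(qr_x$rank + 1):ncol(Xfull)]]
      stop("design matrix is rank deficient; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    coefs <- qr.coef(qr_x, matrix(timeseries[ri, , ], n_tp, nv))
    betas[ri, , ] <- coefs[seq_along(ids), , drop = FALSE]
  }
  conditions <- data.frame(condition = ids, identity = ids,
                           familiarity = unname(fam[ids]),
                           stringsAsFactors = FALSE)
  beta_pattern_set(betas, runs, conditions, grid, mask)
}

#' CompCor-style noise components
#'
#' Residualizes noise-mask voxel time series on the given confounds (plus an
#' intercept), then returns the first `n_components` principal-component time
#' courses of the residuals, each scaled to unit variance. Component signs are
#' fixed so each component's largest-magnitude loading is positive.
#'
#' @param timeseries timepoints x voxels matrix from a noise mask (>= 5 voxels).
#' @param confounds optional timepoints x k confound matrix.
#' @param n_components number of components (default 5).
#' @return timepoints x n_components matrix.
#' @export
compcor_components <- function(timeseries, confounds = NULL, n_components = 5) {
  timeseries <- as.matrix(timeseries)
  if (ncol(timeseries) < n_components)
    stop("need at least n_components voxels in the noise mask")
  X <- cbind(intercept = rep(1, nrow(timeseries)), confounds)
  resid <- timeseries - X %*% qr.coef(qr(X), timeseries)
  resid[is.na(resid)] <- 0
  s <- svd(resid, nu = n_components, nv = 0)
  if (sum(s$d > 1e-10) < n_components)
    stop("residual rank is smaller than n_components")
  comp <- s$u[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    j <- which.max(abs(comp[, k]))
    if (comp[j, k] < 0) comp[, k] <- -comp[, k]
    comp[, k] <- comp[, k] / sd(comp[, k])
  }
  colnames(comp) <- paste0("compcor", seq_len(n_components))
  comp
}

#' Z-score betas within each run, separately per voxel
#'
#' For each run and voxel, the across-condition mean becomes 0 and the SD 1.
#' The default divisor is the population SD (divide by n), matching the
#' convention of the toolkit family this analysis style comes from; sample SD
#' is selectable. Voxels constant within a run map to all-zeros with a
#' warning.
#'
#' @param betas a [beta_pattern_set()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return a z-scored [beta_pattern_set()].
#' @export
zscore_within_run <- function(betas, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  b <- betas$betas
  n_cond <- dim(b)[2]
  if (n_cond < 2) stop("need at least 2 conditions per run to z-score")
  any_const <- FALSE
  for (ri in seq_len(dim(b)[1])) {
    m <- matrix(b[ri, , ], n_cond, dim(b)[3])
    mu <- colMeans(m)
    centered <- sweep(m, 2, mu)
    ss <- sqrt(colMeans(centered^2))
    if (sd_type == "sample") ss <- ss * sqrt(n_cond / (n_cond - 1))
    const <- ss < 1e-12
    if (any(const)) {
      any_const <- TRUE
      ss[const] <- 1
      centered[, const] <- 0
    }
    b[ri, , ] <- sweep(centered, 2, ss, "/")
  }
  if (any_const)
    warning("constant voxels within a run were set to zero after z-scoring")
  betas$betas <- b
  betas
}

#' Keep only familiar and unfamiliar identity conditions
#'
#' Drops the self condition (and would never include oddball/blank, which are
#' not conditions). The canonical design retains exactly 8 of 9 conditions.
#'
#' @param betas a [beta_pattern_set()].
#' @return a [beta_pattern_set()] with familiar + unfamiliar conditions only.
#' @export
filter_conditions <- function(betas) {
  keep <- betas$conditions$familiarity %in% c("familiar", "unfamiliar")
  if (!any(keep)) stop("no familiar/unfamiliar conditions present")
  if (all(keep)) return(betas)
  betas$betas <- betas$betas[, keep, , drop = FALSE]
  betas$conditions <- betas$conditions[keep, , drop = FALSE]
  rownames(betas$conditions) <- NULL
  betas
}

#' Standard feature preparation: filter conditions, then z-score within run
#'
#' The pipeline fixes the order as filter first, then z-score, so the
#' classifier features are standardized over exactly the 8 retained
#' conditions.
#' @param betas a [beta_pattern_set()].
#' @param sd_type passed to [zscore_within_run()].
#' @export
prepare_features <- function(betas, sd_type = "population") {
  zscore_within_run(filter_conditions(betas), sd_type = sd_type)
}
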