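# Group-level permutation inference with threshold-free cluster enhancement.

#' Threshold-free cluster enhancement of a 3D image
#'
#' For each voxel, integrates `extent(h)^e * h^H` over suprathreshold height
#' levels from `dh` up to the voxel's height in steps of `dh`, where
#' `extent(h)` is the size of the connected suprathreshold component the voxel
#' belongs to at level `h`. Negative and non-finite voxels contribute nothing
#' (the caller centers accuracy maps at chance first; the test is one-tailed).
#'
#' @param x numeric 3D array.
#' @param e_param extent exponent (default 0.5).
#' @param h_param height exponent (default 2).
#' @param dh integration step; `NULL` (default) uses `max(x)/100`.
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return 3D array of TFCE scores.
#' @export
tfce_transform <- function(x, e_param = 0.5, h_param = 2, dh = NULL,
                           connectivity = 6) {
  if (length(dim(x)) != 3) stop("x must be a 3D array")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  out <- .tfce_cpp(as.numeric(x), as.integer(dim(x)), e_param, h_param,
                   if (is.null(dh)) -1 else dh, as.integer(connectivity))
  array(out, dim(x))
}

# TFCE of one masked accuracy map: center at chance, truncate negatives,
# embed in the volume, transform, return masked vector.
tfce_masked <- function(values, mask, chance, e_param, h_param, dh, connectivity) {
  vol <- array(0, mask$grid$dims)
  vol[mask$voxels] <- pmax(values - chance, 0)
  tfce_transform(vol, e_param, h_param, dh, connectivity)[mask$voxels]
}

#' Group permutation z-map of TFCE scores
#'
#' The observed group map is the subject mean of TFCE-transformed,
#' chance-centered accuracy maps. The null distribution is built by drawing,
#' `n_draws` times, one permutation map per subject uniformly at random and
#' averaging their TFCE maps across subjects. The default z construction is
#' FWE-corrected: each voxel's p-value is the fraction of draws whose
#' map-wise maximum TFCE reaches the voxel's observed score (max-stat
#' correction, one-tailed), mapped through the normal quantile. Uncorrected
#' per-voxel variants are available via `null_stat = "voxel"` with
#' `z_method` `"rank"` or `"meansd"` (the latter is
#' `(obs - null mean) / null SD`).
#'
#' @param observed list of per-subject `accuracy_map`s (aligned masks).
#' @param nulls list (one per subject) of voxels x n_permutations accuracy
#'   matrices from [searchlight_null_maps()].
#' @param n_draws number of group null draws (default 10000).
#' @param seed integer seed for the draws.
#' @param null_stat `"max"` (FWE, default) or `"voxel"`.
#' @param z_method `"rank"` (default) or `"meansd"` (only for
#'   `null_stat = "voxel"`).
#' @param e_param,h_param,dh,connectivity TFCE parameters.
#' @return object of class `z_map` with `values`, `grid`, `mask`,
#'   `threshold` (1.65) and the draw count.
#' @export
group_null_zmap <- function(observed, nulls, n_draws = 10000, seed = 1L,
                            null_stat = c("max", "voxel"),
                            z_method = c("rank", "meansd"),
                            e_param = 0.5, h_param = 2, dh = NULL,
                            connectivity = 6) {
  null_stat <- match.arg(null_stat)
  z_method <- match.arg(z_method)
  S <- length(observed)
  if (length(nulls) != S) stop("observed and nulls must have one entry per subject")
  mask <- observed[[1]]$mask
  nv <- length(mask$voxels)
  for (s in seq_len(S)) {
    if (!identical(observed[[s]]$mask$voxels, mask$voxels))
      stop("subject maps are not on the same mask")
    if (nrow(nulls[[s]]) != nv) stop("null maps do not match the mask")
  }
  chance <- observed[[1]]$chance

  obs_tfce <- vapply(observed, function(m)
    tfce_masked(m$values, mask, chance, e_param, h_param, dh, connectivity),
    numeric(nv))
  t_obs <- rowMeans(obs_tfce)

  null_tfce <- lapply(nulls, function(nm)
    vapply(seq_len(ncol(nm)), function(j)
      tfce_masked(nm[, j], mask, chance, e_param, h_param, dh, connectivity),
      numeric(nv)))

  with_seed(seed, {
    idx <- vapply(seq_len(S), function(s)
      sample.int(ncol(null_tfce[[s]]), n_draws, replace = TRUE),
      integer(n_draws))
    # chunked accumulation keeps memory bounded at ~voxels x 1000 doubles
    chunk <- 1000L
    max_null <- numeric(n_draws)
    count_ge <- numeric(nv)
    sum_null <- numeric(nv)
    sumsq_null <- numeric(nv)
    for (start in seq(1L, n_draws, by = chunk)) {
      dr <- start:min(start + chunk - 1L, n_draws)
      G <- matrix(0, nv, length(dr))
      for (s in seq_len(S)) G <- G + null_tfce[[s]][, idx[dr, s], drop = FALSE]
      G <- G / S
      max_null[dr] <- apply(G, 2, max)
      count_ge <- count_ge + rowSums(G >= t_obs - 1e-12)
      sum_null <- sum_null + rowSums(G)
      sumsq_null <- sumsq_null + rowSums(G^2)
    }
    # empirical p clamped to [1, n_draws]/(n_draws + 1) so z stays finite
    clamp_p <- function(count) pmin((1 + count) / (n_draws + 1),
                                    n_draws / (n_draws + 1))
    values <- if (null_stat == "max") {
      p <- clamp_p(vapply(t_obs, function(t) sum(max_null >= t - 1e-12),
                          numeric(1)))
      qnorm(1 - p)
    } else if (z_method == "rank") {
      qnorm(1 - clamp_p(count_ge))
    } else {
      mu <- sum_null / n_draws
      sdv <- sqrt(pmax(sumsq_null / n_draws - mu^2, 0))
      ifelse(sdv > 0, (t_obs - mu) / sdv, 0)
    }
    structure(list(values = values, grid = mask$grid, mask = mask,
                   threshold = 1.65, n_draws = n_draws,
                   null_stat = null_stat, z_method = z_method),
              class = "z_map")
  })
}

#' @export
print.z_map <- function(x, ...) {
  cat(sprintf("z_map: %d voxels, max z %.2f, %d flagged at z >= %.2f\n",
              length(x$values), max(x$values),
              sum(x$values >= x$threshold), x$threshold))
  invisible(x)
}

#' Threshold a z-map
#'
#' @param z a `z_map`.
#' @param cutoff threshold (default 1.65, one-tailed p < 0.05); boundary
#'   inclusive (a voxel at exactly the cutoff is flagged).
#' @return logical 3D array, `FALSE` outside the mask.
#' @export
threshold_zmap <- function(z, cutoff = 1.65) {
  if (any(!is.finite(z$values))) stop("z-map contains non-finite values")
  vol <- array(FALSE, z$grid$dims)
  vol[z$mask$voxels] <- z$values >= cutoff
  vol
}
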