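# Synthetic beta-pattern generator: spatially localized familiarity-shared,
# identity-specific and view-dependent components plus smooth Gaussian noise.

#' Planted signal specification
#'
#' Describes where and how strongly the three signal components are planted.
#' Each region entry activates components via multipliers; the global
#' amplitudes scale them. The familiarity component is one fixed spatial
#' pattern shared by all familiar identities; in the default `"signed"` mode
#' it enters with sign +1 for familiar and -1 for unfamiliar identities (and 0
#' for self), in `"familiar-only"` mode it is added for familiar identities
#' only. Identity components are unique per identity and constant across
#' runs; the view component depends on the head-view mixture shown in a run.
#'
#' @param familiarity_amp,identity_amp,view_amp component amplitudes in beta
#'   units (>= 0).
#' @param noise_sd standard deviation of the smooth additive noise (> 0).
#' @param smooth_fwhm_vox noise smoothing FWHM in voxel units (default 3, i.e.
#'   6 mm at 2 mm resolution).
#' @param familiarity_mode `"signed"` or `"familiar-only"`.
#' @param regions list of regions, each a list with `name`, `center` (1-based
#'   voxel triple), `radius_mm`, `system`, and multipliers `familiarity`,
#'   `identity`, `view`. `NULL` uses [default_signal_regions()].
#' @param seed integer; component patterns are drawn once per dataset from
#'   this seed, noise is redrawn per run.
#' @return object of class `signal_spec`.
#' @export
signal_spec <- function(familiarity_amp = 1, identity_amp = 1, view_amp = 0.5,
                        noise_sd = 1, smooth_fwhm_vox = 3,
                        familiarity_mode = c("signed", "familiar-only"),
                        regions = NULL, seed = 1L) {
  familiarity_mode <- match.arg(familiarity_mode)
  amps <- c(familiarity_amp, identity_amp, view_amp)
  if (any(!is.finite(amps)) || any(amps < 0)) stop("amplitudes must be finite and >= 0")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (smooth_fwhm_vox < 0) stop("smooth_fwhm_vox must be >= 0")
  structure(list(familiarity_amp = familiarity_amp, identity_amp = identity_amp,
                 view_amp = view_amp, noise_sd = noise_sd,
                 smooth_fwhm_vox = smooth_fwhm_vox,
                 familiarity_mode = familiarity_mode,
                 regions = regions, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Default planted regions for the desk-scale grid
#'
#' Four spherical regions emulating the functional organization the analyses
#' probe: an early-visual region carrying view and image-specific identity
#' signal, a ventral-core region carrying identity signal, an anterior-core
#' region carrying identity plus familiarity signal, and an extended-system
#' region carrying familiarity signal.
#'
#' @param grid a [volume_grid()]; defaults assume the 24 x 24 x 18 grid of
#'   [default_grid()].
#' @export
default_signal_regions <- function(grid = default_grid()) {
  scale_center <- function(frac) pmax(1L, as.integer(round(frac * grid$dims)))
  list(
    list(name = "EV", center = scale_center(c(0.5, 0.17, 0.33)), radius_mm = 6,
         system = "EV", familiarity = 0, identity = 1, view = 1),
    list(name = "core-ventral", center = scale_center(c(0.33, 0.42, 0.33)),
         radius_mm = 6, system = "core-ventral", familiarity = 0, identity = 1,
         view = 0.5),
    list(name = "core-anterior", center = scale_center(c(0.33, 0.67, 0.44)),
         radius_mm = 6, system = "core-anterior", familiarity = 1, identity = 1,
         view = 0),
    list(name = "extended", center = scale_center(c(0.67, 0.75, 0.67)),
         radius_mm = 6, system = "extended", familiarity = 1, identity = 0.5,
         view = 0))
}

#' Desk-scale default grid
#'
#' 24 x 24 x 18 voxels at nominal 2 mm isotropic resolution: large enough for
#' searchlight and ROI analyses with planted structure, small enough that the
#' full pipeline with permutations runs in minutes.
#' @export
default_grid <- function() volume_grid(c(24, 24, 18), c(2, 2, 2))

# Separable 3D Gaussian smoothing, kernel parameterized by FWHM in voxels.
# Truncated kernels are renormalized at the edges.
gaussian_smooth_3d <- function(arr, fwhm_vox) {
  if (fwhm_vox <= 0) return(arr)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  kernel_matrix <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    K
  }
  d <- dim(arr)
  K1 <- kernel_matrix(d[1]); K2 <- kernel_matrix(d[2]); K3 <- kernel_matrix(d[3])
  m <- K1 %*% matrix(arr, d[1], d[2] * d[3])                       # along x
  arr <- array(m, d)
  arr <- aperm(array(K2 %*% matrix(aperm(arr, c(2, 1, 3)), d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))             # along y
  aperm(array(K3 %*% matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2]),
              c(d[3], d[1], d[2])), c(2, 3, 1))                    # along z
}

# Resolve a signal region to in-mask masked-voxel positions (indices into
# mask$voxels). Errors on zero-voxel regions.
resolve_region <- function(region, mask) {
  grid <- mask$grid
  rv <- ceiling(region$radius_mm / min(grid$voxel_size))
  off <- sphere_offsets(rv)
  cand <- sweep(off, 2, as.integer(region$center), "+")
  dims <- grid$dims
  keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
          cand[, 2] >= 1 & cand[, 2] <= dims[2] &
          cand[, 3] >= 1 & cand[, 3] <= dims[3]
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[mask$included[cand], , drop = FALSE]
  if (nrow(cand) == 0)
    stop(sprintf("signal region '%s' contains no in-mask voxels", region$name))
  ctr <- voxel_to_world(grid, region$center)
  d_mm <- sqrt(rowSums((voxel_to_world(grid, cand) -
                          matrix(ctr, nrow(cand), 3, byrow = TRUE))^2))
  cand <- cand[d_mm <= region$radius_mm + 1e-9, , drop = FALSE]
  pos <- match(ijk_to_linear(dims, cand), mask$voxels)
  if (length(pos) == 0)
    stop(sprintf("signal region '%s' contains no in-mask voxels", region$name))
  pos
}

#' Container for run-wise condition beta patterns
#'
#' @param betas 3D array runs x conditions x voxels (masked voxels only).
#' @param runs integer run labels.
#' @param conditions data.frame with `condition`, `identity`, `familiarity`.
#' @param grid a [volume_grid()].
#' @param mask a [brain_mask()]; `dim(betas)[3]` must equal the number of
#'   included voxels.
#' @return object of class `beta_pattern_set`.
#' @export
beta_pattern_set <- function(betas, runs, conditions, grid, mask) {
  if (length(dim(betas)) != 3) stop("betas must be runs x conditions x voxels")
  if (dim(betas)[1] != length(runs)) stop("run labels do not match betas")
  if (dim(betas)[2] != nrow(conditions)) stop("condition table does not match betas")
  if (dim(betas)[3] != length(mask$voxels)) stop("voxel count does not match mask")
  if (anyDuplicated(conditions$condition) > 0) stop("condition labels must be unique")
  if (any(!is.finite(betas))) stop("betas contain non-finite values inside the mask")
  structure(list(betas = betas, runs = runs, conditions = conditions,
                 grid = grid, mask = mask),
            class = "beta_pattern_set")
}

#' @export
print.beta_pattern_set <- function(x, ...) {
  cat(sprintf("beta_pattern_set: %d runs x %d conditions x %d voxels\n",
              dim(x$betas)[1], dim(x$betas)[2], dim(x$betas)[3]))
  invisible(x)
}

#' Generate run-wise beta patterns with planted signal structure
#'
#' Beta for (run, identity, voxel) is the sum of the familiarity-shared
#' component (signed by familiarity class), the identity-specific component,
#' the view-dependent component weighted by the run's head-view mixture for
#' that identity, and smooth Gaussian noise. Component patterns are drawn once
#' per dataset from `signal$seed`; noise is redrawn for every run.
#'
#' @param design trial table from [generate_design()].
#' @param signal a [signal_spec()].
#' @param grid a [volume_grid()] (default [default_grid()]).
#' @param mask optional [brain_mask()]; default full grid.
#' @return a [beta_pattern_set()] with one condition per identity.
#' @export
generate_betas <- function(design, signal, grid = default_grid(), mask = NULL) {
  if (is.null(mask)) mask <- full_brain_mask(grid)
  regions <- signal$regions
  if (is.null(regions)) regions <- default_signal_regions(grid)
  spec <- attr(design, "design_spec")
  normal <- design[design$trial_type == "normal", ]
  ids <- unique(normal$identity)
  fam <- setNames(normal$familiarity[match(ids, normal$identity)], ids)
  runs <- sort(unique(design$run))
  nv <- length(mask$voxels)
  views <- if (!is.null(spec)) spec$views else c("front", "left30", "right30")

  with_seed(signal$seed, {
    region_pos <- lapply(regions, resolve_region, mask = mask)
    fam_pattern <- numeric(nv)
    id_patterns <- matrix(0, length(ids), nv, dimnames = list(ids, NULL))
    view_patterns <- matrix(0, length(views), nv, dimnames = list(views, NULL))
    for (k in seq_along(regions)) {
      reg <- regions[[k]]
      pos <- region_pos[[k]]
      if (reg$familiarity > 0)
        fam_pattern[pos] <- fam_pattern[pos] + reg$familiarity * rnorm(length(pos))
      if (reg$identity > 0)
        for (i in seq_along(ids))
          id_patterns[i, pos] <- id_patterns[i, pos] + reg$identity * rnorm(length(pos))
      if (reg$view > 0)
        for (v in seq_along(views))
          view_patterns[v, pos] <- view_patterns[v, pos] + reg$view * rnorm(length(pos))
    }
    fam_sign <- switch(signal$familiarity_mode,
      "signed" = c(familiar = 1, unfamiliar = -1, self = 0),
      "familiar-only" = c(familiar = 1, unfamiliar = 0, self = 0))

    betas <- array(0, c(length(runs), length(ids), nv))
    for (ri in seq_along(runs)) {
      rtr <- normal[normal$run == runs[ri], ]
      for (ii in seq_along(ids)) {
        # head-view mixture actually shown for this identity in this run
        vo <- rtr$view_order[rtr$identity == ids[ii]]
        shown <- unlist(strsplit(vo, "|", fixed = TRUE))
        mix <- as.numeric(table(factor(shown, levels = views)))
        mix <- if (sum(mix) > 0) mix / sum(mix) else rep(1 / length(views), length(views))
        mean_sig <- signal$familiarity_amp * fam_sign[[fam[[ids[ii]]]]] * fam_pattern +
          signal$identity_amp * id_patterns[ii, ] +
          signal$view_amp * as.numeric(mix %*% view_patterns)
        noise_vol <- array(rnorm(prod(grid$dims)), grid$dims)
        noise_vol <- gaussian_smooth_3d(noise_vol, signal$smooth_fwhm_vox)
        noise <- noise_vol[mask$voxels]
        emp_sd <- sd(noise)
        if (emp_sd > 0) noise <- noise / emp_sd # keep noise_sd interpretable
        betas[ri, ii, ] <- mean_sig + signal$noise_sd * noise
      }
    }
    conditions <- data.frame(condition = ids, identity = ids,
                             familiarity = unname(fam[ids]),
                             stringsAsFactors = FALSE)
    beta_pattern_set(betas, runs, conditions, grid, mask)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style parameterization: peak at ~5 s, undershoot at ~15 s with 1/6
#' relative amplitude, unit peak of the positive lobe.
#'
#' @param t time in seconds (>= 0).
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(stats::dgamma(seq(0, 30, 0.01), shape = 6, rate = 1))
}

# Condition regressors for one run: trial boxcars (3 x stim_duration) at
# onsets fixation + (trial - 1) * spacing, convolved with the HRF on a fine
# grid and sampled at TR. Returns timepoints x conditions matrix.
build_design_matrix <- function(design_run, conditions, n_timepoints, tr_s = 2,
                                hrf = canonical_hrf, trial_spacing_s = 6,
                                fixation_s = 10, trial_duration_s = 1.5) {
  dt <- 0.1
  total_s <- n_timepoints * tr_s
  fine_t <- seq(0, total_s - dt, by = dt)
  hrf_fine <- hrf(seq(0, 30, by = dt))
  X <- matrix(0, n_timepoints, length(conditions))
  for (ci in seq_along(conditions)) {
    rows <- design_run$trial_type == "normal" &
      !is.na(design_run$identity) & design_run$identity == conditions[ci]
    stim <- numeric(length(fine_t))
    for (tr in design_run$trial[rows]) {
      onset <- fixation_s + (tr - 1) * trial_spacing_s
      stim[fine_t >= onset & fine_t < onset + trial_duration_s] <- 1
    }
    conv <- stats::convolve(stim, rev(hrf_fine), type = "open")[seq_along(fine_t)] * dt
    X[, ci] <- conv[round(seq(0, n_timepoints - 1) * tr_s / dt) + 1]
  }
  colnames(X) <- conditions
  X
}

#' Generate BOLD-like time series from beta patterns
#'
#' Time series = condition regressors (trial boxcars convolved with the HRF)
#' times the condition betas, plus white noise. Round-trips through
#' [estimate_betas()] exactly when `noise_sd = 0`.
#'
#' @param design trial table from [generate_design()].
#' @param betas a [beta_pattern_set()].
#' @param tr_s repetition time in seconds (default 2).
#' @param noise_sd white-noise SD added to the series (default 0).
#' @param hrf hemodynamic response function of time in seconds.
#' @param fixation_s fixation before the first and after the last trial
#'   (default 10).
#' @param trial_spacing_s trial onset asynchrony in seconds (default 6, which
#'   with 48 trials and 2 x 10 s fixation gives 154 volumes at TR = 2 s).
#' @param seed optional seed for the noise.
#' @return list with `series` (runs x timepoints x voxels array) and the
#'   timing parameters used.
#' @export
generate_timeseries <- function(design, betas, tr_s = 2, noise_sd = 0,
                                hrf = canonical_hrf, fixation_s = 10,
                                trial_spacing_s = 6, seed = NULL) {
  if (tr_s <= 0) stop("TR must be positive")
  runs <- betas$runs
  n_trials <- max(design$trial)
  total_s <- 2 * fixation_s + n_trials * trial_spacing_s
  n_tp <- ceiling(total_s / tr_s)
  nv <- dim(betas$betas)[3]
  series <- array(0, c(length(runs), n_tp, nv))
  with_seed(seed, {
    for (ri in seq_along(runs)) {
      dr <- design[design$run == runs[ri], ]
      X <- build_design_matrix(dr, betas$conditions$condition, n_tp, tr_s, hrf,
                               trial_spacing_s, fixation_s)
      series[ri, , ] <- X %*% betas$betas[ri, , ]
      if (noise_sd > 0)
        series[ri, , ] <- series[ri, , ] + rnorm(n_tp * nv, sd = noise_sd)
    }
  })
  list(series = series, tr_s = tr_s, fixation_s = fixation_s,
       trial_spacing_s = trial_spacing_s)
}

#' Write per-run beta volumes as NIfTI plus a conditions sidecar table
#'
#' One 4D NIfTI per run (conditions along the 4th axis), a mask volume and a
#' TSV of condition labels.
#' @param betas a [beta_pattern_set()].
#' @param dir output directory (created if needed).
#' @export
write_betas_dir <- function(betas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- betas$grid$dims
  for (ri in seq_along(betas$runs)) {
    vol <- array(0, c(dims, nrow(betas$conditions)))
    for (ci in seq_len(nrow(betas$conditions))) {
      v3 <- array(0, dims)
      v3[betas$mask$voxels] <- betas$betas[ri, ci, ]
      vol[, , , ci] <- v3
    }
    write_nifti(vol, betas$grid,
                file.path(dir, sprintf("betas_run%02d.nii.gz", betas$runs[ri])))
  }
  write_mask_nifti(betas$mask, file.path(dir, "mask.nii.gz"))
  write.table(betas$conditions, file.path(dir, "conditions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a beta directory written by [write_betas_dir()]
#' @param dir directory path.
#' @return a [beta_pattern_set()].
#' @export
read_betas_dir <- function(dir) {
  mask <- read_mask_nifti(file.path(dir, "mask.nii.gz"))
  conditions <- read.table(file.path(dir, "conditions.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "^betas_run[0-9]+\\.nii\\.gz$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no beta volumes found in ", dir)
  runs <- as.integer(sub(".*betas_run([0-9]+).*", "\\1", files))
  betas <- array(0, c(length(files), nrow(conditions), length(mask$voxels)))
  for (ri in seq_along(files)) {
    vol <- read_nifti(files[ri])$data
    for (ci in seq_len(nrow(conditions)))
      betas[ri, ci, ] <- vol[, , , ci][mask$voxels]
  }
  beta_pattern_set(betas, runs, conditions, mask$grid, mask)
}
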