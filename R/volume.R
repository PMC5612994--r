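#' Volumetric grid
#'
#' A 3D voxel grid with a voxel-to-world affine. Voxel indices are 1-based in
#' the R API; the affine follows the NIfTI convention and maps 0-based indices
#' to world mm coordinates ([voxel_to_world()] handles the shift).
#'
#' @param dims integer vector of 3 positive grid dimensions (voxels).
#' @param voxel_size numeric vector of 3 positive voxel edge lengths (mm).
#'   Default 2 mm isotropic, the template resolution the analyses assume.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(2, 2, 2), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1))
    stop("dims must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive reals")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
    if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  }
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Map 1-based voxel indices to world mm coordinates
#'
#' @param grid a [volume_grid()].
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  v0 <- cbind(ijk - 1, 1) # affine acts on 0-based indices
  w <- v0 %*% t(grid$affine)
  w[, 1:3, drop = FALSE]
}

#' Brain mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param included logical array with `grid$dims` dimensions (or a vector of
#'   matching length). Must include at least one voxel.
#' @return object of class `brain_mask` with fields `grid`, `included`
#'   (logical 3D array) and `voxels` (linear indices of included voxels).
#' @export
brain_mask <- function(grid, included) {
  if (!inherits(grid, "volume_grid")) stop("grid must be a volume_grid")
  included <- array(as.logical(included), dim = grid$dims)
  if (any(is.na(included))) stop("mask must not contain NA")
  if (!any(included)) stop("mask must include at least one voxel")
  structure(list(grid = grid, included = included, voxels = which(included)),
            class = "brain_mask")
}

#' Mask covering the whole grid
#' @param grid a [volume_grid()].
#' @export
full_brain_mask <- function(grid) brain_mask(grid, array(TRUE, grid$dims))

n_voxels <- function(mask) length(mask$voxels)

# linear index <-> ijk helpers (1-based)
ijk_to_linear <- function(dims, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
}

linear_to_ijk <- function(dims, idx) {
  idx0 <- idx - 1
  k <- idx0 %/% (dims[1] * dims[2])
  rem <- idx0 %% (dims[1] * dims[2])
  cbind(rem %% dims[1] + 1, rem %/% dims[1] + 1, k + 1)
}

#' Integer lattice offsets within a Euclidean radius
#'
#' @param radius_vox non-negative radius in voxel units; boundary inclusive.
#' @return m x 3 integer matrix of offsets with `sum(offset^2) <= radius^2`,
#'   always containing `c(0, 0, 0)`.
#' @export
sphere_offsets <- function(radius_vox) {
  if (!is.finite(radius_vox) || radius_vox < 0) stop("radius_vox must be >= 0")
  r <- floor(radius_vox)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g <- g[rowSums(g^2) <= radius_vox^2 + 1e-9, , drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Searchlight sphere neighborhood
#'
#' All in-mask voxels whose integer-offset Euclidean distance (in voxel units)
#' from the center is at most `radius_vox`. The center is always a member.
#'
#' @param mask a [brain_mask()].
#' @param center 1-based voxel index triple; must be inside the mask.
#' @param radius_vox non-negative radius in voxel units (the canonical
#'   searchlight uses 5 voxels = 10 mm at 2 mm resolution).
#' @return n x 3 integer matrix of in-mask voxel indices.
#' @export
sphere_neighborhood <- function(mask, center, radius_vox) {
  center <- as.integer(center)
  dims <- mask$grid$dims
  if (length(center) != 3 || any(center < 1) || any(center > dims))
    stop("center outside grid: invalid searchlight seed")
  if (!mask$included[center[1], center[2], center[3]])
    stop("center outside mask: invalid searchlight seed")
  off <- sphere_offsets(radius_vox)
  cand <- sweep(off, 2, center, "+")
  keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
          cand[, 2] >= 1 & cand[, 2] <= dims[2] &
          cand[, 3] >= 1 & cand[, 3] <= dims[3]
  cand <- cand[keep, , drop = FALSE]
  cand[mask$included[cand], , drop = FALSE]
}

#' Combine subject masks by coverage count
#'
#' A voxel is included iff it is included in at least `min_count` of the input
#' masks (the group searchlight convention: keep voxels where ~80% of subjects
#' have coverage).
#'
#' @param masks list of [brain_mask()] objects on one common grid.
#' @param min_count positive integer threshold.
#' @return a [brain_mask()].
#' @export
build_union_mask <- function(masks, min_count) {
  if (length(masks) == 0) stop("empty mask list")
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1) stop("min_count must be a positive integer")
  g <- masks[[1]]$grid
  for (m in masks) {
    if (!inherits(m, "brain_mask")) stop("all elements must be brain_mask objects")
    if (!isTRUE(all.equal(m$grid$dims, g$dims)) ||
        !isTRUE(all.equal(m$grid$affine, g$affine)))
      stop("masks are not on the same grid")
  }
  counts <- Reduce(`+`, lapply(masks, function(m) m$included * 1L))
  brain_mask(g, counts >= min_count)
}

#' Spherical region-of-interest specification
#'
#' @param name short region label.
#' @param center 1-based voxel index triple of the sphere center.
#' @param radius_mm positive radius in mm (10 mm in the canonical ROI set).
#' @param system one of `"EV"`, `"core-ventral"`, `"core-dorsal"`,
#'   `"core-anterior"`, `"extended"`.
#' @return object of class `roi_spec`; `voxels` is filled in by
#'   [resolve_roi_overlaps()].
#' @export
roi_spec <- function(name, center, radius_mm, system) {
  systems <- c("EV", "core-ventral", "core-dorsal", "core-anterior", "extended")
  system <- match.arg(system, systems)
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("radius_mm must be positive")
  structure(list(name = as.character(name), center = as.integer(center),
                 radius_mm = as.numeric(radius_mm), system = system,
                 voxels = NULL),
            class = "roi_spec")
}

#' Resolve ROI spheres against a mask and reassign overlapping voxels
#'
#' Each ROI is the set of in-mask voxels whose world-coordinate (mm) distance
#' from the ROI center is at most `radius_mm`. Voxels claimed by more than one
#' ROI go to the ROI with the nearest center in mm; exact ties go to the ROI
#' earlier in the input list (deterministic). The union of resolved ROIs
#' equals the union of the raw spheres.
#'
#' @param rois list of [roi_spec()] objects with distinct centers.
#' @param mask a [brain_mask()]; centers must be inside it.
#' @return the input list with `voxels` (n x 3 index matrix) filled in.
#' @export
resolve_roi_overlaps <- function(rois, mask) {
  if (length(rois) == 0) stop("empty ROI list")
  centers <- t(vapply(rois, function(r) r$center, integer(3)))
  if (anyDuplicated(centers) > 0) stop("ROI centers must be distinct")
  grid <- mask$grid
  centers_mm <- voxel_to_world(grid, centers)
  dims <- grid$dims
  claims <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (any(r$center < 1) || any(r$center > dims) ||
        !mask$included[r$center[1], r$center[2], r$center[3]])
      stop(sprintf("ROI '%s' center is outside the mask", r$name))
    rv <- ceiling(r$radius_mm / min(grid$voxel_size))
    off <- sphere_offsets(rv)
    cand <- sweep(off, 2, r$center, "+")
    keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
            cand[, 2] >= 1 & cand[, 2] <= dims[2] &
            cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[mask$included[cand], , drop = FALSE]
    d_mm <- sqrt(rowSums((voxel_to_world(grid, cand) -
                            matrix(centers_mm[i, ], nrow(cand), 3, byrow = TRUE))^2))
    claims[[i]] <- cand[d_mm <= r$radius_mm + 1e-9, , drop = FALSE]
  }
  # assign every claimed voxel to the nearest center (ties: earlier ROI)
  all_lin <- unlist(lapply(claims, function(v) ijk_to_linear(dims, v)))
  owner <- integer(0)
  if (length(all_lin) > 0) {
    uniq <- sort(unique(all_lin))
    best_d <- rep(Inf, length(uniq))
    best_i <- rep(NA_integer_, length(uniq))
    for (i in seq_along(rois)) {
      lin_i <- ijk_to_linear(dims, claims[[i]])
      pos <- match(lin_i, uniq)
      d_mm <- sqrt(rowSums((voxel_to_world(grid, claims[[i]]) -
                              matrix(centers_mm[i, ], nrow(claims[[i]]), 3, byrow = TRUE))^2))
      better <- d_mm < best_d[pos] - 1e-9
      best_d[pos[better]] <- d_mm[better]
      best_i[pos[better]] <- i
    }
    owner <- best_i
    for (i in seq_along(rois)) {
      mine <- uniq[owner == i]
      rois[[i]]$voxels <- linear_to_ijk(dims, mine)
      if (nrow(rois[[i]]$voxels) == 0)
        stop(sprintf("ROI '%s' is empty after overlap reassignment", rois[[i]]$name))
    }
  }
  rois
}

#' Write an ROI set as a plain-text table
#'
#' Columns: name, x, y, z (1-based voxel indices), radius_mm, system.
#' @param rois list of [roi_spec()] objects.
#' @param path output TSV path.
#' @export
write_roi_table <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(name = r$name, x = r$center[1], y = r$center[2], z = r$center[3],
               radius_mm = r$radius_mm, system = r$system)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI set written by [write_roi_table()]
#' @param path TSV path.
#' @return list of [roi_spec()] objects (voxels unresolved).
#' @export
read_roi_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    roi_spec(df$name[i], c(df$x[i], df$y[i], df$z[i]), df$radius_mm[i], df$system[i]))
}
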