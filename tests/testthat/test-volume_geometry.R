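# Masks, sphere neighborhoods, ROI overlap resolution, ROI tables.

test_that("sphere_neighborhood matches the lattice enumeration oracle", {
  mask <- full_brain_mask(volume_grid(c(15, 15, 15)))

  # brute-force oracle: integer offsets with x^2 + y^2 + z^2 <= r^2
  oracle_size <- function(r) {
    g <- expand.grid(-5:5, -5:5, -5:5)
    sum(rowSums(g^2) <= r^2)
  }
  nb <- sphere_neighborhood(mask, c(8, 8, 8), 5)
  expect_equal(nrow(nb), oracle_size(5))
  expect_equal(nrow(nb), 515)

  # degenerate radius: the center alone
  nb0 <- sphere_neighborhood(mask, c(8, 8, 8), 0)
  expect_equal(nrow(nb0), 1)
  expect_equal(as.integer(nb0[1, ]), c(8, 8, 8))

  # corner center: strict in-mask subset of the full sphere
  nbc <- sphere_neighborhood(mask, c(1, 1, 1), 5)
  expect_lt(nrow(nbc), 515)
  expect_true(all(nbc >= 1 & nbc <= 15))

  # monotone in radius
  sizes <- vapply(c(0, 1, 2, 3, 4, 5), function(r)
    nrow(sphere_neighborhood(mask, c(8, 8, 8), r)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(sphere_neighborhood(mask, c(8, 8, 8), 3)) %in%
                    key(sphere_neighborhood(mask, c(8, 8, 8), 5))))

  expect_error(sphere_neighborhood(mask, c(20, 8, 8), 2), "invalid searchlight")
  partial <- brain_mask(mask$grid, {
    a <- array(TRUE, c(15, 15, 15)); a[8, 8, 8] <- FALSE; a
  })
  expect_error(sphere_neighborhood(partial, c(8, 8, 8), 2), "outside mask")
})

test_that("build_union_mask thresholds coverage counts", {
  g <- tiny_grid(c(6, 6, 4))
  full <- full_brain_mask(g)
  expect_equal(build_union_mask(rep(list(full), 33), 26)$included, full$included)

  set.seed(7)
  masks <- lapply(1:5, function(i) brain_mask(g, array(runif(144) > 0.4, g$dims)))
  # per-voxel counting oracle
  counts <- array(0L, g$dims)
  for (m in masks) counts <- counts + m$included
  for (mc in c(1L, 3L, 5L)) {
    got <- build_union_mask(masks, mc)
    expect_equal(got$included, counts >= mc)
  }
  # min_count 1 is the union, min_count n the intersection
  expect_equal(build_union_mask(masks, 1)$included,
               Reduce(`|`, lapply(masks, `[[`, "included")))
  expect_equal(build_union_mask(masks, 5)$included,
               Reduce(`&`, lapply(masks, `[[`, "included")))

  expect_error(build_union_mask(list(), 1), "empty")
  g2 <- volume_grid(c(5, 5, 5))
  expect_error(build_union_mask(list(full, full_brain_mask(g2)), 1),
               "same grid")
})

test_that("resolve_roi_overlaps reassigns shared voxels to the nearest center", {
  g <- volume_grid(c(20, 10, 10))
  mask <- full_brain_mask(g)

  # non-overlapping spheres are unchanged by resolution
  far <- resolve_roi_overlaps(list(
    roi_spec("a", c(4, 5, 5), 4, "EV"),
    roi_spec("b", c(16, 5, 5), 4, "extended")), mask)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_length(intersect(key(far[[1]]$voxels), key(far[[2]]$voxels)), 0)
  # each voxel within its own radius
  d_a <- sqrt(rowSums((voxel_to_world(g, far[[1]]$voxels) -
    matrix(voxel_to_world(g, c(4, 5, 5)), nrow(far[[1]]$voxels), 3, TRUE))^2))
  expect_true(all(d_a <= 4 + 1e-9))

  # overlapping spheres: a shared voxel goes to the nearer center
  rois <- resolve_roi_overlaps(list(
    roi_spec("a", c(8, 5, 5), 8, "EV"),
    roi_spec("b", c(12, 5, 5), 8, "extended")), mask)
  expect_true("9 5 5" %in% key(rois[[1]]$voxels))   # closer to a
  expect_true("11 5 5" %in% key(rois[[2]]$voxels))  # closer to b
  # exact midpoint (distance tie) goes to the earlier ROI in the list
  expect_true("10 5 5" %in% key(rois[[1]]$voxels))
  expect_false("10 5 5" %in% key(rois[[2]]$voxels))

  # set-algebra oracle on random configurations: union conserved, disjoint
  set.seed(42)
  g3 <- volume_grid(c(14, 14, 12))
  mask3 <- full_brain_mask(g3)
  centers <- unique(cbind(sample(3:12, 8, TRUE), sample(3:12, 8, TRUE),
                          sample(3:10, 8, TRUE)))
  raw <- lapply(seq_len(nrow(centers)), function(i)
    roi_spec(paste0("r", i), centers[i, ], 5, "extended"))
  res <- resolve_roi_overlaps(raw, mask3)
  raw_union <- unique(unlist(lapply(seq_len(nrow(centers)), function(i)
    key(sphere_neighborhood(mask3, centers[i, ], 5 / 2)))))
  res_keys <- lapply(res, function(r) key(r$voxels))
  expect_setequal(unlist(res_keys), raw_union)
  for (i in seq_along(res_keys))
    for (j in seq_along(res_keys))
      if (i < j) expect_length(intersect(res_keys[[i]], res_keys[[j]]), 0)

  expect_error(resolve_roi_overlaps(list(
    roi_spec("a", c(5, 5, 5), 4, "EV"),
    roi_spec("b", c(5, 5, 5), 4, "EV")), mask), "distinct")
})

test_that("ROI tables round-trip through TSV", {
  rois <- list(roi_spec("ofa", c(3, 4, 5), 10, "core-ventral"),
               roi_spec("mpfc", c(6, 7, 8), 10, "extended"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_table(rois, path)
  back <- read_roi_table(path)
  expect_equal(back[[1]]$name, "ofa")
  expect_equal(back[[2]]$center, c(6L, 7L, 8L))
  expect_equal(back[[1]]$system, "core-ventral")
  expect_equal(back[[2]]$radius_mm, 10)
})

test_that("voxel/world conversions follow the affine", {
  g <- volume_grid(c(10, 10, 10), c(2, 2, 3))
  expect_equal(as.numeric(voxel_to_world(g, c(1, 1, 1))), c(0, 0, 0))
  expect_equal(as.numeric(voxel_to_world(g, c(3, 2, 2))), c(4, 2, 3))
  expect_error(volume_grid(c(0, 5, 5)), "positive")
  expect_error(volume_grid(c(5, 5, 5), c(2, 0, 2)), "positive")
  expect_error(volume_grid(c(5, 5, 5), affine = matrix(0, 4, 4)), "invertible")
})
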