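test_that("threshold segmentation windows correctly, sphere count matches brute force", {
  # 300-HU sphere in a -50-HU background
  g <- identity_geometry(c(30, 30, 30), origin = c(-14.5, -14.5, -14.5))
  vol_arr <- array(-50, g$shape)
  ctr <- c(2, -3, 1); rad <- 6
  brute <- 0L
  for (k in 1:30) for (i in 1:30) for (j in 1:30) {
    p <- c(j - 15.5, i - 15.5, k - 15.5)
    if (sum((p - ctr)^2) <= rad^2) {
      vol_arr[k, i, j] <- 300
      brute <- brute + 1L
    }
  }
  vol <- ct_volume(vol_arr, g)
  mask <- threshold_segment(vol, 200, 400)
  expect_equal(sum(mask$mask), brute)
  expect_true(all(threshold_segment(vol, -100, 500)$mask))
  expect_false(any(threshold_segment(vol, -3000, -2000)$mask))
  expect_error(threshold_segment(vol, 10, -10), "low_hu")
})

test_that("margin dilation of a single voxel matches lattice enumeration", {
  g <- identity_geometry(c(25, 25, 25))
  m <- array(FALSE, g$shape); m[13, 13, 13] <- TRUE
  mask <- segmentation_mask(m, g, "seed")
  out <- augment_margin(mask, 10)
  # independent oracle: integer lattice points within Euclidean distance 10
  lattice <- expand.grid(-10:10, -10:10, -10:10)
  oracle <- sum(rowSums(lattice^2) <= 100)
  expect_equal(sum(out$mask), oracle)
  # margin 0 is the identity
  expect_identical(augment_margin(mask, 0)$mask, mask$mask)
})

test_that("anisotropic dilation respects physical, not voxel, distances", {
  g <- identity_geometry(c(25, 25, 25), spacing = c(1, 1, 2))
  m <- array(FALSE, g$shape); m[13, 13, 13] <- TRUE
  out <- augment_margin(segmentation_mask(m, g, "seed"), 10)
  ks <- which(apply(out$mask, 1, any))
  # 10 mm at 2 mm slice pitch: 5 slices either side
  expect_equal(range(ks), c(13 - 5, 13 + 5))
  is <- which(apply(out$mask, 2, any))
  expect_equal(range(is), c(13 - 10, 13 + 10))
  # distance-transform oracle on the physical grid
  d <- distance_map(segmentation_mask(m, g, "seed"))
  expect_identical(out$mask, d <= 10 + 1e-9)
})

test_that("distance map agrees with brute force on a random small mask", {
  g <- identity_geometry(c(8, 9, 10), spacing = c(0.8, 1.2, 1.7))
  m <- with_test_seed(31, array(runif(prod(g$shape)) < 0.05, g$shape))
  m[2, 3, 4] <- TRUE  # guarantee non-empty
  d <- distance_map(segmentation_mask(m, g, "mask"))
  seeds <- which(m, arr.ind = TRUE)
  sp <- g$spacing[c(3, 1, 2)]  # mm per array dim (k, i, j)
  for (probe in list(c(1, 1, 1), c(8, 9, 10), c(4, 5, 6), c(7, 2, 9))) {
    brute <- min(sqrt(colSums((t(sweep(seeds, 2, probe)) * sp)^2)))
    expect_equal(d[probe[1], probe[2], probe[3]], brute, tolerance = 1e-9)
  }
})

test_that("dilation is monotone and satisfies the triangle containment", {
  g <- identity_geometry(c(20, 20, 20))
  with_test_seed(32, {
    for (rep in 1:3) {
      m <- array(runif(8000) < 0.01, g$shape)
      if (!any(m)) m[10, 10, 10] <- TRUE
      mask <- segmentation_mask(m, g, "rand")
      a <- augment_margin(mask, 3); ab <- augment_margin(a, 4)
      big <- augment_margin(mask, 7)
      expect_true(all(mask$mask <= a$mask))       # input subset of output
      expect_true(all(a$mask <= big$mask))        # larger margin is a superset
      expect_true(all(ab$mask <= big$mask))       # dilate(m,a+b) contains twice-dilated
    }
  })
})

test_that("surface clearance of an augmented sphere is at least margin minus a voxel diagonal", {
  g <- identity_geometry(c(48, 48, 48), origin = c(-23.5, -23.5, -23.5))
  d0 <- distance_map(segmentation_mask(
    array(replace(logical(prod(g$shape)), 48 * 48 * 23 + 48 * 23 + 24, TRUE),
          g$shape), g, "center"))
  sphere <- segmentation_mask(d0 <= 5, g, "tumor")
  out <- augment_margin(sphere, 10)
  clear <- surface_clearance(sphere, out)
  expect_gte(clear, 10 - sqrt(3))
  expect_gt(clear, 10)  # dilation by definition clears the full margin
})

test_that("box-method dilation is the per-axis Chebyshev margin", {
  g <- identity_geometry(c(25, 25, 25))
  m <- array(FALSE, g$shape); m[13, 13, 13] <- TRUE
  out <- augment_margin(segmentation_mask(m, g, "seed"), 10, method = "box")
  expect_equal(sum(out$mask), 21^3)  # full 21-voxel cube
})

test_that("mirroring reflects the centroid and is an involution on aligned planes", {
  g <- identity_geometry(c(24, 32, 32), origin = c(-15.5, -15.5, -11.5))
  d0 <- distance_map(segmentation_mask(
    array(replace(logical(prod(g$shape)), 24 * (32 * 9 + 15) + 12, TRUE),
          g$shape), g, "x"))
  sphere <- segmentation_mask(d0 <= 4, g, "lesion")
  mirrored <- mirror_mask(sphere, plane_x_mm = 0)  # grid-aligned plane
  expect_equal(sum(mirrored$mask), sum(sphere$mask))
  # centroid reflected across x = 0.5 within one voxel
  centroid <- function(msk) {
    idx <- which(msk$mask, arr.ind = TRUE)
    colMeans(voxel_to_patient(msk$geometry, idx))
  }
  c0 <- centroid(sphere); c1 <- centroid(mirrored)
  expect_equal(c1[1], -c0[1], tolerance = 1)
  expect_equal(c1[2:3], c0[2:3], tolerance = 1)
  # double mirroring restores the original exactly
  back <- mirror_mask(mirrored, plane_x_mm = 0)
  expect_identical(back$mask, sphere$mask)
  # a symmetric mask is a fixed point
  sym <- segmentation_mask(array(TRUE, g$shape), g, "all")
  expect_identical(mirror_mask(sym, 0)$mask, sym$mask)
})

test_that("partly clipped reflections warn with the clipped count", {
  g <- identity_geometry(c(10, 10, 10))
  m <- array(FALSE, g$shape); m[5, 5, 2] <- TRUE
  expect_warning(out <- mirror_mask(segmentation_mask(m, g, "edge"),
                                    plane_x_mm = 9),
                 "outside the grid")
  expect_equal(sum(out$mask), 0)
})

test_that("mask files round trip with their geometry", {
  g <- identity_geometry(c(6, 7, 8), spacing = c(0.5, 1, 2), origin = c(1, 2, 3))
  m <- with_test_seed(33, array(runif(336) < 0.3, g$shape))
  mask <- segmentation_mask(m, g, "roi")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mask(mask, path)
  back <- read_mask(path)
  expect_identical(back$mask, mask$mask)
  expect_true(endicom:::geometry_equal(back$geometry, g))
  expect_equal(back$label, "roi")
})
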