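test_that("self-registration gives identity with zero residual", {
  p <- tetra_fiducials()
  tr <- estimate_rigid(fiducial_set(letters[1:4], p, p))
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tr$rms_error, 0, tolerance = 1e-12)
})

test_that("a known transform is recovered exactly from noise-free pairs", {
  p <- rbind(c(0, 0, 0), c(80, 0, 0), c(0, 90, 0), c(10, 20, 70))
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 deg about z
  q <- p %*% t(Rz) + matrix(c(10, 0, 0), 4, 3, byrow = TRUE)
  tr <- estimate_rigid(fiducial_set(letters[1:4], p, q))
  expect_lt(max(abs(apply_transform(tr, p) - q)), 1e-9)
  expect_lt(tr$rms_error, 1e-9)
  expect_equal(tr$rotation, Rz, tolerance = 1e-9)
})

test_that("noise-free random configurations always recover the generator", {
  with_test_seed(101, {
    for (rep in 1:200) {
      tr_true <- random_rigid_transform()
      p <- matrix(runif(12, -60, 60), 4, 3)
      q <- apply_transform(tr_true, p)
      tr <- estimate_rigid(fiducial_set(letters[1:4], p, q))
      expect_lt(max(abs(tr$rotation - tr_true$rotation)), 1e-8)
      expect_lt(max(abs(tr$translation - tr_true$translation)), 1e-8)
      expect_lt(tr$rms_error, 1e-9)
    }
  })
})

test_that("RMS matches the brute-force residual oracle to 1e-12", {
  with_test_seed(202, {
    for (rep in 1:100) {
      p <- matrix(runif(12, -60, 60), 4, 3)
      q <- apply_transform(random_rigid_transform(), p) +
        matrix(rnorm(12, sd = 0.3), 4, 3)
      fids <- fiducial_set(letters[1:4], p, q)
      tr <- estimate_rigid(fids)
      expect_equal(tr$rms_error, brute_force_rms(tr, p, q), tolerance = 1e-12)
    }
  })
})

test_that("estimate is equivariant and invariant to pair order", {
  with_test_seed(303, {
    p <- matrix(runif(12, -60, 60), 4, 3)
    q <- apply_transform(random_rigid_transform(), p) +
      matrix(rnorm(12, sd = 0.2), 4, 3)
    tr <- estimate_rigid(fiducial_set(letters[1:4], p, q))
    # pre-rotating the physical points changes the estimate by composition
    pre <- random_rigid_transform()
    p2 <- apply_transform(pre, p)
    tr2 <- estimate_rigid(fiducial_set(letters[1:4], p2, q))
    composed <- compose_transforms(tr, invert_transform(pre))
    expect_equal(tr2$rotation, composed$rotation, tolerance = 1e-9)
    expect_equal(tr2$translation, composed$translation, tolerance = 1e-9)
    expect_equal(tr2$rms_error, tr$rms_error, tolerance = 1e-9)
    # permutation of the pairs leaves the estimate unchanged
    perm <- c(3, 1, 4, 2)
    tr3 <- estimate_rigid(fiducial_set(letters[perm], p[perm, ], q[perm, ]))
    expect_equal(tr3$rotation, tr$rotation, tolerance = 1e-12)
    expect_equal(tr3$translation, tr$translation, tolerance = 1e-12)
  })
})

test_that("transform algebra: apply, invert, compose", {
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tr <- rigid_transform(Rz, c(0, 0, 0))
  expect_equal(apply_transform(tr, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  tr2 <- with_test_seed(9, random_rigid_transform())
  p <- c(3, -4, 5)
  expect_equal(apply_transform(invert_transform(tr2), apply_transform(tr2, p)),
               p, tolerance = 1e-9)
  dbl <- invert_transform(invert_transform(tr2))
  expect_equal(dbl$rotation, tr2$rotation, tolerance = 1e-12)
  expect_equal(dbl$translation, tr2$translation, tolerance = 1e-12)
  ident <- compose_transforms(tr2, invert_transform(tr2))
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("degenerate fiducial configurations are rejected", {
  line <- cbind(seq(0, 30, 10), 0, 0)
  expect_error(estimate_rigid(fiducial_set(letters[1:4], line, line + 1)),
               "collinear")
  p <- tetra_fiducials()
  expect_error(fiducial_set(letters[1:2], p[1:2, ], p[1:2, ]), "at least 3")
  dup <- p; dup[2, ] <- dup[1, ] + 1e-9
  expect_error(fiducial_set(letters[1:4], p, dup), "duplicate")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
})

test_that("the RMS gate passes and fails at the 0.8 mm policy threshold", {
  mk <- function(rms) structure(list(rotation = diag(3),
                                     translation = c(0, 0, 0),
                                     rms_error = rms),
                                class = "rigid_transform")
  expect_true(registration_gate(mk(0))$pass)
  expect_true(registration_gate(mk(0.79))$pass)
  expect_false(registration_gate(mk(0.81))$pass)
  # the paper-scale clinical deviation of 1.3 mm fails the planning gate
  expect_false(registration_gate(mk(1.3))$pass)
  expect_error(registration_gate(mk(0.1), threshold_mm = 0), "> 0")
})

test_that("fiducial table round trip through CSV is lossless", {
  p <- tetra_fiducials()
  q <- p + matrix(rnorm(12, sd = 0.1), 4, 3)
  fids <- fiducial_set(c("s1", "s2", "s3", "s4"), p, q)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fiducials(fids, path)
  back <- read_fiducials(path)
  expect_equal(back$labels, fids$labels)
  expect_equal(back$physical, fids$physical, tolerance = 1e-9)
  expect_equal(back$image, fids$image, tolerance = 1e-9)
  # whitespace-delimited input is accepted too
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("label phys_x phys_y phys_z img_x img_y img_z",
               "a 0 0 0 1 0 0", "b 10 0 0 11 0 0",
               "c 0 10 0 1 10 0", "d 0 0 10 1 0 10"), path2)
  f2 <- read_fiducials(path2)
  expect_equal(estimate_rigid(f2)$translation, c(1, 0, 0), tolerance = 1e-9)
})
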