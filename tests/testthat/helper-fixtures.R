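# Shared fixtures and independent oracles. Everything is generated in code;
# the default phantom is built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixture_cache$ph)) .fixture_cache$ph <- make_phantom()
  .fixture_cache$ph
}

small_phantom <- function(...) {
  make_phantom(phantom_spec(shape = c(24, 32, 32), ...))
}

# a deliberately oblique but orthogonal geometry built from a seeded rotation
oblique_geometry <- function(seed = 42, shape = c(7, 9, 11),
                             spacing = c(0.7, 1.1, 2.3),
                             origin = c(-12, 4, 7)) {
  R <- with_test_seed(seed, random_rigid_transform()$rotation)
  volume_geometry(origin,
                  dir_row = R[, 1], dir_col = R[, 2], dir_slice = R[, 3],
                  spacing = spacing, shape = shape)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force residual of a rigid fit: the oracle for estimate_rigid's RMS
brute_force_rms <- function(transform, physical, image) {
  n <- nrow(physical)
  total <- 0
  for (i in seq_len(n)) {
    mapped <- drop(transform$rotation %*% physical[i, ]) + transform$translation
    total <- total + sum((image[i, ] - mapped)^2)
  }
  sqrt(total / n)
}

# regular tetrahedral fiducial cage with the given edge length in mm
# (~100 mm: the span of four screw markers around a head)
tetra_fiducials <- function(edge = 100) {
  edge / (2 * sqrt(2)) *
    rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

# cloud of n image-frame points at given positions, all malignant
malignant_cloud <- function(positions) {
  positions <- matrix(positions, ncol = 3)
  df <- data.frame(sequence = seq_len(nrow(positions)), name = "pt",
                   x = positions[, 1], y = positions[, 2], z = positions[, 3],
                   histology = "malignant", stringsAsFactors = FALSE)
  endicom:::as_point_cloud(df, "image")
}
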