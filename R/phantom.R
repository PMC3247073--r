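#' Specification of a synthetic head CT phantom
#'
#' Describes a deterministic head-like CT test volume: an ellipsoidal head
#' with a cortical bone shell, one or more soft-tissue tumor spheres, and
#' four bright fiducial blobs standing in for the titanium miniscrew / dental
#' splint markers used for navigation registration. All intensities stay at
#' or below `native_max_hu` (default 3071 HU, the ceiling of a conventional
#' 12-bit CT encoding), which is the premise that makes 3500 HU sentinel
#' marks separable by thresholding.
#'
#' @param shape integer (slices, rows, columns); default `c(64, 128, 128)`
#'   — seconds-scale to generate and large enough to hold a head-like
#'   geometry at 1 mm.
#' @param spacing mm (row, column, slice); default 1 mm isotropic.
#' @param background_hu,soft_tissue_hu,bone_hu tissue intensities; defaults
#'   -1000 (air), 40 (brain/soft tissue), 1200 (cortical bone).
#' @param native_max_hu hard ceiling all phantom intensities must respect;
#'   default 3071.
#' @param head_axes_mm ellipsoid semi-axes (x, y, z) of the head; defaults
#'   to 90% of the half-extent of the volume along each axis.
#' @param tumors list of tumor spheres, each
#'   `list(center = c(x, y, z) mm, radius = mm, hu = value)`; the default is
#'   a single 8 mm, 120 HU sphere off-center in the head.
#' @param fiducial_hu intensity of the marker blobs; default 3000 (metal-like
#'   yet below the native ceiling).
#' @param fiducial_radius_mm blob radius; default 2 (a 2.0 mm screw head).
#' @param seed integer fixing every stochastic draw made from this spec
#'   (e.g. the navigation-frame pose); default 1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 128, 128), spacing = c(1, 1, 1),
                         background_hu = -1000, soft_tissue_hu = 40,
                         bone_hu = 1200, native_max_hu = 3071,
                         head_axes_mm = NULL, tumors = NULL,
                         fiducial_hu = 3000, fiducial_radius_mm = 2,
                         seed = 1L) {
  shape <- as.integer(shape)
  extent <- c(shape[3] * spacing[2], shape[2] * spacing[1],
              shape[1] * spacing[3])  # physical size along x, y, z
  head_axes_mm <- head_axes_mm %||% (0.45 * extent)
  tumors <- tumors %||% list(list(
    center = c(0.25, -0.15, 0.1) * head_axes_mm, radius = 8, hu = 120))
  if (any(c(background_hu, soft_tissue_hu, bone_hu, fiducial_hu,
            vapply(tumors, `[[`, 0, "hu")) > native_max_hu))
    stop("phantom_spec: all HU values must be <= native_max_hu")
  if (any(head_axes_mm < 4 * fiducial_radius_mm))
    stop("phantom_spec: geometry too small to contain a head")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 background_hu = background_hu,
                 soft_tissue_hu = soft_tissue_hu, bone_hu = bone_hu,
                 native_max_hu = native_max_hu,
                 head_axes_mm = head_axes_mm, tumors = tumors,
                 fiducial_hu = fiducial_hu,
                 fiducial_radius_mm = fiducial_radius_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-voxel patient coordinates along each array dimension (axis-aligned)
phantom_coords <- function(spec) {
  g <- identity_geometry(spec$shape, spec$spacing,
                         origin = -c((spec$shape[3] - 1) * spec$spacing[2],
                                     (spec$shape[2] - 1) * spec$spacing[1],
                                     (spec$shape[1] - 1) * spec$spacing[3]) / 2)
  z <- g$origin[3] + (seq_len(spec$shape[1]) - 1) * spec$spacing[3]
  y <- g$origin[2] + (seq_len(spec$shape[2]) - 1) * spec$spacing[1]
  x <- g$origin[1] + (seq_len(spec$shape[3]) - 1) * spec$spacing[2]
  list(geometry = g, x = x, y = y, z = z)
}

# vectorized field of per-axis quadratic forms over the (k, i, j) array
ellipsoid_field <- function(spec, co, center, axes) {
  S <- spec$shape[1]; R <- spec$shape[2]; C <- spec$shape[3]
  qz <- ((co$z - center[3]) / axes[3])^2
  qy <- ((co$y - center[2]) / axes[2])^2
  qx <- ((co$x - center[1]) / axes[1])^2
  array(rep(qz, times = R * C) +
          rep(rep(qy, each = S), times = C) +
          rep(qx, each = S * R), dim = c(S, R, C))
}

#' Generate a synthetic head phantom
#'
#' Deterministically rasterizes the phantom described by a [phantom_spec()]:
#' soft-tissue head ellipsoid, bone shell (outer 12% of the ellipsoid),
#' tumor spheres and four fiducial blobs placed non-coplanarly on the head
#' surface. A random navigation-frame pose (drawn from `spec$seed`) relates
#' the physical and image coordinates of the fiducials.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `endicom_phantom`:
#'   \describe{
#'     \item{volume}{the [ct_volume()] (12-bit unsigned storage, intercept
#'       -1024, so its HU ceiling is 3071)}
#'     \item{fiducials}{a [fiducial_set()] with exact image coordinates and
#'       exact physical coordinates under the drawn pose; the pose itself is
#'       attached as attribute `"true_transform"` (navigation to image) and
#'       the interior head region as attribute `"region"`}
#'     \item{masks}{analytic ground-truth [segmentation_mask()]s:
#'       `head`, `bone`, `tumor`}
#'     \item{spec}{the input spec}
#'   }
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  g <- co$geometry
  head_q <- ellipsoid_field(spec, co, c(0, 0, 0), spec$head_axes_mm)
  head <- head_q <= 1
  inner <- head_q <= 0.88^2
  vol <- array(spec$background_hu, spec$shape)
  vol[head] <- spec$bone_hu
  vol[inner] <- spec$soft_tissue_hu
  tumor <- array(FALSE, spec$shape)
  for (tu in spec$tumors) {
    q <- ellipsoid_field(spec, co, tu$center, rep(tu$radius, 3))
    s <- q <= 1
    vol[s] <- tu$hu
    tumor <- tumor | s
  }
  # four non-coplanar fiducials on the head surface (right/left/front/vertex)
  a <- spec$head_axes_mm
  fid_img <- rbind(
    c(-0.95 * a[1], 0, -0.2 * a[3]),
    c( 0.95 * a[1], 0, -0.2 * a[3]),
    c(0, -0.95 * a[2],  0.1 * a[3]),
    c(0,  0.15 * a[2],  0.95 * a[3]))
  for (f in seq_len(nrow(fid_img))) {
    q <- ellipsoid_field(spec, co, fid_img[f, ],
                         rep(spec$fiducial_radius_mm, 3))
    vol[q <= 1] <- spec$fiducial_hu
  }
  stopifnot(max(vol) <= spec$native_max_hu)
  volume <- ct_volume(vol, g, rescale_slope = 1, rescale_intercept = -1024,
                      bits_stored = 12L, pixel_representation = "unsigned")
  true_T <- with_seed(spec$seed, random_rigid_transform(max_translation = 100))
  fid_phys <- apply_transform(invert_transform(true_T), fid_img)
  fids <- fiducial_set(c("screw_R", "screw_L", "screw_frontal", "screw_vertex"),
                       fid_phys, fid_img)
  attr(fids, "true_transform") <- true_T
  attr(fids, "region") <- list(center = c(0, 0, 0),
                               semi_axes = 0.7 * spec$head_axes_mm)
  masks <- list(
    head = segmentation_mask(head, g, "head"),
    bone = segmentation_mask(head & !inner, g, "bone"),
    tumor = segmentation_mask(tumor, g, "tumor"))
  structure(list(volume = volume, fiducials = fids, masks = masks,
                 spec = spec),
            class = "endicom_phantom")
}

#' @export
print.endicom_phantom <- function(x, ...) {
  cat("Synthetic head phantom\n")
  print(x$volume)
  cat(sprintf("  fiducials: %d; tumor voxels: %d\n",
              length(x$fiducials$labels), sum(x$masks$tumor$mask)))
  invisible(x)
}

#' Simulate intraoperative navigation on a phantom
#'
#' Emulates the intraoperative acquisition: the physical-side fiducials are
#' perturbed with isotropic Gaussian localization noise (per-axis standard
#' deviation `sigma_mm`, the scale of a tracked-pointer touch), and
#' `n_points` specimen landmarks are acquired at ground-truth positions
#' drawn uniformly inside the head region, with a reproducible random
#' histology assignment (40% malignant, 40% benign, 20% never released,
#' i.e. unknown).
#'
#' @param fids_true a [fiducial_set()] with exact pairs, as returned in
#'   [make_phantom()] (its `"true_transform"` and `"region"` attributes are
#'   used).
#' @param sigma_mm fiducial localization noise, mm; default 0.25.
#' @param n_points number of acquired specimen points; default 10.
#' @param seed RNG seed; default 1.
#' @return A list: `fiducials` (noisy [fiducial_set()]), `cloud` (the
#'   acquired [point_cloud()] in the navigation frame, histology unknown),
#'   and `truth` (data frame with the exact image-frame position and true
#'   histology per sequence number).
#' @export
simulate_navigation <- function(fids_true, sigma_mm = 0.25, n_points = 10,
                                seed = 1L) {
  stopifnot(inherits(fids_true, "fiducial_set"), sigma_mm >= 0)
  true_T <- attr(fids_true, "true_transform")
  if (is.null(true_T))
    stop("simulate_navigation: fiducial set lacks a 'true_transform' attribute")
  region <- attr(fids_true, "region") %||%
    list(center = colMeans(fids_true$image),
         semi_axes = rep(max(stats::dist(fids_true$image)) / 4, 3))
  with_seed(seed, {
    n_f <- nrow(fids_true$physical)
    noisy <- fiducial_set(
      fids_true$labels,
      fids_true$physical + matrix(rnorm(3 * n_f, sd = sigma_mm), n_f, 3),
      fids_true$image)
    attr(noisy, "true_transform") <- true_T
    attr(noisy, "region") <- region
    # uniform draws inside the (shrunken) head ellipsoid, by rejection
    pts_img <- matrix(0, n_points, 3)
    got <- 0L
    while (got < n_points) {
      cand <- matrix(runif(3, -1, 1), 1, 3)
      if (sum(cand^2) <= 1) {
        got <- got + 1L
        pts_img[got, ] <- region$center + cand * region$semi_axes
      }
    }
    pts_nav <- apply_transform(invert_transform(true_T), pts_img)
    cloud <- point_cloud("navigation")
    sites <- c("orbital_floor", "maxilla", "skull_base", "pterygoid",
               "zygoma", "nasal_wall", "sphenoid", "ethmoid")
    for (m in seq_len(n_points))
      cloud <- acquire_point(cloud,
                             sprintf("%s_%d", sites[(m - 1) %% length(sites) + 1], m),
                             pts_nav[m, ])
    histo <- sample(c("malignant", "benign", "unknown"), n_points,
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
    truth <- data.frame(sequence = cloud$sequence,
                        x = pts_img[, 1], y = pts_img[, 2], z = pts_img[, 3],
                        histology = histo, stringsAsFactors = FALSE)
    list(fiducials = noisy, cloud = cloud, truth = truth)
  })
}
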