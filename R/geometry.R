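#' Voxel/patient coordinate geometry of a CT series
#'
#' A `volume_geometry` object describes the affine mapping between voxel
#' indices of a CT volume and millimetre coordinates in the DICOM patient
#' frame (LPS convention: x increases to the patient's Left, y to Posterior,
#' z to Superior). The origin is the patient-frame position of the *center*
#' of voxel `(1, 1, 1)` (DICOM ImagePositionPatient semantics). Voxel indices
#' are 1-based triples `(k, i, j)` = (slice, row, column).
#'
#' @param origin numeric length-3, mm; patient position of the center of
#'   voxel (1, 1, 1).
#' @param dir_row,dir_col,dir_slice unit length-3 vectors: the patient-frame
#'   directions of increasing row index `i`, column index `j` and slice index
#'   `k`. `dir_col` and `dir_row` correspond to the first and second triplet
#'   of the DICOM ImageOrientationPatient attribute; the three must be
#'   mutually orthogonal.
#' @param spacing numeric length-3, mm: spacing between adjacent rows,
#'   columns and slices (in that order). All strictly positive.
#' @param shape integer length-3: number of slices, rows, columns.
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- identity_geometry(c(4, 5, 6))
#' voxel_to_patient(g, c(1, 1, 1))
#' @export
volume_geometry <- function(origin, dir_row, dir_col, dir_slice, spacing, shape) {
  origin <- as.numeric(origin)
  dir_row <- as.numeric(dir_row); dir_col <- as.numeric(dir_col)
  dir_slice <- as.numeric(dir_slice)
  spacing <- as.numeric(spacing); shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(shape) == 3)
  if (!all(is.finite(c(origin, dir_row, dir_col, dir_slice, spacing))))
    stop("volume_geometry: non-finite component")
  for (d in list(dir_row, dir_col, dir_slice))
    if (abs(sqrt(sum(d^2)) - 1) > 1e-9)
      stop("volume_geometry: direction vectors must be unit length (tol 1e-9)")
  dots <- c(sum(dir_row * dir_col), sum(dir_row * dir_slice), sum(dir_col * dir_slice))
  if (any(abs(dots) > 1e-6))
    stop("volume_geometry: direction vectors must be mutually orthogonal (tol 1e-6)")
  if (any(spacing <= 0)) stop("volume_geometry: spacings must be strictly positive")
  if (any(shape < 1L)) stop("volume_geometry: shape components must be >= 1")
  structure(
    list(origin = origin, dir_row = dir_row, dir_col = dir_col,
         dir_slice = dir_slice, spacing = spacing, shape = shape),
    class = "volume_geometry")
}

#' Axis-aligned geometry with column->x, row->y, slice->z
#'
#' Convenience constructor for the common axis-aligned LPS case in which the
#' column index advances along patient x, the row index along y and the slice
#' index along z.
#'
#' @param shape integer length-3 (slices, rows, columns).
#' @param spacing numeric length-3 mm (row, column, slice); default 1 mm.
#' @param origin numeric length-3 mm; default `c(0, 0, 0)`.
#' @return A [volume_geometry()].
#' @export
identity_geometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volume_geometry(origin,
                  dir_row = c(0, 1, 0), dir_col = c(1, 0, 0),
                  dir_slice = c(0, 0, 1), spacing = spacing, shape = shape)
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("CT volume geometry\n")
  cat(sprintf("  shape   : %d slices x %d rows x %d columns\n",
              x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  spacing : %.4g x %.4g x %.4g mm (row, col, slice)\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin  : (%.4g, %.4g, %.4g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

as_index_matrix <- function(idx) {
  if (is.matrix(idx)) idx else matrix(idx, ncol = 3, byrow = TRUE)
}

#' Map voxel indices to patient coordinates
#'
#' Returns the patient-frame (mm) position of the center of each voxel.
#'
#' @param geom a [volume_geometry()].
#' @param idx integer voxel index `(k, i, j)` (1-based slice, row, column),
#'   or an n x 3 matrix of such indices.
#' @return numeric length-3 for a single index, otherwise an n x 3 matrix of
#'   patient coordinates in mm.
#' @export
voxel_to_patient <- function(geom, idx) {
  single <- !is.matrix(idx)
  idx <- as_index_matrix(idx)
  if (any(idx < 1) || any(sweep(idx, 2, geom$shape, `>`)))
    stop("voxel_to_patient: index out of bounds for shape (",
         paste(geom$shape, collapse = ", "), ")")
  p <- matrix(geom$origin, nrow(idx), 3, byrow = TRUE) +
    outer((idx[, 1] - 1) * geom$spacing[3], geom$dir_slice) +
    outer((idx[, 2] - 1) * geom$spacing[1], geom$dir_row) +
    outer((idx[, 3] - 1) * geom$spacing[2], geom$dir_col)
  if (single) drop(p) else p
}

#' Map patient coordinates to voxel indices
#'
#' Inverts [voxel_to_patient()]. In `"continuous"` mode the fractional index
#' `(k, i, j)` is returned unchecked; in `"nearest"` mode each axis is rounded
#' half-to-even (deterministic tie-break) and points lying more than half a
#' voxel beyond the outermost voxel centers raise an out-of-volume error.
#'
#' @param geom a [volume_geometry()].
#' @param p patient coordinate (mm), length-3 or n x 3 matrix.
#' @param mode `"nearest"` (default) or `"continuous"`.
#' @return voxel index triple(s) `(k, i, j)`; integer in nearest mode.
#' @export
patient_to_voxel <- function(geom, p, mode = c("nearest", "continuous")) {
  mode <- match.arg(mode)
  single <- !is.matrix(p)
  p <- as_index_matrix(p)
  d <- sweep(p, 2, geom$origin)
  cont <- cbind(
    k = d %*% geom$dir_slice / geom$spacing[3] + 1,
    i = d %*% geom$dir_row   / geom$spacing[1] + 1,
    j = d %*% geom$dir_col   / geom$spacing[2] + 1)
  if (mode == "continuous") return(if (single) drop(cont) else cont)
  lo <- cont < 0.5 - 1e-9
  hi <- sweep(cont, 2, geom$shape + 0.5 + 1e-9, `>`)
  if (any(lo | hi)) {
    bad <- which(apply(lo | hi, 1, any))[1]
    stop(sprintf(
      "patient_to_voxel: point (%.6g, %.6g, %.6g) mm lies outside the volume",
      p[bad, 1], p[bad, 2], p[bad, 3]))
  }
  idx <- round(cont)  # round-half-even per axis
  idx <- pmin(pmax(idx, 1), matrix(geom$shape, nrow(idx), 3, byrow = TRUE))
  storage.mode(idx) <- "integer"
  if (single) drop(idx) else idx
}

#' Length of the voxel body diagonal in mm
#'
#' @param geom a [volume_geometry()].
#' @return numeric scalar, `sqrt(sum(spacing^2))` mm — the worst-case
#'   distance bound between a point and the center of its nearest voxel is
#'   half this value.
#' @export
voxel_diagonal <- function(geom) sqrt(sum(geom$spacing^2))

#' Express a geometry in a rigidly transformed patient frame
#'
#' Applies a rigid transform to the origin and direction vectors so that the
#' transformed geometry maps voxel indices to the transformed frame.
#'
#' @param geom a [volume_geometry()].
#' @param transform a [rigid_transform()].
#' @return a [volume_geometry()] in the new frame.
#' @export
transform_geometry <- function(geom, transform) {
  R <- transform$rotation
  volume_geometry(
    origin = drop(R %*% geom$origin) + transform$translation,
    dir_row = drop(R %*% geom$dir_row),
    dir_col = drop(R %*% geom$dir_col),
    dir_slice = drop(R %*% geom$dir_slice),
    spacing = geom$spacing, shape = geom$shape)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$dir_row - b$dir_row) < tol) &&
    all(abs(a$dir_col - b$dir_col) < tol) &&
    all(abs(a$dir_slice - b$dir_slice) < tol) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(a$shape == b$shape)
}
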