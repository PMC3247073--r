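#' Rigid transform between two 3D frames
#'
#' A proper rigid transform `p -> R p + t` with the root-mean-square fiducial
#' residual attached when the transform was estimated from paired points.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1 (tol 1e-9).
#' @param translation numeric length-3, mm.
#' @param rms_error non-negative RMS fiducial registration error in mm
#'   (0 for exactly constructed transforms).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rms_error = 0) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rigid_transform: rotation is not orthonormal (tol 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation must be proper (det +1); reflections are not rigid")
  if (rms_error < 0) stop("rigid_transform: rms_error must be >= 0")
  structure(list(rotation = rotation, translation = translation,
                 rms_error = rms_error),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (R p + t)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation: (%.4g, %.4g, %.4g) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  RMS fiducial residual: %.4g mm\n", x$rms_error))
  invisible(x)
}

#' Paired fiducial coordinates in two frames
#'
#' Holds the paired fiducial positions (e.g. titanium miniscrews or dental
#' splint markers) touched in the physical/navigation frame and identified in
#' the image frame. Pairing is by row.
#'
#' @param labels character vector of fiducial names.
#' @param physical n x 3 matrix, mm, navigation-frame coordinates.
#' @param image n x 3 matrix, mm, image-frame coordinates.
#' @return An object of class `fiducial_set`.
#' @details At least 3 pairs are required; image-side duplicates closer than
#'   1e-6 mm and collinear configurations are rejected (a rigid transform is
#'   not identifiable from them). Four non-coplanar screws are typical
#'   clinical practice.
#' @export
fiducial_set <- function(labels, physical, image) {
  physical <- as.matrix(physical); image <- as.matrix(image)
  storage.mode(physical) <- "double"; storage.mode(image) <- "double"
  labels <- as.character(labels)
  n <- length(labels)
  if (nrow(physical) != n || nrow(image) != n ||
      ncol(physical) != 3 || ncol(image) != 3)
    stop("fiducial_set: labels, physical and image must agree (n x 3)")
  if (n < 3) stop("fiducial_set: at least 3 fiducial pairs are required")
  if (!all(is.finite(physical)) || !all(is.finite(image)))
    stop("fiducial_set: non-finite coordinate")
  dd <- as.matrix(stats::dist(image))
  diag(dd) <- Inf
  if (min(dd) < 1e-6)
    stop("fiducial_set: duplicate image-frame fiducials (closer than 1e-6 mm)")
  structure(list(labels = labels, physical = physical, image = image),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("Fiducial set: %d paired points\n", length(x$labels)))
  df <- data.frame(label = x$labels,
                   phys_x = x$physical[, 1], phys_y = x$physical[, 2],
                   phys_z = x$physical[, 3],
                   img_x = x$image[, 1], img_y = x$image[, 2],
                   img_z = x$image[, 3])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read / write a fiducial pair table
#'
#' Delimited text with header columns
#' `label, phys_x, phys_y, phys_z, img_x, img_y, img_z` (mm). Comma and
#' whitespace delimiters are both accepted on read; writing uses CSV.
#'
#' @param path file path.
#' @return `read_fiducials` returns a [fiducial_set()];
#'   `write_fiducials` returns `path` invisibly.
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop("read_fiducials: no such file: ", path)
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first)) read.csv(path, stringsAsFactors = FALSE)
        else utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("label", "phys_x", "phys_y", "phys_z", "img_x", "img_y", "img_z")
  if (!all(need %in% names(df)))
    stop("read_fiducials: header must contain: ", paste(need, collapse = ", "))
  fiducial_set(df$label,
               cbind(df$phys_x, df$phys_y, df$phys_z),
               cbind(df$img_x, df$img_y, df$img_z))
}

#' @param fids a [fiducial_set()].
#' @rdname read_fiducials
#' @export
write_fiducials <- function(fids, path) {
  df <- data.frame(label = fids$labels,
                   phys_x = fids$physical[, 1], phys_y = fids$physical[, 2],
                   phys_z = fids$physical[, 3],
                   img_x = fids$image[, 1], img_y = fids$image[, 2],
                   img_z = fids$image[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paired-point rigid registration (orthogonal Procrustes)
#'
#' Estimates the least-squares rigid transform mapping the physical
#' (navigation) frame onto the image frame: it minimizes
#' \eqn{\sum_i \| R p_i + t - q_i \|^2} over rotations `R` and translations
#' `t` by the closed-form solution — centroid alignment followed by SVD of
#' the cross-covariance with a sign correction that excludes reflections.
#' The attached `rms_error` is the fiducial registration error (FRE), the
#' quantity checked at the navigation console before surgery proceeds.
#'
#' @param fids a [fiducial_set()].
#' @return A [rigid_transform()] mapping navigation to image coordinates,
#'   with `rms_error` the RMS residual over the fitted pairs in mm.
#' @examples
#' p <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
#' fids <- fiducial_set(letters[1:4], p, p)
#' estimate_rigid(fids)$rms_error  # 0: self-registration
#' @export
estimate_rigid <- function(fids) {
  if (!inherits(fids, "fiducial_set")) stop("estimate_rigid: need a fiducial_set")
  p <- fids$physical; q <- fids$image
  n <- nrow(p)
  if (n < 3) stop("estimate_rigid: at least 3 pairs required")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  # collinearity: a rigid transform is not identifiable about the line
  sv_p <- svd(pc)$d
  if (sv_p[2] < max(1e-9, 1e-9 * sv_p[1]))
    stop("estimate_rigid: fiducials are collinear; configuration is degenerate")
  H <- crossprod(pc, qc)  # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0)
    stop("estimate_rigid: degenerate configuration; no proper rotation found")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (det(R) < 0)
    stop("estimate_rigid: reflection could not be corrected; configuration is degenerate")
  t <- cq - drop(R %*% cp)
  resid <- q - (p %*% t(R) + matrix(t, n, 3, byrow = TRUE))
  rms <- sqrt(mean(rowSums(resid^2)))
  rigid_transform(R, t, rms)
}

#' @export
summary.rigid_transform <- function(object, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object$rotation)) - 1) / 2))) * 180 / pi
  structure(list(transform = object, rotation_angle_deg = ang,
                 translation_norm_mm = sqrt(sum(object$translation^2))),
            class = "summary.rigid_transform")
}

#' @export
print.summary.rigid_transform <- function(x, ...) {
  print(x$transform)
  cat(sprintf("  rotation angle: %.4g deg, translation norm: %.4g mm\n",
              x$rotation_angle_deg, x$translation_norm_mm))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param p length-3 point or n x 3 matrix, mm.
#' @return transformed point(s), same shape as the input.
#' @export
apply_transform <- function(transform, p) {
  single <- !is.matrix(p)
  p <- as_index_matrix(p)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (single) drop(out) else out
}

#' Invert a rigid transform
#'
#' Returns `(R', -R' t)`; the RMS residual of the original fit is carried
#' over unchanged (it is a property of the pairing, not of the direction).
#'
#' @param transform a [rigid_transform()].
#' @return a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation), transform$rms_error)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first and
#' then `a` (i.e. `p -> a(b(p))`). The composed `rms_error` is 0 unless
#' exactly one operand carries a residual, in which case that residual is
#' kept.
#'
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rms <- if (a$rms_error > 0 && b$rms_error > 0) 0 else max(a$rms_error, b$rms_error)
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation,
                  rms)
}

#' Registration acceptance gate
#'
#' Intraoperative practice repeats the registration when the navigation
#' system reports an unacceptable residual; the customary ceiling for the
#' overall RMS error is 0.5 to 0.8 mm, and 0.8 mm is the default gate here.
#'
#' @param transform a [rigid_transform()] with an estimated `rms_error`.
#' @param threshold_mm positive gate in mm; default 0.8.
#' @return A list of class `registration_gate` with fields `pass`,
#'   `rms_error` and `threshold_mm`.
#' @export
registration_gate <- function(transform, threshold_mm = 0.8) {
  if (threshold_mm <= 0) stop("registration_gate: threshold_mm must be > 0")
  structure(list(pass = transform$rms_error <= threshold_mm,
                 rms_error = transform$rms_error,
                 threshold_mm = threshold_mm),
            class = "registration_gate")
}

#' @export
print.registration_gate <- function(x, ...) {
  cat(sprintf("Registration gate: %s (RMS %.4g mm %s threshold %.4g mm)\n",
              if (x$pass) "PASS" else "FAIL", x$rms_error,
              if (x$pass) "<=" else ">", x$threshold_mm))
  invisible(x)
}

#' Draw a uniformly random proper rotation / rigid transform
#'
#' Rotation sampled by QR decomposition of a Gaussian matrix (sign-corrected
#' to det +1), translation uniform in `[-max_translation, max_translation]`
#' per axis. Uses the current RNG stream.
#'
#' @param max_translation mm, default 100.
#' @return a [rigid_transform()].
#' @export
random_rigid_transform <- function(max_translation = 100) {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rigid_transform(R, runif(3, -max_translation, max_translation), 0)
}
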