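#' Landmark-based rigid volume fusion (resampling)
#'
#' Resamples a source CT volume onto the voxel grid of a target volume after
#' a rigid source-to-target transform — the superimposition step that places
#' an enhanced (sentinel-marked) series onto, e.g., the post-operative
#' planning CT. Out-of-source samples take `fill_hu`. Sentinel voxels are
#' always resampled by nearest neighbour, even in trilinear mode: linear
#' interpolation would smear a 3500 HU mark below the extraction threshold,
#' which is the one failure mode the marking scheme cannot tolerate.
#'
#' @param source,target [ct_volume()] objects.
#' @param transform a [rigid_transform()] mapping source patient coordinates
#'   to target patient coordinates (typically from [estimate_rigid()] on
#'   anatomical landmark pairs).
#' @param interp `"trilinear"` (default) or `"nearest"`.
#' @param fill_hu HU assigned outside the source volume; default -1024 (air).
#' @param sentinel_threshold_hu source intensities at or above this are
#'   protected from interpolation; default 3200.
#' @return An object of class `fusion_result`: list with `resampled` (a
#'   [ct_volume()] on the exact target geometry), `transform` and
#'   `interpolation`.
#' @export
fuse_volumes <- function(source, target, transform,
                         interp = c("trilinear", "nearest"),
                         fill_hu = -1024, sentinel_threshold_hu = 3200) {
  interp <- match.arg(interp)
  stopifnot(inherits(source, "ct_volume"), inherits(target, "ct_volume"))
  tg <- target$geometry; sg <- source$geometry
  inv <- invert_transform(transform)
  d <- tg$shape
  idx <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  p_t <- voxel_to_patient(tg, idx)
  p_s <- apply_transform(inv, p_t)
  cont <- patient_to_voxel(sg, p_s, mode = "continuous")

  near <- round(cont)
  near_in <- near[, 1] >= 1 & near[, 1] <= sg$shape[1] &
             near[, 2] >= 1 & near[, 2] <= sg$shape[2] &
             near[, 3] >= 1 & near[, 3] <= sg$shape[3] &
             cont[, 1] >= 0.5 - 1e-9 & cont[, 1] <= sg$shape[1] + 0.5 + 1e-9 &
             cont[, 2] >= 0.5 - 1e-9 & cont[, 2] <= sg$shape[2] + 0.5 + 1e-9 &
             cont[, 3] >= 0.5 - 1e-9 & cont[, 3] <= sg$shape[3] + 0.5 + 1e-9
  vals_near <- rep(fill_hu, nrow(cont))
  ni <- near[near_in, , drop = FALSE]
  storage.mode(ni) <- "integer"
  vals_near[near_in] <- source$intensities[ni]

  vals <- if (interp == "nearest") vals_near else {
    lo <- floor(cont)
    fr <- cont - lo
    tri_in <- lo[, 1] >= 1 & lo[, 1] + 1 <= sg$shape[1] &
              lo[, 2] >= 1 & lo[, 2] + 1 <= sg$shape[2] &
              lo[, 3] >= 1 & lo[, 3] + 1 <= sg$shape[3]
    v <- vals_near  # nearest (or fill) where the 2x2x2 stencil is incomplete
    if (any(tri_in)) {
      l <- lo[tri_in, , drop = FALSE]; f <- fr[tri_in, , drop = FALSE]
      storage.mode(l) <- "integer"
      acc <- 0
      for (dk in 0:1) for (di in 0:1) for (dj in 0:1) {
        w <- (if (dk) f[, 1] else 1 - f[, 1]) *
             (if (di) f[, 2] else 1 - f[, 2]) *
             (if (dj) f[, 3] else 1 - f[, 3])
        corner <- cbind(l[, 1] + dk, l[, 2] + di, l[, 3] + dj)
        acc <- acc + w * source$intensities[corner]
      }
      v[tri_in] <- acc
    }
    # sentinel protection: marks keep their nearest-neighbour value
    sent <- near_in & vals_near >= sentinel_threshold_hu
    v[sent] <- vals_near[sent]
    v
  }
  resampled <- ct_volume(array(vals, d), tg,
                         rescale_slope = source$rescale_slope,
                         rescale_intercept = source$rescale_intercept,
                         bits_stored = source$bits_stored,
                         pixel_representation = source$pixel_representation,
                         uids = list(study = target$uids$study,
                                     series = new_uid(),
                                     frame_of_reference =
                                       target$uids$frame_of_reference))
  structure(list(resampled = resampled, transform = transform,
                 interpolation = interp),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("Fusion result (%s interpolation)\n", x$interpolation))
  print(x$resampled)
  invisible(x)
}

#' Lossless point-level fusion
#'
#' Maps a point cloud from the source image frame into the target frame by
#' the rigid transform alone — the exact alternative to resampling the
#' sentinel voxels, with no quantization loss.
#'
#' @param cloud a [point_cloud()] in the source image frame.
#' @param transform a [rigid_transform()] (source to target).
#' @return the transformed [point_cloud()] (frame `"image"`).
#' @export
fuse_points <- function(cloud, transform) {
  if (cloud_frame(cloud) != "image")
    stop("fuse_points: cloud must be in the (source) image frame")
  df <- bare_df(cloud)
  if (nrow(df)) {
    p <- apply_transform(transform, cloud_positions(cloud))
    df$x <- p[, 1]; df$y <- p[, 2]; df$z <- p[, 3]
  }
  as_point_cloud(df, "image")
}
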