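#' Sentinel-voxel encoding policy
#'
#' Parameters of the enhanced-DICOM encoding. The sentinel intensity is
#' deliberately placed far above the conventional CT range — unmodified CT
#' data tops out around 3100 HU (a 12-bit encoding with intercept -1024
#' reaches 3071 HU) — so marked voxels are unambiguous evidence of
#' manipulation and can be recovered by simple thresholding.
#'
#' @param sentinel_hu HU written at marked voxels; default 3500.
#' @param max_native_hu documented ceiling of unmodified data; default 3100.
#'   Encoding refuses volumes whose native intensities exceed this, since
#'   separability of the marks would be lost.
#' @param collision `"merge"` (default; two points falling in one voxel keep
#'   a single mark, with a warning naming both sequence numbers) or
#'   `"error"`.
#' @param out_of_volume `"error"` (default) or `"skip"` (drop the point with
#'   a warning).
#' @return An object of class `encoding_policy`.
#' @export
encoding_policy <- function(sentinel_hu = 3500, max_native_hu = 3100,
                            collision = c("merge", "error"),
                            out_of_volume = c("error", "skip")) {
  collision <- match.arg(collision)
  out_of_volume <- match.arg(out_of_volume)
  if (sentinel_hu <= max_native_hu)
    stop("encoding_policy: sentinel_hu must exceed max_native_hu")
  structure(list(sentinel_hu = sentinel_hu, max_native_hu = max_native_hu,
                 collision = collision, out_of_volume = out_of_volume),
            class = "encoding_policy")
}

#' Encode tumor-positive points as sentinel voxels (enhanced DICOM)
#'
#' Writes each selected point into a copy of the CT volume as its nearest
#' voxel set to the sentinel intensity (3500 HU by default); every other
#' voxel is bit-identical to the input. If the sentinel is not representable
#' at the volume's stored bit depth, the pixel encoding is widened to signed
#' 16 bit (slope/intercept unchanged) — the minimal change that makes the
#' out-of-range value storable.
#'
#' @param vol a [ct_volume()] whose native intensities must not exceed
#'   `policy$max_native_hu` (separability guarantee; a dense metal artifact
#'   above the ceiling raises an error rather than silently clipping).
#' @param cloud a [point_cloud()] in the image frame — apply
#'   [to_image_frame()] first — normally the [select_malignant()] selection.
#' @param policy an [encoding_policy()].
#' @param mark_radius_mm optional spherical mark radius in mm; default 0
#'   writes a single voxel per point (larger marks only aid visibility in
#'   planning platforms).
#' @return the marked [ct_volume()]; the integer matrix of marked voxel
#'   indices `(k, i, j)` is attached as attribute `"marked_voxels"`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(24, 32, 32)))
#' cl <- point_cloud("image")
#' cl[1, ] <- list(1L, "margin", 0, 0, 0, "malignant")
#' marked <- endicom_encode(ph$volume, cl)
#' max(marked$intensities)  # 3500
#' @export
endicom_encode <- function(vol, cloud, policy = encoding_policy(),
                           mark_radius_mm = 0) {
  stopifnot(inherits(vol, "ct_volume"))
  if (cloud_frame(cloud) != "image")
    stop("endicom_encode: cloud must be in the image frame; apply to_image_frame() first")
  native_max <- max(vol$intensities)
  if (native_max > policy$max_native_hu) {
    bad <- which.max(vol$intensities)
    ijk <- arrayInd(bad, dim(vol$intensities))
    stop(sprintf(paste0(
      "endicom_encode: native intensity %g HU at voxel (k=%d, i=%d, j=%d) ",
      "exceeds the policy ceiling %g HU; sentinel marks would not be ",
      "separable by thresholding"),
      native_max, ijk[1], ijk[2], ijk[3], policy$max_native_hu))
  }
  out <- vol
  geom <- vol$geometry
  if (nrow(cloud) == 0) {
    attr(out, "marked_voxels") <- matrix(integer(0), 0, 3)
    return(out)
  }
  pos <- cloud_positions(cloud)
  cont <- patient_to_voxel(geom, pos, mode = "continuous")
  inside <- cont[, 1] >= 0.5 - 1e-9 & cont[, 1] <= geom$shape[1] + 0.5 + 1e-9 &
            cont[, 2] >= 0.5 - 1e-9 & cont[, 2] <= geom$shape[2] + 0.5 + 1e-9 &
            cont[, 3] >= 0.5 - 1e-9 & cont[, 3] <= geom$shape[3] + 0.5 + 1e-9
  if (any(!inside)) {
    seqs <- cloud$sequence[!inside]
    if (policy$out_of_volume == "error")
      stop("endicom_encode: point(s) outside the volume (sequence ",
           paste(seqs, collapse = ", "), ")")
    warning("endicom_encode: skipping point(s) outside the volume (sequence ",
            paste(seqs, collapse = ", "), ")")
  }
  keep <- which(inside)
  if (length(keep) == 0) {
    attr(out, "marked_voxels") <- matrix(integer(0), 0, 3)
    return(out)
  }
  shp <- matrix(geom$shape, length(keep), 3, byrow = TRUE)
  idx <- pmin(pmax(round(cont[keep, , drop = FALSE]), 1), shp)
  storage.mode(idx) <- "integer"
  lin <- idx[, 1] + geom$shape[1] * ((idx[, 2] - 1) +
                                     geom$shape[2] * (idx[, 3] - 1))
  dup <- duplicated(lin)
  if (any(dup)) {
    groups <- split(cloud$sequence[keep], lin)
    coll <- Filter(function(g) length(g) > 1, groups)
    msg <- paste(vapply(coll, function(g)
      paste(g, collapse = "+"), ""), collapse = "; ")
    if (policy$collision == "error")
      stop("endicom_encode: points map to the same voxel (sequences ", msg, ")")
    warning("endicom_encode: merging points that share a voxel (sequences ",
            msg, ")")
    idx <- idx[!dup, , drop = FALSE]
  }
  if (mark_radius_mm > 0)
    idx <- grow_marks(geom, idx, mark_radius_mm)
  out$intensities[idx] <- policy$sentinel_hu
  if (policy$sentinel_hu > hu_ceiling(out) ||
      (out$pixel_representation == "unsigned" &&
       (policy$sentinel_hu - out$rescale_intercept) / out$rescale_slope < 0)) {
    out$bits_stored <- 16L
    out$pixel_representation <- "signed"
  }
  attr(out, "marked_voxels") <- unique(idx)
  out
}

# expand single-voxel marks to all voxels whose centers lie within radius
grow_marks <- function(geom, idx, radius_mm) {
  r_vox <- ceiling(radius_mm / geom$spacing)
  offs <- expand.grid(dk = -r_vox[3]:r_vox[3], di = -r_vox[1]:r_vox[1],
                      dj = -r_vox[2]:r_vox[2])
  d2 <- (offs$dk * geom$spacing[3])^2 + (offs$di * geom$spacing[1])^2 +
    (offs$dj * geom$spacing[2])^2
  offs <- offs[d2 <= radius_mm^2 + 1e-9, ]
  all_idx <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r)
    cbind(idx[r, 1] + offs$dk, idx[r, 2] + offs$di, idx[r, 3] + offs$dj)))
  ok <- all_idx[, 1] >= 1 & all_idx[, 1] <= geom$shape[1] &
        all_idx[, 2] >= 1 & all_idx[, 2] <= geom$shape[2] &
        all_idx[, 3] >= 1 & all_idx[, 3] <= geom$shape[3]
  out <- unique(all_idx[ok, , drop = FALSE])
  storage.mode(out) <- "integer"
  out
}

#' Recover sentinel-marked points by threshold segmentation
#'
#' The well-defined high intensity of the marks makes recovery a pure
#' threshold operation: every voxel at or above `threshold_hu` becomes one
#' recovered point at that voxel's center. The default threshold of 3200 HU
#' sits strictly between the documented native ceiling (~3100 HU) and the
#' sentinel (3500 HU), giving maximal separation margin on both sides.
#'
#' @param vol a [ct_volume()] (typically a re-read enhanced series).
#' @param threshold_hu recovery threshold, default 3200.
#' @return An object of class `extraction_report`: list with `recovered`
#'   (a [point_cloud()] in the image frame, sequence numbers assigned in
#'   lexicographic `(k, i, j)` voxel order, names `"recovered"`),
#'   `voxel_count` and `threshold_used`. An empty recovery is valid.
#' @export
endicom_extract <- function(vol, threshold_hu = 3200) {
  stopifnot(inherits(vol, "ct_volume"))
  hits <- which(vol$intensities >= threshold_hu)
  if (length(hits) == 0) {
    rep_ <- list(recovered = point_cloud("image"), voxel_count = 0L,
                 threshold_used = threshold_hu)
    class(rep_) <- "extraction_report"
    return(rep_)
  }
  idx <- arrayInd(hits, dim(vol$intensities))  # (k, i, j)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  centers <- voxel_to_patient(vol$geometry, idx)
  df <- data.frame(sequence = seq_len(nrow(idx)),
                   name = "recovered",
                   x = centers[, 1], y = centers[, 2], z = centers[, 3],
                   histology = "malignant", stringsAsFactors = FALSE)
  rep_ <- list(recovered = as_point_cloud(df, "image"),
               voxel_count = length(hits),
               threshold_used = threshold_hu,
               voxel_indices = idx)
  class(rep_) <- "extraction_report"
  rep_
}

#' @export
print.extraction_report <- function(x, ...) {
  cat(sprintf("Extraction report: %d voxel(s) >= %g HU, %d recovered point(s)\n",
              x$voxel_count, x$threshold_used, nrow(x$recovered)))
  invisible(x)
}

#' Positional round-trip error of the voxel encoding
#'
#' Greedily matches each encoded point to the nearest recovered voxel center
#' and reports the per-pair distances; quantization to voxel centers bounds
#' each distance by half the voxel body diagonal.
#'
#' @param cloud the encoded [point_cloud()] (image frame).
#' @param report the [endicom_extract()] result.
#' @param geom the [volume_geometry()] of the marked series.
#' @return numeric vector of distances in mm, one per matched pair, with the
#'   half-voxel-diagonal quantization bound attached as attribute `"bound"`.
#'   A cardinality mismatch (after collision merging) is reported as a
#'   warning, not an error.
#' @export
roundtrip_error <- function(cloud, report, geom) {
  if (nrow(cloud) < 1) stop("roundtrip_error: empty encoded cloud")
  enc <- cloud_positions(cloud)
  rec <- cloud_positions(report$recovered)
  if (nrow(rec) != nrow(enc))
    warning(sprintf(
      "roundtrip_error: %d encoded point(s) but %d recovered (collision merge?)",
      nrow(enc), nrow(rec)))
  n <- min(nrow(enc), nrow(rec))
  if (n == 0) return(structure(numeric(0), bound = voxel_diagonal(geom) / 2))
  d2 <- outer(rowSums(enc^2), rep(1, nrow(rec))) +
    outer(rep(1, nrow(enc)), rowSums(rec^2)) - 2 * enc %*% t(rec)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  out <- numeric(n)
  for (m in seq_len(n)) {
    best <- arrayInd(which.min(dist), dim(dist))
    out[m] <- dist[best[1], best[2]]
    dist[best[1], ] <- Inf
    dist[, best[2]] <- Inf
  }
  structure(out, bound = voxel_diagonal(geom) / 2)
}
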