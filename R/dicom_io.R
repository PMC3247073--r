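cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' CT volume in Hounsfield units
#'
#' Container pairing a 3D intensity array (HU) with its [volume_geometry()]
#' and the pixel-encoding attributes (rescale slope/intercept, stored bit
#' depth, signedness) needed to rewrite the data bit-faithfully. Volumes read
#' from disk also retain the full per-slice DICOM attribute sets so that
#' writing reproduces every attribute except pixel data, bit-depth tags when
#' widened, and freshly generated instance UIDs.
#'
#' @param intensities numeric 3D array of HU values, dim = (slices, rows,
#'   columns) = `geometry$shape`.
#' @param geometry a [volume_geometry()].
#' @param rescale_slope,rescale_intercept mapping stored pixel values to HU:
#'   `HU = slope * stored + intercept`. Defaults 1 and -1024.
#' @param bits_stored stored bit depth (<= 16); default 16.
#' @param pixel_representation `"signed"` or `"unsigned"`; default `"signed"`.
#' @param source_metadata optional list (one entry per slice, in slice order)
#'   of retained DICOM element lists; `NULL` for volumes built in code.
#' @param uids optional named list with `study`, `series`, `frame_of_reference`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, geometry, rescale_slope = 1,
                      rescale_intercept = -1024, bits_stored = 16L,
                      pixel_representation = c("signed", "unsigned"),
                      source_metadata = NULL, uids = NULL) {
  pixel_representation <- match.arg(pixel_representation)
  if (!identical(dim(intensities), NULL) &&
      !all(dim(intensities) == geometry$shape))
    stop("ct_volume: intensities dim must equal geometry$shape")
  if (is.null(dim(intensities)))
    stop("ct_volume: intensities must be a 3D array")
  if (bits_stored < 1L || bits_stored > 16L)
    stop("ct_volume: bits_stored must be in 1..16")
  structure(list(intensities = intensities, geometry = geometry,
                 rescale_slope = rescale_slope,
                 rescale_intercept = rescale_intercept,
                 bits_stored = as.integer(bits_stored),
                 pixel_representation = pixel_representation,
                 source_metadata = source_metadata,
                 uids = uids %||% list(study = new_uid(), series = new_uid(),
                                       frame_of_reference = new_uid())),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume\n")
  print(x$geometry)
  cat(sprintf("  HU range: [%.0f, %.0f]; stored as %d-bit %s, slope %g, intercept %g\n",
              min(x$intensities), max(x$intensities), x$bits_stored,
              x$pixel_representation, x$rescale_slope, x$rescale_intercept))
  cat(sprintf("  metadata: %s\n",
              if (is.null(x$source_metadata)) "synthesized" else "retained from source series"))
  invisible(x)
}

stored_value_range <- function(bits_stored, pixel_representation) {
  if (pixel_representation == "signed")
    c(-(2^(bits_stored - 1)), 2^(bits_stored - 1) - 1)
  else c(0, 2^bits_stored - 1)
}

#' Largest HU value representable by a volume's pixel encoding
#'
#' @param vol a [ct_volume()].
#' @return numeric scalar HU (e.g. 3071 for 12-bit unsigned storage with
#'   intercept -1024).
#' @export
hu_ceiling <- function(vol) {
  r <- stored_value_range(vol$bits_stored, vol$pixel_representation)
  vol$rescale_slope * r[2] + vol$rescale_intercept
}

#' Read a CT DICOM series from a directory
#'
#' Reads all single-frame, explicit-VR little-endian CT files in `path` into
#' a [ct_volume()]. Slices are ordered by the projection of
#' ImagePositionPatient onto the slice normal (never by file name or instance
#' number), the inter-slice spacing is derived from successive positions (the
#' SliceThickness tag is ignored for geometry), and HU values are computed
#' through RescaleSlope/RescaleIntercept. Non-DICOM files in the directory
#' are ignored.
#'
#' @param path directory containing the series.
#' @return a [ct_volume()] with per-slice source metadata retained.
#' @details Errors are raised for mixed SeriesInstanceUIDs, inconsistent
#'   inter-slice orientation, missing geometry tags, and non-uniform slice
#'   spacing beyond 1e-3 mm (a removed slice mid-stack is detected this way).
#' @export
read_dicom_series <- function(path) {
  if (!dir.exists(path)) stop("read_dicom_series: no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[vapply(files, dcm_is_dicom_file, TRUE)]
  if (length(files) < 1) stop("read_dicom_series: no DICOM files in ", path)
  slices <- lapply(files, function(f) {
    parsed <- dcm_read_file(f)
    ds <- parsed$dataset
    need <- function(g, e, what) {
      el <- dcm_get(ds, g, e)
      if (is.null(el)) stop("read_dicom_series: missing ", what, " in ", f)
      el
    }
    list(file = f,
         dataset = ds,
         series_uid = dcm_text(need(0x0020, 0x000E, "SeriesInstanceUID")),
         ipp = dcm_numbers(need(0x0020, 0x0032, "ImagePositionPatient")),
         iop = dcm_numbers(need(0x0020, 0x0037, "ImageOrientationPatient")),
         pixel_spacing = dcm_numbers(need(0x0028, 0x0030, "PixelSpacing")),
         rows = dcm_us(need(0x0028, 0x0010, "Rows")),
         cols = dcm_us(need(0x0028, 0x0011, "Columns")),
         bits_stored = dcm_us(need(0x0028, 0x0101, "BitsStored")),
         pixel_rep = dcm_us(need(0x0028, 0x0103, "PixelRepresentation")),
         slope = dcm_numbers(dcm_get(ds, 0x0028, 0x1053)) %||% 1,
         intercept = dcm_numbers(dcm_get(ds, 0x0028, 0x1052)) %||% 0,
         pixels = need(0x7FE0, 0x0010, "PixelData")$bytes)
  })
  uid <- unique(vapply(slices, `[[`, "", "series_uid"))
  if (length(uid) != 1)
    stop("read_dicom_series: directory mixes ", length(uid),
         " series UIDs; supply a single series")
  iop <- slices[[1]]$iop
  for (s in slices)
    if (max(abs(s$iop - iop)) > 1e-6)
      stop("read_dicom_series: inconsistent ImageOrientationPatient between slices")
  if (length(iop) != 6) stop("read_dicom_series: malformed ImageOrientationPatient")
  dir_col <- iop[1:3]; dir_row <- iop[4:6]
  normal <- cross3(dir_col, dir_row)
  pos <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  n_slices <- length(slices)
  if (n_slices > 1) {
    dz <- diff(pos)
    if (any(dz <= 0))
      stop("read_dicom_series: duplicate slice positions in series")
    if (max(dz) - min(dz) > 1e-3)
      stop(sprintf(paste0(
        "read_dicom_series: non-uniform slice spacing ",
        "(%.4g to %.4g mm); series has gaps or overlaps"),
        min(dz), max(dz)))
    slice_spacing <- mean(dz)
  } else {
    slice_spacing <- 1
  }
  s1 <- slices[[1]]
  rows <- s1$rows; cols <- s1$cols
  geom <- volume_geometry(
    origin = s1$ipp, dir_row = dir_row, dir_col = dir_col,
    dir_slice = normal,
    spacing = c(s1$pixel_spacing[1], s1$pixel_spacing[2], slice_spacing),
    shape = c(n_slices, rows, cols))
  signed <- s1$pixel_rep == 1L
  intens <- array(0, dim = c(n_slices, rows, cols))
  for (k in seq_len(n_slices)) {
    s <- slices[[k]]
    if (s$rows != rows || s$cols != cols)
      stop("read_dicom_series: inconsistent Rows/Columns between slices")
    stored <- readBin(s$pixels, "integer", n = rows * cols, size = 2,
                      signed = TRUE, endian = "little")
    if (!signed) stored <- ifelse(stored < 0, stored + 65536, stored)
    intens[k, , ] <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE) *
      s$slope + s$intercept
  }
  ds1 <- s1$dataset
  ct_volume(intens, geom,
            rescale_slope = s1$slope, rescale_intercept = s1$intercept,
            bits_stored = s1$bits_stored,
            pixel_representation = if (signed) "signed" else "unsigned",
            source_metadata = lapply(slices, `[[`, "dataset"),
            uids = list(
              study = dcm_text(dcm_get(ds1, 0x0020, 0x000D)) %||% new_uid(),
              series = s1$series_uid,
              frame_of_reference =
                dcm_text(dcm_get(ds1, 0x0020, 0x0052)) %||% new_uid()))
}

synth_slice_dataset <- function(vol, k) {
  g <- vol$geometry
  ipp <- voxel_to_patient(g, c(k, 1, 1))
  list(
    dcm_element(0x0008, 0x0016, "UI", dcm_bytes_ui(UID_CT_IMAGE_STORAGE)),
    dcm_element(0x0008, 0x0018, "UI", dcm_bytes_ui(new_uid())),  # replaced on write
    dcm_element(0x0008, 0x0060, "CS", dcm_bytes_str("CT")),
    dcm_element(0x0018, 0x0050, "DS", dcm_bytes_ds(g$spacing[3])),
    dcm_element(0x0020, 0x000D, "UI", dcm_bytes_ui(vol$uids$study)),
    dcm_element(0x0020, 0x000E, "UI", dcm_bytes_ui(vol$uids$series)),
    dcm_element(0x0020, 0x0013, "IS", dcm_bytes_str(as.character(k))),
    dcm_element(0x0020, 0x0032, "DS", dcm_bytes_ds(ipp)),
    dcm_element(0x0020, 0x0037, "DS", dcm_bytes_ds(c(g$dir_col, g$dir_row))),
    dcm_element(0x0020, 0x0052, "UI", dcm_bytes_ui(vol$uids$frame_of_reference)),
    dcm_element(0x0028, 0x0002, "US", dcm_bytes_us(1)),
    dcm_element(0x0028, 0x0004, "CS", dcm_bytes_str("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_bytes_us(g$shape[2])),
    dcm_element(0x0028, 0x0011, "US", dcm_bytes_us(g$shape[3])),
    dcm_element(0x0028, 0x0030, "DS", dcm_bytes_ds(g$spacing[1:2])),
    dcm_element(0x0028, 0x0100, "US", dcm_bytes_us(16)),
    dcm_element(0x0028, 0x0101, "US", dcm_bytes_us(vol$bits_stored)),
    dcm_element(0x0028, 0x0102, "US", dcm_bytes_us(vol$bits_stored - 1L)),
    dcm_element(0x0028, 0x0103, "US",
                dcm_bytes_us(if (vol$pixel_representation == "signed") 1 else 0)),
    dcm_element(0x0028, 0x1052, "DS", dcm_bytes_ds(vol$rescale_intercept)),
    dcm_element(0x0028, 0x1053, "DS", dcm_bytes_ds(vol$rescale_slope)))
}

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian file per slice. For volumes read from
#' disk every retained attribute is copied verbatim except the pixel data,
#' the bit-depth attributes (when the pixel encoding was widened) and the SOP
#' instance UIDs, which are freshly generated so the modified objects never
#' collide with the originals while keeping the same study, series and
#' frame-of-reference UIDs. Re-reading the written series reproduces the
#' intensities exactly.
#'
#' @param vol a [ct_volume()].
#' @param path output directory (created if absent).
#' @param new_series if `TRUE` (default) a fresh SeriesInstanceUID is
#'   generated; study and frame-of-reference UIDs are always preserved.
#' @return invisibly, the vector of file paths written (slice order).
#' @details Every HU value must be representable at the volume's declared
#'   bit depth as `stored = (HU - intercept) / slope`; otherwise an encoding
#'   error names the offending voxel and value (see [endicom_encode()] for
#'   automatic widening when writing sentinel values).
#' @export
write_dicom_series <- function(vol, path, new_series = TRUE) {
  stopifnot(inherits(vol, "ct_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  stored <- (vol$intensities - vol$rescale_intercept) / vol$rescale_slope
  rng <- stored_value_range(vol$bits_stored, vol$pixel_representation)
  bad <- which(stored < rng[1] - 1e-6 | stored > rng[2] + 1e-6)
  if (length(bad)) {
    ijk <- arrayInd(bad[1], dim(vol$intensities))
    stop(sprintf(paste0(
      "write_dicom_series: HU value %g at voxel (k=%d, i=%d, j=%d) is not ",
      "representable as %d-bit %s stored values (HU ceiling %g); widen the ",
      "bit depth first"),
      vol$intensities[bad[1]], ijk[1], ijk[2], ijk[3],
      vol$bits_stored, vol$pixel_representation, hu_ceiling(vol)))
  }
  n_slices <- vol$geometry$shape[1]
  series_uid <- if (new_series && !is.null(vol$source_metadata)) new_uid()
                else vol$uids$series
  signed <- vol$pixel_representation == "signed"
  out <- character(n_slices)
  for (k in seq_len(n_slices)) {
    ds <- if (!is.null(vol$source_metadata)) vol$source_metadata[[k]]
          else synth_slice_dataset(vol, k)
    sop_uid <- new_uid()
    ds <- dcm_set(ds, 0x0008, 0x0018, "UI", dcm_bytes_ui(sop_uid))
    if (new_series && !is.null(vol$source_metadata))
      ds <- dcm_set(ds, 0x0020, 0x000E, "UI", dcm_bytes_ui(series_uid))
    ds <- dcm_set(ds, 0x0028, 0x0100, "US", dcm_bytes_us(16))
    ds <- dcm_set(ds, 0x0028, 0x0101, "US", dcm_bytes_us(vol$bits_stored))
    ds <- dcm_set(ds, 0x0028, 0x0102, "US", dcm_bytes_us(vol$bits_stored - 1L))
    ds <- dcm_set(ds, 0x0028, 0x0103, "US",
                  dcm_bytes_us(if (signed) 1 else 0))
    ds <- dcm_set(ds, 0x0028, 0x1052, "DS", dcm_bytes_ds(vol$rescale_intercept))
    ds <- dcm_set(ds, 0x0028, 0x1053, "DS", dcm_bytes_ds(vol$rescale_slope))
    slice_stored <- round(t(matrix(stored[k, , ],
                                   vol$geometry$shape[2], vol$geometry$shape[3])))
    ds <- dcm_set(ds, 0x7FE0, 0x0010, "OW",
                  dcm_bytes_pixels(as.vector(slice_stored), signed))
    out[k] <- file.path(path, sprintf("ct_%04d.dcm", k))
    dcm_write_file(out[k], ds, sop_uid)
  }
  invisible(out)
}
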