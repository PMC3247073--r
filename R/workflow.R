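#' Workflow configuration
#'
#' Collects every tunable of the marking workflow in one serializable
#' object; all values are logged into the run report so a run is fully
#' reproducible from its artifacts.
#'
#' @param sentinel_hu sentinel intensity written at marked voxels (HU);
#'   default 3500.
#' @param native_max_hu documented ceiling of unmodified CT data (HU);
#'   default 3100.
#' @param extraction_threshold_hu recovery threshold (HU); default 3200,
#'   strictly between the native ceiling and the sentinel.
#' @param rms_gate_mm registration acceptance gate (mm); default 0.8.
#' @param margin_mm resection margin for [augment_margin()] (mm); default 10.
#' @param interpolation `"trilinear"` or `"nearest"` for volume fusion.
#' @param seed integer; the single source for all randomness in a run.
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(sentinel_hu = 3500, native_max_hu = 3100,
                            extraction_threshold_hu = 3200,
                            rms_gate_mm = 0.8, margin_mm = 10,
                            interpolation = c("trilinear", "nearest"),
                            seed = 1L) {
  interpolation <- match.arg(interpolation)
  if (extraction_threshold_hu <= native_max_hu ||
      extraction_threshold_hu > sentinel_hu)
    stop("workflow_config: extraction threshold must lie in (native_max_hu, sentinel_hu]")
  policy <- encoding_policy(sentinel_hu, native_max_hu)  # validates ordering
  structure(list(sentinel_hu = policy$sentinel_hu,
                 native_max_hu = policy$max_native_hu,
                 extraction_threshold_hu = extraction_threshold_hu,
                 rms_gate_mm = rms_gate_mm, margin_mm = margin_mm,
                 interpolation = interpolation, seed = as.integer(seed)),
            class = "workflow_config")
}

#' Read / write a workflow configuration file (YAML)
#'
#' @param path file path.
#' @return `read_workflow_config` returns a [workflow_config()];
#'   `write_workflow_config` returns `path` invisibly.
#' @export
read_workflow_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(workflow_config, v)
}

#' @param config a [workflow_config()].
#' @rdname read_workflow_config
#' @export
write_workflow_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full marking workflow
#'
#' Executes the five-step pipeline on file inputs: read the CT series,
#' register the navigation frame to the image frame from the fiducial pairs,
#' apply the RMS acceptance gate, map the acquired points into the image
#' frame, select the tumor-positive points, encode them as sentinel voxels
#' and write the enhanced series plus a sidecar point table (voxel values
#' alone cannot carry names and sequence numbers). A machine-readable JSON
#' run report is written alongside.
#'
#' @param config a [workflow_config()].
#' @param series_dir directory with the input CT DICOM series.
#' @param fiducials_file fiducial pair table (see [read_fiducials()]).
#' @param points_file acquired point table in the navigation frame, with
#'   histology already classified (see [read_point_table()]).
#' @param out_dir output directory for the enhanced series, sidecar table
#'   and report.
#' @param force write outputs even if the registration gate fails; default
#'   `FALSE` (gate failure stops the run and writes nothing, mirroring the
#'   intraoperative rule that registration is redone on unacceptable
#'   discrepancies).
#' @return invisibly, the run report (class `endicom_report`): registration
#'   RMS, gate outcome, marked voxel count and output paths.
#' @export
run_workflow <- function(config, series_dir, fiducials_file, points_file,
                         out_dir, force = FALSE) {
  stopifnot(inherits(config, "workflow_config"))
  vol <- read_dicom_series(series_dir)
  fids <- read_fiducials(fiducials_file)
  cloud <- read_point_table(points_file)
  transform <- estimate_rigid(fids)
  gate <- registration_gate(transform, config$rms_gate_mm)
  if (!gate$pass && !force)
    stop(sprintf(paste0(
      "run_workflow: registration gate failed (RMS %.3g mm > %.3g mm); ",
      "re-register or pass force = TRUE"),
      gate$rms_error, gate$threshold_mm))
  if (cloud_frame(cloud) == "navigation")
    cloud <- to_image_frame(cloud, transform)
  selected <- select_malignant(cloud)
  policy <- encoding_policy(config$sentinel_hu, config$native_max_hu)
  marked <- endicom_encode(vol, selected, policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series_out <- file.path(out_dir, "endicom_series")
  write_dicom_series(marked, series_out)
  sidecar <- file.path(out_dir, "selected_points.csv")
  write_point_table(selected, sidecar)
  report <- structure(list(
    config = unclass(config),
    rms_error_mm = transform$rms_error,
    gate_passed = gate$pass,
    n_points_total = nrow(cloud),
    n_points_malignant = nrow(selected),
    n_voxels_marked = nrow(attr(marked, "marked_voxels")),
    series_dir = normalizePath(series_out),
    sidecar_table = normalizePath(sidecar)),
    class = "endicom_report")
  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.endicom_report <- function(x, ...) {
  cat("enDICOM run report\n")
  cat(sprintf("  registration RMS: %.4g mm (gate %s at %.3g mm)\n",
              x$rms_error_mm, if (x$gate_passed) "passed" else "FAILED",
              x$config$rms_gate_mm))
  cat(sprintf("  points: %d acquired, %d malignant, %d voxel(s) marked\n",
              x$n_points_total, x$n_points_malignant, x$n_voxels_marked))
  cat(sprintf("  enhanced series: %s\n", x$series_dir))
  invisible(x)
}
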