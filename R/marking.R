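#' Intraoperative landmark point cloud
#'
#' A `point_cloud` is a data frame of acquired landmarks — the locations
#' where frozen sections, biopsies or resection margins were taken — with
#' columns `sequence` (strictly increasing positive integers), `name`
#' (anatomic site), `x`, `y`, `z` (mm) and `histology`
#' (`"unknown"`, `"benign"` or `"malignant"`). The whole cloud lives in one
#' coordinate frame, `"navigation"` (tracker space, at acquisition) or
#' `"image"` (CT patient space), stored in the `frame` attribute.
#'
#' @param frame `"navigation"` (default) or `"image"`.
#' @return An empty `point_cloud` (also a `data.frame`).
#' @export
point_cloud <- function(frame = c("navigation", "image")) {
  frame <- match.arg(frame)
  df <- data.frame(sequence = integer(0), name = character(0),
                   x = numeric(0), y = numeric(0), z = numeric(0),
                   histology = character(0), stringsAsFactors = FALSE)
  structure(df, frame = frame, class = c("point_cloud", "data.frame"))
}

as_point_cloud <- function(df, frame) {
  histologies <- c("unknown", "benign", "malignant")
  if (!all(df$histology %in% histologies))
    stop("point_cloud: histology must be one of ",
         paste(histologies, collapse = ", "))
  if (anyDuplicated(df$sequence))
    stop("point_cloud: sequence numbers must be unique")
  if (is.unsorted(df$sequence, strictly = TRUE))
    stop("point_cloud: sequence numbers must be strictly increasing")
  if (any(df$sequence < 1))
    stop("point_cloud: sequence numbers must be positive")
  rownames(df) <- NULL
  structure(df, frame = frame, class = c("point_cloud", "data.frame"))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d acquired points (%s frame)\n",
              nrow(x), attr(x, "frame")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Coordinate frame of a point cloud
#' @param cloud a [point_cloud()].
#' @return `"navigation"` or `"image"`.
#' @export
cloud_frame <- function(cloud) attr(cloud, "frame")

cloud_positions <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

# strip the point_cloud class/attrs to get a plain data.frame
bare_df <- function(x) {
  attr(x, "frame") <- NULL
  class(x) <- "data.frame"
  x
}

#' Record an acquired landmark
#'
#' Appends a point at the pointer position with the next sequence number and
#' unknown histology; in practice each specimen is anatomically named and
#' sequentially numbered as it is taken.
#'
#' @param cloud a [point_cloud()] in the navigation frame.
#' @param name anatomic name of the specimen location.
#' @param position length-3 navigation-frame coordinate, mm.
#' @return the extended [point_cloud()].
#' @export
acquire_point <- function(cloud, name, position) {
  if (cloud_frame(cloud) != "navigation")
    stop("acquire_point: points are acquired in the navigation frame")
  position <- as.numeric(position)
  stopifnot(length(position) == 3, all(is.finite(position)))
  nxt <- if (nrow(cloud)) max(cloud$sequence) + 1L else 1L
  df <- rbind(bare_df(cloud),
              data.frame(sequence = nxt, name = as.character(name),
                         x = position[1], y = position[2], z = position[3],
                         histology = "unknown", stringsAsFactors = FALSE))
  as_point_cloud(df, "navigation")
}

#' Attach final histology results to acquired points
#'
#' After release of the final histological findings, each point is classified
#' benign or malignant; points without a released result stay unknown.
#'
#' @param cloud a [point_cloud()].
#' @param results named vector/list mapping sequence numbers (names) to
#'   `"benign"` or `"malignant"`.
#' @return the classified [point_cloud()].
#' @export
classify_points <- function(cloud, results) {
  if (length(results) == 0) return(cloud)
  seqs <- as.integer(names(results))
  vals <- as.character(unlist(results))
  if (any(is.na(seqs)))
    stop("classify_points: results must be named by sequence number")
  if (!all(vals %in% c("benign", "malignant")))
    stop("classify_points: results must be 'benign' or 'malignant'")
  missing <- setdiff(seqs, cloud$sequence)
  if (length(missing))
    stop("classify_points: unknown sequence number(s): ",
         paste(missing, collapse = ", "))
  df <- bare_df(cloud)
  df$histology[match(seqs, df$sequence)] <- vals
  as_point_cloud(df, cloud_frame(cloud))
}

#' Select the tumor-positive points for export
#'
#' Only points with confirmed malignant histology are carried into the
#' enhanced DICOM export; unknown histology is conservatively excluded
#' (an unconfirmed mark would corrupt radiotherapy planning). Original
#' sequence numbers are preserved.
#'
#' @param cloud a [point_cloud()].
#' @return the malignant sub-cloud.
#' @export
select_malignant <- function(cloud) {
  df <- bare_df(cloud)
  as_point_cloud(df[df$histology == "malignant", , drop = FALSE],
                 cloud_frame(cloud))
}

#' Map a navigation-frame cloud into the image frame
#'
#' @param cloud a [point_cloud()] in the navigation frame.
#' @param transform a [rigid_transform()] mapping navigation to image
#'   coordinates (from [estimate_rigid()]).
#' @return the [point_cloud()] with transformed positions, frame `"image"`.
#' @export
to_image_frame <- function(cloud, transform) {
  if (cloud_frame(cloud) == "image")
    stop("to_image_frame: cloud is already in the image frame")
  df <- bare_df(cloud)
  if (nrow(df)) {
    p <- apply_transform(transform, cloud_positions(cloud))
    df$x <- p[, 1]; df$y <- p[, 2]; df$z <- p[, 3]
  }
  as_point_cloud(df, "image")
}

#' Read / write a point-cloud table
#'
#' Flat delimited text (CSV) with header
#' `sequence, name, x, y, z, histology, frame`; the round trip is lossless.
#'
#' @param path file path.
#' @return `read_point_table` returns a [point_cloud()];
#'   `write_point_table` returns `path` invisibly.
#' @export
read_point_table <- function(path) {
  if (!file.exists(path)) stop("read_point_table: no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "name", "x", "y", "z", "histology", "frame")
  if (!all(need %in% names(df)))
    stop("read_point_table: header must contain: ", paste(need, collapse = ", "))
  frame <- unique(df$frame)
  if (nrow(df) == 0) frame <- "navigation"
  if (length(frame) != 1 || !frame %in% c("navigation", "image"))
    stop("read_point_table: frame column must be uniform ('navigation' or 'image')")
  df$frame <- NULL
  df$sequence <- as.integer(df$sequence)
  df$name <- as.character(df$name)
  as_point_cloud(df, frame)
}

#' @param cloud a [point_cloud()].
#' @rdname read_point_table
#' @export
write_point_table <- function(cloud, path) {
  df <- bare_df(cloud)
  df$frame <- rep(cloud_frame(cloud), nrow(df))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
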