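# Minimal DICOM part-10 element layer: explicit VR little endian only,
# single-frame objects, no sequences with undefined length. Enough to carry
# a CT series faithfully; networking, compression and multi-frame objects
# are deliberately out of scope.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_CT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.9.7484.1"
UID_ROOT <- "1.2.826.0.1.3680043.9.7484"

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.uid_env <- new.env(parent = emptyenv())
.uid_env$counter <- 0L

#' Generate a fresh DICOM unique identifier
#'
#' UIDs are derived from a private root plus process id, wall-clock time and
#' a monotone counter; independent of the R random number stream so writes
#' never perturb seeded analyses.
#'
#' @return character scalar, a DICOM UID of at most 64 characters.
#' @export
new_uid <- function() {
  .uid_env$counter <- .uid_env$counter + 1L
  paste(UID_ROOT, Sys.getpid(),
        gsub("\\D", "", format(Sys.time(), "%Y%m%d%H%M%S")),
        .uid_env$counter, sep = ".")
}

u16_raw <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, floor(x / 256) %% 256,
           floor(x / 65536) %% 256, floor(x / 16777216) %% 256))
}
raw_u16 <- function(r) as.integer(r[1]) + 256L * as.integer(r[2])
raw_u32 <- function(r) sum(as.numeric(r) * c(1, 256, 65536, 16777216))

dcm_element <- function(group, element, vr, bytes) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, bytes = bytes)
}

# value encoders ------------------------------------------------------------

dcm_bytes_str <- function(s, pad = " ") {
  b <- charToRaw(paste(s, collapse = "\\"))
  if (length(b) %% 2L == 1L) b <- c(b, charToRaw(pad))
  b
}
dcm_bytes_ui <- function(s) {
  b <- charToRaw(paste(s, collapse = "\\"))
  if (length(b) %% 2L == 1L) b <- c(b, as.raw(0))
  b
}
dcm_bytes_ds <- function(v) {
  s <- vapply(v, function(x) {
    for (digits in c(10, 8, 6)) {
      out <- sprintf("%.*g", digits, x)
      if (nchar(out) <= 16) return(out)
    }
    out
  }, character(1))
  dcm_bytes_str(s)
}
dcm_bytes_us <- function(v) do.call(c, lapply(as.integer(v), u16_raw))
dcm_bytes_pixels <- function(stored, signed) {
  stored <- as.numeric(stored)
  if (!signed) stored <- ifelse(stored >= 32768, stored - 65536, stored)
  writeBin(as.integer(round(stored)), raw(), size = 2, endian = "little")
}

# value decoders ------------------------------------------------------------

dcm_text <- function(el) {
  if (is.null(el)) return(NULL)
  b <- el$bytes
  # strip trailing NUL / space padding at the byte level (rawToChar rejects NUL)
  while (length(b) && (b[length(b)] == as.raw(0) || b[length(b)] == as.raw(32)))
    b <- b[-length(b)]
  rawToChar(b)
}
dcm_numbers <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_text(el), "\\", fixed = TRUE)[[1]])
}
dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  n <- length(el$bytes) %/% 2L
  vapply(seq_len(n), function(i) raw_u16(el$bytes[(2 * i - 1):(2 * i)]), 0L)
}

# element list helpers -------------------------------------------------------

dcm_find <- function(elements, group, element) {
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    if (e$group == group && e$element == element) return(i)
  }
  0L
}
dcm_get <- function(elements, group, element) {
  i <- dcm_find(elements, group, element)
  if (i == 0L) NULL else elements[[i]]
}
dcm_set <- function(elements, group, element, vr, bytes) {
  new <- dcm_element(group, element, vr, bytes)
  i <- dcm_find(elements, group, element)
  if (i > 0L) { elements[[i]] <- new; return(elements) }
  keys <- vapply(elements, function(e) e$group * 65536 + e$element, 0)
  pos <- sum(keys < group * 65536 + element)
  append(elements, list(new), after = pos)
}
dcm_drop <- function(elements, group, element) {
  i <- dcm_find(elements, group, element)
  if (i > 0L) elements[[i]] <- NULL
  elements
}

# serialization ---------------------------------------------------------------

dcm_encode_element <- function(el) {
  len <- length(el$bytes)
  if (el$vr %in% .long_vrs)
    c(u16_raw(el$group), u16_raw(el$element), charToRaw(el$vr),
      raw(2), u32_raw(len), el$bytes)
  else {
    if (len > 65535L)
      stop("dicom: value too long for short-form VR ", el$vr)
    c(u16_raw(el$group), u16_raw(el$element), charToRaw(el$vr),
      u16_raw(len), el$bytes)
  }
}

dcm_encode_elements <- function(elements) {
  do.call(c, lapply(elements, dcm_encode_element))
}

dcm_parse_elements <- function(raw, pos, end) {
  elements <- list()
  n <- 0L
  while (pos <= end) {
    if (pos + 7 > end + 1) stop("dicom: truncated element header")
    group <- raw_u16(raw[pos:(pos + 1)])
    element <- raw_u16(raw[(pos + 2):(pos + 3)])
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("dicom: invalid VR; only explicit-VR little-endian files are supported")
    if (vr %in% .long_vrs) {
      len <- raw_u32(raw[(pos + 8):(pos + 11)])
      pos <- pos + 12
    } else {
      len <- raw_u16(raw[(pos + 6):(pos + 7)])
      pos <- pos + 8
    }
    if (len == 4294967295)
      stop("dicom: undefined-length values (sequences) are not supported")
    if (pos + len - 1 > end + 0) {
      if (len > 0 && pos + len - 1 > length(raw))
        stop("dicom: truncated element value")
    }
    bytes <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    n <- n + 1L
    elements[[n]] <- dcm_element(group, element, vr, bytes)
  }
  elements
}

dcm_is_dicom_file <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$isdir || info$size < 140) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && identical(rawToChar(hdr[129:132]), "DICM")
}

dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || !identical(rawToChar(raw[129:132]), "DICM"))
    stop("dicom: not a DICOM part-10 file: ", path)
  # file meta group (always explicit VR LE): (0002,0000) UL group length
  if (raw_u16(raw[133:134]) != 2L || raw_u16(raw[135:136]) != 0L)
    stop("dicom: missing file meta group length: ", path)
  meta_len <- raw_u32(raw[141:144])
  meta_end <- 144 + meta_len
  meta <- dcm_parse_elements(raw, 145, meta_end)
  ts <- dcm_text(dcm_get(meta, 0x0002, 0x0010))
  if (!identical(ts, UID_EXPLICIT_VR_LE))
    stop("dicom: unsupported transfer syntax '", ts,
         "'; only explicit VR little endian (", UID_EXPLICIT_VR_LE,
         ") is supported")
  dataset <- dcm_parse_elements(raw, meta_end + 1, length(raw))
  list(meta = meta, dataset = dataset)
}

dcm_write_file <- function(path, dataset, sop_instance_uid,
                           sop_class_uid = UID_CT_IMAGE_STORAGE) {
  meta <- list(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", dcm_bytes_ui(sop_class_uid)),
    dcm_element(0x0002, 0x0003, "UI", dcm_bytes_ui(sop_instance_uid)),
    dcm_element(0x0002, 0x0010, "UI", dcm_bytes_ui(UID_EXPLICIT_VR_LE)),
    dcm_element(0x0002, 0x0012, "UI", dcm_bytes_ui(UID_IMPL_CLASS)))
  meta_bytes <- dcm_encode_elements(meta)
  meta_full <- c(
    dcm_encode_element(dcm_element(0x0002, 0x0000, "UL",
                                   u32_raw(length(meta_bytes)))),
    meta_bytes)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta_full, con)
  writeBin(dcm_encode_elements(dataset), con)
  invisible(path)
}
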