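#' Metadata schema
#'
#' The metadata table is a plain CSV with exactly these lower-case columns:
#' `filename, plate, well_row, well_col, site, channel, compound,
#' concentration, role, moa`.  `role` is one of `negative_control`,
#' `positive_control`, `sample`.
#'
#' @name metadata-schema
#' @keywords internal
NULL

metadata_columns <- c(
  "filename", "plate", "well_row", "well_col", "site", "channel",
  "compound", "concentration", "role", "moa"
)

image_roles <- c("negative_control", "positive_control", "sample")

image_key_cols <- c("plate", "well_row", "well_col", "site", "channel")

#' Read an image-set metadata table
#'
#' Parses the metadata CSV describing a multi-plate, multi-well, multi-site,
#' multi-channel collection of single-channel images and validates it against
#' the schema: required columns present, `(plate, well_row, well_col, site,
#' channel)` unique, and every referenced image file present on disk.
#'
#' @param metadata_path Path to the metadata CSV (see [metadata-schema]).
#' @param image_root Directory that `filename` entries are relative to.
#'   Defaults to the directory containing the metadata file.
#' @param check_files Verify that each referenced image exists (default TRUE).
#' @return A tibble of image records, one row per image, in table order, with
#'   derived columns `well` (e.g. `"A01"`) and `path` (resolved file path),
#'   carrying the image root in attribute `"image_root"`.
#' @examples
#' \dontrun{
#' images <- read_image_set("plate1/metadata.csv")
#' }
#' @export
read_image_set <- function(metadata_path, image_root = dirname(metadata_path),
                           check_files = TRUE) {
  if (!file.exists(metadata_path)) {
    stop_io(paste0("metadata file not found: ", metadata_path))
  }
  records <- readr::read_csv(metadata_path, show_col_types = FALSE,
                             progress = FALSE)
  missing <- setdiff(metadata_columns, names(records))
  if (length(missing) > 0) {
    stop_config(paste0("metadata is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  records <- dplyr::mutate(
    records,
    plate = as.character(.data$plate),
    well_row = as.character(.data$well_row),
    well_col = as.integer(.data$well_col),
    site = as.integer(.data$site),
    channel = as.character(.data$channel),
    compound = as.character(.data$compound),
    concentration = as.numeric(.data$concentration),
    role = as.character(.data$role),
    moa = as.character(.data$moa)
  )
  as_image_set(records, image_root, check_files = check_files)
}

#' Build an image set from an in-memory record table
#'
#' @param records Data frame with the columns of [metadata-schema].
#' @param image_root Directory that `filename` entries are relative to.
#' @param check_files Verify that referenced files exist.
#' @return A validated image-set tibble (see [read_image_set()]).
#' @export
as_image_set <- function(records, image_root, check_files = TRUE) {
  records <- as_tibble(records)
  missing <- setdiff(metadata_columns, names(records))
  if (length(missing) > 0) {
    stop_config(paste0("records are missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  bad_role <- setdiff(unique(records$role), image_roles)
  if (length(bad_role) > 0) {
    stop_data(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  dup <- dplyr::count(records, !!!rlang::syms(image_key_cols)) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    keys <- apply(dup[image_key_cols], 1, paste, collapse = "/")
    stop_data(paste0("duplicate (plate, well, site, channel) record(s): ",
                     paste(keys, collapse = "; ")))
  }
  records$well <- sprintf("%s%02d", records$well_row, records$well_col)
  records$path <- file.path(image_root, records$filename)
  if (check_files) {
    absent <- records$path[!file.exists(records$path)]
    if (length(absent) > 0) {
      stop_io(paste0("image file(s) not found: ",
                     paste(head(absent, 5), collapse = ", "),
                     if (length(absent) > 5) sprintf(" (+%d more)", length(absent) - 5) else ""))
    }
  }
  attr(records, "image_root") <- image_root
  records
}

#' Write an image set's metadata table
#'
#' @param images Image-set tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_image_set <- function(images, path) {
  readr::write_csv(images[metadata_columns], path, progress = FALSE)
  invisible(path)
}

#' Load a single-channel image
#'
#' Reads a single-plane grayscale TIFF into a numeric matrix in native
#' intensity units: integer samples are returned as their stored values (a
#' 16-bit value 4095 stays 4095), 32-bit float samples are returned as
#' stored.  No rescaling to \[0, 1\] happens anywhere in the pipeline.
#'
#' @param x An image record (one-row data frame with a `path` column) or a
#'   file path.
#' @return Numeric matrix of non-negative intensities.
#' @export
load_image <- function(x) {
  path <- if (is.data.frame(x)) {
    if (nrow(x) != 1) stop_value("load_image() expects a single record")
    x$path
  } else {
    x
  }
  if (!file.exists(path)) stop_io(paste0("image file not found: ", path))
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop_io(paste0("unreadable TIFF: ", path,
                                                      " (", conditionMessage(e), ")")))
  if (is.data.frame(info)) info <- as.list(info[1, ])
  if (!is.null(info$samples.per.pixel) && info$samples.per.pixel > 1) {
    stop_data(paste0("expected a single-channel image, got ",
                     info$samples.per.pixel, " samples per pixel: ", path))
  }
  is_float <- identical(info$sample.format, "float")
  pixels <- if (is_float) {
    tiff::readTIFF(path)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(pixels)) == 3) {
    if (dim(pixels)[3] != 1) {
      stop_data(paste0("expected a single-channel image, got ",
                       dim(pixels)[3], " channels: ", path))
    }
    pixels <- pixels[, , 1]
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop_data(paste0("non-finite pixel values in ", path))
  }
  if (any(pixels < 0)) {
    stop_data(paste0("negative pixel values in ", path))
  }
  pixels
}

#' Write an image as TIFF
#'
#' Integer depths (8/16 bit) round and clamp to the sample range; 32-bit
#' output is IEEE float in native units (single strip, uncompressed), the
#' format used for ICFs and corrected images so that downstream readouts are
#' not re-quantized.
#'
#' @param pixels Numeric matrix.
#' @param path Output path.
#' @param bits One of 8, 16 (integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(pixels, path, bits = 16) {
  if (!is.matrix(pixels)) stop_value("pixels must be a matrix")
  if (bits == 32) return(write_float_tiff(pixels, path))
  if (!bits %in% c(8, 16)) stop_value("bits must be 8, 16 or 32")
  top <- 2^bits - 1
  v <- pmin(pmax(round(pixels), 0), top)
  tiff::writeTIFF(v / top, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# Minimal single-strip uncompressed 32-bit float grayscale TIFF writer
# (little-endian, SampleFormat = IEEE float).  Written because no installed
# TIFF writer emits float samples; readable by libtiff and any viewer.
write_float_tiff <- function(pixels, path) {
  h <- nrow(pixels)
  w <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  n_entries <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(n_entries, con, size = 2, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entry(256, 4, 1, w)             # ImageWidth
  entry(257, 4, 1, h)             # ImageLength
  entry(258, 3, 1, 32)            # BitsPerSample
  entry(259, 3, 1, 1)             # Compression: none
  entry(262, 3, 1, 1)             # Photometric: black is zero
  entry(273, 4, 1, data_offset)   # StripOffsets
  entry(277, 3, 1, 1)             # SamplesPerPixel
  entry(278, 4, 1, h)             # RowsPerStrip
  entry(279, 4, 1, h * w * 4L)    # StripByteCounts
  entry(339, 3, 1, 3)             # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.numeric(t(pixels)), con, size = 4, endian = "little")
  invisible(path)
}

icf_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Persist an ICF to disk
#'
#' Writes the correction function as a 32-bit float TIFF (inspectable in any
#' image viewer, as recommended practice for ICF review) plus a JSON sidecar
#' carrying its provenance: grouping key and value, channel, median window,
#' number of contributing images, rescaling convention and creation time.
#'
#' @param icf An `illum_icf` object from [estimate_icf()] or [new_icf()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @seealso [read_icf()]
#' @export
persist_icf <- function(icf, path) {
  validate_icf(icf)
  write_float_tiff(icf$pixels, path)
  sidecar <- list(
    group_key = icf$group_key,
    group_value = icf$group_value,
    channel = icf$channel,
    window_px = icf$window_px,
    n_images = icf$n_images,
    rescale = "min_one",
    created_utc = icf$created_utc,
    software = paste0("illumfield ", as.character(utils::packageVersion("illumfield")))
  )
  jsonlite::write_json(sidecar, icf_sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a persisted ICF
#'
#' @param path Path to the ICF float TIFF written by [persist_icf()].
#' @return An `illum_icf` object; pixel values round-trip bit-exactly at
#'   32-bit float precision.
#' @export
read_icf <- function(path) {
  sidecar_path <- icf_sidecar_path(path)
  if (!file.exists(sidecar_path)) {
    stop_data(paste0("ICF sidecar not found: ", sidecar_path))
  }
  meta <- tryCatch(jsonlite::read_json(sidecar_path),
                   error = function(e) stop_data(paste0("corrupt ICF sidecar: ",
                                                        sidecar_path)))
  needed <- c("group_key", "group_value", "channel", "window_px", "n_images")
  if (!all(needed %in% names(meta))) {
    stop_data(paste0("ICF sidecar missing field(s): ",
                     paste(setdiff(needed, names(meta)), collapse = ", ")))
  }
  pixels <- load_image(path)
  new_icf(pixels,
          channel = meta$channel,
          group_key = meta$group_key,
          group_value = meta$group_value,
          window_px = as.integer(meta$window_px),
          n_images = as.integer(meta$n_images),
          created_utc = meta$created_utc %||% NA_character_)
}
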