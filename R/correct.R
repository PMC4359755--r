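#' Correct a single image by an ICF
#'
#' Pixelwise division of the image by the (min-one rescaled) correction
#' function.  Because the ICF minimum is 1 the output never exceeds the
#' input maximum, so no clipping is applied and values stay in native units.
#'
#' @param image Numeric matrix.
#' @param icf An `illum_icf` object, or a positive matrix with minimum 1.
#' @return Corrected numeric matrix.
#' @export
correct_image <- function(image, icf) {
  px <- if (inherits(icf, "illum_icf")) icf$pixels else icf
  if (!identical(dim(image), dim(px))) {
    stop_data(sprintf("image shape %dx%d does not match ICF shape %dx%d",
                      nrow(image), ncol(image), nrow(px), ncol(px)))
  }
  if (abs(min(px) - 1) > 1e-6) {
    stop_value("ICF is not rescaled to min 1; run rescale_icf() first")
  }
  image / px
}

#' Correct a whole image set
#'
#' Divides every image by the ICF of its (group, channel), writes the result
#' as 32-bit float TIFF (no re-quantization) under `out_dir`, mirrors the
#' metadata table with updated filenames, and returns the corrected set.
#'
#' @param images Image-set tibble.
#' @param icfs Named list of `illum_icf` objects as returned by
#'   [estimate_icfs()] (keys `"<group_value>/<channel>"`).
#' @param grouping Grouping key the ICFs were estimated under.
#' @param out_dir Output directory (created if needed).
#' @return The corrected image-set tibble rooted at `out_dir`.
#' @export
correct_batch <- function(images, icfs, grouping = "plate", out_dir) {
  grouping <- match.arg(grouping, grouping_keys)
  gv <- group_value_of(images, grouping)
  needed <- unique(paste0(gv, "/", images$channel))
  missing <- setdiff(needed, names(icfs))
  if (length(missing) > 0) {
    stop_config(paste0("no ICF for group/channel: ", paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- images
  new_names <- paste0(tools::file_path_sans_ext(basename(images$filename)), ".tiff")
  for (i in seq_len(nrow(images))) {
    icf <- icfs[[paste0(gv[i], "/", images$channel[i])]]
    corrected <- correct_image(load_image(images[i, ]), icf)
    write_float_tiff(corrected, file.path(out_dir, new_names[i]))
  }
  out$filename <- new_names
  write_image_set(out, file.path(out_dir, "metadata.csv"))
  read_image_set(file.path(out_dir, "metadata.csv"), out_dir)
}
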