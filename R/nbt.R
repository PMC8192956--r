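#' Quantify NBT-formazan staining in a masked micrograph
#'
#' Converts the image to 8-bit gray (luminance weights 0.299/0.587/0.114 for
#' RGB input), averages the gray level over the tissue mask, and normalizes
#' against a reference gray level:
#' `stain_index = (255 - mean_gray) / (255 - reference_mean)`, so the
#' reference tissue scores 1 and darker tissue (more formazan, i.e. more
#' reactive oxygen species) scores > 1. The raw mean gray value is always
#' reported alongside the index.
#'
#' @param image Numeric matrix (gray) or rows x cols x 3 array (RGB). Values
#'   may be on the 0-255 or 0-1 scale (0-1 input is rescaled).
#' @param mask Logical or 0/1 matrix; nonzero marks tissue. Must select at
#'   least one pixel.
#' @param reference_mean Mean gray level of the reference group, < 255.
#' @param specimen_id Identifier carried into the output row.
#' @return A tibble row: `specimen_id`, `mean_gray`, `stain_index`,
#'   `n_pixels`.
#' @export
quantify_staining <- function(image, mask, reference_mean,
                              specimen_id = NA_character_) {
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] < 3) {
      vs_abort("RGB image must have 3 channels", "valvespectra_value_error")
    }
    gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    gray <- as.matrix(image)
  }
  if (max(gray) <= 1) gray <- gray * 255
  mask <- as.matrix(mask) != 0
  if (!any(mask)) vs_abort("mask selects no pixels", "valvespectra_mask_error")
  if (any(dim(mask) != dim(gray))) {
    vs_abort("mask and image dimensions differ", "valvespectra_mask_error")
  }
  if (reference_mean >= 255) {
    vs_abort("reference_mean must be < 255", "valvespectra_degenerate_reference_error")
  }
  mg <- mean(gray[mask])
  tibble::tibble(specimen_id = as.character(specimen_id),
                 mean_gray = mg,
                 stain_index = (255 - mg) / (255 - reference_mean),
                 n_pixels = sum(mask))
}

#' Group summary of staining measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1) of the stain index
#' and raw mean gray per group; the SD of a single-member group is `NA`.
#'
#' @param measurements Tibble from [quantify_staining()] rows.
#' @param groups Group label per measurement.
#' @return Tibble: `group`, `n`, `mean_stain_index`, `sd_stain_index`,
#'   `mean_gray`, `sd_gray`.
#' @export
summarize_staining <- function(measurements, groups) {
  groups <- as.character(groups)
  if (nrow(measurements) != length(groups)) {
    vs_abort("one group label per measurement required",
             "valvespectra_precondition_error")
  }
  out <- lapply(unique(groups), function(g) {
    sub <- measurements[groups == g, , drop = FALSE]
    tibble::tibble(group = g, n = nrow(sub),
                   mean_stain_index = mean(sub$stain_index),
                   sd_stain_index = if (nrow(sub) > 1) sd(sub$stain_index) else NA_real_,
                   mean_gray = mean(sub$mean_gray),
                   sd_gray = if (nrow(sub) > 1) sd(sub$mean_gray) else NA_real_)
  })
  do.call(rbind, out)
}

#' Read an image file as a matrix or array
#'
#' Thin reader for PNG micrograph/mask files (requires the `png` package).
#' Returned values are on the 0-1 scale as read.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix (gray) or array (RGB/RGBA).
#' @export
read_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    vs_abort("reading PNG files requires the 'png' package",
             "valvespectra_format_error")
  }
  if (!file.exists(path)) {
    vs_abort(sprintf("file not found: %s", path), "valvespectra_format_error")
  }
  png::readPNG(path)
}
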