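#' Construct a tumor region-of-interest image
#'
#' The basic image container of the pipeline: a 2D intensity matrix, a binary
#' tumor mask of the same shape, and provenance metadata. All texture features
#' are computed from masked pixels only; any nonzero mask value counts as
#' foreground.
#'
#' @param pixels Numeric matrix of finite intensities (rows = image height).
#' @param mask Logical or numeric matrix of the same shape; nonzero/`TRUE`
#'   marks tumor pixels. Must contain at least 16 foreground pixels, the
#'   minimum needed to populate co-occurrence and run-length matrices.
#' @param subject_id Character scalar identifying the subject.
#' @param pixel_spacing Optional mm-per-pixel scalar (carried, not used by
#'   texture code).
#'
#' @return An object of class `roi_image`: a list with elements `pixels`,
#'   `mask`, `subject_id`, `pixel_spacing`.
#' @export
roi_image <- function(pixels, mask, subject_id = "subject", pixel_spacing = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) {
    abort("`pixels` must be finite everywhere.", class = "radiotex_invalid_roi")
  }
  mask <- as.matrix(mask) != 0
  if (!identical(dim(pixels), dim(mask))) {
    abort(
      sprintf(
        "Image (%d x %d) and mask (%d x %d) shapes differ.",
        nrow(pixels), ncol(pixels), nrow(mask), ncol(mask)
      ),
      class = "radiotex_shape_mismatch"
    )
  }
  if (sum(mask) == 0) {
    abort(sprintf("Subject '%s': mask is empty (no foreground pixels).", subject_id),
          class = "radiotex_empty_mask")
  }
  if (sum(mask) < 16) {
    abort(
      sprintf("Subject '%s': mask has %d foreground pixels; at least 16 are required.",
              subject_id, sum(mask)),
      class = "radiotex_degenerate_roi"
    )
  }
  structure(
    list(
      pixels = pixels, mask = mask,
      subject_id = as.character(subject_id)[1],
      pixel_spacing = pixel_spacing
    ),
    class = "roi_image"
  )
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf(
    "<roi_image> subject '%s': %d x %d pixels, %d in mask, intensity [%.4g, %.4g]\n",
    x$subject_id, nrow(x$pixels), ncol(x$pixels), sum(x$mask),
    min(x$pixels[x$mask]), max(x$pixels[x$mask])
  ))
  invisible(x)
}

read_gray_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "radiotex_io_error")
  }
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    a <- tryCatch(png::readPNG(path), error = function(e) {
      abort(sprintf("Unreadable PNG '%s': %s", path, conditionMessage(e)),
            class = "radiotex_io_error")
    })
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("TIFF support requires the 'tiff' package.", class = "radiotex_io_error")
    }
    a <- tryCatch(tiff::readTIFF(path), error = function(e) {
      abort(sprintf("Unreadable TIFF '%s': %s", path, conditionMessage(e)),
            class = "radiotex_io_error")
    })
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    a <- tryCatch(as.array(RNifti::readNifti(path)), error = function(e) {
      abort(sprintf("Unreadable NIfTI '%s': %s", path, conditionMessage(e)),
            class = "radiotex_io_error")
    })
    a <- drop(a)
  } else {
    abort(sprintf("Unsupported image format: %s", path), class = "radiotex_io_error")
  }
  if (length(dim(a)) == 3L) a <- a[, , 1L]  # first channel of gray+alpha PNGs
  if (length(dim(a)) != 2L) {
    abort(sprintf("'%s' is not a single 2D slice.", path), class = "radiotex_io_error")
  }
  # strip any format-specific attributes (e.g. NIfTI pixdim/pixunits)
  matrix(as.double(a), nrow(a), ncol(a))
}

#' Read an image/mask pair from disk
#'
#' Supports 8/16-bit grayscale PNG and TIFF and single-slice NIfTI
#' (`.nii`/`.nii.gz`). The mask is binarized at > 0.
#'
#' @param image_path,mask_path Paths to the intensity image and its mask.
#' @inheritParams roi_image
#' @return A [roi_image()].
#' @export
read_roi <- function(image_path, mask_path, subject_id = "subject",
                     pixel_spacing = NULL) {
  px <- read_gray_matrix(image_path)
  mk <- read_gray_matrix(mask_path)
  roi_image(px, mk, subject_id = subject_id, pixel_spacing = pixel_spacing)
}

#' Write an ROI to disk as a 16-bit grayscale PNG pair
#'
#' Intensities are min-max scaled to the 16-bit range over the whole canvas.
#'
#' @param roi A [roi_image()].
#' @param image_path,mask_path Output PNG paths.
#' @return Invisibly, the two paths.
#' @export
write_roi_png <- function(roi, image_path, mask_path) {
  rng <- range(roi$pixels)
  px <- if (diff(rng) > 0) (roi$pixels - rng[1]) / diff(rng) else roi$pixels * 0
  png_write_gray16(px, image_path)
  png::writePNG(roi$mask * 1, mask_path)
  invisible(c(image_path, mask_path))
}

#' Normalize ROI intensities to [0, 1]
#'
#' Masked intensities are min-max mapped to \[0, 1\] using the masked minimum
#' and maximum; pixels outside the mask are set to 0. A constant masked region
#' maps to all zeros with a warning. Normalization is idempotent and invariant
#' to positive affine transforms of the input intensities, which makes every
#' downstream gray-level-matrix feature intensity-scale free.
#'
#' @param roi A [roi_image()].
#' @return A normalized [roi_image()].
#' @export
normalize_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi$pixels[roi$mask]
  out <- matrix(0, nrow(roi$pixels), ncol(roi$pixels))
  rng <- range(v)
  if (diff(rng) == 0) {
    warn(sprintf(
      "Subject '%s': constant masked intensity (%.4g); normalized to all zeros.",
      roi$subject_id, rng[1]
    ))
  } else {
    out[roi$mask] <- (v - rng[1]) / diff(rng)
  }
  roi$pixels <- out
  roi
}

#' Quantize a normalized ROI to discrete gray levels
#'
#' Equal-width binning of \[0, 1\] into `n_levels` bins; the value 1.0 falls in
#' the top level. Masked pixels get levels `1..n_levels`; everything outside
#' the mask is level 0 and excluded from all statistics.
#'
#' @param roi A normalized [roi_image()] (see [normalize_roi()]).
#' @param n_levels Integer >= 2, number of gray levels. The default of 32
#'   keeps co-occurrence matrices populated for small-animal-cohort ROIs.
#' @return An object of class `quantized_image`: list with `levels` (integer
#'   matrix), `mask`, `n_levels`, `subject_id`.
#' @export
quantize <- function(roi, n_levels = 32L) {
  stopifnot(inherits(roi, "roi_image"))
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) {
    abort("`n_levels` must be an integer >= 2.", class = "radiotex_config_error")
  }
  lev <- matrix(0L, nrow(roi$pixels), ncol(roi$pixels))
  v <- roi$pixels[roi$mask]
  if (any(v < 0 | v > 1)) {
    abort("quantize() expects a normalized ROI with intensities in [0, 1].",
          class = "radiotex_config_error")
  }
  lev[roi$mask] <- pmin(n_levels, as.integer(floor(v * n_levels)) + 1L)
  structure(
    list(levels = lev, mask = roi$mask, n_levels = n_levels,
         subject_id = roi$subject_id),
    class = "quantized_image"
  )
}
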