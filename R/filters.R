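#' Sobel gradient-magnitude image
#'
#' Per-pixel gradient magnitude `sqrt(Gx^2 + Gy^2)` from 3x3 Sobel operators
#' with reflect padding. The mask is eroded by one pixel so that no retained
#' pixel's stencil crosses the ROI boundary.
#'
#' @param roi A normalized [roi_image()].
#' @return A [roi_image()] holding the gradient magnitude with the eroded mask.
#' @export
gradient_image <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- conv3(roi$pixels, kx)
  gy <- conv3(roi$pixels, ky)
  mag <- sqrt(gx^2 + gy^2)
  m <- erode3(roi$mask)
  if (sum(m) < 16) {
    abort(
      sprintf("Subject '%s': mask shrank below 16 pixels after 1-px erosion.",
              roi$subject_id),
      class = "radiotex_degenerate_roi"
    )
  }
  mag[!m] <- 0
  structure(
    list(pixels = mag, mask = m, subject_id = roi$subject_id,
         pixel_spacing = roi$pixel_spacing),
    class = "roi_image"
  )
}

sobel_gradients <- function(pixels) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = conv3(pixels, kx), gy = conv3(pixels, t(kx)))
}

pad_to_even <- function(m) {
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  m
}

#' Single-level 2D orthonormal Haar wavelet decomposition
#'
#' Each non-overlapping 2x2 block `(a b / c d)` maps to approximate
#' `(a+b+c+d)/2`, horizontal detail `(a+b-c-d)/2` (responds to horizontal
#' edges / vertical intensity change), vertical detail `(a-b+c-d)/2`, and
#' diagonal detail `(a-b-c+d)/2`. The 1/2 factor makes the transform
#' orthonormal, so the summed squared coefficients over all four bands equal
#' the summed squared (padded) input pixels exactly. Odd dimensions are
#' symmetric-padded (edge replication) to even before the transform. Each
#' band carries the input mask downsampled over 2x2 blocks.
#'
#' @param roi A normalized [roi_image()].
#' @param mask_rule `"or"` (default) keeps a band pixel when any of its four
#'   source pixels is masked, retaining boundary texture; `"and"` requires all
#'   four.
#' @return An object of class `wavelet_bands`: list of four [roi_image()]s
#'   named `approximate`, `horizontal`, `vertical`, `diagonal`, plus the
#'   padded input under `padded`.
#' @export
haar_dwt <- function(roi, mask_rule = c("or", "and")) {
  stopifnot(inherits(roi, "roi_image"))
  mask_rule <- match.arg(mask_rule)
  px <- pad_to_even(roi$pixels)
  mk <- pad_to_even(roi$mask)
  ro <- seq(1L, nrow(px), by = 2L)
  co <- seq(1L, ncol(px), by = 2L)
  a <- px[ro, co, drop = FALSE]
  b <- px[ro, co + 1L, drop = FALSE]
  cc <- px[ro + 1L, co, drop = FALSE]
  d <- px[ro + 1L, co + 1L, drop = FALSE]
  comb <- if (mask_rule == "or") `|` else `&`
  m <- comb(comb(mk[ro, co, drop = FALSE], mk[ro, co + 1L, drop = FALSE]),
            comb(mk[ro + 1L, co, drop = FALSE], mk[ro + 1L, co + 1L, drop = FALSE]))
  band <- function(v) {
    structure(
      list(pixels = v, mask = m, subject_id = roi$subject_id,
           pixel_spacing = roi$pixel_spacing),
      class = "roi_image"
    )
  }
  structure(
    list(
      approximate = band((a + b + cc + d) / 2),
      horizontal  = band((a + b - cc - d) / 2),
      vertical    = band((a - b + cc - d) / 2),
      diagonal    = band((a - b - cc + d) / 2),
      padded = px
    ),
    class = "wavelet_bands"
  )
}

#' Invert a single-level Haar decomposition
#'
#' Reconstructs the (padded) input image from the four sub-bands; with the
#' orthonormal normalization the round trip is exact to machine precision.
#'
#' @param bands A `wavelet_bands` object from [haar_dwt()].
#' @return The reconstructed padded image matrix.
#' @export
haar_idwt <- function(bands) {
  stopifnot(inherits(bands, "wavelet_bands"))
  A <- bands$approximate$pixels
  H <- bands$horizontal$pixels
  V <- bands$vertical$pixels
  D <- bands$diagonal$pixels
  out <- matrix(0, 2L * nrow(A), 2L * ncol(A))
  ro <- seq(1L, nrow(out), by = 2L)
  co <- seq(1L, ncol(out), by = 2L)
  out[ro, co]           <- (A + H + V + D) / 2
  out[ro, co + 1L]      <- (A + H - V - D) / 2
  out[ro + 1L, co]      <- (A - H + V - D) / 2
  out[ro + 1L, co + 1L] <- (A - H - V + D) / 2
  out
}

#' Global histogram of oriented gradients
#'
#' Sobel gradients are computed on the eroded mask; each pixel votes with its
#' gradient magnitude for its unsigned orientation (atan2 folded to
#' \[0, 180) degrees), the vote split linearly between the two nearest of 9
#' bins centered at 10, 30, ..., 170 degrees (wrapping across 0/180). The
#' histogram is normalized to sum 1; an all-zero gradient field yields the
#' uniform histogram with a warning.
#'
#' @param roi A normalized [roi_image()].
#' @return A tibble with columns `bin_center` (degrees) and `value`
#'   (9 rows, values summing to 1).
#' @export
hog_histogram <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  g <- sobel_gradients(roi$pixels)
  m <- erode3(roi$mask)
  if (sum(m) < 16) {
    abort(sprintf("Subject '%s': mask too small for gradient features.",
                  roi$subject_id),
          class = "radiotex_degenerate_roi")
  }
  gx <- g$gx[m]
  gy <- g$gy[m]
  mag <- sqrt(gx^2 + gy^2)
  centers <- seq(10, 170, by = 20)
  if (sum(mag) == 0) {
    warn(sprintf("Subject '%s': all gradients zero; uniform orientation histogram.",
                 roi$subject_id))
    return(tibble::tibble(bin_center = centers, value = rep(1 / 9, 9)))
  }
  theta <- (atan2(gy, gx) * 180 / pi) %% 180
  # linear vote split between the two nearest bin centers, wrapping at 180
  pos <- (theta - 10) / 20          # fractional bin index from center 10
  lo <- floor(pos)
  frac <- pos - lo
  lo_bin <- (as.integer(lo) %% 9L) + 1L
  hi_bin <- (lo_bin %% 9L) + 1L
  h <- vapply(1:9, function(b) {
    sum(mag[lo_bin == b] * (1 - frac[lo_bin == b])) + sum(mag[hi_bin == b] * frac[hi_bin == b])
  }, numeric(1))
  tibble::tibble(bin_center = centers, value = h / sum(h))
}
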