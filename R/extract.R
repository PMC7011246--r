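# Assembly of the canonical 152-feature vector.
#
# Inventory structure (152 = 39 + 21 + 4*22 + 4):
#   base : fos 4 + glcm 6 + glrm 11 + lbp 10 + fractal 2 + shape 6 = 39
#   grad : fos 4 + glcm 6 + glrm 11                               = 21
#   wav_a/wav_h/wav_v/wav_d : power 1 + fos 4 + glcm 6 + glrm 11  = 22 each
#   hog  : fos 4
# The per-family feature sets (FoS = {mean, variance, skewness, entropy},
# GLCM = {contrast, correlation, energy, homogeneity, entropy, dissimilarity})
# are a documented reconstruction: they are the unique small family sizes
# consistent with the stated structure and the named features, and the
# inventory is frozen (names, order, count) across releases.

fos_names <- c("mean", "variance", "skewness", "entropy")
glcm_names <- c("contrast", "correlation", "energy", "homogeneity", "entropy",
                "dissimilarity")
glrm_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge",
                "srhge", "lrlge", "lrhge")
lbp_names <- c(paste0("riu2_", 0:8), "riu2_nonuniform")
fractal_names <- c("fd", "lacunarity")
shape_names <- c("area", "perimeter", "circularity", "eccentricity",
                 "solidity", "extent")

#' The frozen canonical feature inventory
#'
#' @return Character vector of the 152 feature names in canonical order,
#'   using the grammar `<source>.<family>.<feature>` with sources `base`,
#'   `grad`, `wav_a`/`wav_h`/`wav_v`/`wav_d` (Haar approximate / horizontal /
#'   vertical / diagonal sub-bands) and `hog`.
#' @export
feature_inventory <- function() {
  nm <- function(src, fam, feats) paste(src, fam, feats, sep = ".")
  c(
    nm("base", "fos", fos_names),
    nm("base", "glcm", glcm_names),
    nm("base", "glrm", glrm_names),
    nm("base", "lbp", lbp_names),
    nm("base", "fractal", fractal_names),
    nm("base", "shape", shape_names),
    nm("grad", "fos", fos_names),
    nm("grad", "glcm", glcm_names),
    nm("grad", "glrm", glrm_names),
    unlist(lapply(c("wav_a", "wav_h", "wav_v", "wav_d"), function(src) {
      c(nm(src, "power", "mean_square"),
        nm(src, "fos", fos_names),
        nm(src, "glcm", glcm_names),
        nm(src, "glrm", glrm_names))
    }), use.names = FALSE),
    nm("hog", "fos", fos_names)
  )
}

matrix_family_block <- function(img, n_levels) {
  # re-normalize the derived image over its own mask, then quantize
  q <- quantize(suppressWarnings(normalize_roi(img)), n_levels)
  c(
    setNames(glcm_features(glcm_matrix(q)), paste0("glcm.", glcm_names)),
    setNames(glrm_features(q), paste0("glrm.", glrm_names))
  )
}

extract_vector <- function(roi, n_levels = 32L) {
  stopifnot(inherits(roi, "roi_image"))
  norm <- suppressWarnings(normalize_roi(roi))
  out <- c()
  add <- function(src, vals) setNames(vals, paste(src, names(vals), sep = "."))

  step <- function(src, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        sprintf("Feature extraction failed for subject '%s' at source '%s': %s",
                roi$subject_id, src, conditionMessage(e)),
        class = "radiotex_extraction_error"
      )
    })
  }

  out <- c(out, step("base", {
    c(
      # base FoS on the raw intensities: mean/variance deliberately keep the
      # input scale; every matrix-based family goes through normalize+quantize
      add("base", setNames(fos(roi$pixels[roi$mask]), paste0("fos.", fos_names))),
      add("base", matrix_family_block(norm, n_levels)),
      add("base", setNames(lbp_features(norm), paste0("lbp.", lbp_names))),
      add("base", setNames(fractal_features(norm), paste0("fractal.", fractal_names))),
      add("base", setNames(shape_features(norm$mask), paste0("shape.", shape_names)))
    )
  }))

  out <- c(out, step("grad", {
    g <- gradient_image(norm)
    c(
      add("grad", setNames(fos(g$pixels[g$mask]), paste0("fos.", fos_names))),
      add("grad", matrix_family_block(g, n_levels))
    )
  }))

  out <- c(out, step("wavelet", {
    bands <- haar_dwt(norm)
    res <- c()
    band_src <- c(wav_a = "approximate", wav_h = "horizontal",
                  wav_v = "vertical", wav_d = "diagonal")
    for (src in names(band_src)) {
      band <- bands[[band_src[[src]]]]
      coefs <- band$pixels[band$mask]
      res <- c(
        res,
        add(src, c(power.mean_square = mean(coefs^2))),
        add(src, setNames(fos(coefs), paste0("fos.", fos_names))),
        add(src, matrix_family_block(band, n_levels))
      )
    }
    res
  }))

  out <- c(out, step("hog", {
    h <- hog_histogram(norm)
    add("hog", setNames(fos(h$value), paste0("fos.", fos_names)))
  }))

  inv <- feature_inventory()
  stopifnot(setequal(names(out), inv))
  out <- out[inv]
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    abort(sprintf("Non-finite features for subject '%s': %s",
                  roi$subject_id, paste(bad, collapse = ", ")),
          class = "radiotex_extraction_error")
  }
  out
}

#' Extract the canonical 152-feature vector from one ROI
#'
#' Runs the full per-subject extraction: first-order statistics, co-occurrence
#' (GLCM), run-length (GLRM), local binary pattern, fractal, and shape
#' features on the base image; FoS + GLCM + GLRM on the Sobel gradient image;
#' power (mean squared coefficient) + FoS + GLCM + GLRM on each of the four
#' Haar sub-bands; FoS of the 9-bin orientation histogram. Base FoS is
#' computed on the raw intensities; all other families work on the min-max
#' normalized image, and each derived image is independently re-normalized
#' and re-quantized before matrix features, so everything except
#' `base.fos.mean` / `base.fos.variance` is invariant to positive affine
#' rescaling of the input intensities.
#'
#' @param roi A [roi_image()].
#' @param n_levels Gray levels for quantization (default 32).
#' @return A tibble with columns `feature` and `value` (152 rows, canonical
#'   order).
#' @export
extract_features <- function(roi, n_levels = 32L) {
  v <- extract_vector(roi, n_levels)
  tibble::tibble(feature = names(v), value = unname(v))
}

#' Extract a cohort feature table
#'
#' @param rois A list of [roi_image()] objects (e.g. `cohort$subjects` images
#'   from [generate_cohort()], or read from disk).
#' @param n_levels Gray levels for quantization.
#' @return A tibble: `subject_id` plus the 152 canonical feature columns,
#'   one row per subject.
#' @export
extract_feature_table <- function(rois, n_levels = 32L) {
  stopifnot(length(rois) > 0)
  rows <- purrr::map(rois, function(r) {
    v <- extract_vector(r, n_levels)
    tibble::as_tibble_row(c(list(subject_id = r$subject_id), as.list(v)))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$subject_id)) {
    abort("Duplicate subject ids in cohort.", class = "radiotex_config_error")
  }
  out
}
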