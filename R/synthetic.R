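#' Configuration for a synthetic two-group tumor cohort
#'
#' Defines the study conditions the generator emulates: two groups of
#' textured elliptical tumor phantoms whose texture differs by the
#' correlation length of a Gaussian random field (not by mean intensity or
#' size), survival monotonically linked to the realized texture scale, and
#' histology markers tied to the same latent by a Gaussian copula.
#'
#' @param n_per_group Subjects per group (>= 2). Default 8, a typical
#'   small-animal treatment-study arm.
#' @param image_size Square canvas side in pixels (default 64).
#' @param tumor_axes_range Min/max ellipse semi-axes in pixels; must fit the
#'   canvas. Default `c(12, 24)`.
#' @param texture_params_control,texture_params_treated Lists with
#'   `correlation_length` (px), `noise_sd` (intensity units), `mean_level`
#'   (intensity units). Defaults: correlation lengths 1 px (control) vs 6 px
#'   (treated) with matched noise 0.15 and mean 0.5, so the groups differ in
#'   texture but not in brightness or size.
#' @param corr_length_jitter_sd Per-subject SD (px) of the realized
#'   correlation length around the group value (default 0.5, a meaningful
#'   biological heterogeneity on the 1-6 px scale; the realized length is
#'   floored at 0.3 px so it stays positive).
#' @param survival_link List with `baseline_days`, `slope` (days per px of
#'   realized correlation length), `noise_sd_days`. Defaults (31, 4, 18) put
#'   group mean survivals near 35 (control) and 55 days (treated) with
#'   within-group SDs near 18 days, the overall-survival contrast of the
#'   emulated study design.
#' @param histology_link List of lists with `marker_name`,
#'   `target_correlation` in \[-1, 1\] (population Pearson correlation between
#'   the marker and the latent texture scale), `mean`, `sd`. Defaults create
#'   `fibrosis_pct` (r = 0.84), `ck19_pct` (r = -0.97), `ki67_per_field`
#'   (r = 0.81).
#' @param censoring_rate Probability a subject is censored (default 0: all
#'   deaths observed, as in a terminal small-animal study).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 8L,
                          image_size = 64L,
                          tumor_axes_range = c(12, 24),
                          texture_params_control = list(
                            correlation_length = 1, noise_sd = 0.15, mean_level = 0.5
                          ),
                          texture_params_treated = list(
                            correlation_length = 6, noise_sd = 0.15, mean_level = 0.5
                          ),
                          corr_length_jitter_sd = 0.5,
                          survival_link = list(
                            baseline_days = 31, slope = 4, noise_sd_days = 18
                          ),
                          histology_link = list(
                            list(marker_name = "fibrosis_pct", target_correlation = 0.84,
                                 mean = 30, sd = 10),
                            list(marker_name = "ck19_pct", target_correlation = -0.97,
                                 mean = 40, sd = 15),
                            list(marker_name = "ki67_per_field", target_correlation = 0.81,
                                 mean = 50, sd = 20)
                          ),
                          censoring_rate = 0,
                          seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), image_size = as.integer(image_size),
    tumor_axes_range = as.numeric(tumor_axes_range),
    texture_params_control = texture_params_control,
    texture_params_treated = texture_params_treated,
    corr_length_jitter_sd = corr_length_jitter_sd,
    survival_link = survival_link, histology_link = histology_link,
    censoring_rate = censoring_rate, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("Invalid cohort config field `%s`: %s", field, msg),
          class = "radiotex_config_error")
  }
  if (is.na(cfg$n_per_group) || cfg$n_per_group < 2L) {
    bad("n_per_group", "must be an integer >= 2")
  }
  if (cfg$image_size < 16L) bad("image_size", "canvas too small")
  ax <- cfg$tumor_axes_range
  if (length(ax) != 2L || any(ax <= 0) || ax[1] > ax[2]) {
    bad("tumor_axes_range", "must be positive c(min, max) with min <= max")
  }
  if (2 * ax[2] >= cfg$image_size) {
    bad("tumor_axes_range", "largest tumor does not fit the canvas")
  }
  for (side in c("texture_params_control", "texture_params_treated")) {
    tp <- cfg[[side]]
    if (!all(c("correlation_length", "noise_sd", "mean_level") %in% names(tp))) {
      bad(side, "needs correlation_length, noise_sd, mean_level")
    }
    if (tp$correlation_length <= 0 || tp$noise_sd < 0) {
      bad(side, "correlation_length must be > 0 and noise_sd >= 0")
    }
  }
  for (h in cfg$histology_link) {
    if (abs(h$target_correlation) > 1) {
      bad("histology_link", sprintf("|target_correlation| > 1 for '%s'", h$marker_name))
    }
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    bad("censoring_rate", "must be in [0, 1)")
  }
  invisible(cfg)
}

# Documented seed-splitting scheme: one derived child seed per subject so
# subjects are independent streams and the cohort is reproducible regardless
# of evaluation order.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 100003 + 7919 * i) %% 2147483647)
}

# Gaussian random-field phantom: white noise smoothed at `corr_len`,
# standardized so the *masked* pixels have sd `noise_sd` and mean
# `mean_level`, clipped to [0, 1]. Standardizing inside the mask keeps the
# tumor's first-order intensity statistics matched across correlation
# lengths, so only the spatial texture distinguishes the groups.
synth_field <- function(n, corr_len, noise_sd, mean_level, mask) {
  z <- matrix(rnorm(n * n), n, n)
  f <- gauss_smooth(z, corr_len)
  mu <- mean(f[mask])
  s <- sd(f[mask])
  if (s > 0) f <- (f - mu) / s else f <- f * 0
  matrix(pmin(1, pmax(0, mean_level + noise_sd * f)), n, n)
}

ellipse_mask <- function(n, a, b, theta) {
  cx <- (n + 1) / 2
  cy <- (n + 1) / 2
  r <- row(matrix(0, n, n)) - cx
  cc <- col(matrix(0, n, n)) - cy
  u <- r * cos(theta) + cc * sin(theta)
  v <- -r * sin(theta) + cc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic two-group cohort
#'
#' Each subject's image is a Gaussian random field (white noise smoothed with
#' an isotropic Gaussian kernel at the subject's realized correlation length,
#' scaled to the group noise SD and shifted to the group mean level) masked
#' by a filled ellipse with semi-axes drawn uniformly from
#' `tumor_axes_range`. The realized correlation length (group value plus
#' per-subject jitter) is the latent texture scale: survival is
#' `baseline_days + slope * latent + N(0, noise_sd_days)`, floored at 1 day,
#' and each histology marker is generated from a Gaussian copula so its
#' population correlation with the latent equals `target_correlation`.
#'
#' @param config A [cohort_config()].
#' @param with_images If `FALSE`, skip field synthesis and return metadata
#'   only (useful for large-n calibration studies of the survival and
#'   histology links).
#' @return A `cohort_dataset`: list with `subjects` (list of per-subject
#'   lists: `subject_id`, `roi` ([roi_image()] or `NULL`), `group`,
#'   `survival_days`, `event`, `histology`) and `metadata` (tibble with
#'   columns subject_id, group, survival_days, event, texture_latent, and one
#'   column per histology marker).
#' @export
generate_cohort <- function(config, with_images = TRUE) {
  validate_cohort_config(config)
  groups <- rep(c("control", "treated"), each = config$n_per_group)
  n_total <- length(groups)
  subjects <- vector("list", n_total)
  meta <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(subject_seed(config$seed, i))
    grp <- groups[i]
    tp <- if (grp == "control") config$texture_params_control else config$texture_params_treated
    latent <- max(0.3, tp$correlation_length + rnorm(1, 0, config$corr_length_jitter_sd))
    a <- runif(1, config$tumor_axes_range[1], config$tumor_axes_range[2])
    b <- runif(1, config$tumor_axes_range[1], config$tumor_axes_range[2])
    theta <- runif(1, 0, pi)
    surv <- max(1, config$survival_link$baseline_days +
                  config$survival_link$slope * latent +
                  rnorm(1, 0, config$survival_link$noise_sd_days))
    event <- runif(1) >= config$censoring_rate
    # Gaussian copula: marker = mean + sd * (rho * z + sqrt(1-rho^2) * eps),
    # where z is the standardized latent (population standardization over the
    # known jitter distribution), so cor(marker, latent) -> rho.
    z <- (latent - tp$correlation_length) / config$corr_length_jitter_sd
    hist_vals <- purrr::map_dbl(config$histology_link, function(h) {
      rho <- h$target_correlation
      h$mean + h$sd * (rho * z + sqrt(1 - rho^2) * rnorm(1))
    })
    names(hist_vals) <- purrr::map_chr(config$histology_link, "marker_name")
    sid <- sprintf("%s_%02d", substr(grp, 1, 4), i)
    roi <- NULL
    if (with_images) {
      mk <- ellipse_mask(config$image_size, a, b, theta)
      px <- synth_field(config$image_size, latent, tp$noise_sd, tp$mean_level, mk)
      roi <- roi_image(px * mk, mk, subject_id = sid)
    }
    subjects[[i]] <- list(
      subject_id = sid, roi = roi, group = grp,
      survival_days = surv, event = event, histology = as.list(hist_vals)
    )
    meta[[i]] <- tibble::as_tibble_row(c(
      list(subject_id = sid, group = grp, survival_days = surv, event = event,
           texture_latent = latent),
      as.list(hist_vals)
    ))
  }
  structure(
    list(subjects = subjects, metadata = dplyr::bind_rows(meta),
         config = config),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects (%s)\n",
              length(x$subjects),
              paste(table(x$metadata$group), names(table(x$metadata$group)),
                    collapse = " + ")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits 16-bit grayscale PNG image/mask pairs and a metadata CSV with
#' columns subject_id, group, survival_days, event, and the histology
#' markers.
#'
#' @param cohort A `cohort_dataset` generated with images.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the metadata CSV path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    if (is.null(s$roi)) abort("Cohort was generated without images.",
                              class = "radiotex_config_error")
    write_roi_png(s$roi,
                  file.path(dir, paste0(s$subject_id, "_image.png")),
                  file.path(dir, paste0(s$subject_id, "_mask.png")))
  }
  meta_path <- file.path(dir, "metadata.csv")
  readr::write_csv(dplyr::select(cohort$metadata, -"texture_latent"), meta_path)
  invisible(meta_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `*_image.png` / `*_mask.png` pairs and
#'   `metadata.csv`.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"), show_col_types = FALSE)
  extra <- setdiff(names(meta), c("subject_id", "group", "survival_days", "event"))
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$subject_id[i]
    roi <- read_roi(
      file.path(dir, paste0(sid, "_image.png")),
      file.path(dir, paste0(sid, "_mask.png")),
      subject_id = sid
    )
    list(subject_id = sid, roi = roi, group = meta$group[i],
         survival_days = meta$survival_days[i], event = meta$event[i],
         histology = as.list(meta[i, extra]))
  })
  structure(list(subjects = subjects, metadata = meta, config = NULL),
            class = "cohort_dataset")
}

#' Hand-checkable worked fixtures
#'
#' Tiny labelled arrays used across the test suites, with their expected
#' values embedded: a two-level 2x3 run-length example, a 2x2 Haar example,
#' and a two-level 2x2 co-occurrence example.
#'
#' @return Named list of fixtures; each has `data` and `expected`.
#' @export
generate_worked_fixtures <- function() {
  list(
    glrm_toy = list(
      data = matrix(c(1, 2, 1, 2, 2, 2), nrow = 2),  # [[1,1,2],[2,2,2]]
      expected = list(
        runs_deg0 = list(g = c(1L, 2L, 2L), l = c(2L, 1L, 3L)),
        sre = (1 / 4 + 1 + 1 / 9) / 3, lre = 14 / 3, rp = 0.5,
        gln = 5 / 3, rln = 1, lgre = 0.5
      )
    ),
    haar_toy = list(
      data = matrix(c(1, 5, 3, 7), nrow = 2),  # [[1,3],[5,7]]
      expected = list(approximate = 8, horizontal = -4, vertical = -2,
                      diagonal = 0, energy = 84)
    ),
    glcm_toy = list(
      data = matrix(c(1, 2, 1, 2), nrow = 2),  # [[1,1],[2,2]]
      expected = list(
        deg0 = c(p11 = 0.5, p22 = 0.5),
        deg90 = c(p12 = 0.5, p21 = 0.5),
        features_deg0 = c(contrast = 0, correlation = 1, energy = 0.5,
                          homogeneity = 1, entropy = 1, dissimilarity = 0),
        features_deg90 = c(contrast = 1, correlation = -1)
      )
    )
  )
}
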