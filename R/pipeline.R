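#' Run the full radiomics pipeline
#'
#' Orchestrates extract -> reduce -> select -> associate on a cohort directory
#' (image/mask PNG pairs plus `metadata.csv`, the layout written by
#' [write_cohort()]) and writes versioned outputs to `out_dir`:
#' `features.csv` (subject_id + 152 canonical columns), `reduction.json`,
#' `trace.json`, `assoc.csv`, `km.json`, and `run_manifest.json` (config,
#' package version, wall-clock). Reruns with identical inputs and config are
#' byte-identical (the pipeline itself is deterministic).
#'
#' @param config A named list or path to a YAML file with entries:
#'   `cohort_dir` (input directory), `out_dir`, and optionally `n_levels`
#'   (default 32), `cor_threshold` (default 0.5), `label_col` (default
#'   `"group"`), `targets` (character vector of metadata columns to
#'   associate; default survival + any histology columns present), and the
#'   [selection_config()] fields under `selection`.
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `reduction`, `trace`, `associations`, `km`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (req in c("cohort_dir", "out_dir")) {
    if (is.null(config[[req]])) {
      abort(sprintf("Pipeline config is missing `%s`.", req),
            class = "radiotex_config_error")
    }
  }
  if (!dir.exists(config$cohort_dir)) {
    abort(sprintf("Cohort directory not found: %s", config$cohort_dir),
          class = "radiotex_io_error")
  }
  n_levels <- config$n_levels %||% 32L
  cor_threshold <- config$cor_threshold %||% 0.5
  label_col <- config$label_col %||% "group"
  sel_cfg <- do.call(selection_config, config$selection %||% list())
  t0 <- Sys.time()

  cohort <- read_cohort(config$cohort_dir)
  rois <- purrr::map(cohort$subjects, "roi")
  features <- extract_feature_table(rois, n_levels = n_levels)
  meta <- cohort$metadata
  stopifnot(identical(features$subject_id, meta$subject_id))

  red <- suppressWarnings(correlation_filter(features, threshold = cor_threshold))
  trace <- exhaustive_search(red$table, meta[[label_col]], config = sel_cfg)

  default_targets <- intersect(
    c("survival_days", "fibrosis_pct", "ck19_pct", "ki67_per_field"),
    names(meta)
  )
  targets <- config$targets %||% default_targets
  assoc <- dplyr::bind_rows(purrr::map(targets, function(tg) {
    feature_survival_screen(features, meta[[tg]], target_name = tg)
  }))
  km <- km_estimate(meta$survival_days, meta$event, meta[[label_col]])

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  readr::write_csv(features, out("features.csv"))
  jsonlite::write_json(
    list(kept = red$kept, dropped = red$dropped, constant = red$constant,
         threshold = red$threshold),
    out("reduction.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(schema_version = 1L,
         trace = tidy(trace), stopped_at = trace$stopped_at,
         selected = as.list(trace$selected),
         selected_accuracy = trace$selected_accuracy),
    out("trace.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(assoc, out("assoc.csv"))
  jsonlite::write_json(
    list(curves = tidy(km), logrank_chi2 = km$logrank_chi2,
         logrank_p = km$logrank_p),
    out("km.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("radiotex")),
      config = config[setdiff(names(config), "out_dir")],
      n_subjects = nrow(meta),
      wallclock_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    out("run_manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(features = features, reduction = red, trace = trace,
                 associations = assoc, km = km, out_dir = config$out_dir))
}
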