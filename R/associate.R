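#' Pearson association between a feature and a continuous target
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' distribution on n - 2 degrees of freedom
#' (`t = r * sqrt((n - 2) / (1 - r^2))`).
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @param feature,target Optional names carried into the result.
#' @return A one-row tibble: `feature`, `target`, `r`, `t_stat`, `p`, `n`.
#' @export
pearson_assoc <- function(x, y, feature = "x", target = "y") {
  if (length(x) != length(y) || length(x) < 3) {
    abort("pearson_assoc() needs equal-length vectors with n >= 3.",
          class = "radiotex_config_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("pearson_assoc() requires finite values.", class = "radiotex_config_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance input.",
          class = "radiotex_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    feature = feature, target = target,
    r = unname(ct$estimate), t_stat = unname(ct$statistic),
    p = ct$p.value, n = length(x)
  )
}

#' Two-group comparison: Student t and Cohen's d
#'
#' With raw data, a pooled-variance two-tailed Student t-test is run
#' (Welch via `welch = TRUE`) and Cohen's d is the absolute standardized mean
#' difference with the n-weighted pooled SD. With summary statistics
#' (mean/SD per group, n unknown), the equal-weight pooled SD
#' `sqrt((s1^2 + s2^2) / 2)` is used and no p-value is computed.
#'
#' @param values Numeric vector of measurements (raw-data interface).
#' @param groups Two-level grouping vector, same length.
#' @param feature Optional feature name carried into the result.
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @return A one-row tibble: `feature`, per-group mean/sd/n, `t_stat`, `p`,
#'   `cohens_d`.
#' @export
group_compare <- function(values, groups, feature = "feature", welch = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    abort("group_compare() needs exactly 2 groups.", class = "radiotex_config_error")
  }
  v1 <- values[groups == levels(groups)[1]]
  v2 <- values[groups == levels(groups)[2]]
  if (length(v1) < 2 || length(v2) < 2) {
    abort("Need at least 2 observations per group.", class = "radiotex_config_error")
  }
  n1 <- length(v1); n2 <- length(v2)
  s_pooled <- sqrt(((n1 - 1) * var(v1) + (n2 - 1) * var(v2)) / (n1 + n2 - 2))
  dm <- abs(mean(v1) - mean(v2))
  if (s_pooled == 0) {
    if (dm > 0) {
      abort("Zero pooled variance with unequal means: Cohen's d is infinite.",
            class = "radiotex_degenerate_input")
    }
    return(tibble::tibble(
      feature = feature,
      group1 = levels(groups)[1], mean1 = mean(v1), sd1 = 0, n1 = n1,
      group2 = levels(groups)[2], mean2 = mean(v2), sd2 = 0, n2 = n2,
      t_stat = 0, p = 1, cohens_d = 0
    ))
  }
  tt <- t.test(v1, v2, var.equal = !welch)
  tibble::tibble(
    feature = feature,
    group1 = levels(groups)[1], mean1 = mean(v1), sd1 = sd(v1), n1 = n1,
    group2 = levels(groups)[2], mean2 = mean(v2), sd2 = sd(v2), n2 = n2,
    t_stat = unname(tt$statistic), p = tt$p.value,
    cohens_d = dm / s_pooled
  )
}

#' @rdname group_compare
#' @param mean1,sd1,mean2,sd2 Group summary statistics (per-group sample
#'   sizes unknown).
#' @return For the summary interface: one-row tibble `feature`, `cohens_d`
#'   (equal-weight pooled).
#' @export
cohens_d_from_summary <- function(mean1, sd1, mean2, sd2, feature = "feature") {
  s <- sqrt((sd1^2 + sd2^2) / 2)
  if (s == 0) {
    if (mean1 != mean2) {
      abort("Zero pooled SD with unequal means: Cohen's d is infinite.",
            class = "radiotex_degenerate_input")
    }
    return(tibble::tibble(feature = feature, cohens_d = 0))
  }
  tibble::tibble(feature = feature, cohens_d = abs(mean1 - mean2) / s)
}

#' Kaplan-Meier estimate with two-group log-rank test
#'
#' Product-limit survival estimate per group (via the survival package) and,
#' when two groups are present, the log-rank chi-square and p-value.
#'
#' @param times Positive survival times (days).
#' @param events Logical event indicators (`TRUE` = death observed,
#'   `FALSE` = censored).
#' @param groups Optional grouping vector.
#' @return A `km_estimate`: list with `curves` (tibble: `group`, `time`,
#'   `n_risk`, `n_event`, `survival`), `logrank_chi2`, `logrank_p` (NA for a
#'   single group), and the underlying `survfit` object.
#' @export
km_estimate <- function(times, events = rep(TRUE, length(times)),
                        groups = rep("all", length(times))) {
  if (any(times <= 0)) abort("Survival times must be positive.",
                             class = "radiotex_config_error")
  groups <- factor(groups)
  if (any(table(groups) == 0) || length(groups) != length(times)) {
    abort("Empty group or length mismatch.", class = "radiotex_config_error")
  }
  d <- data.frame(time = times, event = as.integer(events), group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(levels(groups)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble::tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
  chi2 <- NA_real_
  p <- NA_real_
  if (nlevels(groups) == 2) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chi2 <- lr$chisq
    p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  }
  structure(
    list(curves = curves, logrank_chi2 = chi2, logrank_p = p, fit = fit),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> %d event times; log-rank chi2 = %s, p = %s\n",
              nrow(x$curves),
              format(x$logrank_chi2, digits = 4),
              format(x$logrank_p, digits = 4)))
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `km_estimate`.
#' @param ... Unused.
#' @export
tidy.km_estimate <- function(x, ...) {
  x$curves
}

#' @rdname km_estimate
#' @export
glance.km_estimate <- function(x, ...) {
  tibble::tibble(logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p)
}

#' @rdname km_estimate
#' @param object A `km_estimate`.
#' @export
autoplot.km_estimate <- function(object, ...) {
  steps <- dplyr::bind_rows(
    dplyr::reframe(dplyr::group_by(object$curves, .data$group),
                   time = 0, survival = 1),
    object$curves
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                      color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  title = "Kaplan-Meier survival") +
    ggplot2::theme_minimal()
}

#' Screen all features for association with survival (or another target)
#'
#' One Pearson association per feature column, ranked by absolute
#' correlation, flagged significant at p < 0.05 (uncorrected by default,
#' matching the univariate-screen convention; Benjamini-Hochberg adjusted
#' p-values are added when `adjust = "BH"`).
#'
#' @param table Feature table (optional `subject_id` column plus numeric
#'   feature columns).
#' @param target Numeric target vector (e.g. survival days), or the name of a
#'   column in `table`.
#' @param target_name Name recorded in the output.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of [pearson_assoc()] rows plus `significant` (and
#'   `p_adjusted` when requested), sorted by decreasing |r|.
#' @export
feature_survival_screen <- function(table, target, target_name = "survival_days",
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(target) == 1 && is.character(target) && target %in% names(table)) {
    target_name <- target
    target <- table[[target]]
    table <- table[setdiff(names(table), target_name)]
  }
  feats <- setdiff(names(table), "subject_id")
  res <- purrr::map(feats, function(f) {
    pearson_assoc(table[[f]], target, feature = f, target = target_name)
  })
  out <- dplyr::arrange(dplyr::bind_rows(res), dplyr::desc(abs(.data$r)))
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adjusted < 0.05
  } else {
    out$significant <- out$p < 0.05
  }
  out
}
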