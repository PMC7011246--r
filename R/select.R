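#' Selection configuration for the exhaustive-search SVM
#'
#' The classifier is an RBF-kernel support vector machine. The emulated
#' analysis states only that its classifier was kernel-based, so every knob
#' is exposed here with documented reconstruction defaults: `C = 1`,
#' `gamma = 1 / (k * pooled variance of the standardized training subset)`
#' (which is `1/k` once columns are standardized), per-fold standardization
#' on, and the stopping tolerance `tol = 1e-3` on leave-one-out accuracy
#' improvement.
#'
#' @param C SVM cost (default 1).
#' @param gamma Fixed RBF gamma, or `NULL` (default) for the
#'   `1/(k * pooled variance)` rule.
#' @param max_k Cap on subset size (default 5).
#' @param tol Improvement threshold on LOO accuracy (default 1e-3).
#' @param standardize Standardize columns inside each training fold (default
#'   `TRUE`).
#' @param max_evaluations Guard on total subset evaluations (default 1e7).
#' @return A `selection_config` list.
#' @export
selection_config <- function(C = 1, gamma = NULL, max_k = 5L, tol = 1e-3,
                             standardize = TRUE, max_evaluations = 1e7) {
  if (C <= 0) abort("`C` must be positive.", class = "radiotex_config_error")
  if (tol <= 0) abort("`tol` must be positive.", class = "radiotex_config_error")
  structure(
    list(C = C, gamma = gamma, max_k = as.integer(max_k), tol = tol,
         standardize = standardize, max_evaluations = max_evaluations),
    class = "selection_config"
  )
}

split_features_labels <- function(table, labels) {
  if (length(labels) == 1 && is.character(labels) && labels %in% names(table)) {
    lab <- table[[labels]]
    table <- table[setdiff(names(table), labels)]
  } else {
    lab <- labels
  }
  id_cols <- intersect("subject_id", names(table))
  X <- as.matrix(table[setdiff(names(table), id_cols)])
  y <- factor(lab)
  if (nlevels(y) != 2) {
    abort("Labels must have exactly 2 classes.", class = "radiotex_config_error")
  }
  if (length(y) != nrow(X)) {
    abort("Label length does not match table rows.", class = "radiotex_config_error")
  }
  if (min(table(y)) < 2) {
    abort("Need at least 2 subjects per class.", class = "radiotex_config_error")
  }
  if (anyNA(X)) abort("Feature table contains missing values.",
                      class = "radiotex_config_error")
  list(X = X, y = y)
}

# Per-fold standardized copies of every column: fold_std[[i]] is the full
# n x p matrix standardized with the mean/sd of the rows excluding i. A
# zero-variance training column is set to 0 everywhere (with no warning here;
# loo_accuracy warns once).
fold_standardized <- function(X) {
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    mu <- colMeans(X[-i, , drop = FALSE])
    s <- apply(X[-i, , drop = FALSE], 2, sd)
    Z <- sweep(X, 2, mu, "-")
    Z <- sweep(Z, 2, ifelse(s > 0, s, 1), "/")
    Z[, s == 0] <- 0
    Z
  })
}

svm_fold_correct <- function(Z, y, i, C, gamma) {
  fit <- e1071::svm(
    x = Z[-i, , drop = FALSE], y = y[-i], type = "C-classification",
    kernel = "radial", cost = C, gamma = gamma, scale = FALSE
  )
  pred <- stats::predict(fit, Z[i, , drop = FALSE])
  as.character(pred) == as.character(y[i])
}

loo_over_folds <- function(Zs, y, cols, C, gamma_fixed) {
  n <- length(y)
  correct <- 0L
  for (i in seq_len(n)) {
    Z <- Zs[[i]][, cols, drop = FALSE]
    gamma <- if (is.null(gamma_fixed)) {
      v <- mean(apply(Z[-i, , drop = FALSE], 2, var))
      if (v > 0) 1 / (length(cols) * v) else 1 / length(cols)
    } else {
      gamma_fixed
    }
    correct <- correct + svm_fold_correct(Z, y, i, C, gamma)
  }
  correct / n
}

#' Leave-one-out accuracy of the RBF-SVM on a feature subset
#'
#' For each held-out subject, the remaining subjects' columns are
#' standardized with their own mean/SD (the held-out subject never touches
#' the scaler), the SVM is fit on the remainder, and the held-out subject is
#' predicted. A training fold containing one class only is an error; a
#' zero-variance training column is standardized to zero with a warning.
#'
#' @param table Feature table (data frame; optional `subject_id` column,
#'   remaining columns are the subset to score), or pass a wider table and
#'   restrict with `dplyr::select()` first.
#' @param labels Two-class vector (or the name of a column in `table`).
#' @param config A [selection_config()].
#' @return The fraction of correctly predicted held-out subjects.
#' @export
loo_accuracy <- function(table, labels, config = selection_config()) {
  d <- split_features_labels(table, labels)
  n <- nrow(d$X)
  for (i in seq_len(n)) {
    if (length(unique(d$y[-i])) < 2) {
      abort("A leave-one-out training fold contains a single class.",
            class = "radiotex_config_error")
    }
  }
  if (config$standardize) {
    zero_var <- any(vapply(seq_len(n), function(i) {
      any(apply(d$X[-i, , drop = FALSE], 2, sd) == 0)
    }, logical(1)))
    if (zero_var) {
      warn("Zero-variance column(s) inside a training fold; standardized to 0.")
    }
    Zs <- fold_standardized(d$X)
  } else {
    Zs <- rep(list(d$X), n)
  }
  loo_over_folds(Zs, d$y, seq_len(ncol(d$X)), config$C, config$gamma)
}

#' Exhaustive-search feature selection under leave-one-out validation
#'
#' For subset sizes k = 1, 2, ... every size-k subset of the candidate
#' features is scored by leave-one-out SVM accuracy; the best subset per k is
#' recorded (ties resolved to the lexicographically first subset in canonical
#' column order). The search stops when the best accuracy improves by no more
#' than `tol` over the previous size (with best(0) := 0, so k = 1 is always
#' evaluated) or `max_k` is reached; the selected subset is the best at the
#' last improving size.
#'
#' @param table Feature table (optional `subject_id` column plus candidate
#'   feature columns, normally the output of [correlation_filter()]).
#' @param labels Two-class vector or name of a label column in `table`.
#' @param config A [selection_config()].
#' @param force Evaluate even past the `max_evaluations` guard.
#' @return A `selection_trace`: tibble `trace` (per k: `k`, `loo_accuracy`,
#'   `n_subsets_evaluated`, `best_subset` list-column), `stopped_at`,
#'   `selected` (feature names) and `selected_accuracy`.
#' @export
exhaustive_search <- function(table, labels, config = selection_config(),
                              force = FALSE) {
  d <- split_features_labels(table, labels)
  p <- ncol(d$X)
  max_k <- min(config$max_k, p)
  total <- sum(vapply(seq_len(max_k), function(k) choose(p, k), numeric(1)))
  if (total > config$max_evaluations && !force) {
    abort(sprintf(
      "Search would evaluate %.3g subsets (> %.3g); reduce features/max_k or use force = TRUE.",
      total, config$max_evaluations
    ), class = "radiotex_config_error")
  }
  Zs <- if (config$standardize) fold_standardized(d$X) else
    rep(list(d$X), nrow(d$X))
  feat_names <- colnames(d$X)
  rows <- list()
  best_prev <- 0
  stopped_at <- NA_integer_
  selected <- character()
  selected_acc <- 0
  for (k in seq_len(max_k)) {
    subsets <- combn(p, k, simplify = FALSE)
    best_acc <- -Inf
    best_sub <- NULL
    for (s in subsets) {
      acc <- loo_over_folds(Zs, d$y, s, config$C, config$gamma)
      if (acc > best_acc) {  # strict: keeps the lexicographically first tie
        best_acc <- acc
        best_sub <- s
      }
    }
    rows[[k]] <- tibble::tibble(
      k = k, loo_accuracy = best_acc, n_subsets_evaluated = length(subsets),
      best_subset = list(feat_names[best_sub])
    )
    improvement <- best_acc - best_prev
    if (improvement > config$tol) {
      selected <- feat_names[best_sub]
      selected_acc <- best_acc
      best_prev <- best_acc
      stopped_at <- k
    } else {
      stopped_at <- k
      break
    }
  }
  structure(
    list(
      trace = dplyr::bind_rows(rows),
      stopped_at = stopped_at,
      selected = selected,
      selected_accuracy = selected_acc,
      config = config
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "<selection_trace> stopped at k = %d; selected {%s} with LOO accuracy %.4f\n",
    x$stopped_at, paste(x$selected, collapse = ", "), x$selected_accuracy
  ))
  invisible(x)
}

#' @rdname exhaustive_search
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @export
tidy.selection_trace <- function(x, ...) {
  dplyr::mutate(x$trace,
                best_subset = purrr::map_chr(.data$best_subset, paste, collapse = " + "))
}

#' @rdname exhaustive_search
#' @export
glance.selection_trace <- function(x, ...) {
  tibble::tibble(
    stopped_at = x$stopped_at,
    selected_size = length(x$selected),
    selected_accuracy = x$selected_accuracy,
    n_subsets_evaluated = sum(x$trace$n_subsets_evaluated)
  )
}

#' @rdname exhaustive_search
#' @param object A `selection_trace`.
#' @export
autoplot.selection_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$k, y = .data$loo_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$trace$k) +
    ggplot2::labs(x = "subset size k", y = "best LOO accuracy",
                  title = "Exhaustive-search feature selection") +
    ggplot2::theme_minimal()
}
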