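#' Remove highly correlated features
#'
#' Greedy redundancy elimination on pairwise Pearson correlation: while any
#' feature pair exceeds the threshold in absolute correlation, the member of
#' the worst pair with the larger mean absolute correlation to all remaining
#' features is dropped (ties drop the later feature in canonical column
#' order). Absolute correlation governs removal — a perfectly anti-correlated
#' duplicate is as redundant as a correlated one. Constant columns are
#' dropped up front with a warning (their correlation is undefined). The
#' procedure is deterministic given column order and invariant to row
#' permutation.
#'
#' @param table A feature table: data frame with an optional `subject_id`
#'   column plus numeric feature columns, >= 3 rows.
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.50.
#' @return A list of class `reduction_report`: `table` (the reduced tibble,
#'   canonical column order preserved), `kept`, `dropped` (tibble with
#'   `feature`, `partner`, `r_value`), `constant` (dropped constant columns),
#'   `threshold`.
#' @export
correlation_filter <- function(table, threshold = 0.50) {
  stopifnot(is.data.frame(table))
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1).", class = "radiotex_config_error")
  }
  id_cols <- intersect("subject_id", names(table))
  feats <- setdiff(names(table), id_cols)
  X <- as.matrix(table[feats])
  if (nrow(X) < 3) {
    abort("Correlation filtering needs at least 3 subjects.",
          class = "radiotex_config_error")
  }
  const <- feats[apply(X, 2, function(v) sd(v) == 0)]
  if (length(const)) {
    warn(sprintf("Dropping %d constant column(s): %s",
                 length(const), paste(const, collapse = ", ")))
    feats <- setdiff(feats, const)
    X <- X[, feats, drop = FALSE]
  }
  R <- abs(cor(X))
  diag(R) <- 0
  alive <- setNames(rep(TRUE, length(feats)), feats)
  dropped <- list()
  repeat {
    Ra <- R[alive, alive, drop = FALSE]
    if (max(Ra) <= threshold) break
    w <- which(Ra == max(Ra), arr.ind = TRUE)[1, ]
    f1 <- rownames(Ra)[w[1]]
    f2 <- colnames(Ra)[w[2]]
    m1 <- mean(Ra[f1, ])
    m2 <- mean(Ra[f2, ])
    victim <- if (m1 > m2) f1 else if (m2 > m1) f2 else {
      # tie: drop the later feature in canonical order
      feats[max(match(c(f1, f2), feats))]
    }
    partner <- setdiff(c(f1, f2), victim)
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      feature = victim, partner = partner, r_value = R[f1, f2]
    )
    alive[victim] <- FALSE
  }
  kept <- feats[alive[feats]]
  structure(
    list(
      table = dplyr::select(table, dplyr::all_of(c(id_cols, kept))),
      kept = kept,
      dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
        tibble::tibble(feature = character(), partner = character(),
                       r_value = numeric()),
      constant = const,
      threshold = threshold
    ),
    class = "reduction_report"
  )
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf(
    "<reduction_report> kept %d / dropped %d features at |r| > %.2f (%d constant)\n",
    length(x$kept), nrow(x$dropped), x$threshold, length(x$constant)
  ))
  invisible(x)
}

#' @rdname correlation_filter
#' @param x A `reduction_report`.
#' @param ... Unused.
#' @export
tidy.reduction_report <- function(x, ...) {
  x$dropped
}

#' @rdname correlation_filter
#' @export
glance.reduction_report <- function(x, ...) {
  tibble::tibble(
    n_kept = length(x$kept), n_dropped = nrow(x$dropped),
    n_constant = length(x$constant), threshold = x$threshold
  )
}
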