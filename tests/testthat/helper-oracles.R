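# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit pixel loops, direct formulas) so they cannot
# share a defect with the vectorized implementation they check.

make_roi <- function(pixels, mask = NULL, subject_id = "t") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  roi_image(pixels, mask, subject_id = subject_id)
}

make_quantized <- function(levels, n_levels, mask = NULL) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  if (is.null(mask)) mask <- levels > 0L
  structure(
    list(levels = levels * (mask * 1L), mask = mask,
         n_levels = as.integer(n_levels), subject_id = "t"),
    class = "quantized_image"
  )
}

# random quantized image on a random mask, guaranteed non-degenerate
random_quantized <- function(nr = 8, nc = 8, L = 4) {
  lev <- matrix(sample.int(L, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
  while (sum(mask) < 16) mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
  make_quantized(lev, L, mask)
}

oracle_offsets <- list(deg0 = c(0, 1), deg45 = c(-1, 1),
                       deg90 = c(-1, 0), deg135 = c(-1, -1))

# Pixel-loop co-occurrence enumerator.
oracle_glcm <- function(q, direction) {
  off <- oracle_offsets[[direction]]
  L <- q$n_levels
  P <- matrix(0, L, L)
  for (r in seq_len(nrow(q$levels))) {
    for (cc in seq_len(ncol(q$levels))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q$levels) && c2 >= 1 && c2 <= ncol(q$levels) &&
          q$mask[r, cc] && q$mask[r2, c2]) {
        P[q$levels[r, cc], q$levels[r2, c2]] <- P[q$levels[r, cc], q$levels[r2, c2]] + 1
      }
    }
  }
  if (sum(P) == 0) return(NULL)
  P <- P + t(P)
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  mu <- 0; for (i in 1:L) for (j in 1:L) mu <- mu + i * P[i, j]
  sig2 <- 0; for (i in 1:L) for (j in 1:L) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  f <- c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0,
         entropy = 0, dissimilarity = 0)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    f["contrast"] <- f["contrast"] + p * (i - j)^2
    f["energy"] <- f["energy"] + p^2
    f["homogeneity"] <- f["homogeneity"] + p / (1 + (i - j)^2)
    if (p > 0) f["entropy"] <- f["entropy"] - p * log2(p)
    f["dissimilarity"] <- f["dissimilarity"] + p * abs(i - j)
    if (sig2 > 0) f["correlation"] <- f["correlation"] + (i - mu) * (j - mu) * p / sig2
  }
  f
}

# Walk every scan line pixel by pixel and enumerate maximal runs.
oracle_glrm_runs <- function(q, direction) {
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(direction,
    deg0 = lapply(seq_len(nr), function(r) cbind(r, seq_len(nc))),
    deg90 = lapply(seq_len(nc), function(cc) cbind(seq_len(nr), cc)),
    deg45 = {
      starts <- rbind(cbind(nr, seq_len(nc)), cbind(seq_len(nr - 1), 1))
      lapply(seq_len(nrow(starts)), function(k) {
        r <- starts[k, 1]; cc <- starts[k, 2]; out <- NULL
        while (r >= 1 && cc <= nc) { out <- rbind(out, c(r, cc)); r <- r - 1; cc <- cc + 1 }
        out
      })
    },
    deg135 = {
      starts <- rbind(cbind(1, seq_len(nc)), cbind(2:nr, 1))
      if (nr == 1) starts <- cbind(1, seq_len(nc))
      lapply(seq_len(nrow(starts)), function(k) {
        r <- starts[k, 1]; cc <- starts[k, 2]; out <- NULL
        while (r <= nr && cc <= nc) { out <- rbind(out, c(r, cc)); r <- r + 1; cc <- cc + 1 }
        out
      })
    }
  )
  g <- integer(0); l <- integer(0)
  for (ln in lines) {
    cur <- 0L; len <- 0L
    vals <- apply(ln, 1, function(rc) if (q$mask[rc[1], rc[2]]) lev[rc[1], rc[2]] else 0L)
    for (v in c(vals, 0L)) {
      if (v == cur) {
        len <- len + 1L
      } else {
        if (cur > 0L) { g <- c(g, cur); l <- c(l, len) }
        cur <- v; len <- 1L
      }
    }
  }
  list(g = g, l = l)
}

oracle_glrm_features <- function(q) {
  np <- sum(q$mask)
  per <- list()
  for (d in names(oracle_offsets)) {
    runs <- oracle_glrm_runs(q, d)
    if (!length(runs$g)) next
    g <- runs$g; l <- runs$l; nr <- length(g)
    per[[d]] <- c(
      sre = sum(1 / l^2) / nr, lre = sum(l^2) / nr,
      gln = sum(table(g)^2) / nr, rln = sum(table(l)^2) / nr,
      rp = nr / np, lgre = sum(1 / g^2) / nr, hgre = sum(g^2) / nr,
      srlge = sum(1 / (g^2 * l^2)) / nr, srhge = sum(g^2 / l^2) / nr,
      lrlge = sum(l^2 / g^2) / nr, lrhge = sum(l^2 * g^2) / nr
    )
  }
  Reduce(`+`, per) / length(per)
}

# Independent exhaustive-search re-implementation on the same LOO folds:
# plain loops, svm called directly per fold.
oracle_exhaustive <- function(X, y, C = 1, tol = 1e-3, max_k = 3) {
  n <- nrow(X); p <- ncol(X)
  y <- factor(y)
  loo <- function(cols) {
    ok <- 0
    for (i in seq_len(n)) {
      tr <- X[-i, cols, drop = FALSE]
      mu <- colMeans(tr); s <- apply(tr, 2, sd)
      s1 <- ifelse(s > 0, s, 1)
      trz <- sweep(sweep(tr, 2, mu), 2, s1, "/")
      trz[, s == 0] <- 0
      tez <- (X[i, cols] - mu) / s1
      tez[s == 0] <- 0
      v <- mean(apply(trz, 2, var))
      gam <- if (v > 0) 1 / (length(cols) * v) else 1 / length(cols)
      fit <- e1071::svm(x = trz, y = y[-i], type = "C-classification",
                        kernel = "radial", cost = C, gamma = gam, scale = FALSE)
      pr <- predict(fit, matrix(tez, nrow = 1))
      ok <- ok + (as.character(pr) == as.character(y[i]))
    }
    ok / n
  }
  best_prev <- 0; sel <- NULL; sel_acc <- 0; per_k <- numeric(0)
  for (k in seq_len(max_k)) {
    subsets <- combn(p, k, simplify = FALSE)
    accs <- vapply(subsets, loo, numeric(1))
    b <- which.max(accs)
    per_k[k] <- accs[b]
    if (accs[b] - best_prev > tol) {
      sel <- subsets[[b]]; sel_acc <- accs[b]; best_prev <- accs[b]
    } else {
      break
    }
  }
  list(selected = sel, accuracy = sel_acc, per_k = per_k)
}

# textured two-group phantom cohort small enough for fast unit tests
tiny_cohort <- function(seed = 1, n_per_group = 4, image_size = 48) {
  generate_cohort(cohort_config(
    n_per_group = n_per_group, image_size = image_size,
    tumor_axes_range = c(10, 18), seed = seed
  ))
}
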