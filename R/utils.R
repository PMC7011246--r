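# Internal numeric helpers shared across modules.

# Reflect-pad a matrix by `w` pixels on every side (edge mirroring without
# repeating the border pixel would be "symmetric"; here we use symmetric
# half-sample reflection: [1 2 3] -> [2 1 | 1 2 3 | 3 2] for w = 1... we use
# whole-sample reflection including the edge, which is what "reflect" padding
# means for Sobel stencils: [1 2 3] -> [1 | 1 2 3 | 3]).
pad_reflect <- function(m, w = 1L) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(rep(1L, w), seq_len(nr), rep(nr, w))
  ci <- c(rep(1L, w), seq_len(nc), rep(nc, w))
  m[ri, ci, drop = FALSE]
}

# 3x3 correlation of `m` with kernel `k`, reflect padding. Vectorized over
# shifted copies; fine for the image sizes this package targets.
conv3 <- function(m, k) {
  p <- pad_reflect(m, 1L)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      w <- k[dr + 2L, dc + 2L]
      if (w != 0) {
        out <- out + w * p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
      }
    }
  }
  out
}

# Binary erosion of a logical mask with a 3x3 structuring element.
erode3 <- function(mask) {
  p <- pad_reflect(mask, 1L)
  # reflect padding would keep border pixels; force the outside to background
  p[c(1L, nrow(p)), ] <- FALSE
  p[, c(1L, ncol(p))] <- FALSE
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      out <- out & p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
    }
  }
  out
}

# Separable Gaussian smoothing via explicit smoothing matrices (row and
# column), reflect boundary handling. sigma in pixels.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smooth_1d <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + (-r:r)
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      idx <- ifelse(idx > n, 2L * n - idx, idx)
      for (j in seq_along(idx)) S[i, idx[j]] <- S[i, idx[j]] + k[j]
    }
    S
  }
  Sr <- smooth_1d(nrow(m))
  Sc <- smooth_1d(ncol(m))
  Sr %*% m %*% t(Sc)
}

# Otsu threshold on values in [0, 1] (256-bin histogram). Returns the
# between-class-variance-maximizing cut; ties resolved at the first maximum.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  h <- tabulate(pmin(255L, pmax(0L, as.integer(floor(x * 256)))) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256L) - 1L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b)) / 256
}

# Label 4-connected components of a logical mask; returns an integer matrix
# (0 = background). Iterative queue-based flood fill.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1L]; c2 <- cc + d[2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- current
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# Shoelace polygon area for points in hull order.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Shannon entropy in bits of a probability vector; 0 log 0 := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
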