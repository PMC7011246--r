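# Texture feature families. Naming grammar: <source>.<family>.<feature> with
# source in {base, grad, wav_a, wav_h, wav_v, wav_d, hog}.

#' First-order statistics of a set of values
#'
#' @param values Numeric vector (>= 2 values).
#' @return Named numeric vector: `mean`, `variance` (population, divisor n),
#'   `skewness` (Fisher, `m3 / m2^1.5`, 0 for constant input), `entropy`
#'   (Shannon entropy in bits of a 32-bin equal-width histogram over the
#'   observed min-max; constant input has entropy 0).
#' @export
fos <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values))) {
    abort("fos() needs at least 2 finite values.", class = "radiotex_degenerate_input")
  }
  n <- length(values)
  m <- mean(values)
  dev <- values - m
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  skew <- if (m2 == 0) 0 else m3 / m2^1.5
  ent <- if (diff(range(values)) == 0) {
    0
  } else {
    br <- seq(min(values), max(values), length.out = 33L)
    cnt <- tabulate(
      pmin(32L, as.integer(floor((values - min(values)) / diff(range(values)) * 32)) + 1L),
      nbins = 32L
    )
    entropy_bits(cnt / n)
  }
  c(mean = m, variance = m2, skewness = skew, entropy = ent)
}

glcm_offsets <- list(
  deg0   = c(0L, 1L),
  deg45  = c(-1L, 1L),
  deg90  = c(-1L, 0L),
  deg135 = c(-1L, -1L)
)

#' Gray-level co-occurrence matrices
#'
#' Distance-1 co-occurrence at 0, 45, 90 and 135 degrees, counting only pixel
#' pairs that are both inside the mask. Each direction's matrix is
#' symmetrized (P + t(P)) and normalized to sum 1. Directions with no valid
#' pair are returned as `NULL` and excluded from feature averaging.
#'
#' @param q A `quantized_image` from [quantize()].
#' @return Named list of four L x L matrices (or `NULL` where empty).
#' @export
glcm_matrix <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  L <- q$n_levels
  nr <- nrow(q$levels)
  nc <- ncol(q$levels)
  out <- lapply(glcm_offsets, function(off) {
    dr <- off[1L]; dc <- off[2L]
    r1 <- seq_len(nr)[(seq_len(nr) + dr) >= 1L & (seq_len(nr) + dr) <= nr]
    c1 <- seq_len(nc)[(seq_len(nc) + dc) >= 1L & (seq_len(nc) + dc) <= nc]
    if (!length(r1) || !length(c1)) return(NULL)
    a <- q$levels[r1, c1, drop = FALSE]
    b <- q$levels[r1 + dr, c1 + dc, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (!any(ok)) return(NULL)
    cnt <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
    P <- matrix(cnt, L, L, byrow = TRUE)
    P <- P + t(P)
    P / sum(P)
  })
  if (all(vapply(out, is.null, logical(1)))) {
    abort("No valid co-occurrence pairs in any direction.",
          class = "radiotex_degenerate_roi")
  }
  out
}

glcm_features_one <- function(P) {
  L <- nrow(P)
  i <- row(P)
  j <- col(P)
  pm <- rowSums(P)                 # marginal; equals colSums by symmetry
  mu <- sum(seq_len(L) * pm)
  sig2 <- sum((seq_len(L) - mu)^2 * pm)
  corr <- if (sig2 == 0) 0 else sum((i - mu) * (j - mu) * P) / sig2
  c(
    contrast = sum(P * (i - j)^2),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = entropy_bits(as.numeric(P)),
    dissimilarity = sum(P * abs(i - j))
  )
}

#' Haralick-style features of co-occurrence matrices
#'
#' Six features per direction — contrast, correlation, energy, homogeneity,
#' entropy (bits), dissimilarity — averaged over the non-empty directions.
#'
#' @param matrices Output of [glcm_matrix()].
#' @return Named numeric vector of 6 features.
#' @export
glcm_features <- function(matrices) {
  keep <- matrices[!vapply(matrices, is.null, logical(1))]
  if (!length(keep)) {
    abort("All co-occurrence directions are empty.", class = "radiotex_degenerate_roi")
  }
  Reduce(`+`, lapply(keep, glcm_features_one)) / length(keep)
}

# Extract directional scan lines of a quantized image (level 0 = outside mask).
scan_lines <- function(lev, direction) {
  switch(direction,
    deg0 = lapply(seq_len(nrow(lev)), function(r) lev[r, ]),
    deg90 = lapply(seq_len(ncol(lev)), function(cc) lev[, cc]),
    deg45 = {  # bottom-left to top-right anti-diagonals
      idx <- row(lev) + col(lev)
      lapply(split(lev[order(idx, -row(lev))], sort(idx)), as.integer)
    },
    deg135 = {  # top-left to bottom-right diagonals
      idx <- col(lev) - row(lev)
      lapply(split(lev[order(idx, row(lev))], sort(idx)), as.integer)
    }
  )
}

glrm_counts <- function(lev, direction) {
  runs_g <- integer(0)
  runs_l <- integer(0)
  for (line in scan_lines(lev, direction)) {
    r <- rle(as.integer(line))
    keep <- r$values > 0L
    runs_g <- c(runs_g, r$values[keep])
    runs_l <- c(runs_l, r$lengths[keep])
  }
  list(g = runs_g, l = runs_l)
}

glrm_features_one <- function(g, l, n_pixels) {
  nr <- length(g)
  c(
    sre = sum(1 / l^2) / nr,
    lre = sum(l^2) / nr,
    gln = sum(tapply(rep(1, nr), g, sum)^2) / nr,
    rln = sum(tapply(rep(1, nr), l, sum)^2) / nr,
    rp = nr / n_pixels,
    lgre = sum(1 / g^2) / nr,
    hgre = sum(g^2) / nr,
    srlge = sum(1 / (g^2 * l^2)) / nr,
    srhge = sum(g^2 / l^2) / nr,
    lrlge = sum(l^2 / g^2) / nr,
    lrhge = sum(l^2 * g^2) / nr
  )
}

#' Gray-level run-length features
#'
#' Runs are maximal same-level masked segments along each of the four scan
#' directions (0, 45, 90, 135 degrees); a masked-out pixel breaks a run. The
#' eleven standard run-length features (SRE, LRE, GLN, RLN, RP, LGRE, HGRE,
#' SRLGE, SRHGE, LRLGE, LRHGE) are computed per direction and averaged.
#'
#' @param q A `quantized_image` from [quantize()].
#' @return Named numeric vector of 11 features.
#' @export
glrm_features <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  n_pixels <- sum(q$mask)
  per_dir <- lapply(names(glcm_offsets), function(d) {
    runs <- glrm_counts(q$levels, d)
    if (!length(runs$g)) return(NULL)
    glrm_features_one(runs$g, runs$l, n_pixels)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (!length(per_dir)) {
    abort("No runs in any direction.", class = "radiotex_degenerate_roi")
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

#' Rotation-invariant uniform local binary pattern histogram
#'
#' For every masked pixel whose full 8-neighborhood is masked, an 8-bit code
#' is formed (bit = 1 iff neighbor >= center, neighbors in circular order at
#' radius 1). Codes with at most 2 circular bit transitions are "uniform" and
#' labelled by their number of set bits (0..8); all others share one
#' non-uniform label. The normalized 10-bin histogram is returned.
#'
#' @param roi A normalized [roi_image()].
#' @return Named numeric vector `riu2_0` .. `riu2_8`, `riu2_nonuniform`,
#'   summing to 1.
#' @export
lbp_features <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  m <- erode3(roi$mask)
  if (sum(m) < 16) {
    abort(sprintf("Subject '%s': mask too small for LBP.", roi$subject_id),
          class = "radiotex_degenerate_roi")
  }
  px <- roi$pixels
  nr <- nrow(px)
  nc <- ncol(px)
  # circular neighbor order (angle 0, 45, ..., 315): E, NE, N, NW, W, SW, S, SE
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
               c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  p <- pad_reflect(px, 1L)
  bits <- lapply(offs, function(off) {
    nb <- p[(2L + off[1L]):(nr + 1L + off[1L]), (2L + off[2L]):(nc + 1L + off[2L]), drop = FALSE]
    (nb >= px)[m]
  })
  B <- do.call(cbind, bits)          # n_pixels x 8 logical
  ones <- rowSums(B)
  trans <- rowSums(B != B[, c(2:8, 1), drop = FALSE])
  label <- ifelse(trans <= 2, ones, 9L)
  h <- tabulate(label + 1L, nbins = 10L)
  setNames(h / sum(h),
           c(paste0("riu2_", 0:8), "riu2_nonuniform"))
}

#' Fractal features: box-counting dimension and lacunarity
#'
#' The masked, normalized image is binarized at its Otsu threshold. `fd` is
#' the slope of the least-squares fit of `log N(s)` against `log(1/s)` over
#' dyadic box sizes spanning the binary pattern's bounding box, where `N(s)`
#' counts occupied s x s boxes. `lacunarity` is the gliding-box
#' mass-variance statistic `var(mass)/mean(mass)^2 + 1` at box size 4 px
#' (population variance; stride 1, boxes fully inside the bounding box).
#'
#' @param roi A normalized [roi_image()].
#' @return Named numeric vector `fd`, `lacunarity`. If binarization leaves
#'   fewer than 2 occupied pixels both are 0 with a warning.
#' @export
fractal_features <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi$pixels[roi$mask]
  thr <- otsu_threshold(v)
  binary <- roi$mask & (roi$pixels > thr)
  if (sum(binary) < 2) {
    warn(sprintf("Subject '%s': Otsu binarization left < 2 pixels; fractal features set to 0.",
                 roi$subject_id))
    return(c(fd = 0, lacunarity = 0))
  }
  rr <- range(which(rowSums(binary) > 0))
  cr <- range(which(colSums(binary) > 0))
  B <- binary[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  smax <- 2^floor(log2(min(dim(B))))
  sizes <- 2^(0:max(1, log2(max(smax, 2))))
  sizes <- sizes[sizes <= max(smax, 2)]
  if (length(sizes) < 2) sizes <- c(1L, 2L)
  counts <- vapply(sizes, function(s) {
    gi <- (row(B) - 1L) %/% s
    gj <- (col(B) - 1L) %/% s
    length(unique((gi * (max(gj) + 1L) + gj)[B]))
  }, numeric(1))
  fd <- unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
  lac <- gliding_box_lacunarity(B, 4L)
  c(fd = fd, lacunarity = lac)
}

gliding_box_lacunarity <- function(B, s) {
  s <- min(s, dim(B))
  # box sums via 2D cumulative sums (dim-safe for 1-row/1-col patterns)
  cs <- matrix(B * 1, nrow(B), ncol(B))
  for (j in seq_len(ncol(cs))) cs[, j] <- cumsum(cs[, j])
  for (i in seq_len(nrow(cs))) cs[i, ] <- cumsum(cs[i, ])
  cs <- rbind(0, cbind(0, cs))
  nr <- nrow(B); nc <- ncol(B)
  ri <- seq_len(nr - s + 1L)
  ci <- seq_len(nc - s + 1L)
  mass <- cs[ri + s, ci + s, drop = FALSE] - cs[ri, ci + s, drop = FALSE] -
    cs[ri + s, ci, drop = FALSE] + cs[ri, ci, drop = FALSE]
  mu <- mean(mass)
  if (mu == 0) return(0)
  vr <- mean((mass - mu)^2)
  vr / mu^2 + 1
}

#' Shape features of a binary mask
#'
#' Computed on the largest 4-connected component: `area` (pixel count),
#' `perimeter` (count of exposed pixel edges, 4-connectivity), `circularity`
#' (`4*pi*A / P^2`), `eccentricity` (from central second moments of the pixel
#' lattice), `solidity` (area / convex-hull area, hull taken over pixel
#' corners so a filled rectangle scores 1), `extent` (area / bounding-box
#' area). All are invariant to translation.
#'
#' @param mask Logical matrix.
#' @return Named numeric vector of 6 features.
#' @export
shape_features <- function(mask) {
  mask <- as.matrix(mask) != 0
  if (!any(mask)) abort("Empty mask.", class = "radiotex_empty_mask")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)
  A <- sum(comp)
  p <- pad_reflect(comp, 1L)
  p[c(1L, nrow(p)), ] <- FALSE
  p[, c(1L, ncol(p))] <- FALSE
  nr <- nrow(comp); nc <- ncol(comp)
  exposed <- 0L
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- p[(2L + d[1L]):(nr + 1L + d[1L]), (2L + d[2L]):(nc + 1L + d[2L]), drop = FALSE]
    exposed <- exposed + sum(comp & !nb)
  }
  rs <- row(comp)[comp]
  cs <- col(comp)[comp]
  mu20 <- mean((rs - mean(rs))^2)
  mu02 <- mean((cs - mean(cs))^2)
  mu11 <- mean((rs - mean(rs)) * (cs - mean(cs)))
  tr <- mu20 + mu02
  det_rt <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + det_rt) / 2
  l2 <- (tr - det_rt) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  # convex hull over the 4 corners of every component pixel
  hx <- c(rs - 0.5, rs - 0.5, rs + 0.5, rs + 0.5)
  hy <- c(cs - 0.5, cs + 0.5, cs - 0.5, cs + 0.5)
  hull <- grDevices::chull(hx, hy)
  hull_area <- polygon_area(hx[hull], hy[hull])
  bbox_area <- (diff(range(rs)) + 1) * (diff(range(cs)) + 1)
  c(
    area = A,
    perimeter = exposed,
    circularity = 4 * pi * A / exposed^2,
    eccentricity = ecc,
    solidity = A / hull_area,
    extent = A / bbox_area
  )
}
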