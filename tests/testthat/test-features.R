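test_that("first-order statistics match hand-computed moments", {
  f <- fos(c(2, 4, 4, 4, 5, 5, 7, 9))
  # deviations (-3,-1,-1,-1,0,0,2,4): m2 = 32/8 = 4, m3 = 42/8, skew = 5.25/8
  expect_equal(f[["mean"]], 5)
  expect_equal(f[["variance"]], 4)
  expect_equal(f[["skewness"]], 0.65625)

  fc <- fos(rep(3, 10))
  expect_equal(unname(fc[c("variance", "skewness", "entropy")]), c(0, 0, 0))

  f2 <- fos(rep(c(1, 2), 8))  # two occupied bins at p = 0.5
  expect_equal(f2[["entropy"]], 1)

  expect_error(fos(3), class = "radiotex_degenerate_input")
})

test_that("co-occurrence matrices enumerate the 2x2 toy example", {
  fx <- generate_worked_fixtures()$glcm_toy
  q <- make_quantized(fx$data, 2)
  mats <- glcm_matrix(q)
  expect_equal(mats$deg0, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(mats$deg90, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(sum(mats$deg45), 1)
  expect_true(all(vapply(mats[!vapply(mats, is.null, TRUE)],
                         function(P) isTRUE(all.equal(P, t(P))), TRUE)))

  f0 <- radiotex:::glcm_features_one(mats$deg0)
  expect_equal(unname(f0[c("contrast", "correlation", "energy", "homogeneity",
                           "entropy", "dissimilarity")]),
               c(0, 1, 0.5, 1, 1, 0))
  f90 <- radiotex:::glcm_features_one(mats$deg90)
  expect_equal(unname(f90[c("contrast", "correlation")]), c(1, -1))
})

test_that("uniform co-occurrence matrix hits the closed-form features", {
  L <- 4
  P <- matrix(1 / L^2, L, L)
  f <- radiotex:::glcm_features_one(P)
  expect_equal(f[["energy"]], 1 / L^2)
  expect_equal(f[["entropy"]], 2 * log2(L))
})

test_that("run-length features reproduce the hand-enumerated 2x3 example", {
  fx <- generate_worked_fixtures()$glrm_toy
  q <- make_quantized(fx$data, 2)
  runs <- radiotex:::glrm_counts(q$levels, "deg0")
  expect_equal(sort(paste(runs$g, runs$l)),
               sort(paste(fx$expected$runs_deg0$g, fx$expected$runs_deg0$l)))
  f <- radiotex:::glrm_features_one(runs$g, runs$l, 6)
  expect_equal(f[["sre"]], fx$expected$sre, tolerance = 1e-12)
  expect_equal(f[["lre"]], fx$expected$lre, tolerance = 1e-12)
  expect_equal(f[["rp"]], fx$expected$rp)
  expect_equal(f[["gln"]], fx$expected$gln, tolerance = 1e-12)
  expect_equal(f[["rln"]], fx$expected$rln)
  expect_equal(f[["lgre"]], fx$expected$lgre)
})

test_that("checkerboard runs all have length 1", {
  lev <- 1L + (outer(1:8, 1:8, `+`) %% 2L)
  q <- make_quantized(lev, 2)
  for (d in c("deg0", "deg90")) {
    runs <- radiotex:::glrm_counts(q$levels, d)
    f <- radiotex:::glrm_features_one(runs$g, runs$l, sum(q$mask))
    expect_equal(unname(f[c("sre", "lre", "rp")]), c(1, 1, 1))
  }
})

test_that("GLCM and GLRM agree with brute-force enumerators on random images", {
  set.seed(42)
  for (rep in 1:25) {
    q <- random_quantized(8, 8, 4)
    mats <- glcm_matrix(q)
    for (d in names(mats)) {
      expect_equal(mats[[d]], oracle_glcm(q, d), tolerance = 1e-12)
    }
    keep <- mats[!vapply(mats, is.null, TRUE)]
    expected <- Reduce(`+`, lapply(keep, oracle_glcm_features)) / length(keep)
    expect_equal(glcm_features(mats), expected, tolerance = 1e-12)
    expect_equal(glrm_features(q), oracle_glrm_features(q), tolerance = 1e-12)
  }
})

test_that("masked-out pixels break runs and are excluded from pairs", {
  lev <- matrix(1L, 1, 5)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE), 1, 5)
  q <- make_quantized(lev, 2, mask)
  runs <- radiotex:::glrm_counts(q$levels, "deg0")
  expect_equal(runs$l, c(2L, 2L))  # the gap splits one run of 5 into two of 2
})

test_that("LBP histogram is normalized, concentrated for flat input, rotation-invariant", {
  flat <- lbp_features(make_roi(matrix(0.5, 10, 10)))
  expect_equal(flat[["riu2_8"]], 1)  # all neighbors >= center everywhere
  set.seed(8)
  px <- matrix(runif(400), 20, 20)
  h1 <- lbp_features(make_roi(px))
  expect_equal(sum(h1), 1)
  h2 <- lbp_features(make_roi(t(px[nrow(px):1, ])))  # 90-degree rotation
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("box-counting dimension recovers plane and line patterns", {
  # bright half-plane: binarized foreground is a filled 32x16 rectangle
  px <- matrix(0, 32, 32); px[, 17:32] <- 1
  f <- fractal_features(make_roi(px))
  expect_lt(abs(f[["fd"]] - 2), 0.1)
  # single bright row: foreground is a 1x32 line
  px2 <- matrix(0, 32, 32); px2[16, ] <- 1
  f2 <- fractal_features(make_roi(px2))
  expect_lt(abs(f2[["fd"]] - 1), 0.1)
  # homogeneous mass: gliding-box variance is 0, lacunarity 1
  expect_equal(f[["lacunarity"]], 1)
})

test_that("shape features match hand counts and are translation-invariant", {
  sq <- matrix(FALSE, 7, 7); sq[2:4, 2:4] <- TRUE
  f <- shape_features(sq)
  expect_equal(f[["area"]], 9)
  expect_equal(f[["perimeter"]], 12)
  expect_equal(f[["circularity"]], 4 * pi * 9 / 144)
  expect_equal(f[["extent"]], 1)
  expect_equal(f[["solidity"]], 1)

  line <- matrix(FALSE, 4, 14); line[2, 2:11] <- TRUE
  fl <- shape_features(line)
  expect_equal(fl[["extent"]], 1)
  expect_equal(fl[["eccentricity"]], 1)

  sq2 <- matrix(FALSE, 7, 7); sq2[4:6, 3:5] <- TRUE
  expect_equal(shape_features(sq2), f)
  expect_error(shape_features(matrix(FALSE, 3, 3)), class = "radiotex_empty_mask")
})

test_that("shape features use the largest connected component", {
  m <- matrix(FALSE, 10, 10)
  m[2:6, 2:6] <- TRUE   # 25-pixel square
  m[9, 9] <- TRUE       # stray pixel
  expect_equal(shape_features(m)[["area"]], 25)
})
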