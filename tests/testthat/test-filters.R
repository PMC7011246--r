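test_that("Sobel gradient magnitude matches hand-applied stencils", {
  const <- gradient_image(make_roi(matrix(0.5, 10, 10)))
  expect_true(all(const$pixels == 0))

  ramp <- make_roi(matrix(rep(seq_len(10), 10), 10, 10))  # I[r, c] = r
  g <- gradient_image(normalize_roi(ramp))
  # unit-step ramp: |G| = 8 with rows-(1,2,1) Sobel weights; the normalized
  # ramp has step 1/9
  interior <- g$pixels[3:8, 3:8]
  expect_equal(max(abs(interior - 8 / 9)), 0, tolerance = 1e-10)

  small <- matrix(FALSE, 10, 10); small[3:6, 3:6] <- TRUE
  expect_error(gradient_image(make_roi(matrix(runif(100), 10, 10), small)),
               class = "radiotex_degenerate_roi")
})

test_that("gradient magnitude multiset is preserved under 90-degree rotation", {
  set.seed(3)
  px <- matrix(runif(144), 12, 12)
  g1 <- gradient_image(make_roi(px))
  g2 <- gradient_image(make_roi(t(px[nrow(px):1, ])))
  expect_equal(sort(g1$pixels[g1$mask]), sort(g2$pixels[g2$mask]),
               tolerance = 1e-12)
})

test_that("gradient and orientation histogram ignore constant offsets", {
  set.seed(4)
  px <- matrix(runif(256), 16, 16)
  g1 <- gradient_image(make_roi(px))
  g2 <- gradient_image(make_roi(px + 5))
  expect_equal(g1$pixels, g2$pixels, tolerance = 1e-12)
  expect_equal(hog_histogram(make_roi(px))$value,
               hog_histogram(make_roi(px + 5))$value, tolerance = 1e-12)
})

test_that("Haar transform reproduces the hand-computed 2x2 example", {
  fx <- generate_worked_fixtures()$haar_toy
  m <- matrix(0, 6, 6)
  m[1:2, 1:2] <- fx$data
  roi <- make_roi(m)
  b <- haar_dwt(roi)
  expect_equal(b$approximate$pixels[1, 1], fx$expected$approximate)
  expect_equal(b$horizontal$pixels[1, 1], fx$expected$horizontal)
  expect_equal(b$vertical$pixels[1, 1], fx$expected$vertical)
  expect_equal(b$diagonal$pixels[1, 1], fx$expected$diagonal)
  block_energy <- b$approximate$pixels[1, 1]^2 + b$horizontal$pixels[1, 1]^2 +
    b$vertical$pixels[1, 1]^2 + b$diagonal$pixels[1, 1]^2
  expect_equal(block_energy, fx$expected$energy)  # 84 = 1 + 9 + 25 + 49
})

test_that("constant images put everything in the approximate band", {
  b <- haar_dwt(make_roi(matrix(3, 8, 8) / 3))
  expect_true(all(b$approximate$pixels == 2))
  expect_true(all(b$horizontal$pixels == 0))
  expect_true(all(b$vertical$pixels == 0))
  expect_true(all(b$diagonal$pixels == 0))
})

test_that("Haar conserves energy and reconstructs exactly, odd and even sizes", {
  set.seed(9)
  for (dims in list(c(16, 16), c(33, 47), c(17, 24), c(8, 31))) {
    px <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    roi <- structure(list(pixels = px, mask = matrix(TRUE, dims[1], dims[2]),
                          subject_id = "t", pixel_spacing = NULL),
                     class = "roi_image")
    b <- haar_dwt(roi)
    e_bands <- sum(b$approximate$pixels^2) + sum(b$horizontal$pixels^2) +
      sum(b$vertical$pixels^2) + sum(b$diagonal$pixels^2)
    expect_equal(e_bands, sum(b$padded^2), tolerance = 1e-9)
    expect_equal(haar_idwt(b), b$padded, tolerance = 1e-9)
  }
})

test_that("band masks follow the 2x2 OR (default) and AND rules", {
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE; mask[3:4, 3:4] <- TRUE
  mask[1, 3] <- TRUE; mask[2, 3] <- TRUE; mask[1, 4] <- TRUE; mask[2, 4] <- TRUE
  mask[3, 1] <- TRUE; mask[4, 1] <- TRUE; mask[3, 2] <- TRUE; mask[4, 2] <- TRUE
  roi <- structure(list(pixels = matrix(runif(16), 4, 4), mask = mask,
                        subject_id = "t", pixel_spacing = NULL),
                   class = "roi_image")
  b_or <- haar_dwt(roi, mask_rule = "or")
  b_and <- haar_dwt(roi, mask_rule = "and")
  expect_identical(b_or$approximate$mask, matrix(TRUE, 2, 2))
  expect_identical(b_and$approximate$mask,
                   matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
})

test_that("orientation histogram localizes a vertical ramp at 90 degrees", {
  ramp <- normalize_roi(make_roi(matrix(rep(seq_len(12), 12), 12, 12)))
  h <- hog_histogram(ramp)
  expect_equal(h$value[h$bin_center == 90], 1)
  # rotate 90 degrees: gradients fold onto the 0/180 wraparound, splitting
  # between the two boundary bins
  rot <- normalize_roi(make_roi(t(matrix(rep(seq_len(12), 12), 12, 12))))
  h2 <- hog_histogram(rot)
  expect_equal(sum(h2$value[h2$bin_center %in% c(10, 170)]), 1)
})

test_that("orientation histogram is unsigned and degenerates to uniform", {
  set.seed(12)
  px <- matrix(runif(400), 20, 20)
  h1 <- hog_histogram(make_roi(px))
  h2 <- hog_histogram(make_roi(px[20:1, 20:1]))  # 180-degree rotation
  expect_equal(h1$value, h2$value, tolerance = 1e-10)
  expect_equal(sum(h1$value), 1)
  expect_warning(hu <- hog_histogram(make_roi(matrix(1, 10, 10))), "zero")
  expect_equal(hu$value, rep(1 / 9, 9))
})
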