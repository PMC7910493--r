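test_that("grayscale conversion uses Rec. 601 luminance", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(as.vector(rgbToGrayscale(px(255, 255, 255))), 255)
  expect_equal(as.vector(rgbToGrayscale(px(255, 0, 0))), 76)
  expect_equal(as.vector(rgbToGrayscale(px(37, 37, 37))), 37)
  # unit-range float input stays float
  expect_equal(as.vector(rgbToGrayscale(px(0.5, 0.5, 0.5))), 0.5)
  expect_error(rgbToGrayscale(array(0, dim = c(2, 2, 4))), "3-channel")
})

test_that("TPS reproduces affine maps with zero warping", {
  src <- cbind(c(0, 10, 0, 10, 5), c(0, 0, 10, 10, 5))
  idT <- fitTPS(src, src)
  expect_equal(max(abs(idT@weights)), 0, tolerance = 1e-9)
  expect_equal(idT@affine, rbind(c(0, 0), c(1, 0), c(0, 1)),
               tolerance = 1e-9)

  shift <- fitTPS(src, src + cbind(rep(5, 5), rep(-3, 5)))
  expect_equal(max(abs(shift@weights)), 0, tolerance = 1e-9)
  expect_equal(tpsMap(shift, cbind(2, 2)), cbind(7, -1), tolerance = 1e-9)

  withr::with_seed(2, {
    A <- matrix(stats::rnorm(4, sd = 0.3), 2) + diag(2)
    tA <- c(3, -7)
    dst <- src %*% t(A) + matrix(tA, 5, 2, byrow = TRUE)
    aff <- fitTPS(src, dst)
    expect_equal(max(abs(aff@weights)), 0, tolerance = 1e-8)
    expect_equal(tpsBendingEnergy(aff), 0, tolerance = 1e-10)
  })
})

test_that("TPS interpolates 18 random landmarks to sub-1e-6 pixels", {
  withr::with_seed(7, {
    src <- cbind(stats::runif(18, 0, 100), stats::runif(18, 0, 100))
    dst <- src + cbind(stats::rnorm(18, sd = 4), stats::rnorm(18, sd = 4))
    tr <- fitTPS(src, dst)
    resid <- sqrt(rowSums((tpsMap(tr, src) - dst)^2))
    expect_lt(max(resid), 1e-6)
    # side conditions: weights orthogonal to 1 and to the source coords
    expect_lt(max(abs(colSums(tr@weights))), 1e-8)
    expect_lt(max(abs(t(tr@source) %*% tr@weights)), 1e-6)
  })
})

test_that("TPS rejects degenerate landmark sets", {
  dup <- cbind(c(0, 0, 5), c(1, 1, 2))
  expect_error(fitTPS(dup, dup), "duplicate")
  col <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_error(fitTPS(col, col + 1), "singular|collinear")
  expect_error(fitTPS(cbind(0, 0), cbind(1, 1)), "n >= 3")
})

test_that("bending energy is non-increasing in regularization", {
  withr::with_seed(9, {
    src <- cbind(stats::runif(12, 0, 50), stats::runif(12, 0, 50))
    dst <- src + cbind(stats::rnorm(12, sd = 6), stats::rnorm(12, sd = 6))
    lams <- c(0, 1, 10, 100)
    be <- vapply(lams, function(l) tpsBendingEnergy(fitTPS(src, dst, l)),
                 numeric(1))
    expect_true(all(diff(be) <= 1e-9))
  })
})

test_that("warping resamples correctly for identity and translation", {
  withr::with_seed(3, img <- matrix(stats::runif(64), 8, 8))
  corners <- cbind(c(0, 7, 0, 7), c(0, 0, 7, 7))
  idT <- fitTPS(corners, corners)
  expect_equal(warpImage(img, idT, mode = "bilinear"), img, tolerance = 1e-9)
  expect_equal(warpImage(img, idT, mode = "nearest"), img)

  # transform maps output to input coordinates: output pixel (x, y)
  # samples input (x + 2, y + 1), i.e. content shifts left/up
  tr <- fitTPS(corners, corners + cbind(rep(2, 4), rep(1, 4)))
  w <- warpImage(img, tr, mode = "nearest")
  expect_equal(w[1:7, 1:6], img[2:8, 3:8])
  expect_true(all(w[8, ] == 0))   # out-of-domain background

  lab <- matrix(sample(c(0, 3, 7), 64, replace = TRUE), 8, 8)
  wl <- warpImage(lab, tr, mode = "nearest")
  expect_true(all(wl %in% c(lab, 0)))
  expect_error(warpImage(img, idT, mode = "cubic"), "arg")
})

test_that("ROI transfer assigns majority labels on the MRI grid", {
  # 20x20 histology grid onto a 5x5 MRI grid: pure 4x scale
  hist <- cbind(c(0, 19, 0, 19), c(0, 0, 19, 19))
  mri <- hist / 4
  tr <- fitTPS(hist, mri)
  full <- matrix(TRUE, 20, 20)
  lab <- transferROIs(list(tumor = full), tr, c(5, 5))
  expect_true(all(lab == 1L))
  expect_equal(attr(lab, "ties"), 0L)

  left <- matrix(FALSE, 20, 20); left[, 1:10] <- TRUE
  right <- !left
  lab2 <- transferROIs(list(a = left, b = right), tr, c(5, 5))
  # brute-force expectation: columns of the left half map to MRI cols 1-3
  expect_true(all(lab2[, 1:2] == 1L))
  expect_true(all(lab2[, 4:5] == 2L))

  expect_error(transferROIs(list(a = left, b = left), tr, c(5, 5)),
               "overlapping")
  empty <- transferROIs(list(), tr, c(5, 5))
  expect_true(all(is.na(empty)))
})
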