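test_that("DTI fit recovers isotropic and cylindrical tensors", {
  sch <- testScheme(30)
  iso <- voxelModel(spectrum = isotropicSpectrum(0.7, 1))
  f <- fitDTI(predictSignal(iso, sch), sch)
  expect_equal(f$meanAdc, 0.7, tolerance = 1e-3)
  expect_equal(f$meanFa, 0, tolerance = 1e-3)

  cyl <- voxelModel(list(anisotropicComponent(1, 1.5, 0.3, c(0, 0, 1))))
  f2 <- fitDTI(predictSignal(cyl, sch), sch)
  expect_equal(f2$meanFa, 0.7698, tolerance = 1e-3)
  expect_equal(sort(f2$eigvals), sort(c(1.5, 0.3, 0.3)), tolerance = 1e-3)
})

test_that("DTI fit rejects rank-deficient designs", {
  sch5 <- gradientScheme(
    c(0, rep(2000, 5)),
    rbind(c(0, 0, 0), diag(3), c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2)))
  s <- rep(0.5, 6)
  expect_error(fitDTI(s, sch5), "ill-posed")
})

test_that("design matrix columns are normalized basis signals", {
  sch <- gradientScheme(c(0, 1000, 2000),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  U <- rbind(c(0, 0, 1))
  A <- buildDesignMatrix(sch, U, isoGrid = c(0.5, 1.5),
                         lambdaInit = c(1.5, 0.3))
  expect_equal(dim(A), c(3L, 3L))
  expect_equal(A[1, ], rep(1, 3))                 # b = 0 row
  expect_equal(A[2, 1], exp(-1 * 0.3))            # gradient perp to axis
  expect_equal(A[3, 1], exp(-2 * 1.5))            # gradient along axis
  expect_equal(A[2, 2], exp(-1 * 0.5))
  expect_true(all(A > 0 & A <= 1))
})

test_that("noiseless single-compartment voxels recover their band", {
  sch <- generateScheme(99, 3000, seed = 1)
  cases <- list(c(0.1, 1), c(0.5, 2), c(1.2, 3), c(2.5, 4))
  bands <- c("highly_restricted_fraction", "restricted_fraction",
             "hindered_fraction", "free_fraction")
  for (cs in cases) {
    m <- voxelModel(spectrum = isotropicSpectrum(cs[1], 1))
    fit <- fitVoxel(predictSignal(m, sch), sch)
    expect_gte(fit$features[[bands[cs[2]]]], 0.95)
    expect_lte(fit$features[["fiber_fraction"]], 0.02)
  }
})

test_that("noiseless single fibers recover fraction and axis", {
  sch <- generateScheme(99, 3000, seed = 1)
  ax <- c(0.3, -0.5, 0.81); ax <- ax / sqrt(sum(ax^2))
  m <- voxelModel(list(anisotropicComponent(1, 1.5, 0.3, ax)))
  fit <- fitVoxel(predictSignal(m, sch), sch)
  expect_gte(fit$features[["fiber_fraction"]], 0.95)
  fitted <- fit$model@components[[1]]@axis
  angle <- acos(min(1, abs(sum(fitted * ax)))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("band edges follow the closed-upper-bound convention", {
  sch <- generateScheme(99, 3000, seed = 1)
  # mass exactly at D = 0.8 counts as restricted, at D = 2.0 as hindered
  m8 <- voxelModel(spectrum = isotropicSpectrum(0.8, 1))
  f8 <- fitVoxel(predictSignal(m8, sch), sch)
  expect_gt(f8$features[["restricted_fraction"]],
            f8$features[["hindered_fraction"]])
  m2 <- voxelModel(spectrum = isotropicSpectrum(2.0, 1))
  f2 <- fitVoxel(predictSignal(m2, sch), sch)
  expect_gt(f2$features[["hindered_fraction"]],
            f2$features[["free_fraction"]])
})

test_that("mixture composition is recovered and beats the iso-only fit", {
  sch <- generateScheme(99, 3000, seed = 1)
  s <- predictSignal(mixtureModel(), sch)
  fit <- fitVoxel(s, sch)
  expect_equal(fit$features[["fiber_fraction"]], 0.4, tolerance = 0.05)
  expect_equal(fit$features[["restricted_fraction"]], 0.35, tolerance = 0.05)
  expect_equal(fit$features[["hindered_fraction"]], 0.25, tolerance = 0.05)
  isoOnly <- fitVoxel(s, sch, dbsiConfig(anisoThreshold = 2))  # no axes pass
  expect_lte(fit$residual, isoOnly$residual + 1e-8)
})

test_that("acquisition order does not affect the fit", {
  sch <- testScheme(30)
  s <- addNoise(predictSignal(mixtureModel(), sch), 50, seed = 2)
  fit <- fitVoxel(s, sch)
  withr::with_seed(4, perm <- sample.int(nAcquisitions(sch)))
  schP <- gradientScheme(bValues(sch)[perm], gradientDirections(sch)[perm, ])
  fitP <- fitVoxel(s[perm], schP)
  expect_equal(fit$features, fitP$features, tolerance = 1e-6)
})

test_that("degenerate voxel inputs raise the documented errors", {
  sch <- testScheme(30)
  expect_error(fitVoxel(rep(0, nAcquisitions(sch)), sch), "masked")
  expect_error(fitVoxel(rep(0.5, 10), sch), "match")
  single <- gradientScheme(c(0, rep(1000, 8)),
                           rbind(matrix(0, 1, 3),
                                 gradientDirections(testScheme(8))[-1, ]))
  expect_error(fitVoxel(rep(0.7, 9), single, dbsiConfig()), "distinct b")
})

test_that("volume fitting honors masks and propagates NA", {
  sch <- testScheme(30)
  lm <- array(0L, dim = c(2, 2, 1))
  ph <- buildSignalPhantom(lm, sch, snr = Inf, seed = 3)
  dwi <- ph$dwi
  dwi[2, ] <- NA
  fv <- fitVolume(dwi, sch)
  expect_true(all(is.na(fv$features[2, ])))
  expect_false(any(is.na(fv$features[1, ])))
  # empty mask: empty output, no error
  fv0 <- fitVolume(dwi, sch, mask = rep(FALSE, 4))
  expect_true(all(is.na(as.matrix(fv0$features))))
  expect_error(fitVolume(dwi[, 1:10], sch), "acquisitions")
})

test_that("noiseless WM phantom maps recover fiber fraction within 0.05", {
  sch <- generateScheme(99, 3000, seed = 1)
  lm <- array(0L, dim = c(8, 8, 1))
  ph <- buildSignalPhantom(lm, sch, snr = Inf, seed = 9)
  fv <- fitVolume(ph$dwi, sch)
  err <- abs(fv$features$fiber_fraction - ph$truth$fiber_fraction)
  expect_lte(mean(err), 0.05)
  expect_lte(max(err), 0.10)
})

test_that("metric maps are written as one NIfTI per metric", {
  sch <- testScheme(20)
  lm <- array(0L, dim = c(2, 2, 1))
  ph <- buildSignalPhantom(lm, sch, snr = Inf, seed = 3)
  fv <- fitVolume(ph$dwi, sch)
  fv$dim <- c(2, 2, 1)
  pref <- file.path(tempdir(), "maps")
  paths <- writeMetricMaps(fv, pref, metrics = c("fiber_fraction", "mean_adc"))
  expect_true(all(file.exists(paths)))
  vol <- RNifti::readNifti(paths[1])
  expect_equal(dim(vol)[1:2], c(2L, 2L))
  expect_equal(as.vector(vol), fv$features$fiber_fraction, tolerance = 1e-6)
})
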