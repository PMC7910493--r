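test_that("8:1:1 split sizes follow the rounding contract", {
  big <- data.frame(voxel_id = seq_len(99388), x = 0)
  sp <- splitDataset(big, seed = 1)
  expect_equal(nrow(sp$test), 9939L)
  expect_equal(nrow(sp$validation), 9939L)
  expect_equal(nrow(sp$train), 99388L - 2L * 9939L)

  ten <- data.frame(voxel_id = 1:10, x = 0)
  sp10 <- splitDataset(ten, seed = 1)
  expect_equal(vapply(sp10, nrow, integer(1)),
               c(train = 8L, validation = 1L, test = 1L))
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  tab <- separableTable(30)
  sp <- splitDataset(tab, seed = 11, stratified = TRUE)
  ids <- sort(unlist(lapply(sp, `[[`, "voxel_id"), use.names = FALSE))
  expect_identical(ids, tab$voxel_id)
  expect_length(intersect(sp$test$voxel_id, sp$train$voxel_id), 0L)
  sp2 <- splitDataset(tab, seed = 11, stratified = TRUE)
  expect_identical(sp, sp2)
  sp3 <- splitDataset(tab, seed = 12, stratified = TRUE)
  expect_false(identical(sp$test$voxel_id, sp3$test$voxel_id))
  # stratification keeps class shares in the test partition
  expect_true(all(abs(table(sp$test$class) - 3) <= 1))

  tiny <- data.frame(x = 1:5, class = c("a", "a", "b", "b", "b"))
  expect_error(splitDataset(tiny, stratified = TRUE), ">= 3 rows")
})

test_that("SMOTE balances to the majority count with convex rows", {
  tab <- twoClassTable(100, 40)
  bal <- smoteBalance(tab, k = 5, seed = 2)
  expect_equal(as.vector(table(bal$class)), c(100L, 100L))
  expect_equal(attr(bal, "nSynthetic"), 60L)
  # originals retained unchanged, synthetics appended
  expect_identical(bal[seq_len(nrow(tab)), ], tab, ignore_attr = TRUE)
  synth <- bal[is.na(bal$voxel_id), c("f1", "f2")]
  orig <- as.matrix(tab[tab$class == "B", c("f1", "f2")])
  for (i in seq_len(nrow(synth))) {
    p <- as.numeric(synth[i, ])
    hit <- FALSE
    for (a in seq_len(nrow(orig) - 1)) for (b in (a + 1):nrow(orig)) {
      if (onSegment(p, orig[a, ], orig[b, ])) { hit <- TRUE; break }
    }
    expect_true(hit)
  }
})

test_that("SMOTE edge cases warn and fall back sensibly", {
  bal0 <- smoteBalance(twoClassTable(50, 50), seed = 1)
  expect_equal(attr(bal0, "nSynthetic"), 0L)

  small <- twoClassTable(10, 3)
  expect_warning(smoteBalance(small, k = 5, seed = 1), "clamped")

  one <- twoClassTable(5, 1)
  expect_warning(bal1 <- smoteBalance(one, seed = 1), "duplicat")
  expect_equal(as.vector(table(bal1$class)), c(5L, 5L))
})

test_that("backpropagation matches numerical gradients", {
  withr::with_seed(13, {
    X <- matrix(stats::rnorm(8 * 3), 8, 3)
    yIdx <- sample.int(2, 8, replace = TRUE)
    Y <- matrix(0, 8, 2); Y[cbind(1:8, yIdx)] <- 1
    layers <- dhikit:::.initLayers(3, c(4, 4), 2)
    loss <- function(layers) {
      fw <- dhikit:::.dnnForward(layers, X, training = TRUE)
      dhikit:::.crossEntropy(fw$probs, Y)
    }
    fw <- dhikit:::.dnnForward(layers, X, training = TRUE)
    grads <- dhikit:::.dnnBackward(layers, fw$cache, fw$probs, Y)
    eps <- 1e-5
    for (l in c(1, 2, 3)) for (pn in names(grads[[l]])) {
      if (is.null(grads[[l]][[pn]])) next
      p <- layers[[l]][[pn]]
      for (ix in utils::head(seq_along(p), 3)) {
        lp <- layers; lm <- layers
        lp[[l]][[pn]][ix] <- p[ix] + eps
        lm[[l]][[pn]][ix] <- p[ix] - eps
        num <- (loss(lp) - loss(lm)) / (2 * eps)
        expect_equal(as.numeric(grads[[l]][[pn]][ix]), num,
                     tolerance = 1e-4)
      }
    }
  })
})

test_that("the default architecture is ten hidden layers plus softmax-6", {
  tab <- separableTable(12)
  sp <- splitDataset(tab, seed = 1, stratified = TRUE)
  mod <- trainDNN(sp$train, sp$validation,
                  dnnConfig(maxEpochs = 1, batchSize = 20, seed = 1))
  expect_length(mod@layers, 11L)                     # 10 hidden + head
  expect_equal(ncol(mod@layers[[1]]$W), 128L)
  expect_equal(ncol(mod@layers[[11]]$W), 6L)
  expect_identical(mod@classLevels, histologyClasses())
  pr <- predict(mod, sp$test)
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, nrow(sp$test)),
               tolerance = 1e-6)
})

test_that("training separates a two-class toy problem deterministically", {
  withr::with_seed(21, {
    n <- 250
    X <- rbind(matrix(stats::rnorm(n * 4, 0), n, 4),
               matrix(stats::rnorm(n * 4, 4), n, 4))
    tab <- as.data.frame(X)
    names(tab) <- c("m1", "m2", "m3", "m4")
    tab$class <- factor(rep(c("neg", "pos"), each = n))
  })
  sp <- splitDataset(tab, seed = 2, stratified = TRUE)
  cfg <- dnnConfig(hiddenLayers = 4, hiddenWidth = 32, maxEpochs = 50,
                   batchSize = 50, seed = 3)
  mod <- trainDNN(sp$train, sp$validation, cfg,
                  features = c("m1", "m2", "m3", "m4"))
  pr <- predict(mod, sp$validation)
  expect_gte(mean(pr$labels == sp$validation$class), 0.98)
  # training rows themselves are reproduced on a separable problem
  prTr <- predict(mod, sp$train)
  expect_gte(mean(prTr$labels == sp$train$class), 0.98)
  # loss decreases over the first epochs
  expect_lt(mod@history$trainLoss[min(5, nrow(mod@history))],
            mod@history$trainLoss[1])

  mod2 <- trainDNN(sp$train, sp$validation, cfg,
                   features = c("m1", "m2", "m3", "m4"))
  expect_identical(mod@history$valLoss, mod2@history$valLoss)
})

test_that("validation and test data are never touched by balancing/training", {
  tab <- separableTable(40)
  sp <- splitDataset(tab, seed = 5, stratified = TRUE)
  valBefore <- serialize(sp$validation, NULL)
  testBefore <- serialize(sp$test, NULL)
  bal <- smoteBalance(sp$train, seed = 6)
  mod <- trainDNN(bal, sp$validation,
                  dnnConfig(hiddenLayers = 2, hiddenWidth = 16,
                            maxEpochs = 3, seed = 7))
  expect_identical(serialize(sp$validation, NULL), valBefore)
  expect_identical(serialize(sp$test, NULL), testBefore)
  # balanced table has exactly equal class counts
  expect_length(unique(table(bal$class)), 1L)
})

test_that("prediction validates feature schemas", {
  tab <- separableTable(12)
  sp <- splitDataset(tab, seed = 1)
  mod <- trainDNN(sp$train, sp$validation,
                  dnnConfig(hiddenLayers = 2, hiddenWidth = 8,
                            maxEpochs = 1, seed = 1))
  expect_error(predict(mod, sp$test[, 1:4]), "missing feature")
  expect_error(predict(mod, as.matrix(sp$test[, 2:5])), "mismatch")
  # all-zero features still give valid probability rows
  z <- predict(mod, matrix(0, 3, 12))
  expect_false(any(is.na(z$probabilities)))
  expect_equal(rowSums(z$probabilities), rep(1, 3), tolerance = 1e-6)
})
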