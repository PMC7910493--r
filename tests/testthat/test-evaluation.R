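test_that("confusion matrices count, normalize and score correctly", {
  perfect <- confusionStats(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(diag(perfect$matrix), rep(1L, 3), ignore_attr = TRUE)

  cs <- confusionStats(c(0, 0, 1), c(0, 1, 1))
  expect_equal(cs$accuracy, 2 / 3)
  expect_equal(unname(cs$tpr), c(0.5, 1.0))
  expect_equal(rowSums(cs$normalized), c(`0` = 1, `1` = 1))

  one <- confusionStats(rep("x", 4), c("x", "x", "y", "x"),
                        levels = c("x", "y"))
  expect_equal(one$accuracy, unname(one$tpr["x"]))
  expect_error(confusionStats(character(0), character(0)), "empty")
})

test_that("ROC analysis matches hand-worked and degenerate cases", {
  roc <- rocOneVsRest(c(0.8, 0.35, 0.4, 0.1), c(1, 1, 0, 0), 1)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(utils::tail(roc$points$fpr, 1), 1)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)

  expect_equal(rocOneVsRest(c(3, 4, 1, 2), c(1, 1, 0, 0), 1)$auc, 1)
  expect_equal(rocOneVsRest(rep(0.5, 6), rep(c(1, 0), 3), 1)$auc, 0.5)
  expect_error(rocOneVsRest(1:3, c(1, 1, 1), 1), "undefined")
})

test_that("trapezoidal AUC equals brute-force pair counting", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(10:50, 1)
      y <- rbinom(n, 1, 0.5)
      if (sum(y) == 0 || sum(y) == n) next
      s <- round(stats::rnorm(n), sample(0:1, 1))  # induce ties sometimes
      expect_equal(rocOneVsRest(s, y, 1)$auc, pairwiseAUC(y, s))
    }
  })
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    y <- rbinom(80, 1, 0.4)
    s <- stats::rnorm(80) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
    expect_equal(rocOneVsRest(s, y, 1)$auc, ref, tolerance = 1e-10)
  })
})

test_that("Youden operating points break ties toward specificity", {
  perfect <- youdenPoint(rocOneVsRest(c(3, 4, 1, 2), c(1, 1, 0, 0), 1))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$youden, 1)

  yp <- youdenPoint(rocOneVsRest(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0), 1))
  expect_equal(yp$youden, 0.5)
  expect_equal(yp$sensitivity, 0.5)
  expect_equal(yp$specificity, 1.0)

  flat <- youdenPoint(rocOneVsRest(rep(0.3, 6), rep(c(1, 0), 3), 1))
  expect_equal(flat$youden, 0)
})

test_that("precision-recall uses the average-precision convention", {
  pr <- prOneVsRest(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0), 1)
  expect_equal(pr$auc, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(prOneVsRest(c(0.9, 0.8), c(1, 0), 1)$auc, 1)
  # F1 from hard labels: precision 0.5, recall 1 -> 2/3
  f <- prOneVsRest(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0), 1,
                   predictedLabels = c(1, 1, 1, 1))
  expect_equal(f$f1, 2 / 3)
  expect_error(prOneVsRest(1:3, c(0, 0, 0), 1), "no positive")
})

test_that("micro-averaged one-vs-rest TPRs reproduce overall accuracy", {
  withr::with_seed(41, {
    true <- sample(histologyClasses(), 300, replace = TRUE)
    pred <- ifelse(stats::runif(300) < 0.7, true,
                   sample(histologyClasses(), 300, replace = TRUE))
    cs <- confusionStats(true, pred, levels = histologyClasses())
    counts <- rowSums(cs$matrix)
    present <- counts > 0
    micro <- sum(cs$tpr[present] * counts[present]) / sum(counts)
    expect_equal(micro, cs$accuracy, tolerance = 1e-12)
  })
})

test_that("bootstrap CIs are deterministic and degenerate-safe", {
  const <- bootstrapCI(function(l, s) 1.5, rep(1, 30), rnorm(30),
                       nReps = 200, seed = 1)
  expect_equal(const$lower, 1.5)
  expect_equal(const$upper, 1.5)

  withr::with_seed(5, {
    y <- rep(c(1, 0), each = 40)
    s <- c(stats::rnorm(40, 1.5), stats::rnorm(40))
  })
  ci1 <- bootstrapCI(aucMetric(1), y, s, nReps = 500, seed = 9)
  ci2 <- bootstrapCI(aucMetric(1), y, s, nReps = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)

  expect_error(
    bootstrapCI(function(l, s) stop("nope"), y, s, nReps = 50, seed = 1),
    "unreliable")
})

test_that("bootstrap CI width shrinks with sample size", {
  width <- function(n, seed) {
    withr::with_seed(seed, {
      y <- rep(c(1, 0), each = n / 2)
      s <- c(stats::rnorm(n / 2, 1.2), stats::rnorm(n / 2))
    })
    ci <- bootstrapCI(aucMetric(1), y, s, nReps = 400, seed = 2)
    ci$upper - ci$lower
  }
  w50 <- mean(vapply(1:4, function(k) width(50, k), numeric(1)))
  w800 <- mean(vapply(1:4, function(k) width(800, k), numeric(1)))
  expect_lt(w800, w50 / 2)   # ~ sqrt(16) = 4x expected
})

test_that("Mann-Whitney matches exact small-sample enumeration", {
  sep <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)

  ex <- mannWhitney(c(1, 3), c(2, 4))
  expect_equal(ex$U, 1)
  expect_equal(ex$p, 2 / 3, tolerance = 1e-6)

  same <- mannWhitney(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$p, 1, tolerance = 0.01)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("group statistics reproduce published percent differences", {
  expect_equal(percentDifference(0.43, 0.52), -17)
  expect_equal(percentDifference(0.43, 0.68), -37)
  expect_equal(percentDifference(0.35, 0.26), 35)
  expect_equal(percentDifference(0.35, 0.29), 21)
  expect_equal(percentDifference(0.35, 0.22), 59)
  expect_equal(percentDifference(0.4, 0.4), 0)

  withr::with_seed(3, {
    tab <- data.frame(
      restricted_fraction = c(stats::rnorm(50, 0.35, 0.02),
                              stats::rnorm(50, 0.26, 0.02)),
      class = rep(c("dc_tumor", "normal_wm"), each = 50))
  })
  gs <- groupStats(tab, "restricted_fraction")
  expect_equal(gs$stats$n, c(50L, 50L))
  expect_equal(gs$percentDiff["dc_tumor", "normal_wm"],
               percentDifference(gs$stats$mean[1], gs$stats$mean[2]))
  # population vs sample SD conventions
  gp <- groupStats(tab, "restricted_fraction", sdType = "population")
  expect_lt(gp$stats$sd[1], gs$stats$sd[1])
  expect_error(groupStats(tab, "restricted_fraction", classes = c("necrosis")),
               "missing class")
})

test_that("cohort demographics summarize as published", {
  d <- patientDemographics()
  expect_equal(nrow(d), 9L)
  expect_equal(range(d$ageDiagnosis), c(4, 17))
  expect_equal(range(d$ageAutopsy), c(7, 18))
})

test_that("evaluation reports assemble and serialize completely", {
  withr::with_seed(8, {
    n <- 120
    true <- sample(histologyClasses(), n, replace = TRUE)
    probs <- matrix(stats::runif(n * 6), n, 6)
    probs <- probs / rowSums(probs)
    colnames(probs) <- histologyClasses()
  })
  rep <- evalReport(true, probs, nBoot = 100, seed = 2)
  expect_s3_class(rep, "EvalReport")
  expect_equal(dim(rep$confusion$matrix), c(6L, 6L))
  expect_length(rep$perClass, 6L)
  for (pc in rep$perClass) {
    expect_true(is.finite(pc$roc$auc))
    expect_true(is.finite(pc$pr$auc))
    expect_true(!is.null(pc$aucCI))
  }
  dir <- file.path(tempdir(), "evalrep")
  path <- writeEvalReport(rep, dir)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "roc_necrosis.tsv")))
  js <- jsonlite::read_json(path)
  expect_length(js$perClass, 6L)
})
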