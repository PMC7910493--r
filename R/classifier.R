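#' Split a feature table into train / validation / test
#'
#' Default 8:1:1 split: the test partition gets `round(0.1 N)` rows, the
#' validation partition `round(0.1 N)`, training the remainder.
#' Partitions are disjoint and exhaustive and the assignment is
#' reproducible per seed.  With `stratified = TRUE` the test and
#' validation counts are allocated across classes by largest remainder,
#' preserving the exact global partition sizes.
#'
#' @param table data.frame with a `class` column.
#' @param ratios three positive numbers (normalized to sum 1).
#' @param seed integer seed.
#' @param stratified stratify the split by class.
#' @return list of data.frames `train`, `validation`, `test`.
#' @examples
#' tab <- sampleFeatureTable(c(dc_tumor = 40, necrosis = 40), seed = 1)
#' sp <- splitDataset(tab, seed = 1)
#' vapply(sp, nrow, integer(1))  # 64, 8, 8
#' @export
splitDataset <- function(table, ratios = c(8, 1, 1), seed = 1,
                         stratified = FALSE) {
  if (length(ratios) != 3L || any(ratios <= 0))
    .stopf("ratios must be three positive numbers")
  r <- ratios / sum(ratios)
  N <- nrow(table)
  nTest <- round(r[3] * N)
  nVal <- round(r[2] * N)
  if (nTest + nVal >= N) .stopf("split leaves no training rows")
  assignRole <- function(idxByGroup, counts) {
    # counts: target size per role c(val, test) overall; idxByGroup:
    # list of (already permuted) row indices per stratum
    sizes <- vapply(idxByGroup, length, integer(1))
    out <- list(validation = integer(0), test = integer(0))
    for (role in c("test", "validation")) {
      want <- if (role == "test") counts[2] else counts[1]
      exact <- want * sizes / sum(sizes)
      base <- floor(exact)
      rem <- want - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      taken <- vector("list", length(idxByGroup))
      for (gi in seq_along(idxByGroup)) {
        take <- min(base[gi], length(idxByGroup[[gi]]))
        taken[[gi]] <- idxByGroup[[gi]][seq_len(take)]
        idxByGroup[[gi]] <- idxByGroup[[gi]][-seq_len(take)]
      }
      out[[role]] <- unlist(taken, use.names = FALSE)
      sizes <- vapply(idxByGroup, length, integer(1))
    }
    out$train <- unlist(idxByGroup, use.names = FALSE)
    out
  }
  .withSeed(seed, {
    if (stratified) {
      cls <- as.character(table$class)
      cnt <- table(cls)
      if (any(cnt < 3L))
        .stopf("stratified split needs >= 3 rows per class (smallest has %d)",
               min(cnt))
      groups <- split(seq_len(N), cls)
      groups <- lapply(groups, function(ix) ix[sample.int(length(ix))])
      roles <- assignRole(groups, c(nVal, nTest))
    } else {
      perm <- sample.int(N)
      roles <- list(test = perm[seq_len(nTest)],
                    validation = perm[nTest + seq_len(nVal)],
                    train = perm[-seq_len(nTest + nVal)])
    }
    list(train = table[sort(roles$train), , drop = FALSE],
         validation = table[sort(roles$validation), , drop = FALSE],
         test = table[sort(roles$test), , drop = FALSE])
  })
}

#' SMOTE class balancing
#'
#' Brings every class up to the majority-class count by synthesizing
#' minority-class rows: each synthetic row is `x + u (x_nn - x)` for a
#' random original row `x` of that class, one of its `k` nearest
#' same-class neighbors `x_nn` (Euclidean distance on the feature
#' columns) and `u ~ Uniform(0, 1)`.  Original rows are retained
#' unchanged.  Apply to training data only.
#'
#' @param table data.frame with feature columns and a `class` column.
#' @param k number of nearest neighbors (clamped with a warning when a
#'   class has fewer than `k + 1` rows; single-row classes fall back to
#'   duplication with a warning).
#' @param seed integer seed.
#' @param features feature column names; default every numeric column
#'   except `voxel_id`.
#' @return balanced data.frame; synthetic rows have `voxel_id = NA` and
#'   `attr(, "nSynthetic")` gives their count.
#' @export
smoteBalance <- function(table, k = 5, seed = 1, features = NULL) {
  if (k < 1) .stopf("k must be >= 1")
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], "voxel_id")
  }
  cls <- as.character(table$class)
  cnt <- table(cls)
  if (any(cnt < 1L)) .stopf("every class must have at least one row")
  target <- max(cnt)
  if (all(cnt == target)) {
    attr(table, "nSynthetic") <- 0L
    return(table)
  }
  .withSeed(seed, {
    synth <- list()
    for (cl in names(cnt)) {
      need <- target - cnt[[cl]]
      if (need == 0L) next
      rows <- which(cls == cl)
      X <- as.matrix(table[rows, features, drop = FALSE])
      n <- nrow(X)
      if (n == 1L) {
        .warnf("class '%s' has a single row; duplicating instead of SMOTE", cl)
        block <- table[rep(rows, need), , drop = FALSE]
        if ("voxel_id" %in% names(block)) block$voxel_id <- NA
        synth[[cl]] <- block
        next
      }
      kEff <- min(k, n - 1L)
      if (kEff < k)
        .warnf("class '%s': k clamped from %d to %d (class size %d)",
               cl, k, kEff, n)
      D <- as.matrix(stats::dist(X))
      diag(D) <- Inf
      nnIdx <- t(apply(D, 1, function(d) order(d)[seq_len(kEff)]))
      base <- sample.int(n, need, replace = TRUE)
      pick <- nnIdx[cbind(base, sample.int(kEff, need, replace = TRUE))]
      u <- stats::runif(need)
      newX <- X[base, , drop = FALSE] +
        u * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
      block <- table[rep(rows[1], need), , drop = FALSE]
      block[, features] <- newX
      if ("voxel_id" %in% names(block)) block$voxel_id <- NA
      synth[[cl]] <- block
    }
    out <- rbind(table, do.call(rbind, synth))
    rownames(out) <- NULL
    attr(out, "nSynthetic") <- nrow(out) - nrow(table)
    out
  })
}

#' DNN training configuration
#'
#' Defaults follow the published architecture where stated (ten fully
#' connected hidden layers, batch normalization with mini-batch size
#' 200, exponential linear units, softmax output over the six classes,
#' Adam with beta1 = 0.9, beta2 = 0.999, cross-entropy loss, early
#' stopping on validation loss); layer width, learning rate, epoch
#' budget and patience are unreported there and are package defaults.
#'
#' @param hiddenLayers number of hidden layers.
#' @param hiddenWidth units per hidden layer.
#' @param batchSize mini-batch size.
#' @param learningRate Adam step size.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param maxEpochs epoch budget.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed integer seed (initialization and batch shuffling).
#' @return list of class `dnnConfig`.
#' @export
dnnConfig <- function(hiddenLayers = 10, hiddenWidth = 128, batchSize = 200,
                      learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8, maxEpochs = 100, patience = 10,
                      seed = 1) {
  stopifnot(batchSize >= 1, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            hiddenLayers >= 1, hiddenWidth >= 1)
  structure(list(hiddenLayers = hiddenLayers, hiddenWidth = hiddenWidth,
                 batchSize = batchSize, learningRate = learningRate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 maxEpochs = maxEpochs, patience = patience, seed = seed),
            class = "dnnConfig")
}

.elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
.eluGrad <- function(x, fx) ifelse(x > 0, 1, fx + 1)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.bnEps <- 1e-5

# forward through the network; training = TRUE uses batch statistics
# and returns a cache for backprop.
.dnnForward <- function(layers, X, training = FALSE, momentum = 0.9) {
  nL <- length(layers)
  cache <- vector("list", nL)
  H <- X
  for (l in seq_len(nL)) {
    L <- layers[[l]]
    Z <- H %*% L$W + matrix(L$b, nrow(H), length(L$b), byrow = TRUE)
    if (l < nL) {
      if (training) {
        mu <- colMeans(Z)
        vr <- colMeans(sweep(Z, 2, mu)^2)
        layers[[l]]$runMean <- momentum * L$runMean + (1 - momentum) * mu
        layers[[l]]$runVar <- momentum * L$runVar + (1 - momentum) * vr
      } else {
        mu <- L$runMean
        vr <- L$runVar
      }
      Zc <- sweep(Z, 2, mu)
      inv <- 1 / sqrt(vr + .bnEps)
      Xhat <- sweep(Zc, 2, inv, `*`)
      Y <- sweep(sweep(Xhat, 2, L$gamma, `*`), 2, L$beta, `+`)
      A <- .elu(Y)
      cache[[l]] <- list(H = H, Z = Z, Zc = Zc, inv = inv, Xhat = Xhat,
                         Y = Y, A = A)
      H <- A
    } else {
      cache[[l]] <- list(H = H, Z = Z)
      H <- Z
    }
  }
  list(logits = H, probs = .softmax(H), cache = cache, layers = layers)
}

# gradients of mean cross-entropy wrt all parameters
.dnnBackward <- function(layers, cache, probs, Yonehot) {
  nL <- length(layers)
  m <- nrow(probs)
  grads <- vector("list", nL)
  dZ <- (probs - Yonehot) / m
  for (l in rev(seq_len(nL))) {
    L <- layers[[l]]
    cc <- cache[[l]]
    if (l < nL) {
      dA <- dZ                       # gradient wrt this layer's activation
      dY <- dA * .eluGrad(cc$Y, cc$A)
      dgamma <- colSums(dY * cc$Xhat)
      dbeta <- colSums(dY)
      dXhat <- sweep(dY, 2, L$gamma, `*`)
      dvar <- colSums(dXhat * cc$Zc) * (-0.5) * cc$inv^3
      dmu <- colSums(sweep(dXhat, 2, -cc$inv, `*`)) +
        dvar * colMeans(-2 * cc$Zc)
      dZl <- sweep(dXhat, 2, cc$inv, `*`) +
        sweep(cc$Zc, 2, 2 * dvar / m, `*`) +
        matrix(dmu / m, m, length(dmu), byrow = TRUE)
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZl <- dZ
    }
    grads[[l]] <- list(W = t(cc$H) %*% dZl, b = colSums(dZl),
                       gamma = dgamma, beta = dbeta)
    dZ <- dZl %*% t(L$W)
  }
  grads
}

.crossEntropy <- function(probs, Yonehot) {
  -mean(log(pmax(rowSums(probs * Yonehot), 1e-12)))
}

.initLayers <- function(nIn, widths, nOut) {
  dims <- c(nIn, widths)
  layers <- vector("list", length(widths) + 1L)
  for (l in seq_along(widths)) {
    fanIn <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fanIn * widths[l], 0, sqrt(2 / fanIn)),
                 fanIn, widths[l]),
      b = rep(0, widths[l]),
      gamma = rep(1, widths[l]), beta = rep(0, widths[l]),
      runMean = rep(0, widths[l]), runVar = rep(1, widths[l]))
  }
  fanIn <- dims[length(dims)]
  layers[[length(layers)]] <- list(
    W = matrix(stats::rnorm(fanIn * nOut, 0, sqrt(1 / fanIn)), fanIn, nOut),
    b = rep(0, nOut))
  layers
}

#' Train the histology DNN classifier
#'
#' Mini-batch Adam on the cross-entropy loss; features are z-scored
#' with training-set statistics, each hidden layer applies linear /
#' batch-normalization / ELU, and the softmax head emits one likelihood
#' per histology class.  Training stops early when the validation loss
#' has not improved for `patience` epochs and the best-validation
#' weights are restored.  Deterministic given the config seed.
#'
#' @param train,validation data.frames sharing the feature columns and a
#'   `class` column.  Balance (e.g. [smoteBalance()]) the training table
#'   only; validation must stay untouched.
#' @param config a [dnnConfig()].
#' @param features feature column names (default [featureMetrics()]
#'   intersected with the table).
#' @return a [DNNClassifier-class].
#' @export
trainDNN <- function(train, validation, config = dnnConfig(),
                     features = NULL) {
  if (is.null(validation) || !nrow(validation))
    .stopf("validation table is empty")
  if (is.null(features)) {
    features <- intersect(featureMetrics(auxiliary = TRUE), names(train))
    if (!length(features)) {
      num <- vapply(train, is.numeric, logical(1))
      features <- setdiff(names(train)[num], "voxel_id")
    }
  }
  if (!all(features %in% names(validation)))
    .stopf("train and validation tables must share the feature schema")
  X <- as.matrix(train[, features, drop = FALSE])
  if (any(!is.finite(X))) .stopf("training features must be finite")
  yf <- factor(train$class)
  classLevels <- levels(yf)
  yIdx <- as.integer(yf)
  center <- colMeans(X)
  scaleSd <- apply(X, 2, stats::sd)
  scaleSd[scaleSd == 0 | !is.finite(scaleSd)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scaleSd, `/`)
  Xv <- sweep(sweep(as.matrix(validation[, features, drop = FALSE]),
                    2, center), 2, scaleSd, `/`)
  yv <- as.integer(factor(validation$class, levels = classLevels))
  if (any(is.na(yv))) .stopf("validation contains classes unseen in training")
  nC <- length(classLevels)
  onehot <- function(idx) {
    M <- matrix(0, length(idx), nC)
    M[cbind(seq_along(idx), idx)] <- 1
    M
  }
  Yv <- onehot(yv)
  .withSeed(config$seed, {
    layers <- .initLayers(ncol(Xs), rep(config$hiddenWidth,
                                        config$hiddenLayers), nC)
    adam <- lapply(layers, function(L)
      lapply(L[intersect(names(L), c("W", "b", "gamma", "beta"))],
             function(p) list(m = p * 0, v = p * 0)))
    t <- 0
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                          valLoss = numeric(0))
    wait <- 0L
    n <- nrow(Xs)
    for (epoch in seq_len(config$maxEpochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epLoss <- 0; nb <- 0L
      for (st in starts) {
        ix <- perm[st:min(st + config$batchSize - 1L, n)]
        if (length(ix) < 2L) next   # batch norm needs >= 2 rows
        fw <- .dnnForward(layers, Xs[ix, , drop = FALSE], training = TRUE)
        layers <- fw$layers          # running-stat update
        Yb <- onehot(yIdx[ix])
        loss <- .crossEntropy(fw$probs, Yb)
        if (!is.finite(loss))
          .stopf("training diverged (NaN loss); lower learningRate = %g",
                 config$learningRate)
        epLoss <- epLoss + loss; nb <- nb + 1L
        grads <- .dnnBackward(layers, fw$cache, fw$probs, Yb)
        t <- t + 1
        for (l in seq_along(layers)) {
          for (pn in names(adam[[l]])) {
            gBar <- grads[[l]][[pn]]
            st2 <- adam[[l]][[pn]]
            st2$m <- config$beta1 * st2$m + (1 - config$beta1) * gBar
            st2$v <- config$beta2 * st2$v + (1 - config$beta2) * gBar^2
            mh <- st2$m / (1 - config$beta1^t)
            vh <- st2$v / (1 - config$beta2^t)
            layers[[l]][[pn]] <- layers[[l]][[pn]] -
              config$learningRate * mh / (sqrt(vh) + config$epsilon)
            adam[[l]][[pn]] <- st2
          }
        }
      }
      vfw <- .dnnForward(layers, Xv, training = FALSE)
      valLoss <- .crossEntropy(vfw$probs, Yv)
      history <- rbind(history, data.frame(epoch = epoch,
                                           trainLoss = epLoss / max(nb, 1L),
                                           valLoss = valLoss))
      if (valLoss < best$loss - 1e-9) {
        best <- list(loss = valLoss, layers = layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    new("DNNClassifier", layers = best$layers, classLevels = classLevels,
        featureNames = features, center = center, scaleSd = scaleSd,
        history = history, config = unclass(config))
  })
}

#' Predict class probabilities and labels
#'
#' @param object a [DNNClassifier-class].
#' @param newdata data.frame (with the model's feature columns) or a
#'   numeric matrix with matching column count.
#' @param ... ignored.
#' @return list with `probabilities` (rows summing to 1) and `labels`
#'   (factor; argmax with lowest-class-index tie-break).
#' @export
setMethod("predict", "DNNClassifier", function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object@featureNames, names(newdata))
    if (length(miss))
      .stopf("missing feature column(s): %s", paste(miss, collapse = ", "))
    X <- as.matrix(newdata[, object@featureNames, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object@featureNames))
      .stopf("feature count mismatch: model expects %d, got %d",
             length(object@featureNames), ncol(X))
  }
  Xs <- sweep(sweep(X, 2, object@center), 2, object@scaleSd, `/`)
  fw <- .dnnForward(object@layers, Xs, training = FALSE)
  p <- fw$probs
  colnames(p) <- object@classLevels
  lab <- factor(object@classLevels[max.col(p, ties.method = "first")],
                levels = object@classLevels)
  list(probabilities = p, labels = lab)
})
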