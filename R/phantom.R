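#' Histology classes and feature metrics
#'
#' `histologyClasses()` returns the six tumor-histology class labels in
#' their stable code order (codes 0--5): normal white matter, densely
#' cellular tumor, less densely cellular tumor, tumor infiltrative edge,
#' necrosis and hemorrhage.  `featureMetrics()` returns the names of the
#' twelve DTI/DBSI metrics used as classifier features (plus, when
#' `auxiliary = TRUE`, the highly restricted fraction auxiliary band
#' output).
#'
#' @param auxiliary include `highly_restricted_fraction`.
#' @return character vector.
#' @export
histologyClasses <- function() {
  c("normal_wm", "dc_tumor", "ldc_tumor", "infiltrative_edge",
    "necrosis", "hemorrhage")
}

#' @rdname histologyClasses
#' @export
featureMetrics <- function(auxiliary = FALSE) {
  m <- c("mean_adc", "mean_fa", "fiber_fraction", "fiber_fa", "fiber_ad",
         "fiber_rd", "restricted_fraction", "restricted_adc",
         "hindered_fraction", "hindered_adc", "free_fraction", "free_adc")
  if (auxiliary) c(m, "highly_restricted_fraction") else m
}

.fractionMetrics <- c("fiber_fraction", "highly_restricted_fraction",
                      "restricted_fraction", "hindered_fraction",
                      "free_fraction")

#' Per-class diffusion-metric profiles
#'
#' Means and standard deviations of every feature metric for each of the
#' six histology classes.  Values whose `source` is `"printed"` are the
#' published group statistics (ADC, DTI-FA, fiber fraction and the
#' isotropic band fractions where available); `"derived"` marks the
#' normal-white-matter ADC, implied by the published "115% higher"
#' densely-cellular-vs-WM ADC contrast; `"default"` marks plausible
#' fixed-tissue values supplied where no group statistic was published.
#' The whole hemorrhage profile is synthesized (low ADC, low anisotropy,
#' elevated highly restricted fraction) since no diffusion statistics
#' were published for it; `profiles$hemorrhage$synthetic` is `TRUE`.
#'
#' Each class entry also carries `signal`, the parameter ranges used by
#' [buildSignalPhantom()] to draw per-voxel ground-truth models:
#' representative in-band diffusivities for the four isotropic bands and
#' fiber diffusivity ranges typical of fixed tissue.
#'
#' @return named list, one element per class, each with elements
#'   `features` (data.frame: metric, mean, sd, source), `signal` (list)
#'   and `synthetic` (logical).
#' @examples
#' p <- defaultProfiles()
#' subset(p$dc_tumor$features, metric == "restricted_fraction")
#' @export
defaultProfiles <- function() {
  metrics <- featureMetrics(auxiliary = TRUE)
  tbl <- function(means, sds, sources) {
    data.frame(metric = metrics, mean = means, sd = sds, source = sources,
               stringsAsFactors = FALSE)
  }
  P <- "printed"; D <- "default"; V <- "derived"
  profs <- list(
    normal_wm = tbl(
      c(0.20, 0.24, 0.38, 0.55, 1.20, 0.30, 0.26, 0.50, 0.18, 1.20, 0.04,
        2.40, 0.12),
      c(0.10, 0.11, 0.12, 0.12, 0.25, 0.12, 0.11, 0.12, 0.09, 0.25, 0.04,
        0.25, 0.06),
      c(V, P, P, D, D, D, P, D, D, D, D, D, D)),
    dc_tumor = tbl(
      c(0.43, 0.12, 0.13, 0.40, 1.10, 0.40, 0.35, 0.55, 0.38, 1.30, 0.08,
        2.45, 0.03),
      c(0.17, 0.06, 0.08, 0.15, 0.30, 0.15, 0.10, 0.12, 0.14, 0.25, 0.06,
        0.25, 0.03),
      c(P, D, D, D, D, D, P, D, D, D, D, D, D)),
    ldc_tumor = tbl(
      c(0.52, 0.13, 0.15, 0.40, 1.15, 0.40, 0.29, 0.55, 0.40, 1.35, 0.10,
        2.45, 0.03),
      c(0.26, 0.07, 0.09, 0.15, 0.30, 0.15, 0.09, 0.12, 0.15, 0.25, 0.07,
        0.25, 0.03),
      c(P, D, D, D, D, D, P, D, D, D, D, D, D)),
    infiltrative_edge = tbl(
      c(0.30, 0.23, 0.36, 0.50, 1.20, 0.32, 0.29, 0.50, 0.22, 1.25, 0.05,
        2.40, 0.08),
      c(0.15, 0.14, 0.17, 0.15, 0.30, 0.12, 0.12, 0.12, 0.11, 0.25, 0.05,
        0.25, 0.05),
      c(P, P, P, D, D, D, P, D, D, D, D, D, D)),
    necrosis = tbl(
      c(0.68, 0.08, 0.08, 0.35, 1.00, 0.45, 0.22, 0.55, 0.42, 1.45, 0.11,
        2.50, 0.06),
      c(0.37, 0.05, 0.06, 0.15, 0.30, 0.18, 0.15, 0.15, 0.21, 0.30, 0.12,
        0.30, 0.05),
      c(P, D, D, D, D, D, P, D, P, D, P, D, D)),
    hemorrhage = tbl(
      c(0.25, 0.10, 0.12, 0.35, 1.00, 0.45, 0.28, 0.45, 0.38, 1.20, 0.06,
        2.35, 0.14),
      c(0.12, 0.06, 0.08, 0.15, 0.30, 0.18, 0.12, 0.12, 0.15, 0.25, 0.05,
        0.25, 0.07),
      rep(D, 13))
  )
  sig <- list(
    normal_wm = list(lambdaPar = c(1.0, 1.4), lambdaPerp = c(0.2, 0.4)),
    dc_tumor = list(lambdaPar = c(0.9, 1.3), lambdaPerp = c(0.3, 0.5)),
    ldc_tumor = list(lambdaPar = c(0.9, 1.4), lambdaPerp = c(0.3, 0.5)),
    infiltrative_edge = list(lambdaPar = c(1.0, 1.4), lambdaPerp = c(0.2, 0.45)),
    necrosis = list(lambdaPar = c(0.8, 1.2), lambdaPerp = c(0.3, 0.55)),
    hemorrhage = list(lambdaPar = c(0.8, 1.2), lambdaPerp = c(0.3, 0.55))
  )
  bandD <- list(highly_restricted = c(0.05, 0.15), restricted = c(0.35, 0.65),
                hindered = c(1.1, 1.7), free = c(2.3, 2.7))
  out <- lapply(histologyClasses(), function(cl) {
    list(features = profs[[cl]],
         signal = c(sig[[cl]], list(bandD = bandD)),
         synthetic = identical(cl, "hemorrhage"))
  })
  names(out) <- histologyClasses()
  out
}

# Draw n rows of the five fraction metrics for one class.  Deviations
# from the profile means are projected onto the zero-sum subspace
# (minimum-variance allocation), so compartment fractions compete for
# signal: marginal means are exact, the fraction sum is the (constant)
# sum of profile means, and marginal SDs are mildly shrunk.
.drawFractionBlock <- function(n, means, sds) {
  k <- length(means)
  e <- matrix(stats::rnorm(n * k), n, k)
  r <- sweep(e, 2, sds, `*`)
  s <- rowSums(r)
  alloc <- sds^2 / sum(sds^2)
  d <- r - outer(s, alloc)
  x <- sweep(d, 2, means, `+`)
  x[x < 0] <- 0
  x[x > 1] <- 1
  # clipping can push the row sum above 1 only via upper clips; rescale then
  rs <- rowSums(x)
  over <- rs > 1
  if (any(over)) x[over, ] <- x[over, , drop = FALSE] / rs[over]
  x
}

#' Sample a class-conditional voxel feature table
#'
#' Draws per-voxel feature vectors for the requested classes.  The five
#' signal-fraction metrics are drawn jointly under a sum-preserving
#' scheme (fractions sum to the class profile's fraction-mean total,
#' which is at most 1); diffusivity and FA metrics are independent
#' truncated normals (diffusivities at 0, FA to [0, 1]).  Rows are
#' labeled and shuffled; the result is reproducible per seed.
#'
#' @param nPerClass named integer vector (names from
#'   [histologyClasses()]), or a single count applied to all six classes.
#' @param profiles output of [defaultProfiles()] (or an edited copy).
#' @param seed integer seed.
#' @param auxiliary include the highly restricted fraction column.
#' @return data.frame with columns `voxel_id`, the feature metrics and
#'   `class` (factor with the class levels in code order).
#' @examples
#' tab <- sampleFeatureTable(c(dc_tumor = 50, necrosis = 50), seed = 1)
#' table(tab$class)
#' @export
sampleFeatureTable <- function(nPerClass, profiles = defaultProfiles(),
                               seed = 1, auxiliary = FALSE) {
  if (is.null(names(nPerClass)) && length(nPerClass) == 1L) {
    nPerClass <- stats::setNames(rep(nPerClass, 6L), histologyClasses())
  }
  if (!length(nPerClass)) .stopf("empty class list")
  bad <- setdiff(names(nPerClass), histologyClasses())
  if (length(bad)) .stopf("unknown class(es): %s", paste(bad, collapse = ", "))
  if (any(nPerClass < 1)) .stopf("need at least one voxel per requested class")
  metrics <- featureMetrics(auxiliary = TRUE)
  .withSeed(seed, {
    blocks <- lapply(names(nPerClass), function(cl) {
      n <- nPerClass[[cl]]
      pf <- profiles[[cl]]$features
      rownames(pf) <- pf$metric
      out <- matrix(NA_real_, n, length(metrics),
                    dimnames = list(NULL, metrics))
      fr <- .fractionMetrics
      out[, fr] <- .drawFractionBlock(n, pf[fr, "mean"], pf[fr, "sd"])
      for (m in setdiff(metrics, fr)) {
        up <- if (m == "mean_fa" || m == "fiber_fa") 1 else Inf
        out[, m] <- .rtruncnorm(n, pf[m, "mean"], pf[m, "sd"], 0, up)
      }
      # cylindrical symmetry of the fiber tensor: AD >= RD
      swap <- out[, "fiber_ad"] < out[, "fiber_rd"]
      if (any(swap)) {
        tmp <- out[swap, "fiber_ad"]
        out[swap, "fiber_ad"] <- out[swap, "fiber_rd"]
        out[swap, "fiber_rd"] <- tmp
      }
      df <- as.data.frame(out)
      df$class <- cl
      df
    })
    tab <- do.call(rbind, blocks)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    keep <- featureMetrics(auxiliary = auxiliary)
    tab <- data.frame(voxel_id = seq_len(nrow(tab)), tab[, keep],
                      class = factor(tab$class, levels = histologyClasses()))
    tab
  })
}

# Draw one ground-truth VoxelModel for a histology class.
.drawVoxelModel <- function(cl, profiles) {
  pf <- profiles[[cl]]$features
  rownames(pf) <- pf$metric
  sg <- profiles[[cl]]$signal
  fr <- as.vector(.drawFractionBlock(1, pf[.fractionMetrics, "mean"],
                                     pf[.fractionMetrics, "sd"]))
  names(fr) <- .fractionMetrics
  fr <- fr / sum(fr)   # signal model must be normalized
  ax <- stats::rnorm(3)
  while (sum(ax^2) < 1e-12) ax <- stats::rnorm(3)
  lp <- stats::runif(1, sg$lambdaPar[1], sg$lambdaPar[2])
  lr <- stats::runif(1, sg$lambdaPerp[1], sg$lambdaPerp[2])
  if (lr > lp) lr <- lp
  bd <- sg$bandD
  Dvals <- c(stats::runif(1, bd$highly_restricted[1], bd$highly_restricted[2]),
             stats::runif(1, bd$restricted[1], bd$restricted[2]),
             stats::runif(1, bd$hindered[1], bd$hindered[2]),
             stats::runif(1, bd$free[1], bd$free[2]))
  w <- fr[c("highly_restricted_fraction", "restricted_fraction",
            "hindered_fraction", "free_fraction")]
  keep <- w > 0
  ord <- order(Dvals[keep])
  spec <- isotropicSpectrum(Dvals[keep][ord], unname(w[keep][ord]))
  comps <- if (fr[["fiber_fraction"]] > 0)
    list(anisotropicComponent(fr[["fiber_fraction"]], lp, lr, ax)) else list()
  list(model = voxelModel(comps, spec),
       truth = c(fiber_fraction = unname(fr[["fiber_fraction"]]),
                 highly_restricted_fraction =
                   unname(fr[["highly_restricted_fraction"]]),
                 restricted_fraction = unname(fr[["restricted_fraction"]]),
                 hindered_fraction = unname(fr[["hindered_fraction"]]),
                 free_fraction = unname(fr[["free_fraction"]])))
}

#' Build a signal-level diffusion-weighted phantom
#'
#' Assigns each labeled voxel a ground-truth [VoxelModel-class] drawn
#' from its class profile, predicts the DBSI signal with
#' [predictSignal()] and adds Rician noise at the requested SNR
#' (`snr = Inf` for noiseless data).  The ground truth is retained so
#' fitting accuracy can be scored voxel by voxel.
#'
#' @param labelMap integer array (any dimensionality up to 3) of class
#'   codes 0--5; `NA` marks background voxels.
#' @param scheme a [GradientScheme-class].
#' @param profiles see [defaultProfiles()].
#' @param snr S0-referenced signal-to-noise ratio.
#' @param seed integer seed; signals are deterministic given
#'   (seed, scheme, label map).
#' @param noiseModel passed to [addNoise()].
#' @return list with elements `dwi` (matrix, voxels x acquisitions),
#'   `labels` (the input map), `models` (list of ground-truth voxel
#'   models, `NULL` for background), `truth` (data.frame of ground-truth
#'   fractions per voxel, `NA` rows for background) and `dim`.
#' @export
buildSignalPhantom <- function(labelMap, scheme, profiles = defaultProfiles(),
                               snr = Inf, seed = 1,
                               noiseModel = c("rician", "gaussian")) {
  stopifnot(is(scheme, "GradientScheme"))
  noiseModel <- match.arg(noiseModel)
  lab <- as.integer(labelMap)
  if (!length(lab)) .stopf("label map is empty")
  known <- lab[!is.na(lab)]
  if (length(known) == 0L) .stopf("label map has no labeled voxels")
  if (any(known < 0L | known > 5L))
    .stopf("unknown label code(s): %s",
           paste(unique(known[known < 0L | known > 5L]), collapse = ", "))
  classes <- histologyClasses()
  nv <- length(lab)
  na <- nAcquisitions(scheme)
  dwi <- matrix(NA_real_, nv, na)
  models <- vector("list", nv)
  truth <- matrix(NA_real_, nv, 5,
                  dimnames = list(NULL, c("fiber_fraction",
                                          "highly_restricted_fraction",
                                          "restricted_fraction",
                                          "hindered_fraction",
                                          "free_fraction")))
  .withSeed(seed, {
    for (v in seq_len(nv)) {
      if (is.na(lab[v])) next
      drawn <- .drawVoxelModel(classes[lab[v] + 1L], profiles)
      models[[v]] <- drawn$model
      truth[v, ] <- drawn$truth
      s <- predictSignal(drawn$model, scheme)
      dwi[v, ] <- addNoise(s, snr, model = noiseModel)
    }
  })
  list(dwi = dwi, labels = labelMap, models = models,
       truth = as.data.frame(truth),
       dim = if (is.null(dim(labelMap))) length(labelMap) else dim(labelMap))
}

#' Write / read a feature table as TSV
#'
#' @param table data.frame as produced by [sampleFeatureTable()].
#' @param path file path.
#' @return `readFeatureTable()` the table with `class` restored as a
#'   factor with the canonical level order.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if ("class" %in% names(tab))
    tab$class <- factor(tab$class, levels = histologyClasses())
  tab
}
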