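#' Read a pipeline run configuration
#'
#' JSON (or YAML, when the yaml package is installed) file holding the
#' nested stage configurations; see [runEndToEnd()] for the recognized
#' fields.
#'
#' @param path config file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("YAML configs need the yaml package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; returns findings instead of throwing,
#' so a bad config can be reported in full.  An empty character vector
#' means the config is valid.
#'
#' @param config named list (see [runEndToEnd()]).
#' @return character vector of problems.
#' @export
validateConfig <- function(config) {
  f <- character(0)
  say <- function(...) sprintf(...)
  if (!is.list(config)) return("config must be a named list")
  mode <- config$mode %||% "features"
  if (!mode %in% c("features", "signals"))
    f <- c(f, say("unknown mode '%s' (features|signals)", mode))
  if (!is.null(config$split$ratios)) {
    r <- config$split$ratios
    if (length(r) != 3 || any(r <= 0))
      f <- c(f, "split ratios must be three positive numbers")
    else if (abs(sum(r) - 1) > 1e-9 && abs(sum(r) - 10) > 1e-9)
      f <- c(f, "ratios do not sum to 1")
  }
  if (!is.null(config$smote$k) && config$smote$k < 1)
    f <- c(f, "smote k_neighbors must be >= 1")
  n <- config$phantom$nPerClass
  if (!is.null(n)) {
    if (any(n < 1)) f <- c(f, "phantom nPerClass must be >= 1")
    if (!is.null(names(n))) {
      bad <- setdiff(names(n), histologyClasses())
      if (length(bad))
        f <- c(f, say("unknown class(es): %s", paste(bad, collapse = ", ")))
    }
  }
  if (mode == "signals") {
    sc <- config$scheme
    if (is.null(sc))
      f <- c(f, "signals mode requires a scheme section")
    else if (!is.null(sc$bvalPath) || !is.null(sc$bvecPath)) {
      if (is.null(sc$bvalPath) || is.null(sc$bvecPath))
        f <- c(f, "scheme needs both bvalPath and bvecPath (or neither)")
      else {
        for (p in c(sc$bvalPath, sc$bvecPath))
          if (!file.exists(p)) f <- c(f, say("unreadable file: %s", p))
      }
    }
    if (is.null(config$phantom$labelMapDim) && is.null(config$phantom$snr))
      f <- c(f, "signals mode requires phantom labelMapDim / snr")
  }
  tr <- config$train
  if (!is.null(tr)) {
    chk <- try(do.call(dnnConfig, tr[intersect(names(tr),
                                               names(formals(dnnConfig)))]),
               silent = TRUE)
    if (inherits(chk, "try-error"))
      f <- c(f, "invalid train section")
  }
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# striped demo label map covering all requested classes
.demoLabelMap <- function(dims, classes = 0:5) {
  arr <- array(NA_integer_, dim = dims)
  n <- length(arr)
  arr[] <- classes[((seq_len(n) - 1) %% length(classes)) + 1]
  arr
}

#' Run the end-to-end histology-classification pipeline
#'
#' Orchestrates phantom generation, (optionally) voxel-wise DBSI
#' fitting, dataset splitting, SMOTE balancing, DNN training and the
#' evaluation battery, persisting every intermediate artifact plus a
#' manifest (config copy, seed, file hashes, package version) into one
#' run directory.  Reruns with the same config and seed reproduce the
#' deterministic artifacts bit for bit.
#'
#' Config fields (all optional unless noted): `mode` ("features" to
#' sample feature tables directly, "signals" to synthesize DWI signals
#' and fit them); `seed`; `phantom$nPerClass` (named or scalar; signal
#' mode instead uses `phantom$labelMapDim` and `phantom$snr`);
#' `scheme$nDirs/bMax/nB0` or `scheme$bvalPath/bvecPath`;
#' `split$ratios/stratified`; `smote$k`; `train$...` ([dnnConfig()]
#' fields); `eval$nBoot/level`.
#'
#' @param config named list or path to a config file.
#' @param outDir run directory (created; default a tempdir subdir).
#' @return list with `report` (an [evalReport()]), `model`, `paths`,
#'   `manifest`; invisibly written under `outDir`.
#' @export
runEndToEnd <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  problems <- validateConfig(config)
  if (length(problems))
    .stopf("invalid config:\n  - %s", paste(problems, collapse = "\n  - "))
  if (is.null(outDir))
    outDir <- file.path(tempdir(), sprintf("dhi-run-%s",
                                           format(Sys.time(), "%H%M%OS3")))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  mode <- config$mode %||% "features"
  stage <- "config"
  paths <- list()
  tryCatch({
    jsonlite::write_json(config, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    paths$config <- file.path(outDir, "config.json")

    stage <- "phantom"
    if (mode == "features") {
      n <- config$phantom$nPerClass %||% 600
      tab <- sampleFeatureTable(n, seed = seed)
    } else {
      sc <- config$scheme
      scheme <- if (!is.null(sc$bvalPath))
        loadScheme(sc$bvalPath, sc$bvecPath)
      else generateScheme(sc$nDirs %||% 99, sc$bMax %||% 3000,
                          sc$nB0 %||% 1, seed = seed)
      dims <- config$phantom$labelMapDim %||% c(6, 6, 1)
      lm <- .demoLabelMap(dims)
      ph <- buildSignalPhantom(lm, scheme, snr = config$phantom$snr %||% 50,
                               seed = seed)
      stage <- "fit"
      fv <- fitVolume(ph$dwi, scheme)
      tab <- fv$features
      tab$class <- factor(histologyClasses()[as.integer(lm) + 1L],
                          levels = histologyClasses())
      tab <- tab[stats::complete.cases(tab), , drop = FALSE]
      tab <- data.frame(voxel_id = seq_len(nrow(tab)), tab)
    }
    paths$features <- file.path(outDir, "features.tsv")
    writeFeatureTable(tab, paths$features)

    stage <- "split"
    sp <- splitDataset(tab, ratios = config$split$ratios %||% c(8, 1, 1),
                       seed = seed,
                       stratified = isTRUE(config$split$stratified))

    stage <- "smote"
    bal <- smoteBalance(sp$train, k = config$smote$k %||% 5, seed = seed)

    stage <- "train"
    trArgs <- config$train %||% list()
    trArgs <- trArgs[intersect(names(trArgs), names(formals(dnnConfig)))]
    trArgs$seed <- trArgs$seed %||% seed
    model <- trainDNN(bal, sp$validation, do.call(dnnConfig, trArgs))

    stage <- "predict"
    pred <- predict(model, sp$test)

    stage <- "evaluate"
    report <- evalReport(sp$test$class, pred$probabilities, pred$labels,
                         nBoot = config$eval$nBoot %||% 10000,
                         level = config$eval$level %||% 0.95, seed = seed)
    paths$report <- writeEvalReport(report, file.path(outDir, "eval"))

    stage <- "manifest"
    hashed <- unlist(paths[c("features")], use.names = TRUE)
    manifest <- list(seed = seed, mode = mode,
                     package = as.character(utils::packageVersion("dhikit")),
                     hashes = as.list(tools::md5sum(hashed)),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$manifest <- file.path(outDir, "manifest.json")
    list(report = report, model = model, paths = paths, manifest = manifest,
         splits = sp)
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s (partial outputs in %s)",
           stage, conditionMessage(e), outDir)
  })
}
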