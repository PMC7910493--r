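#' Accessors for scheme and model objects
#'
#' `bValues()` returns b-values in s/mm^2, `gradientDirections()` the
#' n x 3 matrix of unit directions, `nAcquisitions()` the acquisition
#' count and `isB0()` the logical non-diffusion-weighted flag.
#'
#' @param object a [GradientScheme-class] (or, where documented, another
#'   dhikit object).
#' @return see the individual generic.
#' @name scheme-accessors
#' @aliases bValues gradientDirections nAcquisitions isB0
#' @examples
#' sch <- generateScheme(nDirs = 12, bMax = 2000, seed = 1)
#' bValues(sch)[1:3]
#' sum(isB0(sch))
NULL

#' @rdname scheme-accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname scheme-accessors
#' @export
setGeneric("gradientDirections",
           function(object) standardGeneric("gradientDirections"))

#' @rdname scheme-accessors
#' @export
setGeneric("nAcquisitions", function(object) standardGeneric("nAcquisitions"))

#' @rdname scheme-accessors
#' @export
setGeneric("isB0", function(object) standardGeneric("isB0"))

#' @rdname scheme-accessors
#' @export
setMethod("bValues", "GradientScheme", function(object) object@bvals)

#' @rdname scheme-accessors
#' @export
setMethod("gradientDirections", "GradientScheme", function(object) object@dirs)

#' @rdname scheme-accessors
#' @export
setMethod("nAcquisitions", "GradientScheme",
          function(object) length(object@bvals))

#' @rdname scheme-accessors
#' @export
setMethod("isB0", "GradientScheme",
          function(object) object@bvals <= object@b0Threshold)

setMethod("show", "GradientScheme", function(object) {
  cat(sprintf(
    "GradientScheme: %d acquisitions (%d b=0), b in [%g, %g] s/mm^2\n",
    nAcquisitions(object), sum(isB0(object)),
    min(object@bvals), max(object@bvals)))
})

setMethod("show", "VoxelModel", function(object) {
  fa <- sum(vapply(object@components, slot, numeric(1), "fraction"))
  cat(sprintf(
    "VoxelModel: %d anisotropic component(s) (fraction %.3f), %d-point isotropic spectrum (weight %.3f)\n",
    length(object@components), fa, length(object@spectrum@grid),
    sum(object@spectrum@weights)))
})

setMethod("show", "TPSTransform", function(object) {
  cat(sprintf("TPSTransform: %d landmarks, affine + warp\n",
              nrow(object@source)))
})

setMethod("show", "DNNClassifier", function(object) {
  cat(sprintf(
    "DNNClassifier: %d features -> %d hidden layers (width %d) -> %d classes\n",
    length(object@featureNames), length(object@layers) - 1L,
    if (length(object@layers) > 1L) ncol(object@layers[[1]]$W) else 0L,
    length(object@classLevels)))
})
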