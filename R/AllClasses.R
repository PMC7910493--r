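#' @import methods
NULL

#' Diffusion-encoding scheme
#'
#' A `GradientScheme` holds one b-value (s/mm^2) and one unit gradient
#' direction per acquisition.  Acquisitions with b below `b0Threshold`
#' are treated as non-diffusion-weighted; their direction may be the
#' zero vector.
#'
#' @slot bvals numeric vector of b-values in s/mm^2, one per acquisition.
#' @slot dirs numeric matrix, one row per acquisition, three columns;
#'   unit vectors (zero rows allowed for b = 0 entries).
#' @slot b0Threshold b-values at or below this (s/mm^2) count as b = 0.
#'
#' @seealso [generateScheme()], [loadScheme()], [bValues()],
#'   [gradientDirections()]
#' @export
setClass("GradientScheme",
  representation(bvals = "numeric", dirs = "matrix", b0Threshold = "numeric"),
  prototype(b0Threshold = 10)
)

setValidity("GradientScheme", function(object) {
  msgs <- character()
  if (nrow(object@dirs) != length(object@bvals))
    msgs <- c(msgs, "number of directions must equal number of b-values")
  if (ncol(object@dirs) != 3L)
    msgs <- c(msgs, "directions must have 3 columns")
  if (any(!is.finite(object@bvals)) || any(object@bvals < 0))
    msgs <- c(msgs, "b-values must be finite and non-negative")
  nrm <- sqrt(rowSums(object@dirs^2))
  dw <- object@bvals > object@b0Threshold
  bad <- abs(nrm - 1) > 1e-6 & !(nrm == 0 & !dw)
  if (any(bad))
    msgs <- c(msgs, sprintf(
      "%d direction(s) are not unit vectors (zero rows only allowed at b = 0)",
      sum(bad)))
  if (length(msgs)) msgs else TRUE
})

#' Anisotropic tensor component of a voxel model
#'
#' One cylindrically symmetric diffusion tensor: an axial diffusivity
#' along `axis` and an equal pair of radial diffusivities perpendicular
#' to it, carrying signal-intensity fraction `fraction`.
#'
#' @slot fraction signal-intensity fraction in [0, 1].
#' @slot lambdaPar axial diffusivity (um^2/ms).
#' @slot lambdaPerp radial diffusivity (um^2/ms), `<= lambdaPar`.
#' @slot axis unit 3-vector, principal direction.
#' @export
setClass("AnisotropicComponent",
  representation(fraction = "numeric", lambdaPar = "numeric",
                 lambdaPerp = "numeric", axis = "numeric")
)

setValidity("AnisotropicComponent", function(object) {
  msgs <- character()
  if (object@fraction < 0 || object@fraction > 1)
    msgs <- c(msgs, "fraction must lie in [0, 1]")
  if (object@lambdaPerp < 0 || object@lambdaPar < object@lambdaPerp)
    msgs <- c(msgs, "diffusivities must satisfy lambdaPar >= lambdaPerp >= 0")
  if (length(object@axis) != 3L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
    msgs <- c(msgs, "axis must be a unit 3-vector")
  if (length(msgs)) msgs else TRUE
})

#' Isotropic diffusivity spectrum
#'
#' Discretized spectrum f(D): non-negative signal-intensity weights on an
#' ascending diffusivity grid (um^2/ms).  Weights carry the measure, so
#' band fractions are plain sums over grid points falling in a band.
#'
#' @slot grid strictly increasing diffusivities, `grid[1] >= 0`.
#' @slot weights non-negative weights, same length as `grid`.
#' @export
setClass("IsotropicSpectrum",
  representation(grid = "numeric", weights = "numeric")
)

setValidity("IsotropicSpectrum", function(object) {
  msgs <- character()
  if (length(object@grid) != length(object@weights))
    msgs <- c(msgs, "grid and weights must have equal length")
  if (length(object@grid) && (object@grid[1] < 0 ||
      any(diff(object@grid) <= 0)))
    msgs <- c(msgs, "grid must be strictly increasing and non-negative")
  if (any(object@weights < 0))
    msgs <- c(msgs, "weights must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Multi-compartment voxel model
#'
#' Ground truth or fitted composition of one voxel: a list of discrete
#' anisotropic tensor components plus an isotropic diffusivity spectrum.
#' The model is "normalized" when all fractions sum to 1.
#'
#' @slot components list of [AnisotropicComponent-class] objects.
#' @slot spectrum an [IsotropicSpectrum-class].
#' @export
setClass("VoxelModel",
  representation(components = "list", spectrum = "IsotropicSpectrum")
)

setValidity("VoxelModel", function(object) {
  ok <- vapply(object@components, is, logical(1), class2 = "AnisotropicComponent")
  if (!all(ok)) return("components must all be AnisotropicComponent objects")
  TRUE
})

#' Two-dimensional thin-plate-spline transform
#'
#' Affine part plus radial-basis warping weights fitted to landmark
#' pairs; kernel U(r) = r^2 log(r^2), U(0) = 0.  The TPS side conditions
#' (weights orthogonal to constants and to the source coordinates) hold
#' at machine precision for an exactly solved system.
#'
#' @slot affine 3 x 2 matrix; rows are intercept, x and y coefficients,
#'   columns the two output axes.
#' @slot weights n x 2 matrix of warping weights.
#' @slot source n x 2 matrix of source landmarks.
#' @export
setClass("TPSTransform",
  representation(affine = "matrix", weights = "matrix", source = "matrix")
)

setValidity("TPSTransform", function(object) {
  if (!all(dim(object@affine) == c(3L, 2L)))
    return("affine must be a 3 x 2 matrix")
  if (ncol(object@weights) != 2L || ncol(object@source) != 2L ||
      nrow(object@weights) != nrow(object@source))
    return("weights and source must be index-aligned n x 2 matrices")
  TRUE
})

#' Feed-forward neural-network histology classifier
#'
#' Fully connected network: z-scored features, then `length(layers) - 1`
#' hidden blocks of linear / batch-normalization / ELU, then a linear
#' softmax head with one unit per histology class.
#'
#' @slot layers list of per-layer parameter lists (`W`, `b`, and for
#'   hidden layers `gamma`, `beta`, `runMean`, `runVar`).
#' @slot classLevels character vector, output class order.
#' @slot featureNames character vector of input feature columns.
#' @slot center,scaleSd training-set feature means / SDs used to z-score
#'   inputs.
#' @slot history data.frame of per-epoch training and validation loss.
#' @slot config list, the [dnnConfig()] the model was trained with.
#' @export
setClass("DNNClassifier",
  representation(layers = "list", classLevels = "character",
                 featureNames = "character", center = "numeric",
                 scaleSd = "numeric", history = "data.frame", config = "list")
)

setValidity("DNNClassifier", function(object) {
  if (!length(object@layers)) return("model has no layers")
  out <- object@layers[[length(object@layers)]]
  if (ncol(out$W) != length(object@classLevels))
    return("output layer width must equal the number of classes")
  TRUE
})
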