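#' Build voxel-model pieces
#'
#' Constructors for the multi-compartment voxel model of the DBSI signal
#' equation: discrete cylindrically symmetric anisotropic tensors plus a
#' discretized isotropic diffusivity spectrum.
#'
#' @param fraction signal-intensity fraction in [0, 1].
#' @param lambdaPar,lambdaPerp axial / radial diffusivity (um^2/ms).
#' @param axis principal direction (any non-zero 3-vector; normalized).
#' @return `anisotropicComponent()` an [AnisotropicComponent-class].
#' @export
anisotropicComponent <- function(fraction, lambdaPar, lambdaPerp, axis) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) .stopf("component axis must be non-zero")
  new("AnisotropicComponent", fraction = fraction, lambdaPar = lambdaPar,
      lambdaPerp = lambdaPerp, axis = axis / n)
}

#' @rdname anisotropicComponent
#' @param grid ascending diffusivity grid (um^2/ms).
#' @param weights non-negative weights, same length as `grid`.
#' @return `isotropicSpectrum()` an [IsotropicSpectrum-class].
#' @export
isotropicSpectrum <- function(grid, weights) {
  new("IsotropicSpectrum", grid = as.numeric(grid),
      weights = as.numeric(weights))
}

#' @rdname anisotropicComponent
#' @param components list of [AnisotropicComponent-class] objects.
#' @param spectrum an [IsotropicSpectrum-class]; defaults to an empty one.
#' @return `voxelModel()` a [VoxelModel-class].
#' @examples
#' m <- voxelModel(
#'   components = list(anisotropicComponent(0.4, 1.5, 0.3, c(0, 0, 1))),
#'   spectrum = isotropicSpectrum(c(0.5, 1.2), c(0.35, 0.25)))
#' modelFractionTotal(m)  # 1
#' @export
voxelModel <- function(components = list(),
                       spectrum = isotropicSpectrum(numeric(0), numeric(0))) {
  new("VoxelModel", components = components, spectrum = spectrum)
}

#' @rdname anisotropicComponent
#' @param model a [VoxelModel-class].
#' @return `modelFractionTotal()` the sum of all signal fractions.
#' @export
modelFractionTotal <- function(model) {
  sum(vapply(model@components, slot, numeric(1), "fraction")) +
    sum(model@spectrum@weights)
}

#' Predict normalized diffusion-weighted signals
#'
#' Evaluates the DBSI signal equation for each acquisition k:
#' \deqn{S_k/S_0 = \sum_i f_i\, e^{-b_k \lambda_{\perp i}}
#'   e^{-b_k (\lambda_{\parallel i} - \lambda_{\perp i}) \cos^2\phi_{ik}}
#'   + \sum_j f(D_j)\, e^{-b_k D_j}}
#' with \eqn{\cos\phi_{ik}} the dot product of the k-th gradient
#' direction and the i-th component axis.  b-values are converted to
#' ms/um^2 internally so diffusivities are in um^2/ms throughout.
#'
#' @param model a normalized [VoxelModel-class] (fractions summing to 1);
#'   set `checkNormalized = FALSE` to evaluate an unnormalized model.
#' @param scheme a [GradientScheme-class].
#' @param checkNormalized require fractions to sum to 1 (+- 1e-6).
#' @return numeric vector of S_k/S_0 values in (0, 1].
#' @examples
#' sch <- gradientScheme(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 1)))
#' m <- voxelModel(spectrum = isotropicSpectrum(1.0, 1.0))
#' predictSignal(m, sch)   # c(1, exp(-1))
#' @export
predictSignal <- function(model, scheme, checkNormalized = TRUE) {
  stopifnot(is(model, "VoxelModel"), is(scheme, "GradientScheme"))
  tot <- modelFractionTotal(model)
  if (checkNormalized && abs(tot - 1) > 1e-6)
    .stopf("voxel model is not normalized (fractions sum to %.6f); pass checkNormalized = FALSE to override", tot)
  b <- .bInternal(scheme)
  g <- gradientDirections(scheme)
  s <- numeric(length(b))
  for (comp in model@components) {
    ct2 <- as.vector(g %*% comp@axis)^2
    s <- s + comp@fraction *
      exp(-b * comp@lambdaPerp -
            b * (comp@lambdaPar - comp@lambdaPerp) * ct2)
  }
  sp <- model@spectrum
  if (length(sp@grid))
    s <- s + as.vector(exp(-outer(b, sp@grid)) %*% sp@weights)
  s
}

#' Closed-form DTI scalar metrics
#'
#' Mean diffusivity and fractional anisotropy from three tensor
#' eigenvalues:
#' MD = mean(lambda), FA = sqrt(3/2 * sum((lambda - MD)^2) / sum(lambda^2)).
#'
#' @param eigvals three non-negative eigenvalues (um^2/ms), not all zero.
#' @return list with elements `md` and `fa`.
#' @examples
#' dtiClosedForms(c(1.5, 0.3, 0.3))  # md 0.7, fa ~0.7698
#' @export
dtiClosedForms <- function(eigvals) {
  stopifnot(length(eigvals) == 3L)
  if (any(eigvals < 0)) .stopf("eigenvalues must be non-negative")
  if (all(eigvals == 0)) .stopf("FA is undefined for an all-zero tensor")
  md <- mean(eigvals)
  fa <- sqrt(1.5 * sum((eigvals - md)^2) / sum(eigvals^2))
  list(md = md, fa = fa)
}

#' Add measurement noise to normalized signals
#'
#' Magnitude-MRI noise referenced to the unweighted signal S_0 = 1: the
#' noise standard deviation is `1/snr`.  Rician noise (default) forms
#' `sqrt((S + e1)^2 + e2^2)` with independent Gaussian `e1`, `e2`;
#' Gaussian noise adds `e1` only.
#'
#' @param signals numeric vector of normalized signals.
#' @param snr signal-to-noise ratio (S0-referenced), `> 0`.
#' @param model `"rician"` or `"gaussian"`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return noisy signal vector, same length.
#' @export
addNoise <- function(signals, snr, model = c("rician", "gaussian"),
                     seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0)
    .stopf("snr must be a single positive number")
  if (!is.finite(snr)) return(signals)
  sigma <- 1 / snr
  n <- length(signals)
  .withSeed(seed, {
    e1 <- stats::rnorm(n, 0, sigma)
    if (model == "gaussian") {
      signals + e1
    } else {
      e2 <- stats::rnorm(n, 0, sigma)
      sqrt((signals + e1)^2 + e2^2)
    }
  })
}
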