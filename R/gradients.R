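#' Construct a diffusion-encoding scheme
#'
#' Low-level constructor; most users will call [loadScheme()] or
#' [generateScheme()].  Directions whose norm deviates from 1 by less
#' than `1e-3` are renormalized; larger deviations are an error (except
#' zero rows on b = 0 acquisitions).
#'
#' @param bvals numeric b-values (s/mm^2).
#' @param dirs n x 3 matrix of gradient directions.
#' @param b0Threshold b-values at or below this count as b = 0.
#' @return a [GradientScheme-class].
#' @export
gradientScheme <- function(bvals, dirs, b0Threshold = 10) {
  bvals <- as.numeric(bvals)
  dirs <- as.matrix(dirs)
  if (nrow(dirs) == 3L && length(bvals) != 3L && ncol(dirs) == length(bvals))
    dirs <- t(dirs)
  if (nrow(dirs) != length(bvals))
    .stopf("scheme format error: %d b-values but %d directions",
           length(bvals), nrow(dirs))
  if (any(bvals < 0))
    .stopf("invalid scheme: negative b-values")
  nrm <- sqrt(rowSums(dirs^2))
  renorm <- nrm > 0 & abs(nrm - 1) < 1e-3
  dirs[renorm, ] <- dirs[renorm, , drop = FALSE] / nrm[renorm]
  # rows like (3,4,0) are direction specifications, not near-unit vectors:
  # normalize any non-zero row on a diffusion-weighted acquisition
  dw <- bvals > b0Threshold
  fix <- nrm > 0 & dw & abs(nrm - 1) >= 1e-3
  dirs[fix, ] <- dirs[fix, , drop = FALSE] / nrm[fix]
  new("GradientScheme", bvals = bvals, dirs = unname(dirs),
      b0Threshold = b0Threshold)
}

#' Read an FSL-style bval/bvec pair
#'
#' `bval` is one row of whitespace-separated b-values (s/mm^2); `bvec`
#' is three rows holding the x, y and z components of each direction.
#' Non-unit direction rows are renormalized; zero vectors are accepted
#' on b = 0 acquisitions and flagged non-diffusion-weighted.
#'
#' @param bvalPath,bvecPath paths to the two text files.
#' @param b0Threshold see [gradientScheme()].
#' @return a [GradientScheme-class].
#' @examples
#' sch <- generateScheme(nDirs = 12, bMax = 2000, seed = 7)
#' tf <- tempfile()
#' saveScheme(sch, paste0(tf, ".bval"), paste0(tf, ".bvec"))
#' sch2 <- loadScheme(paste0(tf, ".bval"), paste0(tf, ".bvec"))
#' all.equal(bValues(sch), bValues(sch2))
#' @export
loadScheme <- function(bvalPath, bvecPath, b0Threshold = 10) {
  if (!file.exists(bvalPath)) .stopf("bval file not found: %s", bvalPath)
  if (!file.exists(bvecPath)) .stopf("bvec file not found: %s", bvecPath)
  bvals <- scan(bvalPath, quiet = TRUE)
  rows <- utils::read.table(bvecPath)
  if (nrow(rows) != 3L)
    .stopf("bvec format error: expected 3 rows, found %d", nrow(rows))
  if (ncol(rows) != length(bvals))
    .stopf("scheme format error: %d b-values but %d bvec columns",
           length(bvals), ncol(rows))
  gradientScheme(bvals, t(as.matrix(rows)), b0Threshold = b0Threshold)
}

#' Write a scheme as FSL bval/bvec text files
#'
#' @param scheme a [GradientScheme-class].
#' @param bvalPath,bvecPath output paths.
#' @return invisibly, the scheme.
#' @export
saveScheme <- function(scheme, bvalPath, bvecPath) {
  stopifnot(is(scheme, "GradientScheme"))
  writeLines(paste(format(scheme@bvals, digits = 17, trim = TRUE),
                   collapse = " "), bvalPath)
  vec <- t(scheme@dirs)
  lines <- apply(vec, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " "))
  writeLines(lines, bvecPath)
  invisible(scheme)
}

#' Generate a multi-b diffusion-encoding scheme
#'
#' Directions are placed quasi-uniformly on the sphere by a golden-spiral
#' lattice (deterministic); non-zero b-values are uniformly spaced on
#' `(0, bMax]` and paired with directions in a seed-reproducible random
#' order, so that every direction subset spans many diffusion weightings
#' (an isotropic diffusivity spectrum cannot be constrained from a single
#' shell).  `nB0` unweighted acquisitions are prepended.
#'
#' @param nDirs number of diffusion-weighted directions, `>= 6`.
#' @param bMax maximum b-value (s/mm^2).
#' @param nB0 number of b = 0 acquisitions to prepend.
#' @param seed integer seed for the direction/b pairing.
#' @param bMin smallest non-zero b-value; default `bMax / nDirs`.
#' @return a [GradientScheme-class] with `nDirs + nB0` acquisitions.
#' @examples
#' sch <- generateScheme(nDirs = 99, bMax = 3000, seed = 1)
#' nAcquisitions(sch)   # 100
#' max(bValues(sch))    # 3000
#' @export
generateScheme <- function(nDirs, bMax, nB0 = 1, seed = 1, bMin = NULL) {
  if (nDirs < 6) .stopf("invalid scheme request: nDirs must be >= 6")
  if (bMax <= 0) .stopf("invalid scheme request: bMax must be positive")
  dirs <- .sphereDirections(nDirs)
  if (is.null(bMin)) bMin <- bMax / nDirs
  b <- seq(bMin, bMax, length.out = nDirs)
  perm <- .withSeed(seed, sample.int(nDirs))
  b <- b[perm]
  bvals <- c(rep(0, nB0), b)
  dirs <- rbind(matrix(0, nB0, 3), dirs)
  gradientScheme(bvals, dirs)
}
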