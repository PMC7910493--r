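#' Convert an RGB raster to grayscale
#'
#' Rec. 601 luminance: `0.299 R + 0.587 G + 0.114 B`.  Integer-scaled
#' input (values above 1, e.g. 8-bit 0--255) is rounded back to integers;
#' unit-range float input stays float.
#'
#' @param image numeric array `h x w x 3`.
#' @return `h x w` matrix on the input's intensity scale.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgbToGrayscale(px)  # 76
#' @export
rgbToGrayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    .stopf("expected a 3-channel RGB image, got dim %s",
           paste(d, collapse = "x"))
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (max(image, na.rm = TRUE) > 1) g <- round(g)
  g
}

#' Read landmark pairs from TSV
#'
#' Four whitespace/tab-separated columns: `x_src y_src x_dst y_dst`,
#' one row per landmark, pixel coordinates (x = column, y = row, origin
#' at pixel center (0, 0)).
#'
#' @param path file path.
#' @return list with `source` and `target`, each an n x 2 matrix.
#' @export
readLandmarks <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) != 4L) .stopf("landmark file must have 4 columns")
  list(source = as.matrix(tab[, 1:2]), target = as.matrix(tab[, 3:4]))
}

.tpsKernel <- function(r2) {
  u <- r2 * log(r2)
  u[r2 == 0] <- 0   # removable singularity: U(0) = 0
  u
}

.tpsK <- function(p, q) {
  r2 <- outer(p[, 1], q[, 1], `-`)^2 + outer(p[, 2], q[, 2], `-`)^2
  .tpsKernel(r2)
}

#' Fit a 2-D thin-plate-spline transform to landmark pairs
#'
#' Solves the standard TPS linear system with kernel
#' `U(r) = r^2 log(r^2)`.  With `regularization = 0` the transform
#' interpolates: every mapped source landmark equals its target to
#' numerical precision, and any exactly affine correspondence yields
#' zero warping weights.  Positive regularization trades landmark fit
#' for lower bending energy.
#'
#' @param source,target n x 2 landmark matrices (columns x, y), index
#'   aligned, n >= 3, sources distinct and not all collinear.
#' @param regularization non-negative scalar added to the kernel
#'   diagonal.
#' @return a [TPSTransform-class].
#' @examples
#' src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
#' tr <- fitTPS(src, src + cbind(5, -3))
#' tpsMap(tr, cbind(2, 2))   # (7, -1)
#' @export
fitTPS <- function(source, target, regularization = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n < 3L || nrow(target) != n || ncol(source) != 2L || ncol(target) != 2L)
    .stopf("need n >= 3 index-aligned (x, y) landmark pairs")
  if (regularization < 0) .stopf("regularization must be >= 0")
  d2 <- as.matrix(stats::dist(source))^2
  if (any(d2[upper.tri(d2)] < 1e-18))
    .stopf("singular TPS system: duplicate source landmarks")
  K <- .tpsK(source, source) + diag(regularization, n)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs),
                   error = function(e)
                     .stopf("singular TPS system: collinear or degenerate landmarks"))
  new("TPSTransform", affine = coef[n + 1:3, , drop = FALSE],
      weights = coef[1:n, , drop = FALSE], source = unname(source))
}

#' Apply a TPS transform to points
#'
#' @param transform a [TPSTransform-class].
#' @param points m x 2 matrix of (x, y) coordinates.
#' @return m x 2 matrix of mapped coordinates.
#' @export
tpsMap <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  U <- .tpsK(points, transform@source)
  cbind(1, points) %*% transform@affine + U %*% transform@weights
}

#' Bending energy of a fitted TPS
#'
#' The thin-plate integral bending norm, `sum_axis w' K w`; zero for a
#' purely affine transform and non-increasing in the regularization
#' parameter on fixed landmarks.
#'
#' @param transform a [TPSTransform-class].
#' @return non-negative scalar.
#' @export
tpsBendingEnergy <- function(transform) {
  K <- .tpsK(transform@source, transform@source)
  sum(diag(t(transform@weights) %*% K %*% transform@weights))
}

#' Warp a raster through a TPS transform
#'
#' Inverse-mapping resampling: `transform` must map *output* (e.g. MRI)
#' pixel coordinates to *input* (e.g. histology) coordinates; each
#' output pixel samples the input image at its mapped position.
#' Intensity images use bilinear interpolation, label masks
#' `mode = "nearest"` (no new label values are created).  Pixels mapping
#' outside the input domain get background 0.  Coordinates are pixel
#' centers, origin (0, 0), x = column.
#'
#' @param image numeric matrix (input raster).
#' @param transform a [TPSTransform-class] mapping output to input
#'   coordinates.
#' @param outputShape `c(nrow, ncol)` of the result.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return warped matrix of dimension `outputShape`.
#' @export
warpImage <- function(image, transform, outputShape = dim(image),
                      mode = c("bilinear", "nearest")) {
  if (is.character(mode)) mode <- match.arg(mode)
  else .stopf("unknown resampling mode")
  image <- as.matrix(image)
  H <- outputShape[1]; W <- outputShape[2]
  xy <- cbind(rep(seq_len(W) - 1, each = H), rep(seq_len(H) - 1, W))
  src <- tpsMap(transform, xy)
  xs <- src[, 1]; ys <- src[, 2]
  hIn <- nrow(image); wIn <- ncol(image)
  # snap coordinates that fall a rounding error outside the domain
  tol <- 1e-6
  xs[xs < 0 & xs > -tol] <- 0
  ys[ys < 0 & ys > -tol] <- 0
  xs[xs > wIn - 1 & xs < wIn - 1 + tol] <- wIn - 1
  ys[ys > hIn - 1 & ys < hIn - 1 + tol] <- hIn - 1
  out <- numeric(H * W)
  if (mode == "nearest") {
    cs <- round(xs) + 1; rs <- round(ys) + 1
    ok <- cs >= 1 & cs <= wIn & rs >= 1 & rs <= hIn
    out[ok] <- image[cbind(rs[ok], cs[ok])]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    ok <- x0 >= 0 & x0 <= wIn - 1 & y0 >= 0 & y0 <= hIn - 1
    # clamp the +1 neighbor at the border so edge pixels interpolate flat
    x1 <- pmin(x0 + 1, wIn - 1); y1 <- pmin(y0 + 1, hIn - 1)
    i <- which(ok)
    v00 <- image[cbind(y0[i] + 1, x0[i] + 1)]
    v01 <- image[cbind(y0[i] + 1, x1[i] + 1)]
    v10 <- image[cbind(y1[i] + 1, x0[i] + 1)]
    v11 <- image[cbind(y1[i] + 1, x1[i] + 1)]
    out[i] <- (1 - fy[i]) * ((1 - fx[i]) * v00 + fx[i] * v01) +
      fy[i] * ((1 - fx[i]) * v10 + fx[i] * v11)
  }
  matrix(out, H, W)
}

#' Transfer histology ROI labels to the MRI grid
#'
#' Forward-maps every labeled histology pixel center through the
#' histology-to-MRI transform, bins the mapped points into MRI voxels
#' and assigns each voxel the majority class among the histology pixels
#' covering it.  Voxels with no coverage stay unlabeled (`NA`); exact
#' ties are left unlabeled and counted in the `ties` attribute.
#'
#' @param roiMasks named list of logical matrices on the shared
#'   histology grid, one per class; classes must be disjoint.
#' @param transform a [TPSTransform-class] mapping histology to MRI
#'   pixel coordinates.
#' @param mriShape `c(nrow, ncol)` of the MRI slice.
#' @return integer matrix of class indices into `names(roiMasks)`
#'   (`NA` = unlabeled), with attribute `ties` giving the tied-voxel
#'   count.
#' @export
transferROIs <- function(roiMasks, transform, mriShape) {
  H <- mriShape[1]; W <- mriShape[2]
  lab <- matrix(NA_integer_, H, W)
  if (!length(roiMasks)) {
    attr(lab, "ties") <- 0L
    return(lab)
  }
  dims <- unique(lapply(roiMasks, dim))
  if (length(dims) != 1L) .stopf("ROI masks must share the histology grid")
  overlap <- Reduce(`+`, lapply(roiMasks, function(m) m * 1L))
  if (any(overlap > 1L)) .stopf("overlapping input ROIs")
  counts <- array(0L, dim = c(H, W, length(roiMasks)))
  for (ci in seq_along(roiMasks)) {
    m <- roiMasks[[ci]]
    px <- which(m, arr.ind = TRUE)
    if (!nrow(px)) next
    xy <- cbind(px[, 2] - 1, px[, 1] - 1)   # (x = col, y = row), 0-based
    mp <- tpsMap(transform, xy)
    cs <- round(mp[, 1]) + 1; rs <- round(mp[, 2]) + 1
    ok <- cs >= 1 & cs <= W & rs >= 1 & rs <= H
    if (!any(ok)) next
    tt <- table(factor(rs[ok] + (cs[ok] - 1) * H,
                       levels = seq_len(H * W)))
    counts[, , ci] <- counts[, , ci] + matrix(as.integer(tt), H, W)
  }
  totals <- apply(counts, c(1, 2), sum)
  ties <- 0L
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (totals[r, cc] == 0L) next
    v <- counts[r, cc, ]
    top <- which(v == max(v))
    if (length(top) > 1L) ties <- ties + 1L else lab[r, cc] <- top
  }
  attr(lab, "ties") <- ties
  lab
}
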