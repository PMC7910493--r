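# Shared fixtures; everything is generated in code.

# small scheme for fast fitting tests
testScheme <- function(nDirs = 30, seed = 7) {
  generateScheme(nDirs = nDirs, bMax = 3000, nB0 = 1, seed = seed)
}

# one-fiber + two-isotropic-compartment reference model
mixtureModel <- function() {
  voxelModel(
    components = list(anisotropicComponent(0.4, 1.5, 0.3, c(0, 0, 1))),
    spectrum = isotropicSpectrum(c(0.5, 1.2), c(0.35, 0.25)))
}

# well-separated 6-class feature table (class means 5 SDs apart)
separableTable <- function(nPerClass = 200, seed = 42) {
  withr::with_seed(seed, {
    blocks <- lapply(0:5, function(k) {
      X <- matrix(stats::rnorm(nPerClass * 12, mean = k * 5, sd = 1),
                  nPerClass, 12)
      df <- as.data.frame(X)
      names(df) <- featureMetrics()
      df$class <- histologyClasses()[k + 1]
      df
    })
    tab <- do.call(rbind, blocks)
    tab$class <- factor(tab$class, levels = histologyClasses())
    data.frame(voxel_id = seq_len(nrow(tab)), tab)
  })
}

# two-class numeric table for SMOTE tests
twoClassTable <- function(nA = 100, nB = 40, seed = 5) {
  withr::with_seed(seed, {
    tab <- data.frame(
      voxel_id = seq_len(nA + nB),
      f1 = stats::rnorm(nA + nB),
      f2 = stats::rnorm(nA + nB),
      class = factor(rep(c("A", "B"), c(nA, nB))))
    tab
  })
}

# does point p lie on the segment between a and b (coordinate-wise
# consistent interpolation factor in [0, 1])?
onSegment <- function(p, a, b, tol = 1e-8) {
  d <- b - a
  off <- p - a
  if (all(abs(d) < tol)) return(all(abs(off) < tol))
  u <- off[abs(d) >= tol] / d[abs(d) >= tol]
  if (any(abs(off[abs(d) < tol]) > tol)) return(FALSE)
  diff(range(u)) < 1e-6 && u[1] >= -tol && u[1] <= 1 + tol
}

# brute-force pairwise AUC (ties count one half)
pairwiseAUC <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
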