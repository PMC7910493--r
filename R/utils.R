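# Shared internal helpers.

# Quasi-uniform points on the unit sphere (n points) or upper hemisphere,
# by golden-spiral (Fibonacci lattice) placement.  Deterministic.
.sphereDirections <- function(n, hemisphere = FALSE) {
  i <- seq_len(n)
  if (hemisphere) {
    z <- (i - 0.5) / n          # z in (0, 1): upper hemisphere
  } else {
    z <- (2 * i - 1) / n - 1    # z in (-1, 1)
  }
  theta <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# b-values converted to internal units (ms/um^2) so exp(-b*D) is
# consistent with diffusivities in um^2/ms.
.bInternal <- function(scheme) bValues(scheme) / 1000

# Evaluate an RNG-consuming expression under a temporary seed without
# disturbing the caller's RNG stream.  seed = NULL leaves the stream alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated-normal draws by rejection sampling; exact for our purposes,
# falls back to inverse-CDF sampling when the acceptance rate is tiny.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 50L) {
    m <- max(n - length(out), 16L)
    x <- stats::rnorm(ceiling(m * 1.5), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    tries <- tries + 1L
  }
  if (length(out) < n) {
    plo <- stats::pnorm(lower, mean, sd)
    phi <- stats::pnorm(upper, mean, sd)
    u <- stats::runif(n - length(out), plo, phi)
    out <- c(out, stats::qnorm(u, mean, sd))
  }
  out[seq_len(n)]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
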