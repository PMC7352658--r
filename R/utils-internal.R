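# Internal numerics shared across modules.

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitVec <- function(v) v / sqrt(sum(v^2))

#' @noRd
gaussianKernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 2D convolution via zero-padded FFT; returns the "same"-sized central part.
# kernel must have odd dimensions. Zero padding means mass near the border
# leaks out rather than wrapping around (deliberate: densities attenuate at
# edges instead of aliasing).
fftConvolve2d <- function(mat, kernel) {
  dm <- dim(mat); dk <- dim(kernel)
  stopifnot(all(dk %% 2L == 1L))
  dp <- dm + dk - 1L
  # next fast size: plain dp is fine for the sizes used here
  pm <- matrix(0, dp[1], dp[2]); pm[seq_len(dm[1]), seq_len(dm[2])] <- mat
  pk <- matrix(0, dp[1], dp[2]); pk[seq_len(dk[1]), seq_len(dk[2])] <- kernel
  full <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) /
    prod(dp)
  off <- (dk - 1L) / 2L
  full[off[1] + seq_len(dm[1]), off[2] + seq_len(dm[2])]
}

# Isotropic Gaussian smoothing of a matrix (separable kernel, FFT-convolved).
gaussianSmooth2d <- function(mat, sigma, truncate = 4) {
  if (sigma <= 0) return(mat)
  k1 <- gaussianKernel1d(sigma, truncate)
  fftConvolve2d(mat, outer(k1, k1))
}

# Deterministic per-stage seed derivation: one user seed fans out so that
# toggling a stage never shifts the stream of another. Kept below 2^31.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 104729 * (h %% 19997)) %% 2147483647)
}

# Round-half-away-from-zero to the nearest value of an ordinal grid.
snapToGrid <- function(x, grid) {
  grid[apply(abs(outer(x, grid, "-")), 1L, which.min)]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

stopifnotScalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
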