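# Internal numeric helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable Gaussian blur of a matrix; truncated kernels at the borders
# are renormalized, so constants are preserved exactly.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smooth_1d <- function(n) {
    r <- ceiling(3 * sigma)
    k <- stats::dnorm(-r:r, sd = sigma)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K
  }
  smooth_1d(nrow(m)) %*% m %*% t(smooth_1d(ncol(m)))
}

# Smooth zero-mean, unit-variance random field (white noise blurred and
# re-standardized); used for spatial heterogeneity in phantoms.
smooth_field <- function(h, w, sigma) {
  f <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), sigma)
  (f - mean(f)) / stats::sd(f)
}
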