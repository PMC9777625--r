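# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Separable Gaussian blur with mirror (replicate-reflected) boundary.
# Used to impose a correlation length on the white speckle field.
gaussian_blur <- function(X, sigma) {
  if (sigma <= 0) return(X)
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-m):m)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(X, along_rows) {
    n <- if (along_rows) nrow(X) else ncol(X)
    out <- 0
    for (j in seq_along(k)) {
      o <- j - m - 1L
      idx <- seq_len(n) + o
      idx[idx < 1L] <- 1L - (idx[idx < 1L])          # mirror: 0 -> 1, -1 -> 2
      idx[idx > n] <- 2L * n + 1L - idx[idx > n]
      out <- out + k[j] * (if (along_rows) X[idx, , drop = FALSE]
                           else X[, idx, drop = FALSE])
    }
    out
  }
  blur_axis(blur_axis(X, TRUE), FALSE)
}

# variance shrinkage factor of white noise under the same blur (sum k_2d^2)
gaussian_blur_var_factor <- function(sigma) {
  if (sigma <= 0) return(1)
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-m):m)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sum(k^2)^2
}
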