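# Exact zero-padded Gaussian smoothing.
#
# An isotropic 2-D Gaussian kernel is separable, so convolution is two
# matrix products with dense Toeplitz kernel matrices: K_row %*% M %*% K_col.
# Because the kernel matrices cover the full image extent there is no kernel
# truncation -- the result equals brute-force dense convolution with a
# zero-padded boundary up to floating point error. The 1-D weights are
# normalized by the *infinite* discrete Gaussian mass, so the smoothed image
# conserves the input mass except for what falls off the image border.

gaussian_weights_1d <- function(n, sigma) {
  stopifnot(sigma > 0)
  d <- seq.int(-(n - 1L), n - 1L)
  w <- exp(-d^2 / (2 * sigma^2))
  # normalizing constant: discrete Gaussian mass over all integers
  r <- max(n - 1L, ceiling(12 * sigma))
  z <- sum(exp(-(seq.int(-r, r))^2 / (2 * sigma^2)))
  w / z
}

gaussian_kernel_matrix <- function(n, sigma) {
  w <- gaussian_weights_1d(n, sigma)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) i - j + n)
  matrix(w[idx], n, n)
}

# Smooth an H x W matrix with an isotropic Gaussian of sd `sigma` pixels,
# zero-padded boundary.
smooth_gaussian <- function(m, sigma) {
  stopifnot(is.matrix(m))
  kr <- gaussian_kernel_matrix(nrow(m), sigma)
  kc <- gaussian_kernel_matrix(ncol(m), sigma)
  kr %*% m %*% kc
}
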