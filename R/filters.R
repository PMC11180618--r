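# Separable filtering primitives shared by the boundary and map modules.
# All filters are applied by explicit tap-shifted sums so that edge padding
# (replicate for smoothing/derivatives, zero-with-count for moving averages)
# is under control and the same code path serves matrices and frame stacks.

# index a matrix or 3D array along one axis with an index vector
index_axis <- function(x, idx, axis) {
  nd <- length(dim(x))
  if (nd == 2) {
    if (axis == 1) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
  } else if (nd == 3) {
    switch(axis,
      x[idx, , , drop = FALSE],
      x[, idx, , drop = FALSE],
      x[, , idx, drop = FALSE]
    )
  } else {
    stop("index_axis supports 2D and 3D arrays only")
  }
}

# cross-correlate along one axis with replicate edge padding
convolve_axis <- function(x, kernel, axis) {
  d <- dim(x)
  n <- d[axis]
  half <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (j in seq_along(kernel)) {
    if (kernel[j] == 0) next
    idx <- pmin(pmax(base + (j - 1L - half), 1L), n)
    out <- out + kernel[j] * index_axis(x, idx, axis)
  }
  out
}

# Gaussian taps for a window of `size` pixels; sigma from the size by the
# common automatic rule so the size alone determines the filter
gaussian_kernel <- function(size) {
  size <- as.integer(size)
  if (size == 1L) return(1)
  sigma <- 0.3 * ((size - 1) / 2 - 1) + 0.8
  u <- seq(-(size - 1L) %/% 2L, (size - 1L) %/% 2L)
  g <- exp(-(u^2) / (2 * sigma^2))
  g / sum(g)
}

# polynomial-coefficient construction of the extended Sobel taps:
# smoothing = (1+x)^(size-1), derivative = (1+x)^(size-3) * (x^2-1)
poly_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

sobel_taps <- function(size) {
  size <- as.integer(size)
  if (size < 3L) stop("Sobel aperture must be >= 3")
  smooth <- choose(size - 1L, 0:(size - 1L))
  deriv <- c(-1, 0, 1)
  if (size > 3L) {
    for (k in seq_len(size - 3L)) deriv <- poly_conv(deriv, c(1, 1))
  }
  list(smooth = smooth, deriv = deriv)
}

# Sobel response of a matrix: derivative along `axis`, binomial smoothing
# along the other axis; positive where values increase along `axis`
sobel_response <- function(m, size, axis) {
  taps <- sobel_taps(size)
  other <- if (axis == 1) 2 else 1
  convolve_axis(convolve_axis(m, taps$deriv, axis), taps$smooth, other)
}

# shift along an axis, zero-filling vacated cells (used for moving averages)
shift_zero <- function(x, off, axis) {
  d <- dim(x)
  n <- d[axis]
  out <- array(0, d)
  if (abs(off) >= n) return(out)
  src <- if (off >= 0) seq_len(n - off) + off else seq_len(n + off)
  dst <- if (off >= 0) seq_len(n - off) else seq_len(n + off) - off
  if (length(d) == 2) {
    if (axis == 1) out[dst, ] <- x[src, , drop = FALSE] else out[, dst] <- x[, src, drop = FALSE]
  } else {
    stop("shift_zero supports matrices only")
  }
  out
}

# centred moving average along one axis of a matrix; NA cells are excluded
# from the window and cells with an all-NA window stay NA
moving_average_axis <- function(m, window, axis) {
  window <- as.integer(window)
  half <- (window - 1L) %/% 2L
  nas <- is.na(m)
  v <- m
  v[nas] <- 0
  w <- array(as.numeric(!nas), dim(m))
  num <- array(0, dim(m))
  den <- array(0, dim(m))
  for (off in seq(-half, half)) {
    num <- num + shift_zero(v, off, axis)
    den <- den + shift_zero(w, off, axis)
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out[nas] <- NA_real_
  out
}
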