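# Internal array helpers: axis shifts, reflective-boundary separable
# convolution, and sampled Gaussian kernels. These are the numeric
# workhorses behind blurring, membrane rendering and morphology.

# Shift a 3D array by one voxel along an axis, padding with `fill`.
shift3 <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Reflect out-of-range 1-based indices about the array edges
# (symmetric half-sample convention: 0 -> 1, -1 -> 2, n+1 -> n).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  i <- ((i - 1L) %% p + p) %% p # 0-based, period 2n
  ifelse(i < n, i + 1L, p - i)
}

# Sampled, normalized 1D Gaussian kernel; radius 4 sigma (>= 1 tap).
gaussian_kernel <- function(sigma_px) {
  stopifnot(sigma_px >= 0)
  if (sigma_px == 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Correlate one axis of a 3D array with a symmetric kernel, reflective
# boundaries. Kernel length must be odd.
convolve_axis3 <- function(a, k, axis) {
  nk <- length(k)
  if (nk == 1L) return(a * k)
  r <- (nk - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, d)
  idx_all <- lapply(d, seq_len)
  for (j in -r:r) {
    w <- k[j + r + 1L]
    idx <- idx_all
    idx[[axis]] <- reflect_index(seq_len(d[axis]) + j, d[axis])
    out <- out + w * a[idx[[1]], idx[[2]], idx[[3]]]
  }
  out
}

# 2D variant used for per-slice lateral blurring.
convolve_axis2 <- function(m, k, axis) {
  nk <- length(k)
  if (nk == 1L) return(m * k)
  r <- (nk - 1L) %/% 2L
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  for (j in -r:r) {
    w <- k[j + r + 1L]
    if (axis == 1L) {
      out <- out + w * m[reflect_index(seq_len(d[1]) + j, d[1]), , drop = FALSE]
    } else {
      out <- out + w * m[, reflect_index(seq_len(d[2]) + j, d[2]), drop = FALSE]
    }
  }
  out
}

# TRUE for foreground voxels with a 6-neighbor carrying a different label
# (out-of-grid neighbors count as exterior label 0).
boundary_voxels6 <- function(labels) {
  a <- as_bare_array(labels)
  storage.mode(a) <- "double"
  b <- array(FALSE, dim(a))
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    nb <- shift3(a, axis, s, fill = 0)
    b <- b | (nb != a)
  }
  b & (a > 0)
}

# One 6-connected binary dilation step restricted to `within`.
dilate6_within <- function(mask, within) {
  m <- mask
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    m <- m | (shift3(mask, axis, s, fill = FALSE) > 0)
  }
  m & within
}
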