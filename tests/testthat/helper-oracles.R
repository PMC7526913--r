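# Independent, naive reference implementations used to validate the fast
# paths. These deliberately re-derive every quantity from first principles
# (full-pass fixpoint iterations, dense convolutions, exhaustive scans).

# Precomputed neighbor lists (linear indices) for a grid.
make_nb <- function(d, conn = 6) {
  n <- prod(d)
  xyz <- arrayInd(seq_len(n), d)
  offs <- if (conn == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  lapply(seq_len(n), function(i) {
    nb <- sweep(offs, 2, xyz[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
  })
}

# -- morphological reconstruction by erosion (full-pass fixpoint) -------------
naive_reconstruct_erosion <- function(marker, mask, nb) {
  r <- marker
  repeat {
    r_old <- r
    for (i in seq_along(r)) r[i] <- max(mask[i], min(r[i], min(r[nb[[i]]])))
    for (i in rev(seq_along(r))) r[i] <- max(mask[i], min(r[i], min(r[nb[[i]]])))
    if (identical(r, r_old)) break
  }
  r
}

# -- regional minima with scan-order labels -----------------------------------
naive_regional_minima <- function(image, nb) {
  lab <- integer(length(image))
  visited <- logical(length(image))
  nxt <- 0L
  for (i in seq_along(image)) {
    if (visited[i]) next
    v <- image[i]
    plateau <- i
    visited[i] <- TRUE
    queue <- i
    is_min <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      nbi <- nb[[p]]
      if (any(image[nbi] < v)) is_min <- FALSE
      eq <- nbi[image[nbi] == v & !visited[nbi]]
      visited[eq] <- TRUE
      plateau <- c(plateau, eq)
      queue <- c(queue, eq)
    }
    if (is_min) {
      nxt <- nxt + 1L
      lab[plateau] <- nxt
    }
  }
  lab
}

# -- naive priority flooding --------------------------------------------------
# Mirrors the deterministic rule of the fast implementation: pop the
# frontier voxel minimizing (value, index); take the label of its labeled
# neighbor minimizing (value, index).
naive_watershed <- function(image, markers, nb) {
  lab <- markers
  frontier <- logical(length(image))
  for (i in which(lab == 0L)) {
    if (any(lab[nb[[i]]] != 0L)) frontier[i] <- TRUE
  }
  while (any(frontier)) {
    cand <- which(frontier)
    p <- cand[order(image[cand], cand)[1]]
    nbi <- nb[[p]]
    nl <- nbi[lab[nbi] != 0L]
    q <- nl[order(image[nl], nl)[1]]
    lab[p] <- lab[q]
    frontier[p] <- FALSE
    frontier[nbi[lab[nbi] == 0L]] <- TRUE
  }
  lab
}

# Full naive analog of morphological_segmentation (basins only).
naive_segmentation <- function(a, h, conn = 6) {
  d <- dim(a)
  nb <- make_nb(d, conn)
  av <- as.vector(a)
  hm <- if (h > 0) naive_reconstruct_erosion(av + h, av, nb) else av
  mk <- naive_regional_minima(hm, nb)
  array(naive_watershed(av, mk, nb), d)
}

# -- dense 3D convolution oracle ----------------------------------------------
dense_gauss3 <- function(a, sigma) {
  d <- dim(a)
  ks <- lapply(1:3, function(ax) {
    s <- sigma[ax]
    if (s == 0) return(1)
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  out <- array(0, d)
  r <- vapply(ks, function(k) (length(k) - 1L) %/% 2L, 0L)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (ix in -r[1]:r[1]) for (iy in -r[2]:r[2]) for (iz in -r[3]:r[3]) {
      sx <- x + ix; sy <- y + iy; sz <- z + iz
      if (sx < 1 || sx > d[1] || sy < 1 || sy > d[2] ||
          sz < 1 || sz > d[3]) next
      acc <- acc + a[sx, sy, sz] *
        ks[[1]][ix + r[1] + 1] * ks[[2]][iy + r[2] + 1] *
        ks[[3]][iz + r[3] + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

# -- exhaustive Otsu ----------------------------------------------------------
brute_otsu <- function(v) {
  lev <- sort(unique(v))
  best <- -Inf
  best_t <- NA
  n <- length(v)
  for (t in lev[-length(lev)]) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    w0 <- length(g0) / n; w1 <- 1 - w0
    sb <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  best_t
}

# -- digital phantom builders -------------------------------------------------
digital_ball <- function(r, pad = 2, voxel = c(1, 1, 1)) {
  n <- 2 * r + 1 + 2 * pad
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  label_grid(array(as.integer(d2 <= r^2), c(n, n, n)), voxel)
}

digital_ellipsoid <- function(semi, pad = 2, voxel = c(1, 1, 1),
                              rot = diag(3)) {
  n <- 2 * ceiling(max(semi)) + 1 + 2 * pad
  ax <- seq_len(n) - (n + 1) / 2
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  b <- g %*% rot  # body-frame coordinates
  q <- (b[, 1] / semi[1])^2 + (b[, 2] / semi[2])^2 + (b[, 3] / semi[3])^2
  label_grid(array(as.integer(q <= 1), c(n, n, n)), voxel)
}

# Two dark cells separated by a bright sheet inside a bright shell.
two_cell_phantom <- function(n = 20) {
  a <- array(0, c(n, n, n))
  a[4:(n - 3), 4:(n - 3), 4:(n - 3)] <- 200
  a[6:(n - 5), 6:(n - 5), 6:(n - 5)] <- 40
  mid <- n %/% 2
  a[mid:(mid + 1), 4:(n - 3), 4:(n - 3)] <- 200
  voxel_grid(a, c(1, 1, 1))
}
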