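#' Sample an intensity line profile
#'
#' Samples gray values by linear (bi-/tri-linear) interpolation at uniform
#' spacing along a straight segment given in micrometre coordinates, with
#' the origin at the corner of the first voxel (voxel centres sit at
#' `(i - 0.5) * voxel_size`). The standard use is a short line drawn
#' perpendicularly across a cell-cell boundary (target length 4.96 um).
#'
#' @param image 2D matrix or 3D array of intensities.
#' @param start_um,end_um segment endpoints in um (length 2 or 3).
#' @param step_um sampling interval along the segment (um).
#' @param voxel_size_um physical pixel/voxel size (um per unit); length
#'   must match the dimensionality.
#' @return A `line_profile` data frame with columns `distance_um`, `gray`.
#' @export
line_profile <- function(image, start_um, end_um, step_um,
                         voxel_size_um = NULL) {
  nd <- length(dim(image))
  if (is.matrix(image)) nd <- 2L
  if (!nd %in% c(2L, 3L)) stop("image must be 2D or 3D")
  vs <- if (nd == 2L) {
    if (is.null(voxel_size_um)) voxel_size_um <- c(1, 1)
    if (length(voxel_size_um) != 2) stop("voxel_size_um must have length 2")
    as.numeric(voxel_size_um)
  } else resolve_voxel_size(image, voxel_size_um)
  if (step_um <= 0) stop("step_um must be positive")
  if (length(start_um) != nd || length(end_um) != nd)
    stop("endpoints must match image dimensionality")
  d <- dim(image)
  extent <- d * vs
  if (any(start_um < 0 | start_um > extent) ||
      any(end_um < 0 | end_um > extent))
    stop("profile endpoints lie outside the image")
  len <- sqrt(sum((end_um - start_um)^2))
  dists <- seq(0, len, by = step_um)
  tt <- if (len > 0) dists / len else rep(0, length(dists))
  pos <- outer(tt, end_um - start_um) + rep(start_um, each = length(tt))
  # continuous voxel coordinates (1-based, centre of voxel i at i)
  cc <- sweep(pos, 2, vs, `/`) + 0.5
  gray <- interp_linear(image, cc)
  structure(data.frame(distance_um = dists, gray = gray),
            class = c("line_profile", "data.frame"))
}

# Multilinear interpolation at continuous 1-based coordinates (rows of cc),
# clamped to the voxel-centre hull at the borders.
interp_linear <- function(image, cc) {
  d <- dim(image)
  nd <- length(d)
  lo <- hi <- w <- vector("list", nd)
  for (k in seq_len(nd)) {
    x <- pmin(pmax(cc[, k], 1), d[k])
    l <- pmin(floor(x), d[k] - ifelse(d[k] > 1, 1, 0))
    l <- pmax(l, 1)
    lo[[k]] <- l
    hi[[k]] <- pmin(l + 1, d[k])
    w[[k]] <- x - l
  }
  out <- numeric(nrow(cc))
  corners <- expand.grid(rep(list(0:1), nd))
  for (i in seq_len(nrow(corners))) {
    idx <- matrix(0, nrow(cc), nd)
    wt <- rep(1, nrow(cc))
    for (k in seq_len(nd)) {
      if (corners[i, k] == 0) {
        idx[, k] <- lo[[k]]
        wt <- wt * (1 - w[[k]])
      } else {
        idx[, k] <- hi[[k]]
        wt <- wt * w[[k]]
      }
    }
    out <- out + wt * image[idx]
  }
  out
}

#' Background-normalized boundary signal
#'
#' Converts a line profile crossing a cell-cell boundary into the
#' normalized signal `gray / background - 1`, where the background is the
#' mean gray over the initial cytoplasmic stretch of the profile (default
#' first 1 um). The peak is the maximum normalized signal beyond the
#' background window; one peak per boundary is the quantity compared
#' across imaging conditions.
#'
#' @param profile a [line_profile()] (columns `distance_um`, `gray`).
#' @param background_window_um length of the initial background stretch.
#' @return list with `background`, `signal` (data frame `distance_um`,
#'   `signal`), and `peak`.
#' @export
boundary_signal <- function(profile, background_window_um = 1.0) {
  stopifnot(all(c("distance_um", "gray") %in% names(profile)))
  dmax <- max(profile$distance_um)
  if (dmax <= background_window_um)
    stop("profile shorter than the background window")
  in_bg <- profile$distance_um < background_window_um
  if (!any(in_bg)) stop("no samples inside the background window")
  bg <- mean(profile$gray[in_bg])
  if (bg <= 0) stop("background mean must be > 0")
  sig <- profile$gray / bg - 1
  peak <- max(sig[!in_bg])
  list(background = bg,
       signal = data.frame(distance_um = profile$distance_um, signal = sig),
       peak = peak)
}

#' Otsu binarization
#'
#' Exact Otsu threshold over the empirical gray histogram: the cut that
#' maximizes the between-class variance, computed over all distinct gray
#' values. Pixels strictly above the threshold are foreground. Used to
#' produce qualitative boundary maps from membrane-channel crops.
#'
#' @param image numeric matrix (or array) with at least two distinct
#'   values.
#' @return list with `binary` (integer 0/1, same shape) and `threshold`.
#' @export
otsu_binarize <- function(image) {
  v <- as.vector(image)
  lev <- sort(unique(v))
  if (length(lev) < 2) stop("constant image: no valid Otsu threshold")
  cnt <- tabulate(match(v, lev))
  n <- length(v)
  w <- cumsum(cnt)                  # class sizes for threshold = lev[i]
  mu <- cumsum(cnt * lev)
  mu_t <- mu[length(mu)] / n
  w0 <- w[-length(w)] / n           # candidate thresholds: all but max level
  mu0 <- mu[-length(mu)] / w[-length(w)]
  # between-class variance sigma_b^2 = w0 w1 (mu0 - mu1)^2
  mu1 <- (mu_t * n - mu[-length(mu)]) / (n - w[-length(w)])
  sb <- w0 * (1 - w0) * (mu0 - mu1)^2
  i <- which.max(sb)                # ties: smallest threshold
  thr <- lev[i]
  bin <- image
  bin[] <- as.integer(image > thr)
  list(binary = bin, threshold = thr)
}
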