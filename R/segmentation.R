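#' Configuration of the 3D segmentation pipeline
#'
#' Bundles the parameters of the three-stage pipeline: per-slice
#' attenuation correction (grayscale opening radius and reference slice),
#' 3D Gaussian blur (sigma per axis in voxels), and tolerance-based
#' marker-controlled watershed of the border-type (bright-membrane) image.
#' Defaults are the settings used for membrane-channel embryo stacks:
#' opening radius 3 px, midplane reference, sigma (2, 2, 0.6) px,
#' watershed tolerance 22 gray levels, 6-connectivity.
#'
#' @param opening_radius_px disc radius of the grayscale opening used to
#'   estimate the per-slice background level.
#' @param reference_slice 1-based slice index, or `"midplane"` for
#'   `floor(n_z / 2) + 1`.
#' @param sigma_px Gaussian blur sigma `c(x, y, z)` in voxels.
#' @param tolerance watershed dynamic h: minima shallower than this merge
#'   with their neighbors.
#' @param connectivity 6 or 26.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(opening_radius_px = 3,
                            reference_slice = "midplane",
                            sigma_px = c(2, 2, 0.6),
                            tolerance = 22,
                            connectivity = 6) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (any(sigma_px < 0) || length(sigma_px) != 3)
    stop("sigma_px must be 3 nonnegative values")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (opening_radius_px <= 0) stop("opening_radius_px must be positive")
  structure(list(opening_radius_px = opening_radius_px,
                 reference_slice = reference_slice,
                 sigma_px = as.numeric(sigma_px),
                 tolerance = tolerance,
                 connectivity = as.integer(connectivity)),
            class = "pipeline_config")
}

resolve_reference_slice <- function(reference_slice, n_z) {
  if (identical(reference_slice, "midplane"))
    return(as.integer(floor(n_z / 2) + 1L))
  r <- as.integer(reference_slice)
  if (r < 1L || r > n_z) stop("reference slice out of range")
  r
}

#' Depth-attenuation correction
#'
#' Normalizes signal intensity across depths by a multiplicative per-slice
#' gain. The signal level of each slice is estimated from its grayscale
#' morphological opening (disc of the given radius), which suppresses
#' thin bright membrane ridges; the mean is taken over specimen
#' foreground only (opened values above a global Otsu threshold, when one
#' separates specimen from empty background), so that the varying
#' specimen cross-section does not bias the estimate. A log-linear decay
#' is then fitted to the per-slice levels (weighted by foreground size)
#' and each slice is scaled by the fitted gain relative to the reference
#' slice: after correction the (fitted) opened-foreground levels of all
#' slices agree with the reference. Fitting, rather than using raw
#' per-slice ratios, keeps the gain profile smooth in z so that estimate
#' noise is not imprinted onto the stack as artificial axial gradients;
#' for a stack whose slices decay exactly exponentially the fit is exact
#' and all corrected levels equal the reference's.
#'
#' @param stack nonnegative [voxel_grid()] (or bare array).
#' @param opening_radius_px disc radius in pixels.
#' @param reference_slice 1-based index or `"midplane"`.
#' @return The corrected stack, with per-slice gains in attribute
#'   `gains`.
#' @export
attenuation_correction <- function(stack, opening_radius_px = 3,
                                   reference_slice = "midplane") {
  a <- as_bare_array(stack)
  stopifnot(length(dim(a)) == 3)
  if (min(a) < 0) stop("stack must be nonnegative")
  nz <- dim(a)[3]
  ref <- resolve_reference_slice(reference_slice, nz)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(opening_radius_px)) + 1L,
                              shape = "disc")
  mx <- max(a)
  if (mx == 0) stop("cannot normalize: stack is identically zero")
  # EBImage grayscale morphology clamps to [0, 1]; opening commutes with
  # positive scaling, so normalize, open, rescale.
  op <- array(0, dim(a))
  for (z in seq_len(nz)) op[, , z] <- EBImage::opening(a[, , z] / mx, brush) * mx
  fg <- tryCatch(op > otsu_binarize(op)$threshold,
                 error = function(e) array(TRUE, dim(op)))
  if (!any(fg)) fg <- array(TRUE, dim(op))
  b <- vapply(seq_len(nz), function(z) {
    sel <- fg[, , z]
    if (any(sel)) mean(op[, , z][sel]) else NA_real_
  }, 0)
  if (all(is.na(b)))
    stop("cannot normalize: no foreground in any slice")
  if (any(b == 0, na.rm = TRUE))
    stop("cannot normalize: opened background is zero in slice(s) ",
         paste(which(b == 0), collapse = ", "))
  n_fg <- vapply(seq_len(nz), function(z) sum(fg[, , z]), 0)
  use <- which(!is.na(b))
  gains <- rep(1, nz)
  if (length(use) >= 2 && stats::sd(b[use]) > 0) {
    fit <- stats::lm(log(b[use]) ~ use, weights = n_fg[use])
    bhat <- exp(stats::predict(fit, newdata = data.frame(use = seq_len(nz))))
    gains <- bhat[ref] / bhat
  } else if (length(use) >= 1) {
    gains <- rep(1, nz)
  }
  out <- a
  for (z in seq_len(nz)) out[, , z] <- a[, , z] * gains[z]
  vs <- attr(stack, "voxel_size_um")
  res <- if (is.null(vs)) out else voxel_grid(out, vs)
  attr(res, "gains") <- gains
  res
}

#' Separable 3D Gaussian blur
#'
#' Convolves the stack with a sampled, normalized Gaussian kernel along
#' each axis (sigma in voxels per axis; 0 skips the axis), with reflective
#' boundary handling.
#'
#' @param stack [voxel_grid()] or bare 3D array.
#' @param sigma_px sigma `c(x, y, z)` in voxels.
#' @return Blurred stack of the same type.
#' @export
gaussian_blur_3d <- function(stack, sigma_px = c(2, 2, 0.6)) {
  a <- as_bare_array(stack)
  stopifnot(length(dim(a)) == 3, length(sigma_px) == 3, all(sigma_px >= 0))
  for (axis in 1:3) {
    if (sigma_px[axis] > 0)
      a <- convolve_axis3(a, gaussian_kernel(sigma_px[axis]), axis)
  }
  vs <- attr(stack, "voxel_size_um")
  if (is.null(vs)) a else voxel_grid(a, vs)
}

#' Tolerance-based marker-controlled 3D watershed
#'
#' Segments a border-type image (bright cell boundaries, dark interiors)
#' into catchment basins: (1) extended minima with dynamic `tolerance` are
#' computed via the h-minima transform (morphological reconstruction by
#' erosion of `image + h` over `image`); (2) each minima component becomes
#' a marker; (3) markers are flooded over the intensity image by a
#' deterministic priority rule, so every voxel joins exactly one basin.
#' The basin with the largest contact area with the grid border is
#' classified as exterior and excluded from the cell count.
#'
#' @param stack the border-type intensity stack.
#' @param tolerance minima dynamic h (gray levels).
#' @param connectivity 6 (default) or 26.
#' @return A `segmentation_result`: list with `basins` ([label_grid()] if
#'   a voxel size is known), `n_cells_detected`, `exterior_label`,
#'   `n_basins`, and `parameters`.
#' @export
morphological_segmentation <- function(stack, tolerance = 22,
                                       connectivity = 6) {
  a <- as_bare_array(stack)
  stopifnot(length(dim(a)) == 3)
  if (tolerance < 0) stop("tolerance must be >= 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(a)
  rng <- range(a)
  if (tolerance > diff(rng)) {
    warning("tolerance exceeds the image dynamic range: single basin")
    basins <- array(1L, d)
    markers <- NULL
  } else {
    av <- as.vector(a)
    hmin <- if (tolerance > 0) {
      cpp_reconstruct_erosion(av + tolerance, av, d, connectivity)
    } else av
    minima <- cpp_regional_minima(hmin, d, connectivity)
    markers <- array(minima, d)
    basins <- array(cpp_marker_watershed(av, minima, d, connectivity), d)
  }
  ext <- exterior_basin(basins)
  n_basins <- length(unique(as.vector(basins)))
  vs <- attr(stack, "voxel_size_um")
  basins_out <- if (is.null(vs)) basins else label_grid(basins, vs)
  structure(list(
    basins = basins_out,
    n_basins = n_basins,
    exterior_label = ext,
    n_cells_detected = n_basins - length(ext),
    parameters = list(tolerance = tolerance, connectivity = connectivity)
  ), class = "segmentation_result")
}

# Label with the largest contact area with the grid border (ties: smallest
# label). Returns integer(0) for an empty grid.
exterior_basin <- function(basins) {
  d <- dim(basins)
  border <- c(basins[1, , ], basins[d[1], , ],
              basins[, 1, ], basins[, d[2], ],
              basins[, , 1], basins[, , d[3]])
  tb <- table(border)
  as.integer(names(tb)[which.max(tb)])
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d basins (%d cells + exterior label %d)\n",
    x$n_basins, x$n_cells_detected, x$exterior_label))
  invisible(x)
}

#' Run the full segmentation pipeline
#'
#' Composition attenuation correction -> 3D Gaussian blur -> tolerance
#' watershed, with a provenance record of every parameter and per-stage
#' timings.
#'
#' @param stack raw membrane-channel [voxel_grid()].
#' @param config a [pipeline_config()].
#' @param correct_attenuation set `FALSE` to ablate the attenuation
#'   correction stage.
#' @return A `segmentation_result` with an added `provenance` entry.
#' @export
run_pipeline <- function(stack, config = pipeline_config(),
                         correct_attenuation = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  x <- stack
  if (correct_attenuation) {
    t0 <- proc.time()[3]
    x <- attenuation_correction(x, config$opening_radius_px,
                                config$reference_slice)
    timings["attenuation_correction"] <- proc.time()[3] - t0
  }
  t0 <- proc.time()[3]
  x <- gaussian_blur_3d(x, config$sigma_px)
  timings["gaussian_blur_3d"] <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  res <- morphological_segmentation(x, config$tolerance, config$connectivity)
  timings["morphological_segmentation"] <- proc.time()[3] - t0
  res$provenance <- list(config = unclass(config),
                         correct_attenuation = correct_attenuation,
                         dim = dim(stack),
                         timings_s = timings)
  res
}

#' Segmentation quality score
#'
#' The ground-truth cell count divided by the detected cell count,
#' expressed as a percentage: alpha = 100 * n_truth / n_detected.
#' Over-segmentation yields alpha < 100, under-segmentation > 100; no
#' capping is applied.
#'
#' @param n_truth true number of cells (>= 1).
#' @param n_detected number of detected cells (>= 1).
#' @return alpha in percent.
#' @export
segmentation_quality <- function(n_truth, n_detected) {
  if (n_truth < 1) stop("n_truth must be >= 1")
  if (n_detected < 1) stop("n_detected must be >= 1 (no cells detected)")
  100 * n_truth / n_detected
}

#' Match predicted labels to ground truth
#'
#' For every ground-truth cell, finds the predicted label with maximal
#' voxel overlap and reports intersection-over-union plus split/merge
#' flags: a truth cell is `split` when at least two predicted labels each
#' cover >= 20% of it; a predicted label causes `merged` when it is the
#' best match of a truth cell and covers >= 20% of at least one other
#' truth cell.
#'
#' @param truth,predicted [label_grid()]s of identical shape (0 =
#'   exterior).
#' @param coverage_frac coverage fraction defining the split/merge flags.
#' @return data frame: `label`, `matched_label`, `iou`, `split`, `merged`.
#' @export
match_labels <- function(truth, predicted, coverage_frac = 0.2) {
  if (!identical(dim(truth), dim(predicted)))
    stop("truth and predicted grids must have the same shape")
  tv <- as.vector(as_bare_array(truth))
  pv <- as.vector(as_bare_array(predicted))
  fg <- tv > 0L
  ct <- table(truth = tv[fg], predicted = pv[fg])
  t_ids <- as.integer(rownames(ct))
  p_sizes <- tabulate(pv[pv > 0L], nbins = max(pv, 1L))
  t_sizes <- rowSums(ct)
  p_ids <- as.integer(colnames(ct))
  best <- apply(ct, 1, which.max)
  res <- data.frame(label = t_ids,
                    matched_label = p_ids[best],
                    iou = NA_real_, split = FALSE, merged = FALSE)
  for (i in seq_along(t_ids)) {
    inter <- ct[i, best[i]]
    pl <- p_ids[best[i]]
    psz <- if (pl > 0L) p_sizes[pl] else sum(pv == 0L)
    res$iou[i] <- inter / (t_sizes[i] + psz - inter)
    res$split[i] <- sum(ct[i, ] >= coverage_frac * t_sizes[i]) >= 2
  }
  # merge: matched predicted label covers >= coverage_frac of another cell
  cov <- sweep(ct, 1, t_sizes, `/`)
  for (i in seq_along(t_ids)) {
    j <- best[i]
    res$merged[i] <- sum(cov[, j] >= coverage_frac) >= 2
  }
  res
}
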