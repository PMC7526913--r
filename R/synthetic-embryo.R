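#' Specification of a synthetic membrane-labeled embryo
#'
#' Describes the geometry and signal levels of a synthetic early
#' C. elegans-like embryo: an ellipsoid (default 50 x 30 x 30 um) whose
#' interior is partitioned into `n_cells` convex-ish blastomere-like
#' regions, imaged as a membrane channel (bright cell outlines over a dim
#' cytoplasm). A subset of cells can be flagged "round": these are
#' re-carved as the largest inscribed ball around their seed, standing in
#' for mitotic or germline-precursor (P4-like) cells.
#'
#' @param n_cells number of cells (>= 1; the paper's stage of interest is
#'   24-32 cells).
#' @param semi_axes_um ellipsoid semi-axes in micrometres.
#' @param voxel_size_um voxel pitch `c(x, y, z)` in micrometres.
#' @param n_round_cells number of cells rendered near-spherical.
#' @param membrane_intensity,cytoplasm_intensity signal levels in
#'   detector counts (EMCCD-like scale); membrane must exceed cytoplasm.
#' @param membrane_thickness_vox membrane half-thickness in voxels.
#' @param margin_vox empty margin around the ellipsoid, in voxels.
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return An `embryo_spec` list.
#' @examples
#' spec <- embryo_spec(n_cells = 8, voxel_size_um = c(1, 1, 1), seed = 1)
#' @export
embryo_spec <- function(n_cells = 24,
                        semi_axes_um = c(25, 15, 15),
                        voxel_size_um = c(0.16, 0.16, 0.5),
                        n_round_cells = 0,
                        membrane_intensity = 2000,
                        cytoplasm_intensity = 400,
                        membrane_thickness_vox = 2,
                        margin_vox = 2,
                        seed = 1) {
  check_voxel_size(voxel_size_um)
  if (!is.numeric(semi_axes_um) || length(semi_axes_um) != 3 ||
      any(semi_axes_um <= 0))
    stop("semi_axes_um must be 3 strictly positive lengths")
  n_cells <- as.integer(n_cells)
  n_round_cells <- as.integer(n_round_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (n_round_cells < 0L || n_round_cells > n_cells)
    stop("n_round_cells must lie in [0, n_cells]")
  if (cytoplasm_intensity < 0 || membrane_intensity <= cytoplasm_intensity)
    stop("need 0 <= cytoplasm_intensity < membrane_intensity")
  if (membrane_thickness_vox < 1L)
    stop("membrane_thickness_vox must be a positive integer")
  structure(list(
    n_cells = n_cells,
    semi_axes_um = as.numeric(semi_axes_um),
    voxel_size_um = as.numeric(voxel_size_um),
    n_round_cells = n_round_cells,
    membrane_intensity = membrane_intensity,
    cytoplasm_intensity = cytoplasm_intensity,
    membrane_thickness_vox = as.integer(membrane_thickness_vox),
    margin_vox = as.integer(margin_vox),
    seed = as.integer(seed)
  ), class = "embryo_spec")
}

# Voxel-center coordinates (um) along each axis for a centered grid.
grid_axes_um <- function(dims, voxel_size_um) {
  lapply(1:3, function(i) {
    (seq_len(dims[i]) - (dims[i] + 1) / 2) * voxel_size_um[i]
  })
}

# Logical mask of voxel centers inside the ellipsoid.
ellipsoid_mask <- function(dims, voxel_size_um, semi_axes_um) {
  ax <- grid_axes_um(dims, voxel_size_um)
  qx <- (ax[[1]] / semi_axes_um[1])^2
  qy <- (ax[[2]] / semi_axes_um[2])^2
  qz <- (ax[[3]] / semi_axes_um[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  array(q <= 1, dims)
}

#' Generate a ground-truthed cell label volume
#'
#' Partitions the discretized embryo ellipsoid into `n_cells` regions by a
#' nearest-seed (Voronoi-style) rule. Seeds are placed by deterministic
#' best-candidate sampling (approximate Poisson-disk), giving convex-ish
#' regions that resemble blastomeres. Cells flagged round are re-carved as
#' the largest ball (in um metric) centred at their seed that fits inside
#' their region; the remainder is reassigned to adjacent cells so that the
#' positive labels still tile the ellipsoid interior exactly.
#'
#' @param spec an [embryo_spec()].
#' @return A list with `labels` (a [label_grid()]) and `truth`, a data
#'   frame with one row per cell: `label`, `centroid_x/y/z_um`,
#'   `volume_um3`, `round_flag`.
#' @examples
#' gt <- generate_label_volume(embryo_spec(n_cells = 4,
#'   semi_axes_um = c(10, 6, 6), voxel_size_um = c(1, 1, 1), seed = 2))
#' table(gt$labels > 0)
#' @export
generate_label_volume <- function(spec) {
  stopifnot(inherits(spec, "embryo_spec"))
  vs <- spec$voxel_size_um
  dims <- as.integer(ceiling(2 * spec$semi_axes_um / vs) +
                       2L * spec$margin_vox)
  inside <- ellipsoid_mask(dims, vs, spec$semi_axes_um)
  n_in <- sum(inside)
  if (n_in < spec$n_cells)
    stop("spec infeasible: ellipsoid interior has ", n_in,
         " voxels for ", spec$n_cells, " cells")
  ax <- grid_axes_um(dims, vs)
  idx_in <- which(inside)
  coords <- arrayInd(idx_in, dims)
  pts <- cbind(ax[[1]][coords[, 1]], ax[[2]][coords[, 2]],
               ax[[3]][coords[, 3]])

  labels <- array(0L, dims)
  if (spec$n_cells == 1L) {
    labels[idx_in] <- 1L
    round_flags <- rep(FALSE, 1L)
  } else {
    seeds <- withr::with_seed(spec$seed, {
      s <- sample_seeds_ellipsoid(spec$n_cells, spec$semi_axes_um)
      list(pos = s, round_ids = if (spec$n_round_cells > 0)
        sort(sample.int(spec$n_cells, spec$n_round_cells)) else integer(0))
    })
    # nearest-seed assignment in um metric
    best_d <- rep(Inf, n_in)
    assign <- integer(n_in)
    for (k in seq_len(spec$n_cells)) {
      d <- (pts[, 1] - seeds$pos[k, 1])^2 + (pts[, 2] - seeds$pos[k, 2])^2 +
        (pts[, 3] - seeds$pos[k, 3])^2
      upd <- d < best_d
      best_d[upd] <- d[upd]
      assign[upd] <- k
    }
    if (length(unique(assign)) < spec$n_cells)
      stop("spec infeasible: some cells received no voxels; ",
           "reduce n_cells or refine voxel_size_um")
    labels[idx_in] <- assign
    round_flags <- seq_len(spec$n_cells) %in% seeds$round_ids
    for (k in seeds$round_ids) {
      labels <- carve_round_cell(labels, k, seeds$pos[k, ], vs)
    }
  }

  lab_in <- labels[idx_in]
  vol_vox <- tabulate(lab_in, nbins = spec$n_cells)
  truth <- data.frame(
    label = seq_len(spec$n_cells),
    centroid_x_um = vapply(seq_len(spec$n_cells),
                           function(k) mean(pts[lab_in == k, 1]), 0),
    centroid_y_um = vapply(seq_len(spec$n_cells),
                           function(k) mean(pts[lab_in == k, 2]), 0),
    centroid_z_um = vapply(seq_len(spec$n_cells),
                           function(k) mean(pts[lab_in == k, 3]), 0),
    volume_um3 = vol_vox * prod(vs),
    round_flag = round_flags
  )
  list(labels = label_grid(labels, vs), truth = truth)
}

# Best-candidate (Mitchell) sampling of n well-separated points inside the
# ellipsoid; deterministic under the caller's seed.
sample_seeds_ellipsoid <- function(n, semi_axes, n_candidates = 30L) {
  draw <- function(m) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < m) {
      p <- matrix(stats::runif(3 * m, -1, 1), ncol = 3)
      keep <- rowSums(p^2) <= 1
      out <- rbind(out, p[keep, , drop = FALSE])
    }
    sweep(out[seq_len(m), , drop = FALSE], 2, semi_axes, `*`)
  }
  seeds <- draw(1)
  while (nrow(seeds) < n) {
    cand <- draw(n_candidates)
    dmin <- apply(cand, 1, function(p) {
      min(colSums((t(seeds) - p)^2))
    })
    seeds <- rbind(seeds, cand[which.max(dmin), ])
  }
  seeds
}

# Re-carve cell k as the largest ball (um metric) around its seed that fits
# in its region; reassign the remainder to 6-adjacent other cells.
carve_round_cell <- function(labels, k, seed_pos, vs) {
  dims <- dim(labels)
  ax <- grid_axes_um(dims, vs)
  dx2 <- (ax[[1]] - seed_pos[1])^2
  dy2 <- (ax[[2]] - seed_pos[2])^2
  dz2 <- (ax[[3]] - seed_pos[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  # ball radius: nearest voxel center (anywhere in the grid, exterior
  # included) that does not belong to cell k
  r2 <- min(d2[labels != k])
  remaining <- which(labels == k & d2 >= r2)
  if (length(remaining) == 0L) return(labels)
  tmp <- labels
  tmp[remaining] <- 0L
  # grow adjacent cells (never k, never exterior) over the shed shell
  repeat {
    if (length(remaining) == 0L) break
    cand <- matrix(0L, length(remaining), 6)
    ci <- 1L
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift3(tmp, axis, s, fill = 0L)
      cand[, ci] <- nb[remaining]
      ci <- ci + 1L
    }
    cand[cand == k] <- 0L
    pick <- apply(cand, 1, function(v) {
      v <- v[v > 0L]
      if (length(v) == 0L) return(0L)
      tb <- table(v)
      as.integer(names(tb)[which.max(tb)]) # ties: smallest label wins
    })
    sel <- pick > 0L
    if (!any(sel)) {
      warning("round-cell remainder could not be reassigned; keeping cell ",
              k, " unchanged")
      return(labels)
    }
    tmp[remaining[sel]] <- pick[sel]
    remaining <- remaining[!sel]
  }
  tmp
}

#' Render the membrane channel of a labeled embryo
#'
#' Paints a bright membrane wherever two cells meet or a cell meets the
#' exterior (any differing 6-neighbor), thickened to
#' `membrane_thickness_vox` voxels, over a dim cytoplasm; the exterior is
#' zero. This emulates a plasma-membrane marker channel (e.g. TagRFP::PH)
#' before any optical degradation.
#'
#' @param labels a [label_grid()].
#' @param spec the [embryo_spec()] providing intensities and thickness.
#' @return A [voxel_grid()] of noiseless intensities.
#' @export
render_membrane_channel <- function(labels, spec) {
  stopifnot(inherits(spec, "embryo_spec"))
  inside <- as_bare_array(labels) > 0L
  memb <- boundary_voxels6(labels)
  t <- spec$membrane_thickness_vox
  if (t > 1L) for (i in seq_len(t - 1L)) memb <- dilate6_within(memb, inside)
  img <- array(0, dim(labels))
  img[inside] <- spec$cytoplasm_intensity
  img[memb] <- spec$membrane_intensity
  voxel_grid(img, voxel_size(labels))
}
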