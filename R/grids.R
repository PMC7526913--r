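#' Voxel grids with physical voxel sizes
#'
#' A `voxel_grid` is a plain 3D numeric array (dimensions `c(nx, ny, nz)`,
#' x fastest, z the depth axis with slice 1 nearest the objective) carrying
#' a `voxel_size_um` attribute `c(x, y, z)` in micrometres. A `label_grid`
#' is the integer counterpart holding one positive label per cell and 0 for
#' the exterior. All package functions accept either the classed array or a
#' bare array plus an explicit `voxel_size_um` argument.
#'
#' @param data 3D numeric (or integer, for labels) array.
#' @param voxel_size_um positive numeric length 3, micrometres per voxel
#'   along x, y, z.
#' @return A `voxel_grid` (or `label_grid`) object.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 2)), c(0.16, 0.16, 0.5))
#' voxel_size(g)
#' @export
voxel_grid <- function(data, voxel_size_um) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  check_voxel_size(voxel_size_um)
  structure(data, voxel_size_um = as.numeric(voxel_size_um),
            class = c("voxel_grid", "array"))
}

#' @rdname voxel_grid
#' @export
label_grid <- function(data, voxel_size_um) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  check_voxel_size(voxel_size_um)
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stop("labels must be nonnegative (0 = exterior)")
  structure(data, voxel_size_um = as.numeric(voxel_size_um),
            class = c("label_grid", "array"))
}

check_voxel_size <- function(v) {
  if (!is.numeric(v) || length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
    stop("voxel_size_um must be 3 strictly positive lengths (x, y, z)")
  invisible(v)
}

#' @rdname voxel_grid
#' @param x object carrying a voxel size.
#' @export
voxel_size <- function(x) {
  v <- attr(x, "voxel_size_um")
  if (is.null(v)) stop("object has no voxel_size_um attribute")
  v
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel_size_um")
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g um/voxel\n",
              d[1], d[2], d[3], v[1], v[2], v[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.label_grid <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel_size_um")
  cat(sprintf("<label_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g um/voxel\n",
              d[1], d[2], d[3], v[1], v[2], v[3]))
  cat(sprintf("  %d labels, %d foreground voxels\n",
              length(setdiff(unique(as.vector(x)), 0L)), sum(x > 0L)))
  invisible(x)
}

# Strip classes/attributes down to a bare array (internal).
as_bare_array <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_size_um") <- NULL
  a
}

# Resolve a voxel size from the object or an explicit argument.
resolve_voxel_size <- function(x, voxel_size_um = NULL) {
  if (!is.null(voxel_size_um)) {
    check_voxel_size(voxel_size_um)
    return(as.numeric(voxel_size_um))
  }
  v <- attr(x, "voxel_size_um")
  if (is.null(v)) stop("no voxel size: supply voxel_size_um")
  v
}
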