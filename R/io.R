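#' Read and write intensity stacks as multi-page TIFF
#'
#' Stacks are written one z-slice per page as 32-bit float TIFF (values
#' divided by the recorded `intensity_scale` so they fit the [0, 1] range
#' the TIFF writer expects), with a JSON sidecar `<path>.json` holding the
#' voxel size and the intensity scale. `read_stack()` restores the
#' original values; an explicit `voxel_size_um` argument overrides the
#' sidecar with a warning when they disagree.
#'
#' @param grid a [voxel_grid()].
#' @param path TIFF file path.
#' @return `write_stack()`: the path, invisibly.
#' @export
write_stack <- function(grid, path) {
  a <- as_bare_array(grid)
  vs <- voxel_size(grid)
  scale <- max(1, max(a))
  pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = vs, intensity_scale = scale),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_stack
#' @param voxel_size_um optional override `c(x, y, z)` in um; wins over
#'   the sidecar metadata (with a warning on mismatch).
#' @return `read_stack()`: a [voxel_grid()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  meta_vs <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    meta_vs <- meta$voxel_size_um
  }
  if (!is.null(voxel_size_um)) {
    check_voxel_size(voxel_size_um)
    if (!is.null(meta_vs) &&
        any(abs(meta_vs - voxel_size_um) > 1e-9 * pmax(1, abs(meta_vs))))
      warning("voxel size flags override stored metadata (",
              paste(signif(meta_vs, 6), collapse = " x "), " -> ",
              paste(signif(voxel_size_um, 6), collapse = " x "), ")")
    vs <- as.numeric(voxel_size_um)
  } else if (!is.null(meta_vs)) {
    vs <- as.numeric(meta_vs)
  } else stop("no voxel size: none stored with the stack and no ",
              "voxel_size_um given")
  d1 <- dim(pages[[1]])
  a <- array(0, c(d1[2], d1[1], length(pages)))
  for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
  voxel_grid(a * scale, vs)
}

#' Read and write label stacks
#'
#' Labels are stored as 16-bit TIFF (integer labels divided by 65535)
#' with the voxel size in the JSON sidecar; values are recovered exactly
#' on read for up to 65535 labels.
#'
#' @param labels a [label_grid()].
#' @param path TIFF file path.
#' @export
write_label_stack <- function(labels, path) {
  a <- as_bare_array(labels)
  if (max(a) > 65535L) stop("more than 65535 labels not supported")
  pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = voxel_size(labels),
                            label_image = TRUE),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_label_stack
#' @param voxel_size_um optional override.
#' @export
read_label_stack <- function(path, voxel_size_um = NULL) {
  g <- read_stack(path, voxel_size_um)
  label_grid(array(as.integer(round(as_bare_array(g) * 65535)), dim(g)),
             voxel_size(g))
}

#' Contrast series CSV round trip
#'
#' @param series a `contrast_series`.
#' @param path CSV path (columns `concentration_pct`, `replicate`,
#'   `contrast`).
#' @export
write_contrast_series <- function(series, path) {
  series <- as_contrast_series(series)
  utils::write.csv(as.data.frame(series)[, c("concentration_pct",
                                             "replicate", "contrast")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_series
#' @export
read_contrast_series <- function(path) {
  as_contrast_series(utils::read.csv(path))
}

#' Run a reproducible end-to-end workflow
#'
#' Executes synthetic-embryo generation, optical degradation,
#' segmentation, morphometry and evaluation from a single configuration
#' (a named list, or the path to a YAML file with the same structure),
#' writing every artifact plus a JSON provenance manifest (parameters,
#' seeds, file hashes) and a log file into `out_dir`. The global `seed`
#' expands deterministically into per-stage seeds, so a rerun of the same
#' configuration reproduces identical outputs.
#'
#' Configuration blocks (all optional, defaults in parentheses):
#' `embryo` (arguments of [embryo_spec()]), `optics` (arguments of
#' [optics_params()] or `preset = "matched"/"mismatched"`), `pipeline`
#' (arguments of [pipeline_config()]), `seed` (1).
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_workflow <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config <- lapply(config, function(block) {
    if (!is.list(block)) return(block)
    lapply(block, function(x) {
      if (is.list(x) && length(x) > 0 &&
          all(vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE)))
        unlist(x) else x
    })
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = log_path,
                               append = TRUE)
  manifest <- list(package = "rimmorph",
                   version = as.character(utils::packageVersion("rimmorph")),
                   status = "running", config = config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  ok <- FALSE
  on.exit({
    manifest$status <- if (ok) "ok" else "failed"
    files <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest$files <- lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  logline("workflow start, seed ", seed)

  spec <- do.call(embryo_spec, modifyList(list(seed = seed),
                                          config$embryo %||% list()))
  gt <- generate_label_volume(spec)
  clean <- render_membrane_channel(gt$labels, spec)
  opt_cfg <- config$optics %||% list()
  optics <- if (!is.null(opt_cfg$preset)) {
    optics_preset(opt_cfg$preset, seed = seed + 1L)
  } else {
    do.call(optics_params, modifyList(list(seed = seed + 1L), opt_cfg))
  }
  stack <- apply_optical_degradation(clean, optics)
  write_stack(stack, file.path(out_dir, "stack.tif"))
  write_label_stack(gt$labels, file.path(out_dir, "truth_labels.tif"))
  utils::write.csv(gt$truth, file.path(out_dir, "truth_cells.csv"),
                   row.names = FALSE)
  logline("generated ", spec$n_cells, "-cell embryo, dims ",
          paste(dim(stack), collapse = "x"))

  cfg <- do.call(pipeline_config, config$pipeline %||% list())
  seg <- run_pipeline(stack, cfg)
  write_label_stack(seg$basins, file.path(out_dir, "basins.tif"))
  logline("segmentation: ", seg$n_cells_detected, " cells detected")

  shapes <- cell_shape_table(seg$basins)
  shapes <- shapes[shapes$label != seg$exterior_label, , drop = FALSE]
  utils::write.csv(shapes, file.path(out_dir, "shapes.csv"),
                   row.names = FALSE)

  alpha <- segmentation_quality(spec$n_cells, seg$n_cells_detected)
  matches <- match_labels(gt$labels, seg$basins)
  utils::write.csv(matches, file.path(out_dir, "matches.csv"),
                   row.names = FALSE)
  report <- list(n_cells_true = spec$n_cells,
                 n_cells_detected = seg$n_cells_detected,
                 alpha_pct = alpha,
                 mean_iou = mean(matches$iou),
                 seeds = list(global = seed, embryo = seed,
                              optics = seed + 1L),
                 parameters = list(embryo = unclass(spec),
                                   optics = unclass(optics),
                                   pipeline = unclass(cfg)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("alpha = ", round(alpha, 1), "%")
  manifest$report <- report[c("n_cells_true", "n_cells_detected",
                              "alpha_pct")]
  ok <- TRUE
  manifest$status <- "ok"
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
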