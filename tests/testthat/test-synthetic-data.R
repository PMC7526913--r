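test_that("a single-cell embryo fills exactly the discretized ellipsoid", {
  spec <- embryo_spec(n_cells = 1, semi_axes_um = c(8, 5, 5),
                      voxel_size_um = c(1, 1, 1), seed = 3)
  gt <- generate_label_volume(spec)
  d <- dim(gt$labels)
  ax <- lapply(1:3, function(i) seq_len(d[i]) - (d[i] + 1) / 2)
  q <- outer(outer((ax[[1]] / 8)^2, (ax[[2]] / 5)^2, `+`), (ax[[3]] / 5)^2, `+`)
  inside <- q <= 1
  expect_identical(as.vector(gt$labels == 1L), as.vector(inside))
  expect_equal(gt$truth$volume_um3, sum(inside))
})

test_that("cell labels partition the ellipsoid interior and are deterministic", {
  spec <- embryo_spec(n_cells = 24, semi_axes_um = c(12, 8, 8),
                      voxel_size_um = c(0.8, 0.8, 0.8), seed = 7)
  gt1 <- generate_label_volume(spec)
  gt2 <- generate_label_volume(spec)
  expect_identical(as.vector(gt1$labels), as.vector(gt2$labels))
  # voxel-count conservation against the direct ellipsoid inequality
  d <- dim(gt1$labels)
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - (d[i] + 1) / 2) * 0.8)
  q <- outer(outer((ax[[1]] / 12)^2, (ax[[2]] / 8)^2, `+`), (ax[[3]] / 8)^2, `+`)
  n_inside <- sum(q <= 1)
  counts <- tabulate(as.vector(gt1$labels), nbins = 24)
  expect_equal(sum(counts), n_inside)
  expect_true(all(counts > 0))
  expect_setequal(gt1$truth$label, 1:24)
  expect_equal(gt1$truth$volume_um3, counts * 0.8^3)
})

test_that("an infeasible spec errors instead of silently degrading", {
  spec <- embryo_spec(n_cells = 500, semi_axes_um = c(3, 2, 2),
                      voxel_size_um = c(1, 1, 1), seed = 1)
  expect_error(generate_label_volume(spec), "infeasible")
})

test_that("membrane voxels equal the brute-force 6-neighbor boundary scan", {
  spec <- embryo_spec(n_cells = 6, semi_axes_um = c(8, 5, 5),
                      voxel_size_um = c(1, 1, 1),
                      membrane_thickness_vox = 1, seed = 5)
  gt <- generate_label_volume(spec)
  img <- render_membrane_channel(gt$labels, spec)
  lab <- unclass(gt$labels)
  d <- dim(lab)
  nb <- make_nb(d, 6)
  memb <- vapply(seq_len(prod(d)), function(i) {
    lab[i] > 0L && (any(lab[nb[[i]]] != lab[i]) || length(nb[[i]]) < 6)
  }, TRUE)
  expect_identical(as.vector(img == spec$membrane_intensity), memb)
  expect_identical(as.vector(img == 0), as.vector(lab == 0L))
})

test_that("a one-cell embryo has a bright shell and no internal membrane", {
  spec <- embryo_spec(n_cells = 1, semi_axes_um = c(6, 4, 4),
                      voxel_size_um = c(1, 1, 1),
                      membrane_thickness_vox = 1, seed = 1)
  gt <- generate_label_volume(spec)
  img <- render_membrane_channel(gt$labels, spec)
  # every membrane voxel touches the exterior
  lab <- unclass(gt$labels)
  nb <- make_nb(dim(lab), 6)
  on_surface <- vapply(which(as.vector(img == spec$membrane_intensity)),
                       function(i) any(lab[nb[[i]]] == 0L) ||
                         length(nb[[i]]) < 6, TRUE)
  expect_true(all(on_surface))
})

test_that("two half-ellipsoid cells share exactly one internal membrane sheet", {
  # hand-built labels: ellipsoid split at the x midplane
  n <- 17
  ax <- seq_len(n) - (n + 1) / 2
  q <- outer(outer((ax / 7)^2, (ax / 5)^2, `+`), (ax / 5)^2, `+`)
  lab <- array(0L, c(n, n, n))
  lab[q <= 1] <- 1L
  lab[q <= 1 & slice.index(lab, 1) > (n + 1) / 2] <- 2L
  spec <- embryo_spec(n_cells = 2, semi_axes_um = c(7, 5, 5),
                      voxel_size_um = c(1, 1, 1),
                      membrane_thickness_vox = 1, seed = 1)
  img <- render_membrane_channel(label_grid(lab, c(1, 1, 1)), spec)
  interior <- img[3:(n - 2), 3:(n - 2), 3:(n - 2)]
  sheet <- img[c(8, 9), , ]
  expect_true(any(sheet == spec$membrane_intensity))
  # away from the split plane and the shell, intensity is cytoplasmic
  core <- img[c(5, 12), (n + 1) / 2, (n + 1) / 2]
  expect_true(all(core == spec$cytoplasm_intensity))
})

test_that("round-cell carving raises the carved cell's sphericity", {
  base <- embryo_spec(n_cells = 8, semi_axes_um = c(12, 8, 8),
                      voxel_size_um = c(0.5, 0.5, 0.5), seed = 11)
  round1 <- embryo_spec(n_cells = 8, semi_axes_um = c(12, 8, 8),
                        voxel_size_um = c(0.5, 0.5, 0.5),
                        n_round_cells = 1, seed = 11)
  gt0 <- generate_label_volume(base)
  gt1 <- generate_label_volume(round1)
  k <- gt1$truth$label[gt1$truth$round_flag]
  expect_length(k, 1)
  sph <- function(labels, id) {
    sphericity(region_volume(labels, id), region_surface_area(labels, id))
  }
  expect_gt(sph(gt1$labels, k), sph(gt0$labels, k))
  # partition is preserved after carving
  expect_equal(sum(gt1$labels > 0), sum(gt0$labels > 0))
})

test_that("optical degradation with all effects disabled is the identity", {
  g <- voxel_grid(array(det_values(4 * 5 * 6) * 100, c(4, 5, 6)),
                  c(1, 1, 1))
  null_optics <- optics_params(attenuation_per_um = 0, base_sigma_um = 0,
                               sigma_growth_per_um = 0, background_offset = 0,
                               read_noise_sd = 0, photon_scale = 0,
                               speckle_per_um = 0)
  expect_equal(unclass(apply_optical_degradation(g, null_optics)),
               unclass(g), ignore_attr = TRUE)
  expect_error(apply_optical_degradation(voxel_grid(array(-1, c(2, 2, 2)),
                                                    c(1, 1, 1)), null_optics),
               "nonnegative")
})

test_that("attenuation follows the closed-form exponential in depth", {
  g <- voxel_grid(array(100, c(6, 6, 10)), c(0.5, 0.5, 2))
  opt <- optics_params(attenuation_per_um = 0.03, base_sigma_um = 0,
                       sigma_growth_per_um = 0, background_offset = 0,
                       read_noise_sd = 0, photon_scale = 0, speckle_per_um = 0)
  out <- apply_optical_degradation(g, opt)
  sm <- apply(unclass(out), 3, mean)
  z_um <- (seq_len(10) - 1) * 2
  expect_equal(sm / sm[1], exp(-0.03 * z_um), tolerance = 1e-9)
})

test_that("depth-growing blur widens an impulse response with depth", {
  d <- c(41, 41, 9)
  a <- array(0, d)
  a[21, 21, 2] <- 1000   # shallow impulse (depth 5 um at z-step 5)
  a[21, 21, 6] <- 1000   # deep impulse (depth 25 um)
  g <- voxel_grid(a, c(1, 1, 5))
  opt <- optics_params(attenuation_per_um = 0, base_sigma_um = 0.5,
                       sigma_growth_per_um = 0.05, background_offset = 0,
                       read_noise_sd = 0, photon_scale = 0, speckle_per_um = 0)
  out <- unclass(apply_optical_degradation(g, opt))
  width <- function(z) {
    prof <- out[, 21, z]
    sqrt(sum(prof * (seq_len(41) - 21)^2) / sum(prof))
  }
  expect_gt(width(6), width(2))
})

test_that("degradation noise is deterministic given the seed", {
  g <- voxel_grid(array(100, c(8, 8, 4)), c(1, 1, 1))
  o1 <- apply_optical_degradation(g, optics_params(seed = 42))
  o2 <- apply_optical_degradation(g, optics_params(seed = 42))
  o3 <- apply_optical_degradation(g, optics_params(seed = 43))
  expect_identical(unclass(o1), unclass(o2))
  expect_false(identical(unclass(o1), unclass(o3)))
})

test_that("the contrast model evaluates exactly at its anchors", {
  m <- dic_model(contrast_gain = 0.5, noise_sd = 0)
  s <- simulate_contrast_series(m, n_replicates = 1, seed = 1)
  expect_equal(s$contrast[s$concentration_pct == 30], 1.0)
  expect_equal(s$contrast[s$concentration_pct == 0], 1 + 0.5 * 0.045)
  # V shape: strictly decreasing to 30, increasing after
  mu <- expected_contrast(m, c(0, 10, 20, 25, 30, 40, 50, 60))
  expect_equal(which.min(mu), 5)
  expect_true(all(diff(mu[1:5]) < 0) && all(diff(mu[5:8]) > 0))
})

test_that("contrast series draws are reproducible and seed-sensitive", {
  m <- dic_model()
  s1 <- simulate_contrast_series(m, n_replicates = 5, seed = 9)
  s2 <- simulate_contrast_series(m, n_replicates = 5, seed = 9)
  s3 <- simulate_contrast_series(m, n_replicates = 5, seed = 10)
  expect_identical(s1$contrast, s2$contrast)
  expect_false(identical(s1$contrast, s3$contrast))
})
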