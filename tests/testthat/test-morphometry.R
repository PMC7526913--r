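test_that("sphericity has its closed-form values on ideal solids", {
  r <- 3.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  a <- 2.1
  expect_equal(sphericity(a^3, 6 * a^2), pi / 6)
  expect_equal(sphericity(10, 42), 36 * pi * 100 / 74088)
  expect_equal(sphericity(10, 42), 0.1526, tolerance = 1e-3)
  expect_error(sphericity(0, 10), "positive")
  expect_error(sphericity(10, -1), "positive")
})

test_that("region volume is voxel count times voxel volume", {
  a <- array(0L, c(12, 12, 12))
  a[2:11, 2:11, 2:11] <- 1L
  lab <- label_grid(a, c(0.16, 0.16, 0.5))
  expect_equal(region_volume(lab, 1), 1000 * 0.16 * 0.16 * 0.5)
  expect_error(region_volume(lab, 9), "not present")
})

test_that("digital-ball voxel count approaches the continuum volume", {
  ball <- digital_ball(20)
  expect_equal(region_volume(ball, 1), 4 / 3 * pi * 20^3, tolerance = 0.01)
})

test_that("per-cell volumes sum to the total foreground volume", {
  spec <- embryo_spec(n_cells = 6, semi_axes_um = c(7, 5, 5),
                      voxel_size_um = c(1, 1, 1), seed = 4)
  gt <- generate_label_volume(spec)
  vols <- vapply(1:6, function(k) region_volume(gt$labels, k), 0)
  expect_equal(sum(vols), sum(gt$labels > 0) * 1)
})

test_that("mesh surface area of a digital ball is near the continuum area", {
  ball <- digital_ball(20)
  S <- region_surface_area(ball, 1)
  expect_equal(S, 4 * pi * 20^2, tolerance = 0.03)
  m <- surface_model(ball, 1)
  expect_equal(mesh_area(m), S) # same mesh, same computation
  expect_equal(mesh_volume(m), region_volume(ball, 1), tolerance = 0.02)
})

test_that("meshes are watertight with consistent outward orientation", {
  ball <- digital_ball(8)
  m <- surface_model(ball, 1)
  f <- m$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # signed divergence-theorem volume is positive for outward winding
  v <- m$vertices
  v0 <- v[f[, 1], ]; v1 <- v[f[, 2], ]; v2 <- v[f[, 3], ]
  det <- v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
    v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
    v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  expect_gt(sum(det), 0)
})

test_that("elongation at fixed volume strictly increases surface area", {
  r <- 12
  ball <- digital_ball(r)
  a <- r / 4^(1 / 3) # 1:1:4 ellipsoid of the same continuum volume
  elong <- digital_ellipsoid(c(a, a, 4 * a))
  expect_gt(region_surface_area(elong, 1), region_surface_area(ball, 1))
  # and their sphericities order accordingly: ball > cube > 1:1:4 box
  cube <- array(0L, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- 1L
  cube <- label_grid(cube, c(1, 1, 1))
  s_ball <- sphericity(region_volume(ball, 1), region_surface_area(ball, 1))
  s_cube <- sphericity(region_volume(cube, 1), region_surface_area(cube, 1))
  s_box <- sphericity(region_volume(elong, 1),
                      region_surface_area(elong, 1))
  expect_true(s_ball > s_cube && s_cube > s_box)
  expect_lte(s_ball, 1.05)
})

test_that("two disjoint balls under one label have additive area", {
  n <- 40
  ax <- seq_len(n)
  a <- array(0L, c(n, n, n))
  d2a <- outer(outer((ax - 10)^2, (ax - 20)^2, `+`), (ax - 20)^2, `+`)
  d2b <- outer(outer((ax - 30)^2, (ax - 20)^2, `+`), (ax - 20)^2, `+`)
  a[d2a <= 36] <- 1L
  a[d2b <= 36] <- 1L
  lab <- label_grid(a, c(1, 1, 1))
  only_a <- label_grid(array(as.integer(d2a <= 36), c(n, n, n)), c(1, 1, 1))
  only_b <- label_grid(array(as.integer(d2b <= 36), c(n, n, n)), c(1, 1, 1))
  # fixed smoothing width so the three measurements share one estimator
  expect_equal(region_surface_area(lab, 1, smooth_sigma_vox = 0.75),
               region_surface_area(only_a, 1, smooth_sigma_vox = 0.75) +
                 region_surface_area(only_b, 1, smooth_sigma_vox = 0.75),
               tolerance = 1e-8)
})

test_that("a single-voxel label still produces a closed positive mesh", {
  a <- array(0L, c(5, 5, 5))
  a[3, 3, 3] <- 1L
  m <- surface_model(label_grid(a, c(1, 1, 1)), 1)
  expect_gt(mesh_volume(m), 0)
  f <- m$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("ellipsoid fits recover axes of digital solids", {
  ball <- digital_ball(15)
  fb <- fit_ellipsoid(ball, 1)
  expect_equal(fb$semi_axes_um / 15, rep(1, 3), tolerance = 0.02)
  el <- digital_ellipsoid(c(20, 10, 10))
  fe <- fit_ellipsoid(el, 1)
  expect_equal(fe$semi_axes_um, c(20, 10, 10), tolerance = 0.05)
  # rigid rotation leaves the axes unchanged
  th <- pi / 5
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fr <- fit_ellipsoid(digital_ellipsoid(c(20, 10, 10), rot = rot), 1)
  expect_equal(fr$semi_axes_um, c(20, 10, 10), tolerance = 0.05)
  # degenerate flat region errors
  flat <- array(0L, c(6, 6, 3))
  flat[2:5, 2:5, 2] <- 1L
  expect_error(fit_ellipsoid(label_grid(flat, c(1, 1, 1)), 1), "degenerate")
})

test_that("STL export round-trips and stores consistent facet normals", {
  ball <- digital_ball(6)
  m <- surface_model(ball, 1)
  path <- withr::local_tempfile(fileext = ".stl")
  export_stl(m, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(m$faces))
  # vertices agree to float32 precision
  orig <- m$vertices[t(m$faces), ]
  expect_equal(back$vertices, orig, tolerance = 1e-5)
  # stored normals agree with normals recomputed from the winding
  v <- back$vertices
  f <- back$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- n / sqrt(rowSums(n^2))
  expect_equal(back$normals, n, tolerance = 1e-5)
})

test_that("a unit tetrahedron exports four facets", {
  tet <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(0, 0, 1)),
              faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  path <- withr::local_tempfile(fileext = ".stl")
  export_stl(tet, path)
  expect_equal(nrow(read_stl(path)$faces), 4)
})

test_that("the shape table covers every cell with consistent descriptors", {
  spec <- embryo_spec(n_cells = 4, semi_axes_um = c(6, 4, 4),
                      voxel_size_um = c(1, 1, 1), seed = 9)
  gt <- generate_label_volume(spec)
  tab <- cell_shape_table(gt$labels)
  expect_setequal(tab$label, 1:4)
  expect_true(all(tab$sphericity > 0 & tab$sphericity <= 1.05))
  expect_true(all(tab$a_um >= tab$b_um & tab$b_um >= tab$c_um))
  expect_equal(tab$volume_um3,
               vapply(1:4, function(k) region_volume(gt$labels, k), 0))
})
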