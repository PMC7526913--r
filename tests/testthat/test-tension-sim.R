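test_that("the 13-cell scene has the expected composition and adjacency", {
  net <- build_embryo13()
  expect_length(net$cells, 13)
  tt <- table(net$types)
  expect_equal(unname(tt[c("Others", "E.p", "P4", "D")]),
               c(10, 1, 1, 1), ignore_attr = TRUE)
  i_p4 <- which(net$types == "P4")
  i_ep <- which(net$types == "E.p")
  i_d <- which(net$types == "D")
  ed <- rimmorph:::network_edges(net)
  inner <- !is.na(ed$owner2)
  pairs <- unique(paste(pmin(ed$owner1[inner], ed$owner2[inner]),
                        pmax(ed$owner1[inner], ed$owner2[inner])))
  expect_true(paste(min(i_p4, i_ep), max(i_p4, i_ep)) %in% pairs)
  expect_true(paste(min(i_p4, i_d), max(i_p4, i_d)) %in% pairs)
  # every boundary (interface or outer arc) has at least 3 elements
  key <- ifelse(inner,
                paste0("i", pmin(ed$owner1, ed$owner2), "_",
                       pmax(ed$owner1, ed$owner2)),
                paste0("o", ed$owner1))
  expect_true(all(table(key) >= 3))
  # all cells have positive area
  areas <- vapply(seq_along(net$cells), function(i)
    rimmorph:::signed_area(net$vertices, net$cells[[i]]), 0)
  expect_true(all(areas > 0))
})

test_that("network energy matches hand-computed cases", {
  sq <- cell_network(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                     list(1:4), "A")
  p0 <- tension_params(outer_tension_by_type = c(A = 0))
  expect_equal(network_energy(sq, p0), 0)
  p1 <- tension_params(outer_tension_by_type = c(A = 0.1))
  expect_equal(network_energy(sq, p1), 0.4)
  # doubling all tensions doubles the tension term exactly
  p2 <- tension_params(outer_tension_by_type = c(A = 0.2))
  expect_equal(network_energy(sq, p2), 0.8)
})

test_that("a symmetric doublet keeps a straight interface", {
  net <- build_cell_doublet(n_side = 6)
  p <- tension_params(outer_tension_by_type = c(A = 0.1, B = 0.1),
                      n_steps = 30000)
  r <- relax(net, p)
  expect_true(r$converged)
  k <- interface_curvature(r$net, 1, 2)
  expect_lt(abs(as.numeric(k)) * attr(k, "interface_length"), 1e-3)
  # energy never increases along the trajectory
  expect_true(all(diff(r$energy) <= 1e-12))
  # mirror symmetry of the converged state: reflecting across x = 0 maps
  # the vertex set onto itself
  v <- r$net$vertices
  refl <- cbind(-v[, 1], v[, 2])
  dmin <- vapply(seq_len(nrow(v)), function(i) {
    min((refl[, 1] - v[i, 1])^2 + (refl[, 2] - v[i, 2])^2)
  }, 0)
  expect_lt(max(sqrt(dmin)), 1e-4)
})

test_that("a tensioned ring relaxes to the area-constrained circle", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- cell_network(cbind(cos(th), sin(th)), list(1:24), "A",
                       target_areas = pi)
  r <- relax(circ, tension_params(outer_tension_by_type = c(A = 0.1),
                                  n_steps = 30000))
  expect_true(r$converged)
  rr <- sqrt(rowSums(sweep(r$net$vertices, 2,
                           colMeans(r$net$vertices))^2))
  expect_equal(mean(rr), sqrt(pi / pi), tolerance = 0.01)
  expect_lt(stats::sd(rr) / mean(rr), 1e-3)
})

test_that("an asymmetric doublet satisfies the Young-Laplace balance", {
  net <- build_cell_doublet(n_side = 8)
  p <- tension_params(outer_tension_by_type = c(A = 0.2, B = 0.1),
                      n_steps = 40000)
  r <- relax(net, p)
  k <- as.numeric(interface_curvature(r$net, 1, 2))
  areas <- vapply(seq_along(r$net$cells), function(i)
    rimmorph:::signed_area(r$net$vertices, r$net$cells[[i]]), 0)
  dP <- 2 * p$area_stiffness * (r$net$target_areas[1] - areas[1]) -
    2 * p$area_stiffness * (r$net$target_areas[2] - areas[2])
  expect_equal(p$inner_tension * k, dP, tolerance = 0.05)
  # the stiffer cell bulges into its neighbor
  expect_gt(k, 0)
  # area penalty keeps areas within 2% of target
  expect_lt(max(abs(areas - r$net$target_areas) / r$net$target_areas), 0.02)
})

test_that("interface curvature fits exact circles and flips with order", {
  th <- seq(0.3, 1.2, length.out = 7)
  R <- 4
  pts <- cbind(R * cos(th), R * sin(th))
  # embed the arc as the shared boundary of two dummy cells
  n <- nrow(pts)
  mid_th <- mean(range(th))
  far_a <- 8 * c(cos(mid_th), sin(mid_th)) # fan apex outside the circle
  far_b <- c(0, 0)   # cell b is the sector toward the circle centre
  verts <- rbind(pts, far_a, far_b)
  cells <- list(c(seq_len(n), n + 1L), c(rev(seq_len(n)), n + 2L))
  net <- cell_network(verts, cells, c("A", "B"))
  k_ab <- interface_curvature(net, 1, 2)
  expect_equal(abs(as.numeric(k_ab)), 1 / R, tolerance = 1e-6)
  k_ba <- interface_curvature(net, 2, 1)
  expect_equal(as.numeric(k_ba), -as.numeric(k_ab))
  # collinear chain reports zero curvature
  col <- rbind(c(0, 0), c(0, 1), c(0, 2), c(2, 2), c(2, 0))
  net3 <- cell_network(rbind(col, c(-2, 1)),
                       list(c(1, 2, 3, 4, 5), c(3, 2, 1, 6)),
                       c("A", "B"))
  expect_equal(as.numeric(interface_curvature(net3, 1, 2)), 0)
})

test_that("cell network construction validates geometry", {
  bad <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)) # bowtie
  expect_error(cell_network(bad, list(1:4), "A"), "self-intersecting")
  expect_error(cell_network(bad, list(1:2), "A"), "fewer than 3")
  # clockwise input is re-oriented counter-clockwise
  cw <- cell_network(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)),
                     list(1:4), "A")
  expect_gt(rimmorph:::signed_area(cw$vertices, cw$cells[[1]]), 0)
})

test_that("element re-splitting preserves energy and boundary counts", {
  net <- build_cell_doublet(n_side = 4)
  p <- tension_params(outer_tension_by_type = c(A = 0.1, B = 0.1))
  e0 <- network_energy(net, p)
  stretched <- rimmorph:::resplit_long_elements(net, 0.01) # force splits
  expect_gt(nrow(stretched$vertices), nrow(net$vertices))
  expect_equal(network_energy(stretched, p), e0, tolerance = 1e-12)
})

test_that("P4-E.p interface curvature grows with P4 cortical tension", {
  net <- build_embryo13()
  p <- tension_params(dt = 0.005, n_steps = 4000, tol = 2e-6)
  i_p4 <- which(net$types == "P4")
  i_ep <- which(net$types == "E.p")
  kk <- vapply(c(0.1, 0.2), function(tp) {
    pp <- p
    pp$outer_tension_by_type <- c(Others = 0.1, E.p = 0.1, D = 0.1, P4 = tp)
    as.numeric(interface_curvature(relax(net, pp)$net, i_p4, i_ep))
  }, 0)
  expect_gt(kk[2], kk[1])
})
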