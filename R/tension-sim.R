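#' 2D cell network for boundary-tension shape simulation
#'
#' A planar aggregate of cells represented by shared vertices and polygon
#' cycles. Every polygon edge is an element carrying contractile tension:
#' elements on the aggregate surface ("outer boundary") use the cortical
#' tension of their owning cell's type; elements shared by two cells
#' ("inner boundary") use the cell-cell interface tension. Cells resist
#' area change through a soft incompressibility penalty, and shapes relax
#' by overdamped gradient descent on the total energy
#'
#'   `E = sum_e gamma(e) * length(e) + sum_c K_A * (A_c - A0_c)^2`.
#'
#' @param vertices n x 2 numeric matrix.
#' @param cells list of integer vertex cycles (counter-clockwise; the
#'   constructor re-orients clockwise input).
#' @param types character vector, one type per cell (e.g. `"E.p"`,
#'   `"P4"`, `"D"`, `"Others"`).
#' @param target_areas per-cell target areas; default: initial areas.
#' @return A `cell_network` object.
#' @export
cell_network <- function(vertices, cells, types,
                         target_areas = NULL) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, is.list(cells),
            length(types) == length(cells))
  cells <- lapply(cells, as.integer)
  for (i in seq_along(cells)) {
    cyc <- cells[[i]]
    if (length(cyc) < 3) stop("cell ", i, " has fewer than 3 vertices")
    if (anyDuplicated(cyc)) stop("cell ", i, " cycle repeats a vertex")
    if (signed_area(vertices, cyc) < 0) cells[[i]] <- rev(cyc)
    if (!is_simple_polygon(vertices[cells[[i]], , drop = FALSE]))
      stop("cell ", i, " polygon is self-intersecting")
  }
  areas <- vapply(cells, function(cyc) signed_area(vertices, cyc), 0)
  if (is.null(target_areas)) target_areas <- areas
  structure(list(vertices = vertices, cells = cells,
                 types = as.character(types),
                 target_areas = as.numeric(target_areas)),
            class = "cell_network")
}

signed_area <- function(vertices, cyc) {
  x <- vertices[cyc, 1]
  y <- vertices[cyc, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

is_simple_polygon <- function(pts) {
  m <- nrow(pts)
  nxt <- c(2:m, 1)
  for (i in seq_len(m - 2)) {
    for (j in (i + 1):m) {
      if (j == i || j == i %% m + 1 || i == j %% m + 1) next
      if (segments_intersect(pts[i, ], pts[nxt[i], ],
                             pts[j, ], pts[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# Unique undirected edges with their owning cells. Returns a list with
# integer vectors i, j (vertex ids), owner1, owner2 (cell ids; owner2 = NA
# for outer elements).
network_edges <- function(net) {
  e1 <- integer(0); e2 <- integer(0); own <- integer(0)
  for (ci in seq_along(net$cells)) {
    cyc <- net$cells[[ci]]
    nn <- length(cyc)
    a <- cyc
    b <- cyc[c(2:nn, 1)]
    e1 <- c(e1, pmin(a, b))
    e2 <- c(e2, pmax(a, b))
    own <- c(own, rep(ci, nn))
  }
  key <- paste(e1, e2)
  first <- !duplicated(key)
  idx2 <- match(key, key[first])
  owner1 <- own[first]
  owner2 <- rep(NA_integer_, sum(first))
  dup <- which(!first)
  owner2[idx2[dup]] <- own[dup]
  list(i = e1[first], j = e2[first], owner1 = owner1, owner2 = owner2)
}

# Per-edge tension from the parameter set.
edge_tensions <- function(net, edges, params) {
  gam <- numeric(length(edges$i))
  inner <- !is.na(edges$owner2)
  gam[inner] <- params$inner_tension
  out_types <- net$types[edges$owner1[!inner]]
  gam[!inner] <- outer_tension_of(params, out_types)
  gam
}

outer_tension_of <- function(params, types) {
  g <- params$outer_tension_by_type
  if (length(g) == 1 && is.null(names(g))) return(rep(g, length(types)))
  if (is.null(names(g))) stop("outer tension vector must be named by type")
  miss <- setdiff(unique(types), names(g))
  if (length(miss)) stop("no outer tension for type(s): ",
                         paste(miss, collapse = ", "))
  unname(g[types])
}

#' Parameters of the tension relaxation
#'
#' @param outer_tension_by_type cortical tension per cell type: a single
#'   number for all types, or a named vector (units: force).
#' @param inner_tension tension of cell-cell interface elements.
#' @param area_stiffness area penalty stiffness K_A.
#' @param drag viscous drag mu of the overdamped dynamics.
#' @param dt explicit time step.
#' @param n_steps maximum number of steps.
#' @param tol convergence tolerance on the maximum vertex displacement per
#'   step.
#' @param resplit re-split elements whose length exceeds twice the initial
#'   mean element length.
#' @param resplit_every steps between re-split checks.
#' @return A `tension_params` list.
#' @export
tension_params <- function(outer_tension_by_type = 0.1,
                           inner_tension = 0.1,
                           area_stiffness = 10,
                           drag = 1,
                           dt = 0.005,
                           n_steps = 20000,
                           tol = 1e-6,
                           resplit = TRUE,
                           resplit_every = 200) {
  if (area_stiffness <= 0 || drag <= 0 || dt <= 0)
    stop("area_stiffness, drag and dt must be positive")
  if (any(outer_tension_by_type < 0) || inner_tension < 0)
    stop("tensions must be nonnegative")
  structure(list(outer_tension_by_type = outer_tension_by_type,
                 inner_tension = inner_tension,
                 area_stiffness = area_stiffness,
                 drag = drag, dt = dt,
                 n_steps = as.integer(n_steps), tol = tol,
                 resplit = resplit,
                 resplit_every = as.integer(resplit_every)),
            class = "tension_params")
}

#' Total energy of a cell network
#'
#' `E = sum_e gamma(e) * length(e) + sum_c K_A * (A_c - A0_c)^2` with
#' gamma the owning cell's cortical tension for outer elements and the
#' interface tension for inner elements.
#'
#' @param net a [cell_network()].
#' @param params a [tension_params()].
#' @return scalar energy.
#' @export
network_energy <- function(net, params) {
  edges <- network_edges(net)
  gam <- edge_tensions(net, edges, params)
  v <- net$vertices
  len <- sqrt(rowSums((v[edges$i, , drop = FALSE] -
                         v[edges$j, , drop = FALSE])^2))
  areas <- vapply(net$cells, function(cyc) signed_area(v, cyc), 0)
  sum(gam * len) +
    params$area_stiffness * sum((areas - net$target_areas)^2)
}

# Energy gradient with respect to vertex positions (n x 2 matrix).
network_gradient <- function(net, edges, gam, params) {
  v <- net$vertices
  g <- matrix(0, nrow(v), 2)
  dvec <- v[edges$i, , drop = FALSE] - v[edges$j, , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  len[len == 0] <- 1
  f <- dvec / len * gam
  for (d in 1:2) {
    g[, d] <- g[, d] +
      rowsum_vec(f[, d], edges$i, nrow(v)) -
      rowsum_vec(f[, d], edges$j, nrow(v))
  }
  for (ci in seq_along(net$cells)) {
    cyc <- net$cells[[ci]]
    A <- signed_area(v, cyc)
    coef <- 2 * params$area_stiffness * (A - net$target_areas[ci])
    nn <- length(cyc)
    nxt <- cyc[c(2:nn, 1)]
    prv <- cyc[c(nn, 1:(nn - 1))]
    g[cyc, 1] <- g[cyc, 1] + coef * 0.5 * (v[nxt, 2] - v[prv, 2])
    g[cyc, 2] <- g[cyc, 2] + coef * 0.5 * (v[prv, 1] - v[nxt, 1])
  }
  g
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

#' Relax a cell network to mechanical equilibrium
#'
#' Overdamped gradient descent `x <- x - (dt / mu) * dE/dx`, stopping
#' when the maximum vertex displacement per nominal step drops below
#' `tol` or after `n_steps`. A backtracking safeguard halves the step
#' whenever it would raise the energy (stiff local modes otherwise
#' excite slow oscillations at practical `dt`), so the energy trace is
#' nonincreasing by construction; if the step collapses by more than
#' eight orders of magnitude the relaxation aborts with advice to lower
#' `dt`. Elements stretched beyond twice the initial mean element length
#' are re-split at their midpoint.
#'
#' @param net a [cell_network()].
#' @param params a [tension_params()].
#' @param check_intersections test final polygons for self-intersection.
#' @return A `sim_result` list: `net` (relaxed), `energy` (trace, one
#'   value per accepted step), `converged`, `steps`.
#' @export
relax <- function(net, params = tension_params(),
                  check_intersections = TRUE) {
  stopifnot(inherits(net, "cell_network"), inherits(params, "tension_params"))
  edges <- network_edges(net)
  gam <- edge_tensions(net, edges, params)
  v0 <- net$vertices
  mean_len0 <- mean(sqrt(rowSums((v0[edges$i, , drop = FALSE] -
                                    v0[edges$j, , drop = FALSE])^2)))
  energy <- numeric(0)
  converged <- FALSE
  step <- 0L
  rate0 <- params$dt / params$drag
  rate <- rate0
  e_prev <- network_energy(net, params)
  while (step < params$n_steps) {
    step <- step + 1L
    g <- network_gradient(net, edges, gam, params)
    repeat {
      trial <- net$vertices - rate * g
      e_new <- network_energy(
        structure(list(vertices = trial, cells = net$cells,
                       types = net$types, target_areas = net$target_areas),
                  class = "cell_network"), params)
      if (e_new <= e_prev + 1e-12 * max(1, abs(e_prev))) break
      rate <- rate / 2
      if (rate < rate0 * 1e-8)
        stop("relaxation unstable even after step-size backtracking: ",
             "decrease dt (current dt = ", params$dt, ")")
    }
    net$vertices <- trial
    energy[step] <- e_prev <- e_new
    # convergence measured as the displacement a nominal step would take
    if (max(abs(rate0 * g)) < params$tol) { converged <- TRUE; break }
    rate <- min(rate0, rate * 1.1)
    if (params$resplit && step %% params$resplit_every == 0L) {
      new_net <- resplit_long_elements(net, 2 * mean_len0)
      if (!identical(dim(new_net$vertices), dim(net$vertices))) {
        net <- new_net
        edges <- network_edges(net)
        gam <- edge_tensions(net, edges, params)
        e_prev <- network_energy(net, params)
      }
    }
  }
  if (check_intersections) {
    for (ci in seq_along(net$cells)) {
      if (!is_simple_polygon(net$vertices[net$cells[[ci]], , drop = FALSE]))
        stop("cell ", ci, " became self-intersecting during relaxation")
    }
  }
  structure(list(net = net, energy = energy, converged = converged,
                 steps = step), class = "sim_result")
}

# Insert midpoints into elements longer than `max_len` (in every cell
# sharing the element).
resplit_long_elements <- function(net, max_len) {
  edges <- network_edges(net)
  v <- net$vertices
  len <- sqrt(rowSums((v[edges$i, , drop = FALSE] -
                         v[edges$j, , drop = FALSE])^2))
  long <- which(len > max_len)
  for (e in long) {
    i <- edges$i[e]; j <- edges$j[e]
    mid <- (net$vertices[i, ] + net$vertices[j, ]) / 2
    net$vertices <- rbind(net$vertices, mid)
    k <- nrow(net$vertices)
    for (ci in seq_along(net$cells)) {
      cyc <- net$cells[[ci]]
      nn <- length(cyc)
      for (p in seq_len(nn)) {
        q <- p %% nn + 1L
        if ((cyc[p] == i && cyc[q] == j) || (cyc[p] == j && cyc[q] == i)) {
          net$cells[[ci]] <- append(cyc, k, after = p)
          break
        }
      }
    }
  }
  net
}

# Ordered shared vertex chain between two cells (along cell_a's cycle).
interface_chain <- function(net, cell_a, cell_b) {
  ca <- net$cells[[cell_a]]
  cb <- net$cells[[cell_b]]
  shared <- ca %in% cb
  if (sum(shared) < 2) stop("cells ", cell_a, " and ", cell_b,
                            " share no interface")
  nn <- length(ca)
  # rotate so the run of shared vertices is contiguous
  if (all(shared)) return(ca)
  start <- which(!shared)[1]
  rot <- c(start:nn, seq_len(start - 1L))
  ca_r <- ca[rot]
  sh_r <- shared[rot]
  runs <- rle(sh_r)
  if (sum(runs$values) != 1)
    warning("cells share more than one vertex run; using the longest")
  ends <- cumsum(runs$lengths)
  k <- which(runs$values)
  k <- k[which.max(runs$lengths[k])]
  ca_r[(ends[k] - runs$lengths[k] + 1L):ends[k]]
}

#' Signed curvature of a cell-cell interface
#'
#' Fits a circle (algebraic least squares) to the vertex chain shared by
#' the two cells and returns the signed curvature `1 / R`: positive when
#' the arc bows into `cell_b`, i.e. `cell_a` bulges into its neighbor;
#' exactly collinear chains return 0. Requires at least 3 shared nodes.
#'
#' @param net a [cell_network()].
#' @param cell_a,cell_b cell indices sharing an interface.
#' @return signed curvature (1 / length units), with attribute
#'   `interface_length`.
#' @export
interface_curvature <- function(net, cell_a, cell_b) {
  chain <- interface_chain(net, cell_a, cell_b)
  if (length(chain) < 3)
    stop("interface needs >= 3 nodes for a curvature fit")
  pts <- net$vertices[chain, , drop = FALSE]
  L <- sum(sqrt(rowSums(diff(pts)^2)))
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  bvec <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, bvec, tol = 1e-12), error = function(e) NULL)
  kappa <- 0
  if (!is.null(fit)) {
    cx <- fit[1]; cy <- fit[2]
    R2 <- fit[3] + cx^2 + cy^2
    if (is.finite(R2) && R2 > 0) {
      R <- sqrt(R2)
      kappa <- 1 / R
      # sign: does the chain bow toward cell_b?
      chord_mid <- (pts[1, ] + pts[nrow(pts), ]) / 2
      arc_mid <- pts[ceiling(nrow(pts) / 2), ]
      sag <- arc_mid - chord_mid
      if (sqrt(sum(sag^2)) < 1e-12 * max(1, L)) {
        kappa <- 0
      } else {
        ctr_b <- colMeans(net$vertices[net$cells[[cell_b]], , drop = FALSE])
        if (sum(sag * (ctr_b - chord_mid)) < 0) kappa <- -kappa
      }
    }
  }
  structure(kappa, interface_length = L)
}

#' Thirteen-cell embryo scene
#'
#' Builds the standard simulation scene: thirteen cells tiling an
#' elliptical cross-section, with a posterior triplet typed `E.p`, `P4`
#' and `D` (P4 at the posterior pole, sharing interfaces with both
#' neighbors) and ten `Others`. Cell outlines come from a clipped Voronoi
#' partition of hand-placed sites; every cell-cell interface and outer
#' arc is subdivided into at least `min_elements` elements. Target areas
#' are the initial polygon areas.
#'
#' @param semi_axes ellipse semi-axes (anterior-posterior, dorso-ventral).
#' @param n_boundary number of points discretizing the ellipse outline.
#' @param min_elements minimum elements per boundary.
#' @return A `cell_network` with 13 cells.
#' @export
build_embryo13 <- function(semi_axes = c(1.6, 1.0), n_boundary = 72,
                           min_elements = 3) {
  sites <- rbind(
    c(-1.30, 0.00), c(-0.95, 0.45), c(-0.95, -0.45),
    c(-0.45, 0.55), c(-0.45, -0.55), c(-0.40, 0.00),
    c(0.15, 0.45), c(0.15, -0.45), c(0.20, 0.00), c(0.75, 0.00),
    c(1.05, 0.42),   # E.p
    c(1.30, 0.00),   # P4
    c(1.05, -0.42))  # D
  types <- c(rep("Others", 10), "E.p", "P4", "D")
  th <- seq(0, 2 * pi, length.out = n_boundary + 1)[-(n_boundary + 1)]
  ellipse <- cbind(semi_axes[1] * cos(th), semi_axes[2] * sin(th))
  polys <- lapply(seq_len(nrow(sites)), function(i) {
    poly <- ellipse
    for (j in seq_len(nrow(sites))) {
      if (j == i) next
      a <- sites[j, ] - sites[i, ]
      cc <- sum(a * (sites[i, ] + sites[j, ]) / 2)
      poly <- clip_halfplane(poly, a, cc)
      if (nrow(poly) < 3) stop("site ", i, " produced a degenerate cell")
    }
    poly
  })
  merged <- merge_polygon_points(polys, tol = 0.03)
  net <- cell_network(merged$vertices, merged$cycles, types)
  subdivide_boundaries(net, min_elements)
}

# Sutherland-Hodgman clip of a convex polygon to the halfplane a.x <= c.
clip_halfplane <- function(poly, a, cc) {
  n <- nrow(poly)
  out <- matrix(0, 0, 2)
  for (p in seq_len(n)) {
    q <- p %% n + 1L
    vp <- poly[p, ]; vq <- poly[q, ]
    ip <- sum(a * vp) <= cc
    iq <- sum(a * vq) <= cc
    if (ip) out <- rbind(out, vp)
    if (xor(ip, iq)) {
      t <- (cc - sum(a * vp)) / sum(a * (vq - vp))
      out <- rbind(out, vp + t * (vq - vp))
    }
  }
  # drop consecutive duplicates
  if (nrow(out) > 1) {
    keep <- c(TRUE, rowSums((out[-1, , drop = FALSE] -
                               out[-nrow(out), , drop = FALSE])^2) > 1e-18)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) > 1 && sum((out[1, ] - out[nrow(out), ])^2) <= 1e-18)
      out <- out[-nrow(out), , drop = FALSE]
  }
  out
}

# Merge per-cell polygon points into a shared vertex table (tolerance
# snap), returning global cycles.
merge_polygon_points <- function(polys, tol = 1e-6) {
  verts <- matrix(0, 0, 2)
  cycles <- vector("list", length(polys))
  for (ci in seq_along(polys)) {
    poly <- polys[[ci]]
    ids <- integer(nrow(poly))
    for (p in seq_len(nrow(poly))) {
      if (nrow(verts) > 0) {
        d2 <- (verts[, 1] - poly[p, 1])^2 + (verts[, 2] - poly[p, 2])^2
        hit <- which(d2 <= tol^2)
      } else hit <- integer(0)
      if (length(hit) > 0) {
        ids[p] <- hit[1]
      } else {
        verts <- rbind(verts, poly[p, ])
        ids[p] <- nrow(verts)
      }
    }
    # collapse consecutive duplicates introduced by the snap
    keep <- ids != c(ids[-1], ids[1])
    cycles[[ci]] <- ids[keep]
  }
  list(vertices = verts, cycles = cycles)
}

# Subdivide every cell-cell interface and outer arc to >= min_elements
# elements by splitting longest segments at midpoints.
subdivide_boundaries <- function(net, min_elements) {
  repeat {
    edges <- network_edges(net)
    # group edges by boundary: inner by unordered cell pair, outer by cell
    inner <- !is.na(edges$owner2)
    key <- ifelse(inner,
                  paste0("i", pmin(edges$owner1, edges$owner2), "_",
                         pmax(edges$owner1, edges$owner2)),
                  paste0("o", edges$owner1))
    counts <- table(key)
    need <- names(counts)[counts < min_elements]
    if (length(need) == 0) break
    grp <- need[1]
    in_grp <- which(key == grp)
    v <- net$vertices
    len <- sqrt(rowSums((v[edges$i[in_grp], , drop = FALSE] -
                           v[edges$j[in_grp], , drop = FALSE])^2))
    e <- in_grp[which.max(len)]
    net <- split_one_edge(net, edges$i[e], edges$j[e])
  }
  net
}

split_one_edge <- function(net, i, j) {
  mid <- (net$vertices[i, ] + net$vertices[j, ]) / 2
  net$vertices <- rbind(net$vertices, mid)
  k <- nrow(net$vertices)
  for (ci in seq_along(net$cells)) {
    cyc <- net$cells[[ci]]
    nn <- length(cyc)
    for (p in seq_len(nn)) {
      q <- p %% nn + 1L
      if ((cyc[p] == i && cyc[q] == j) || (cyc[p] == j && cyc[q] == i)) {
        net$cells[[ci]] <- append(cyc, k, after = p)
        break
      }
    }
  }
  net
}

#' Sweep the P4 cortical tension and detect bulging
#'
#' Relaxes a fresh copy of the scene for each P4 cortical tension value
#' (all other tensions fixed) and reports the signed curvature of the
#' P4-E.p and P4-D interfaces. An interface counts as bulging when its
#' dimensionless curvature `kappa * L` (L = interface length) exceeds
#' `bulge_threshold` with P4 on the convex side; the bulge flag requires
#' both interfaces to bulge. The onset ratio is the smallest tested
#' P4-to-others tension ratio whose relaxed state is flagged.
#'
#' @param net the 13-cell scene (see [build_embryo13()]).
#' @param p4_tensions cortical tension values for P4 (the tested sweep).
#' @param params base [tension_params()]; the `"P4"` entry of the outer
#'   tension map is overridden per sweep value.
#' @param base_tension cortical tension of all non-P4 cells.
#' @param bulge_threshold dimensionless curvature threshold (arc sagitta
#'   about 7.5% of the chord at the default 0.15).
#' @return data frame (one row per tension value) with `p4_tension`,
#'   `ratio`, `kappa_p4_ep`, `kappa_p4_d`, interface lengths, `bulge`;
#'   attribute `onset_ratio` holds the smallest flagged ratio (NA if
#'   none).
#' @export
tension_sweep <- function(net, p4_tensions = c(0.1, 0.15, 0.2),
                          params = tension_params(),
                          base_tension = 0.1,
                          bulge_threshold = 0.15) {
  stopifnot(inherits(net, "cell_network"))
  i_p4 <- which(net$types == "P4")
  i_ep <- which(net$types == "E.p")
  i_d <- which(net$types == "D")
  if (length(i_p4) != 1 || length(i_ep) != 1 || length(i_d) != 1)
    stop("scene must contain exactly one each of P4, E.p and D")
  rows <- lapply(p4_tensions, function(tp) {
    p <- params
    p$outer_tension_by_type <- c(Others = base_tension, E.p = base_tension,
                                 D = base_tension, P4 = tp)
    res <- relax(net, p)
    k_ep <- interface_curvature(res$net, i_p4, i_ep)
    k_d <- interface_curvature(res$net, i_p4, i_d)
    L_ep <- attr(k_ep, "interface_length")
    L_d <- attr(k_d, "interface_length")
    data.frame(p4_tension = tp, ratio = tp / base_tension,
               kappa_p4_ep = as.numeric(k_ep), kappa_p4_d = as.numeric(k_d),
               length_p4_ep = L_ep, length_p4_d = L_d,
               bulge = as.numeric(k_ep) * L_ep > bulge_threshold &&
                 as.numeric(k_d) * L_d > bulge_threshold,
               converged = res$converged)
  })
  out <- do.call(rbind, rows)
  onset <- if (any(out$bulge)) min(out$ratio[out$bulge]) else NA_real_
  attr(out, "onset_ratio") <- onset
  out
}

#' Symmetric two-cell doublet scene
#'
#' Two congruent cells sharing a straight vertical interface, used for
#' force-balance (Young-Laplace) and symmetry checks.
#'
#' @param width,height overall doublet dimensions.
#' @param n_side nodes per outer side; the interface gets `n_side`
#'   interior nodes as well.
#' @return A `cell_network` with cells typed `"A"` and `"B"`.
#' @export
build_cell_doublet <- function(width = 2, height = 1, n_side = 8) {
  w <- width / 2; h <- height / 2
  # shared interface nodes (x = 0), bottom to top
  ys <- seq(-h, h, length.out = n_side + 2)
  iface <- cbind(0, ys)
  # outer outlines: open polylines between the interface endpoints
  left <- sample_path(rbind(c(0, h), c(-w, h), c(-w, -h), c(0, -h)),
                      n_per_side = n_side)
  right <- sample_path(rbind(c(0, -h), c(w, -h), c(w, h), c(0, h)),
                       n_per_side = n_side)
  verts <- rbind(iface, left, right)
  n_if <- nrow(iface)
  idx_l <- n_if + seq_len(nrow(left))
  idx_r <- n_if + nrow(left) + seq_len(nrow(right))
  # cell A (left): up the interface, then around the left outline
  cyc_a <- c(seq_len(n_if), idx_l)
  # cell B (right): down the interface, then around the right outline
  cyc_b <- c(rev(seq_len(n_if)), idx_r)
  cell_network(verts, list(cyc_a, cyc_b), c("A", "B"))
}

# Sample an open polyline through `corners` with n_per_side points per
# segment, excluding both path endpoints (assumed supplied elsewhere).
sample_path <- function(corners, n_per_side) {
  pts <- matrix(0, 0, 2)
  for (s in seq_len(nrow(corners) - 1)) {
    a <- corners[s, ]; b <- corners[s + 1, ]
    tt <- seq(0, 1, length.out = n_per_side + 1)[-1]
    pts <- rbind(pts, cbind(a[1] + tt * (b[1] - a[1]),
                            a[2] + tt * (b[2] - a[2])))
  }
  pts[-nrow(pts), , drop = FALSE]
}
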