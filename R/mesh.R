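#' Two-material tetrahedral meshes
#'
#' A `tet_mesh` is a linear-tetrahedral (Tet4) volume mesh with a material
#' label per element and named node sets used by the loading protocols:
#' `base` (the fixed basal surface at z = 0), `tip_patch` (the loaded /
#' fixed tip area), `measurement_zone` (the outer-surface band where peak
#' von Mises stress is read off) and `outer_surface` (all boundary nodes).
#'
#' @name tet_mesh
#' @keywords internal
NULL

new_tet_mesh <- function(nodes, tets, material, node_sets = list(),
                         provenance = "unknown") {
  storage.mode(tets) <- "integer"
  structure(list(nodes = nodes, tets = tets, material = material,
                 node_sets = node_sets, provenance = provenance),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh (", x$provenance, ")\n", sep = "")
  cat(sprintf("  %d nodes, %d Tet4 elements (%s)\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sprintf("%s: %d", names(table(x$material)),
                            as.integer(table(x$material))), collapse = ", ")))
  ext <- apply(x$nodes, 2, range)
  cat(sprintf("  extent x [%.4g, %.4g] y [%.4g, %.4g] z [%.4g, %.4g] m\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

# signed volumes of all tets (positive under the package ordering convention)
tet_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

# all 4 faces of every tet as a (4E x 3) matrix of node ids, rows sorted
tet_faces <- function(tets) {
  f <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
             tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  t(apply(f, 1, sort))
}

# boundary faces: those appearing exactly once; also checks watertightness
boundary_faces <- function(mesh, check = FALSE) {
  fs <- tet_faces(mesh$tets)
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  cnt <- table(key)
  if (check && any(cnt > 2))
    stop("mesh is not watertight: a face is shared by more than 2 tets")
  fs[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

face_areas <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  u <- nodes[faces[, 2], , drop = FALSE] - a
  v <- nodes[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Validate a tetrahedral mesh
#'
#' Checks the structural invariants every mesh produced by the package must
#' satisfy: strictly positive element volumes, watertightness (each interior
#' face shared by exactly two tets), no duplicated coincident nodes (the
#' material interface is conformal), and non-empty tagged node sets.
#'
#' @param mesh a `tet_mesh`.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0))
    stop("mesh has ", sum(v <= 0), " non-positive-volume tets (first: element ",
         which(v <= 0)[1], ")")
  fs <- tet_faces(mesh$tets)
  cnt <- table(paste(fs[, 1], fs[, 2], fs[, 3]))
  if (any(cnt > 2))
    stop("mesh is not watertight: faces shared by > 2 tets")
  key <- paste(signif(mesh$nodes[, 1], 12), signif(mesh$nodes[, 2], 12),
               signif(mesh$nodes[, 3], 12))
  if (anyDuplicated(key))
    stop("mesh has duplicated coincident nodes (non-conformal interface?)")
  if (length(mesh$material) != nrow(mesh$tets))
    stop("material vector length does not match element count")
  invisible(TRUE)
}

# split quads (rows of a 4-column id matrix, cyclic order) into 2 triangles
# along the diagonal through the smallest global node id, so that any two
# cells sharing the quad split it identically
split_quads <- function(q) {
  pos <- max.col(-q, ties.method = "first")
  odd <- pos == 1L | pos == 3L
  t1 <- ifelse(odd, q[, 1], q[, 2])
  t2 <- ifelse(odd, q[, 2], q[, 3])
  t3 <- ifelse(odd, q[, 3], q[, 4])
  s1 <- ifelse(odd, q[, 1], q[, 2])
  s2 <- ifelse(odd, q[, 3], q[, 4])
  s3 <- ifelse(odd, q[, 4], q[, 1])
  rbind(cbind(t1, t2, t3), cbind(s1, s2, s3))
}

# orient tets so all signed volumes are positive
orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  bad <- v < 0
  if (any(bad)) {
    tmp <- tets[bad, 2]
    tets[bad, 2] <- tets[bad, 3]
    tets[bad, 3] <- tmp
  }
  tets
}

#' Generate a two-material tetrahedral mesh of a parametric bill
#'
#' Builds a structured, conformal, watertight Tet4 mesh of the two-layer
#' maxilla described by `spec`. Cross-sections are discretized as a disk
#' (centre node + concentric rings); the bony core occupies the inner
#' radial layers and the rhamphotheca shell the outer ones, sharing the
#' interface ring nodes so the bond is perfect by construction. Each
#' structured cell (triangular prism at the axis, hexahedron elsewhere) is
#' star-tetrahedralized around its centroid, with quad faces split along the
#' diagonal through the smallest global node id so neighbouring cells always
#' agree on the shared triangulation.
#'
#' @param spec a [bill_spec()].
#' @param n_axial number of axial slabs (>= 4).
#' @param n_circumferential number of angular sectors (>= 8).
#' @param n_radial_core,n_radial_shell radial layers in core and shell;
#'   default scales with `n_circumferential` so that doubling both stated
#'   resolutions multiplies the element count by roughly 8.
#' @param tip_fraction,zone_center_fraction,zone_half_width_fraction
#'   passed to [tag_node_sets()].
#' @return a tagged `tet_mesh` with materials `"bone"` and `"rhamphotheca"`.
#' @examples
#' m <- make_bill_mesh(bill_spec(base_width = 0.016, base_depth = 0.020),
#'                     n_axial = 8, n_circumferential = 8)
#' m
#' @export
make_bill_mesh <- function(spec, n_axial = 24, n_circumferential = 16,
                           n_radial_core = NULL, n_radial_shell = NULL,
                           tip_fraction = 0.05, zone_center_fraction = 2 / 3,
                           zone_half_width_fraction = 0.025) {
  validate_bill_spec(spec)
  if (n_axial < 4) stop("n_axial must be >= 4")
  if (n_circumferential < 8) stop("n_circumferential must be >= 8")
  nc <- as.integer(n_circumferential)
  nrc <- if (is.null(n_radial_core)) max(2L, nc %/% 8L) else as.integer(n_radial_core)
  nrs <- if (is.null(n_radial_shell)) max(1L, nc %/% 16L) else as.integer(n_radial_shell)
  na <- as.integer(n_axial)
  L <- spec$length

  th <- 2 * pi * (0:(nc - 1)) / nc
  cs <- superellipse_cs(th, spec$section_exponent)
  # axial stations honour the protocol breakpoints (measurement-zone centre
  # and tip-patch edge) at every resolution, so the constrained and
  # measured regions have resolution-independent geometry
  t <- axial_stations(na, breaks = c(zone_center_fraction, 1 - tip_fraction))
  ax <- section_half_axes(spec, t)
  # boundary tables: (na+1) x nc inner (core) and outer (shell) sections
  ix <- outer(ax$Ain, cs$cx)
  iy <- outer(ax$Bin, cs$cy)
  ox <- outer(ax$A, cs$cx)
  oy <- outer(ax$B, cs$cy)

  mesh <- build_two_layer_tube(ix, iy, ox, oy, zs = L * t,
                               nrc = nrc, nrs = nrs,
                               provenance = sprintf(
                                 "parametric bill '%s' (n_axial=%d, n_circ=%d, n_r=%d+%d)",
                                 spec$species_label, na, nc, nrc, nrs))
  tag_node_sets(mesh, tip_fraction = tip_fraction,
                zone_center_fraction = zone_center_fraction,
                zone_half_width_fraction = zone_half_width_fraction)
}

# relative axial stations: `n` cells distributed over the segments between
# fixed breakpoints, proportionally to segment length (>= 1 cell each)
axial_stations <- function(n, breaks = numeric(0)) {
  bp <- sort(unique(c(0, breaks[breaks > 0 & breaks < 1], 1)))
  seg <- diff(bp)
  cells <- pmax(1L, round(n * seg))
  # distribute any rounding surplus/deficit over the largest segments
  while (sum(cells) != n) {
    i <- if (sum(cells) > n) which.max(cells - n * seg) else which.min(cells - n * seg)
    cells[i] <- cells[i] + sign(n - sum(cells))
    if (any(cells < 1L)) { cells[cells < 1L] <- 1L; break }
  }
  out <- unlist(lapply(seq_along(seg), function(i)
    seq(bp[i], bp[i + 1], length.out = cells[i] + 1L)[-1]))
  c(0, out)
}

# Structured two-layer tube mesher shared by the parametric generator and
# the lofted surface-pair backend. `ix, iy` and `ox, oy` are
# (n_axial+1) x n_circ matrices of the inner (core boundary) and outer
# (shell boundary) section curves at each axial station `zs`. The core is
# discretized as `nrc` radial layers shrunk from the inner curve towards
# the section centroid, the shell as `nrs` layers interpolating inner to
# outer; cells are star-tetrahedralized around their centroids.
build_two_layer_tube <- function(ix, iy, ox, oy, zs, nrc, nrs,
                                 provenance = "two-layer tube") {
  na <- nrow(ix) - 1L
  nc <- ncol(ix)
  nr <- nrc + nrs

  per_station <- 1L + nr * nc
  n_grid <- (na + 1L) * per_station
  nodes <- matrix(0, n_grid, 3)
  cx0 <- rowMeans(ix)
  cy0 <- rowMeans(iy)
  for (i in 0:na) {
    base_id <- i * per_station
    nodes[base_id + 1L, ] <- c(cx0[i + 1L], cy0[i + 1L], zs[i + 1L])
    row <- base_id + 1L
    for (j in 1:nr) {
      if (j <= nrc) {
        s <- j / nrc
        xs <- cx0[i + 1L] + s * (ix[i + 1L, ] - cx0[i + 1L])
        ys <- cy0[i + 1L] + s * (iy[i + 1L, ] - cy0[i + 1L])
      } else {
        f <- (j - nrc) / nrs
        xs <- ix[i + 1L, ] + f * (ox[i + 1L, ] - ix[i + 1L, ])
        ys <- iy[i + 1L, ] + f * (oy[i + 1L, ] - iy[i + 1L, ])
      }
      idx <- row + (j - 1L) * nc + (1:nc)
      nodes[idx, 1] <- xs
      nodes[idx, 2] <- ys
      nodes[idx, 3] <- zs[i + 1L]
    }
  }
  centre_id <- function(i) i * per_station + 1L
  ring_id <- function(i, j, k) i * per_station + 1L + (j - 1L) * nc + (k %% nc) + 1L

  # cell vertex tables (vectorized over slab i = 1..na, sector k = 0..nc-1)
  i_sl <- rep(1:na, each = nc)
  k_sc <- rep(0:(nc - 1), times = na)

  # triangular prisms at the axis (ring 1)
  pr <- cbind(cb = centre_id(i_sl - 1L),
              ab = ring_id(i_sl - 1L, 1L, k_sc),
              bb = ring_id(i_sl - 1L, 1L, k_sc + 1L),
              ct = centre_id(i_sl),
              at = ring_id(i_sl, 1L, k_sc),
              bt = ring_id(i_sl, 1L, k_sc + 1L))
  cells_v <- list(pr)
  cells_kind <- list(rep("prism", nrow(pr)))
  cells_mat <- list(rep(if (nrc >= 1L) "bone" else "rhamphotheca", nrow(pr)))

  for (j in 1:(nr - 1L)) {
    hx <- cbind(pb = ring_id(i_sl - 1L, j, k_sc),
                qb = ring_id(i_sl - 1L, j + 1L, k_sc),
                rb = ring_id(i_sl - 1L, j + 1L, k_sc + 1L),
                sb = ring_id(i_sl - 1L, j, k_sc + 1L),
                pt = ring_id(i_sl, j, k_sc),
                qt = ring_id(i_sl, j + 1L, k_sc),
                rt = ring_id(i_sl, j + 1L, k_sc + 1L),
                st = ring_id(i_sl, j, k_sc + 1L))
    cells_v[[j + 1L]] <- hx
    cells_kind[[j + 1L]] <- rep("hex", nrow(hx))
    cells_mat[[j + 1L]] <- rep(if (j + 1L <= nrc) "bone" else "rhamphotheca",
                               nrow(hx))
  }

  # centroid node per cell, then star-tetrahedralize each cell
  all_tets <- list()
  all_mat <- list()
  cent_coords <- list()
  next_cent <- n_grid
  for (ci in seq_along(cells_v)) {
    vv <- cells_v[[ci]]
    ncell <- nrow(vv)
    cent_ids <- next_cent + seq_len(ncell)
    next_cent <- next_cent + ncell
    cc <- matrix(0, ncell, 3)
    for (d in 1:3) {
      xm <- matrix(nodes[vv, d], ncell, ncol(vv))
      cc[, d] <- rowMeans(xm)
    }
    cent_coords[[ci]] <- cc
    if (cells_kind[[ci]][1] == "prism") {
      tris <- rbind(vv[, c("cb", "ab", "bb")],
                    vv[, c("ct", "at", "bt")],
                    split_quads(vv[, c("cb", "ab", "at", "ct")]),
                    split_quads(vv[, c("ab", "bb", "bt", "at")]),
                    split_quads(vv[, c("bb", "cb", "ct", "bt")]))
      cent_rep <- rep(cent_ids, 8)
    } else {
      tris <- rbind(split_quads(vv[, c("pb", "qb", "rb", "sb")]),
                    split_quads(vv[, c("pt", "st", "rt", "qt")]),
                    split_quads(vv[, c("pb", "qb", "qt", "pt")]),
                    split_quads(vv[, c("qb", "rb", "rt", "qt")]),
                    split_quads(vv[, c("rb", "sb", "st", "rt")]),
                    split_quads(vv[, c("sb", "pb", "pt", "st")]))
      cent_rep <- rep(cent_ids, 12)
    }
    nrep <- length(cent_rep) / ncell
    all_tets[[ci]] <- cbind(tris, cent_rep)
    all_mat[[ci]] <- rep(cells_mat[[ci]], nrep)
  }
  nodes <- rbind(nodes, do.call(rbind, cent_coords))
  tets <- do.call(rbind, all_tets)
  colnames(tets) <- NULL
  tets <- orient_tets(nodes, tets)
  material <- unlist(all_mat)

  new_tet_mesh(nodes, tets, material, provenance = provenance)
}

#' Tag the node sets used by the loading protocols
#'
#' Recomputes the named node sets on a mesh whose +z axis runs base-to-tip:
#' `base` is all nodes at z = 0 (geometric tolerance), `outer_surface` all
#' boundary nodes, `tip_patch` the boundary nodes within `tip_fraction` of
#' the axial extent from the tip, and `measurement_zone` the boundary nodes
#' in a band of half-width `zone_half_width_fraction * L` centred at
#' `zone_center_fraction * L` — by default two-thirds of the tomial length
#' from the base, away from both loaded regions.
#'
#' @param mesh a `tet_mesh`, axis-aligned with +z from base to tip.
#' @param tip_fraction axial fraction defining the tip patch (default 0.05).
#' @param zone_center_fraction centre of the measurement band as a fraction
#'   of the axial extent (default 2/3).
#' @param zone_half_width_fraction half-width of the band (default 0.025).
#' @return the mesh with `node_sets` replaced.
#' @export
tag_node_sets <- function(mesh, tip_fraction = 0.05,
                          zone_center_fraction = 2 / 3,
                          zone_half_width_fraction = 0.025) {
  z <- mesh$nodes[, 3]
  z0 <- min(z)
  L <- max(z) - z0
  if (L <= 0) stop("mesh has zero axial extent")
  eps <- 1e-6 * L
  bnd <- sort(unique(as.vector(boundary_faces(mesh))))
  zb <- z[bnd]
  base <- which(z <= z0 + eps)
  tip <- bnd[zb >= z0 + (1 - tip_fraction) * L - eps]
  zc <- z0 + zone_center_fraction * L
  zone <- bnd[abs(zb - zc) <= zone_half_width_fraction * L + eps]
  if (length(base) == 0L) stop("empty 'base' node set")
  if (length(tip) == 0L)
    stop("empty 'tip_patch' node set; refine the mesh or widen tip_fraction")
  if (length(zone) == 0L)
    stop("empty 'measurement_zone' node set; refine the mesh or widen ",
         "zone_half_width_fraction")
  mesh$node_sets <- list(base = base, tip_patch = tip,
                         measurement_zone = zone, outer_surface = bnd)
  mesh
}

#' Uniformly scale a mesh to a target length or surface area
#'
#' All species are compared at a common scale: either a fixed axial extent
#' (the standard protocol, 5 cm) or, as a sensitivity option, a fixed
#' outer-surface area. Scaling is a similarity transform about the base
#' centre; node sets are preserved.
#'
#' @param mesh a `tet_mesh`.
#' @param mode `"length"` (match axial extent) or `"surface_area"` (match
#'   total boundary area).
#' @param target target extent in m, or area in m^2.
#' @return the scaled mesh.
#' @export
scale_mesh <- function(mesh, mode = c("length", "surface_area"), target) {
  mode <- match.arg(mode)
  if (target <= 0) stop("target must be > 0")
  z <- mesh$nodes[, 3]
  L <- max(z) - min(z)
  if (L <= 0) stop("mesh has zero axial extent")
  s <- if (mode == "length") {
    target / L
  } else {
    area <- sum(face_areas(mesh$nodes, boundary_faces(mesh)))
    sqrt(target / area)
  }
  mesh$nodes <- mesh$nodes * s
  mesh$provenance <- sprintf("%s; scaled by %.6g (%s)", mesh$provenance, s, mode)
  mesh
}

#' Measure base width and depth of a scaled mesh
#'
#' Emulates the manual measure-tool protocol: the width (x extent) and depth
#' (y extent) of the outer-surface nodes within a basal slice, by default
#' the first 2% of the axial extent.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param basal_slice_fraction slice depth as a fraction of axial extent.
#' @return named numeric vector `c(width =, depth =)` in m.
#' @export
measure_base_dimensions <- function(mesh, basal_slice_fraction = 0.02) {
  z <- mesh$nodes[, 3]
  z0 <- min(z)
  L <- max(z) - z0
  bnd <- mesh$node_sets$outer_surface
  if (is.null(bnd)) bnd <- sort(unique(as.vector(boundary_faces(mesh))))
  sl <- bnd[z[bnd] <= z0 + basal_slice_fraction * L + 1e-9 * L]
  if (length(sl) == 0L) stop("no outer-surface nodes in the basal slice")
  c(width = max(mesh$nodes[sl, 1]) - min(mesh$nodes[sl, 1]),
    depth = max(mesh$nodes[sl, 2]) - min(mesh$nodes[sl, 2]))
}

#' Structured rectangular prism mesh (test geometry)
#'
#' Freudenthal (6-tet) subdivision of a structured hexahedral grid over a
#' `wx` x `wy` x `L` prism centred on the z axis. Used by the analytic
#' verification problems (uniaxial compression, cantilever bending, patch
#' test). With `core_fraction > 0` the cells whose centres fall inside the
#' central `core_fraction` of both cross-section half-widths are labelled
#' `"bone"`, giving a two-material composite prism.
#'
#' @param wx,wy,L prism dimensions in m.
#' @param nx,ny,nz cell counts per direction.
#' @param core_fraction central material fraction in [0, 1); 0 = homogeneous.
#' @param tip_fraction passed to [tag_node_sets()]; 0 tags only the z = L face.
#' @param zone_half_width_fraction measurement band half-width; the default
#'   widens with coarse axial resolution so the band always contains a node
#'   plane.
#' @return a tagged `tet_mesh`.
#' @export
make_prism_mesh <- function(wx, wy, L, nx = 4, ny = 4, nz = 10,
                            core_fraction = 0, tip_fraction = 0,
                            zone_half_width_fraction = max(0.025, 0.6 / nz)) {
  stopifnot(wx > 0, wy > 0, L > 0, nx >= 1, ny >= 1, nz >= 1)
  xs <- seq(-wx / 2, wx / 2, length.out = nx + 1)
  ys <- seq(-wy / 2, wy / 2, length.out = ny + 1)
  zs <- seq(0, L, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  idx <- function(ix, iy, iz) ix + (nx + 1L) * (iy + (ny + 1L) * iz) + 1L

  cell <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1), iz = 0:(nz - 1))
  v <- function(dx, dy, dz) idx(cell$ix + dx, cell$iy + dy, cell$iz + dz)
  v000 <- v(0, 0, 0); v100 <- v(1, 0, 0); v010 <- v(0, 1, 0); v001 <- v(0, 0, 1)
  v110 <- v(1, 1, 0); v101 <- v(1, 0, 1); v011 <- v(0, 1, 1); v111 <- v(1, 1, 1)
  # Kuhn subdivision: 6 tets per cube along the v000-v111 diagonal
  tets <- rbind(cbind(v000, v100, v110, v111),
                cbind(v000, v110, v010, v111),
                cbind(v000, v010, v011, v111),
                cbind(v000, v011, v001, v111),
                cbind(v000, v001, v101, v111),
                cbind(v000, v101, v100, v111))
  tets <- orient_tets(nodes, tets)

  xc <- (xs[cell$ix + 1] + xs[cell$ix + 2]) / 2
  yc <- (ys[cell$iy + 1] + ys[cell$iy + 2]) / 2
  core <- abs(xc) < core_fraction * wx / 2 & abs(yc) < core_fraction * wy / 2
  material <- rep(ifelse(core, "bone", "rhamphotheca"), 6)

  mesh <- new_tet_mesh(nodes, tets, material,
                       provenance = sprintf("prism %gx%gx%g (%dx%dx%d)",
                                            wx, wy, L, nx, ny, nz))
  tag_node_sets(mesh, tip_fraction = tip_fraction,
                zone_half_width_fraction = zone_half_width_fraction)
}
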