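#' Mesh file I/O
#'
#' ASCII PLY surface meshes (the exchange format for segmented bill
#' surfaces) and legacy ASCII VTK unstructured grids (volume meshes and
#' stress heat-map exports, readable by ParaView).
#'
#' @name mesh_io
#' @keywords internal
NULL

#' Write a triangulated surface to an ASCII PLY file
#'
#' @param vertices numeric matrix (n x 3).
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_ply <- function(vertices, faces, path) {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment billmech surface export",
               paste("element vertex", nrow(vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(format(vertices[, 1], digits = 10, scientific = TRUE, trim = TRUE),
                   format(vertices[, 2], digits = 10, scientific = TRUE, trim = TRUE),
                   format(vertices[, 3], digits = 10, scientific = TRUE, trim = TRUE)),
             con)
  writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' Minimal reader for triangulated ASCII PLY files as written by
#' [write_ply()] and common mesh tools. Binary PLY is rejected with an
#' informative error.
#'
#' @param path PLY file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  fmt <- grep("^format", hdr, value = TRUE)
  if (!grepl("ascii", fmt)) stop("only ASCII PLY is supported (got: ", fmt, ")")
  nv <- as.integer(sub(".*element vertex +", "", grep("element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub(".*element face +", "", grep("element face", hdr, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1 || is.na(nv) || is.na(nf))
    stop("malformed PLY header")
  body <- lines[(hdr_end + 1L):length(lines)]
  vtx <- utils::read.table(text = body[seq_len(nv)])[, 1:3]
  fc <- utils::read.table(text = body[nv + seq_len(nf)])
  if (any(fc[, 1] != 3)) stop("only triangulated PLY surfaces are supported")
  list(vertices = as.matrix(vtx), faces = as.matrix(fc[, 2:4]) + 1L)
}

# outward boundary triangles of a material region (or the whole mesh)
surface_triangles <- function(mesh, region = NULL) {
  tets <- if (is.null(region)) mesh$tets
          else mesh$tets[mesh$material == region, , drop = FALSE]
  sub <- new_tet_mesh(mesh$nodes, tets, rep("x", nrow(tets)))
  boundary_faces(sub)
}

#' Export the two bill surfaces as PLY files
#'
#' Writes the outer surface of the whole mesh (the rhamphotheca) and the
#' boundary of the bony-core region as two separate ASCII PLY files, the
#' same exchange layout used for segmented scan data.
#'
#' @param mesh a two-material `tet_mesh`.
#' @param rham_path,bone_path output files.
#' @return invisibly a list of the two paths.
#' @export
write_bill_surfaces <- function(mesh, rham_path, bone_path) {
  compact <- function(faces) {
    ids <- sort(unique(as.vector(faces)))
    remap <- integer(nrow(mesh$nodes))
    remap[ids] <- seq_along(ids)
    list(vertices = mesh$nodes[ids, , drop = FALSE],
         faces = matrix(remap[faces], ncol = 3))
  }
  s1 <- compact(surface_triangles(mesh))
  s2 <- compact(surface_triangles(mesh, "bone"))
  write_ply(s1$vertices, s1$faces, rham_path)
  write_ply(s2$vertices, s2$faces, bone_path)
  invisible(list(rhamphotheca = rham_path, bone = bone_path))
}

# check that every edge of a triangulated surface borders exactly 2 faces
check_manifold <- function(faces, what = "surface") {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2))
    stop(what, " is not a closed manifold: ", sum(cnt != 2),
         " edges are not shared by exactly 2 faces")
  invisible(TRUE)
}

# radius table r(theta_bin, z_bin) of a star-shaped surface around the z
# axis: per-bin maximum vertex radius, gaps filled by angular interpolation
radial_profile <- function(vertices, zs, n_theta, cx = 0, cy = 0) {
  th <- atan2(vertices[, 2] - cy, vertices[, 1] - cx) %% (2 * pi)
  r <- sqrt((vertices[, 1] - cx)^2 + (vertices[, 2] - cy)^2)
  tb <- pmin(floor(th / (2 * pi) * n_theta) + 1L, n_theta)
  zb <- vapply(vertices[, 3], function(z) which.min(abs(zs - z)), integer(1))
  prof <- matrix(NA_real_, length(zs), n_theta)
  for (i in seq_along(r)) {
    cur <- prof[zb[i], tb[i]]
    if (is.na(cur) || r[i] > cur) prof[zb[i], tb[i]] <- r[i]
  }
  for (i in seq_len(nrow(prof))) {        # fill angular gaps (wrap-around)
    row <- prof[i, ]
    if (all(is.na(row))) stop("no surface vertices near axial station ", i)
    if (anyNA(row)) {
      ok <- which(!is.na(row))
      ang <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
      prof[i, ] <- stats::approx(x = c(ang[ok] - 2 * pi, ang[ok], ang[ok] + 2 * pi),
                                 y = rep(row[ok], 3), xout = ang)$y
    }
  }
  prof
}

#' Volume-mesh a rhamphotheca/bone surface pair
#'
#' Ingest route for externally supplied geometry: reads two closed
#' triangulated PLY surfaces (outer rhamphotheca shell, inner bony core)
#' and produces a conformal two-material Tet4 mesh. Tetrahedralization is
#' delegated to a pluggable backend; the built-in `"loft"` backend assumes
#' both surfaces are star-shaped around the z axis (true of near-straight
#' bills), samples their radius profiles on a structured (angle, station)
#' grid, and rebuilds the volume with the same structured mesher used for
#' parametric bills.
#'
#' @param rham_path,bone_path ASCII PLY files of the outer and inner
#'   closed surfaces.
#' @param n_axial,n_circumferential resampling resolution.
#' @param backend `"loft"` or a function
#'   `(rham, bone, n_axial, n_circumferential) -> tet_mesh`.
#' @param ... further arguments passed to [tag_node_sets()].
#' @return a tagged two-material `tet_mesh`.
#' @export
load_surface_pair <- function(rham_path, bone_path, n_axial = 24,
                              n_circumferential = 16, backend = "loft", ...) {
  rham <- read_ply(rham_path)
  bone <- read_ply(bone_path)
  check_manifold(rham$faces, "rhamphotheca surface")
  check_manifold(bone$faces, "bone surface")

  rz <- range(rham$vertices[, 3])
  bz <- range(bone$vertices[, 3])
  tol <- 1e-6 * diff(rz)
  if (bz[1] < rz[1] - tol || bz[2] > rz[2] + tol)
    stop("bone surface is not enclosed by the rhamphotheca surface ",
         "(axial extent exceeds the shell)")

  if (is.function(backend))
    return(backend(rham, bone, n_axial, n_circumferential))
  if (!identical(backend, "loft")) stop("unknown backend: ", backend)

  na <- as.integer(n_axial)
  nc <- as.integer(n_circumferential)
  zs <- seq(rz[1], rz[2], length.out = na + 1L)
  r_out <- radial_profile(rham$vertices, zs, nc)
  r_in <- radial_profile(bone$vertices, zs, nc)
  # clamp stations beyond the bone extent: the core pinches to a sliver
  outside <- zs < bz[1] - tol | zs > bz[2] + tol
  r_in[outside, ] <- NA
  for (i in which(outside)) {
    j <- which.min(abs(zs[!outside] - zs[i]))
    r_in[i, ] <- r_in[which(!outside)[j], ] *
      min(1, max(0.05, 1 - abs(zs[i] - zs[which(!outside)[j]]) / diff(rz)))
  }
  if (any(r_in > r_out + 1e-9 * max(r_out)))
    stop("bone surface is not enclosed by the rhamphotheca surface ",
         "(core radius exceeds shell radius)")
  r_in <- pmin(r_in, 0.98 * r_out)

  th <- 2 * pi * (0:(nc - 1)) / nc
  ix <- r_in * matrix(cos(th), na + 1L, nc, byrow = TRUE)
  iy <- r_in * matrix(sin(th), na + 1L, nc, byrow = TRUE)
  ox <- r_out * matrix(cos(th), na + 1L, nc, byrow = TRUE)
  oy <- r_out * matrix(sin(th), na + 1L, nc, byrow = TRUE)
  nrc <- max(2L, nc %/% 8L)
  nrs <- max(1L, nc %/% 16L)
  mesh <- build_two_layer_tube(ix, iy, ox, oy, zs, nrc, nrs,
                               provenance = sprintf(
                                 "lofted from %s + %s", basename(rham_path),
                                 basename(bone_path)))
  tag_node_sets(mesh, ...)
}

#' Write a mesh (with optional fields) as a legacy ASCII VTK file
#'
#' Unstructured-grid export with the material id as cell data and any
#' nodal scalar fields (e.g. von Mises stress) as point data; the format
#' ParaView and other visualization tools read directly.
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.vtk` file.
#' @param point_data named list of per-node numeric vectors.
#' @param title dataset title line.
#' @return invisibly `path`.
#' @export
write_vtk <- function(mesh, path, point_data = list(), title = "billmech mesh") {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nn, "double")), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(paste("CELLS", ne, 5L * ne), con)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(10L, ne)), con)
  writeLines(c(paste("CELL_DATA", ne), "SCALARS material_id int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$material,
                                            levels = c("bone", "rhamphotheca")))),
             con)
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", nn), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == nn)
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(as.character(v), con)
    }
  }
  invisible(path)
}
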