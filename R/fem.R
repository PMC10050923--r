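#' Small-strain linear-elastic Tet4 finite-element solver
#'
#' The solver assembles the standard constant-strain-tetrahedron stiffness
#' matrix for an isotropic two-material mesh and solves the constrained
#' static problem by sparse Cholesky factorization. Element stresses are
#' constant per tet; nodal von Mises values are volume-weighted averages of
#' the adjacent element values.
#'
#' @name elastic_fem
#' @keywords internal
NULL

# shape-function gradients and volumes for all tets.
# For vertices p1..p4 and D = [p2-p1 | p3-p1 | p4-p1] (columns), the natural
# coordinate gradients are the rows of D^{-1}; grad N1 = -(sum of others).
tet_shape_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  cross3 <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross3(e2, e3)
  det <- rowSums(e1 * c23)
  if (any(det <= 0)) stop("inverted element: tet ", which(det <= 0)[1],
                          " has non-positive volume")
  g2 <- c23 / det
  g3 <- cross3(e3, e1) / det
  g4 <- cross3(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

# per-element Lame parameters from a material assignment
element_lame <- function(mesh, assignment) {
  E <- numeric(nrow(mesh$tets))
  nu <- numeric(nrow(mesh$tets))
  for (id in unique(mesh$material)) {
    m <- assignment$materials[[id]]
    if (is.null(m)) stop("no material assigned to mesh region '", id, "'")
    E[mesh$material == id] <- m$E
    nu[mesh$material == id] <- m$nu
  }
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)),
       E = E, nu = nu)
}

#' Assemble the global stiffness matrix
#'
#' Standard isotropic Tet4 assembly: for shape gradients g_a the 3x3 nodal
#' block is `K_ab = V (lambda g_a g_b' + mu g_b g_a' + mu (g_a . g_b) I)`.
#' The operator is symmetric positive-semidefinite with exactly six
#' rigid-body zero-energy modes before constraints are applied.
#'
#' @param mesh a `tet_mesh`.
#' @param assignment a [material_assignment()].
#' @return a sparse symmetric `dgCMatrix` of dimension `3 n_nodes`.
#' @export
assemble_system <- function(mesh, assignment) {
  sg <- tet_shape_gradients(mesh$nodes, mesh$tets)
  lam <- element_lame(mesh, assignment)
  ne <- nrow(mesh$tets)
  vol <- sg$vol
  nn <- nrow(mesh$nodes)

  ii <- vector("list", 144)
  jj <- vector("list", 144)
  xx <- vector("list", 144)
  slot <- 1L
  for (a in 1:4) {
    ga <- sg$g[[a]]
    dof_a <- 3L * (mesh$tets[, a] - 1L)
    for (b in 1:4) {
      gb <- sg$g[[b]]
      dof_b <- 3L * (mesh$tets[, b] - 1L)
      dot_ab <- rowSums(ga * gb)
      for (i in 1:3) {
        for (j in 1:3) {
          val <- vol * (lam$lambda * ga[, i] * gb[, j] +
                        lam$mu * gb[, i] * ga[, j] +
                        if (i == j) lam$mu * dot_ab else 0)
          ii[[slot]] <- dof_a + i
          jj[[slot]] <- dof_b + j
          xx[[slot]] <- val
          slot <- slot + 1L
        }
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(3L * nn, 3L * nn))
}

# Solve K u = f with Dirichlet constraints; returns full displacement vector.
solve_constrained <- function(K, f, fixed_dofs, fixed_vals, tol = 1e-8) {
  n <- nrow(K)
  if (length(fixed_dofs) == 0L) stop("singular system: no constraints supplied")
  free <- setdiff(seq_len(n), fixed_dofs)
  rhs <- f[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*% fixed_vals)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u_free <- tryCatch(as.vector(Matrix::solve(Kff, rhs)),
                     error = function(e) stop("linear solve failed: ",
                                              conditionMessage(e)))
  res <- sqrt(sum((as.vector(Kff %*% u_free) - rhs)^2))
  den <- sqrt(sum(rhs^2))
  if (den > 0 && res / den > tol)
    stop(sprintf("solver did not converge: relative residual %.3g > %.3g",
                 res / den, tol))
  u <- numeric(n)
  u[free] <- u_free
  u[fixed_dofs] <- fixed_vals
  u
}

# constant element stress tensors (Voigt order xx, yy, zz, xy, yz, zx) from
# a displacement vector
element_stresses <- function(mesh, assignment, u) {
  sg <- tet_shape_gradients(mesh$nodes, mesh$tets)
  lam <- element_lame(mesh, assignment)
  ne <- nrow(mesh$tets)
  exx <- eyy <- ezz <- gxy <- gyz <- gzx <- numeric(ne)
  for (a in 1:4) {
    g <- sg$g[[a]]
    base <- 3L * (mesh$tets[, a] - 1L)
    ux <- u[base + 1L]; uy <- u[base + 2L]; uz <- u[base + 3L]
    exx <- exx + g[, 1] * ux
    eyy <- eyy + g[, 2] * uy
    ezz <- ezz + g[, 3] * uz
    gxy <- gxy + g[, 2] * ux + g[, 1] * uy
    gyz <- gyz + g[, 3] * uy + g[, 2] * uz
    gzx <- gzx + g[, 1] * uz + g[, 3] * ux
  }
  tr <- exx + eyy + ezz
  cbind(sxx = lam$lambda * tr + 2 * lam$mu * exx,
        syy = lam$lambda * tr + 2 * lam$mu * eyy,
        szz = lam$lambda * tr + 2 * lam$mu * ezz,
        sxy = lam$mu * gxy,
        syz = lam$mu * gyz,
        szx = lam$mu * gzx)
}

#' Von Mises equivalent stress
#'
#' Scalar equivalent stress from the deviatoric part of a symmetric stress
#' tensor, the failure-risk proxy used throughout:
#' `sqrt(0.5 * ((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2) + 3 * (sxy^2 + syz^2 + szx^2))`.
#'
#' @param sigma numeric vector of 6 Voigt components
#'   `(sxx, syy, szz, sxy, syz, szx)` or a matrix with those 6 columns.
#' @return von Mises stress, Pa (vector if `sigma` is a matrix).
#' @examples
#' von_mises(c(100, 0, 0, 0, 0, 0))     # uniaxial: 100
#' von_mises(c(0, 0, 0, 100, 0, 0))     # pure shear: 100 * sqrt(3)
#' @export
von_mises <- function(sigma) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  stopifnot(ncol(sigma) == 6)
  vm <- sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 +
                    (sigma[, 2] - sigma[, 3])^2 +
                    (sigma[, 3] - sigma[, 1])^2) +
             3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
  unname(vm)
}

# volume-weighted nodal average of per-element scalars
nodal_average <- function(mesh, elem_vals) {
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  idx <- as.vector(mesh$tets)
  w <- rep(vol, 4)
  v <- rep(elem_vals * vol, 4)
  num <- rowsum(v, idx)
  den <- rowsum(w, idx)
  out <- numeric(nrow(mesh$nodes))
  out[as.integer(rownames(num))] <- num / den
  out
}

new_stress_field <- function(mesh, u, sigma, case, assignment) {
  structure(list(
    displacements = matrix(u, ncol = 3, byrow = TRUE,
                           dimnames = list(NULL, c("ux", "uy", "uz"))),
    element_stress = sigma,
    nodal_vm = nodal_average(mesh, von_mises(sigma)),
    regime = case$regime, mode = assignment$mode,
    element_count = nrow(mesh$tets)), class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("stress_field: %s regime, %s materials, %d elements\n",
              x$regime, x$mode, x$element_count))
  cat(sprintf("  max |u| = %.4g m, max nodal VM = %.4g Pa\n",
              max(abs(x$displacements)), max(x$nodal_vm)))
  invisible(x)
}

# lumped nodal weights over boundary faces fully contained in a node set
patch_node_weights <- function(mesh, set_nodes) {
  bf <- boundary_faces(mesh)
  inset <- matrix(bf %in% set_nodes, nrow(bf), 3)
  keep <- rowSums(inset) == 3L
  w <- numeric(nrow(mesh$nodes))
  if (any(keep)) {
    bf <- bf[keep, , drop = FALSE]
    ar <- face_areas(mesh$nodes, bf)
    acc <- rowsum(rep(ar / 3, 3), as.vector(bf))
    w[as.integer(rownames(acc))] <- acc
  } else {
    w[set_nodes] <- 1
  }
  w[setdiff(seq_len(nrow(mesh$nodes)), set_nodes)] <- 0
  w / sum(w)
}

#' Solve the impact loading regime
#'
#' Fixes all basal nodes (zero displacement in x, y and z) and applies a
#' total force `case$F` in the -z direction over the tip patch, distributed
#' over the patch nodes in proportion to their lumped boundary-face area so
#' the applied nodal forces sum to exactly `(0, 0, -F)`.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param assignment a [material_assignment()].
#' @param case a [load_case()] with `regime = "impact"`.
#' @param K optional pre-assembled stiffness matrix (reused across regimes).
#' @param tol relative residual tolerance for the linear solve.
#' @return a `stress_field`.
#' @export
solve_impact <- function(mesh, assignment, case = load_case("impact"),
                         K = NULL, tol = 1e-8) {
  if (case$regime != "impact") stop("load case regime must be 'impact'")
  ns <- mesh$node_sets
  if (is.null(ns$base) || length(ns$base) == 0L) stop("empty 'base' node set")
  if (is.null(ns$tip_patch) || length(ns$tip_patch) == 0L)
    stop("empty 'tip_patch' node set")
  if (is.null(K)) K <- assemble_system(mesh, assignment)
  f <- numeric(3L * nrow(mesh$nodes))
  w <- patch_node_weights(mesh, ns$tip_patch)
  f[3L * (seq_len(nrow(mesh$nodes)) - 1L) + 3L] <- -case$F * w
  fixed <- as.vector(outer(c(1L, 2L, 3L), 3L * (ns$base - 1L), `+`))
  u <- solve_constrained(K, f, fixed, numeric(length(fixed)), tol = tol)
  new_stress_field(mesh, u, element_stresses(mesh, assignment, u), case,
                   assignment)
}

#' Solve the torsion loading regime
#'
#' Fixes the tip-patch nodes and prescribes a small rigid rotation of the
#' basal nodes about the +z axis through the centroid of the bony-core base:
#' `ux = -theta (y - cy)`, `uy = theta (x - cx)`, `uz = 0`. For theta of
#' order a milliradian the small-angle linearization error is O(theta^2).
#'
#' @inheritParams solve_impact
#' @param case a [load_case()] with `regime = "torsion"`.
#' @return a `stress_field`.
#' @export
solve_torsion <- function(mesh, assignment, case = load_case("torsion"),
                          K = NULL, tol = 1e-8) {
  if (case$regime != "torsion") stop("load case regime must be 'torsion'")
  ns <- mesh$node_sets
  if (is.null(ns$base) || length(ns$base) == 0L) stop("empty 'base' node set")
  if (is.null(ns$tip_patch) || length(ns$tip_patch) == 0L)
    stop("empty 'tip_patch' node set")
  if (is.null(K)) K <- assemble_system(mesh, assignment)

  z <- mesh$nodes[, 3]
  eps <- 1e-6 * (max(z) - min(z))
  core_tets <- mesh$tets[mesh$material == "bone", , drop = FALSE]
  core_nodes <- unique(as.vector(core_tets))
  cb <- core_nodes[z[core_nodes] <= min(z) + eps]
  if (length(cb) == 0L) cb <- ns$base   # homogeneous-label meshes
  cx <- mean(mesh$nodes[cb, 1])
  cy <- mean(mesh$nodes[cb, 2])

  th <- case$theta
  base <- ns$base
  fixed <- c(as.vector(outer(c(1L, 2L, 3L), 3L * (base - 1L), `+`)),
             as.vector(outer(c(1L, 2L, 3L), 3L * (ns$tip_patch - 1L), `+`)))
  vals <- c(as.vector(rbind(-th * (mesh$nodes[base, 2] - cy),
                            th * (mesh$nodes[base, 1] - cx),
                            0)),
            numeric(3L * length(ns$tip_patch)))
  dup <- duplicated(fixed)
  fixed <- fixed[!dup]; vals <- vals[!dup]
  f <- numeric(3L * nrow(mesh$nodes))
  u <- solve_constrained(K, f, fixed, vals, tol = tol)
  new_stress_field(mesh, u, element_stresses(mesh, assignment, u), case,
                   assignment)
}

#' Peak von Mises stress in the measurement zone
#'
#' Maximum nodal von Mises stress over the `measurement_zone` node set (the
#' outer-surface band at two-thirds of the tomial length, chosen away from
#' the constrained and loaded regions to avoid local boundary effects).
#'
#' @param field a `stress_field`.
#' @param mesh the tagged `tet_mesh` the field was solved on.
#' @return peak stress in Pa.
#' @export
peak_vm_in_zone <- function(field, mesh) {
  zone <- mesh$node_sets$measurement_zone
  if (is.null(zone) || length(zone) == 0L) stop("empty 'measurement_zone'")
  max(field$nodal_vm[zone])
}

#' Mesh-convergence study of the peak zone stress
#'
#' Re-meshes the bill at a series of increasing resolutions, solves the
#' given load case at each, and reports the peak measurement-zone von Mises
#' stress together with the percent change between successive levels. The
#' first level at which the absolute percent change drops below `criterion`
#' (default 5%) is flagged as converged.
#'
#' @param spec a [bill_spec()].
#' @param assignment a [material_assignment()].
#' @param case a [load_case()].
#' @param resolutions strictly increasing integer vector (>= 3 values) of
#'   circumferential resolutions; axial resolution is 1.5x each value, so
#'   successive doubling multiplies the element count by roughly 8.
#' @param criterion convergence threshold in percent.
#' @return data.frame with `n_circ`, `element_count`, `peak_vm`,
#'   `pct_change` and `converged`.
#' @export
convergence_study <- function(spec, assignment, case, resolutions,
                              criterion = 5) {
  if (length(resolutions) < 3L)
    stop("at least 3 resolutions are required for a convergence study")
  if (any(diff(resolutions) <= 0))
    stop("resolutions must be strictly increasing")
  peak <- numeric(length(resolutions))
  nel <- integer(length(resolutions))
  for (i in seq_along(resolutions)) {
    nc <- resolutions[i]
    # refine axially, circumferentially and radially in proportion, so the
    # element size shrinks uniformly from level to level
    mesh <- make_bill_mesh(spec, n_axial = max(4L, round(1.5 * nc)),
                           n_circumferential = nc,
                           n_radial_core = max(2L, round(nc / 4)),
                           n_radial_shell = max(1L, ceiling(nc / 8)))
    fld <- if (case$regime == "impact") solve_impact(mesh, assignment, case)
           else solve_torsion(mesh, assignment, case)
    peak[i] <- peak_vm_in_zone(fld, mesh)
    nel[i] <- nrow(mesh$tets)
  }
  pct <- c(NA, 100 * diff(peak) / peak[-length(peak)])
  data.frame(n_circ = resolutions, element_count = nel, peak_vm = peak,
             pct_change = pct,
             converged = !is.na(pct) & abs(pct) < criterion)
}
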