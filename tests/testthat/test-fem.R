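# independent single-element oracle: Ke = V * B' D B assembled from the
# explicit strain-displacement matrix of one tetrahedron
tet4_ke_oracle <- function(nodes, E, nu) {
  g <- solve(cbind(1, nodes))[2:4, ]      # shape gradients, 3 x 4
  V <- abs(det(cbind(nodes[2, ] - nodes[1, ], nodes[3, ] - nodes[1, ],
                     nodes[4, ] - nodes[1, ]))) / 6
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1, a]
    B[2, c0 + 2] <- g[2, a]
    B[3, c0 + 3] <- g[3, a]
    B[4, c0 + 1] <- g[2, a]; B[4, c0 + 2] <- g[1, a]
    B[5, c0 + 2] <- g[3, a]; B[5, c0 + 3] <- g[2, a]
    B[6, c0 + 1] <- g[3, a]; B[6, c0 + 3] <- g[1, a]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  V * t(B) %*% D %*% B
}

one_tet_mesh <- function(nodes) {
  m <- billmech:::new_tet_mesh(nodes, matrix(1:4, 1), "rhamphotheca")
  m$node_sets <- list(base = 1:3, tip_patch = 4L, measurement_zone = 4L,
                      outer_surface = 1:4)
  m
}

test_that("the assembled single-tet stiffness equals the B-matrix closed form", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (nu in c(0, 0.25, 0.4)) {
    asg <- material_assignment("all_keratin",
                               keratin_mat = material("keratin", E = 1, nu = nu))
    K <- as.matrix(assemble_system(one_tet_mesh(nodes), asg))
    expect_equal(K, unname(tet4_ke_oracle(nodes, 1, nu)), tolerance = 1e-12)
  }
})

test_that("the stiffness operator is symmetric with rigid-body null modes", {
  mesh <- fix_bill_mesh()
  K <- assemble_system(mesh, material_assignment("composite"))
  kmax <- max(abs(K))
  expect_lt(max(abs(K - Matrix::t(K))) / kmax, 1e-12)

  n <- nrow(mesh$nodes)
  for (dir in 1:3) {                       # translations
    u <- numeric(3 * n)
    u[3 * (seq_len(n) - 1) + dir] <- 1
    expect_lt(max(abs(K %*% u)) / kmax, 1e-9)
  }
  # infinitesimal rotation about z through the origin
  u <- as.vector(t(cbind(-mesh$nodes[, 2], mesh$nodes[, 1], 0)))
  expect_lt(max(abs(K %*% u)) / (kmax * max(abs(mesh$nodes))), 1e-9)

  # an inverted element is reported by name
  bad <- mesh
  bad$tets[5, ] <- bad$tets[5, c(2, 1, 3, 4)]
  expect_error(assemble_system(bad, material_assignment("composite")),
               "inverted element")
})

test_that("von Mises stress matches its closed form on canonical states", {
  expect_equal(von_mises(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(von_mises(c(0, 0, 0, 100, 0, 0)), 100 * sqrt(3))
  expect_equal(von_mises(c(100, 100, 100, 0, 0, 0)), 0)
  m <- rbind(c(100, 0, 0, 0, 0, 0), c(100, 100, 100, 0, 0, 0))
  expect_equal(von_mises(m), c(100, 0))
})

test_that("a uniaxially loaded prism carries stress F/A, uniform into the zone", {
  prism <- make_prism_mesh(0.01, 0.01, 0.05, 4, 4, 12)
  fld <- solve_impact(prism, material_assignment("all_keratin"),
                      load_case("impact", F = 10))
  expect_equal(peak_vm_in_zone(fld, prism), 1e5, tolerance = 0.01)
  # the interior field is uniform at F/A; only the discretely loaded tip
  # patch shows a small local concentration
  interior <- which(prism$nodes[, 3] > 0.005 & prism$nodes[, 3] < 0.04)
  expect_equal(fld$nodal_vm[interior], rep(1e5, length(interior)),
               tolerance = 0.01)

  # zone restriction: a synthetic spike outside the zone is not reported
  spiked <- fld
  outside <- setdiff(seq_along(fld$nodal_vm), prism$node_sets$measurement_zone)
  spiked$nodal_vm[outside[1]] <- 1e9
  expect_equal(peak_vm_in_zone(spiked, prism), 1e5, tolerance = 0.01)
  spiked$nodal_vm[prism$node_sets$measurement_zone[1]] <- 2e9
  expect_equal(peak_vm_in_zone(spiked, prism), 2e9)
})

test_that("the patch test reproduces a uniform strain state exactly", {
  prism <- make_prism_mesh(0.01, 0.01, 0.02, 3, 3, 5)
  E <- 2e9; nu <- 0.3
  asg <- material_assignment("all_keratin",
                             keratin_mat = material("keratin", E, nu))
  K <- assemble_system(prism, asg)
  S <- matrix(c(1, 0.3, 0.2, 0.3, -0.5, 0.1, 0.2, 0.1, 0.7), 3, 3) * 1e-4
  u_exact <- prism$nodes %*% S             # linear displacement field
  bnd <- prism$node_sets$outer_surface
  fixed <- as.vector(outer(1:3, 3 * (bnd - 1), `+`))
  vals <- as.vector(t(u_exact[bnd, ]))
  u <- billmech:::solve_constrained(K, numeric(3 * nrow(prism$nodes)),
                                    fixed, vals)
  sig <- billmech:::element_stresses(prism, asg, u)
  eps <- (S + t(S)) / 2
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  sig_exact <- c(lam * sum(diag(eps)) + 2 * mu * diag(eps),
                 2 * mu * eps[1, 2], 2 * mu * eps[2, 3], 2 * mu * eps[3, 1])
  for (j in 1:6)
    expect_equal(sig[, j], rep(sig_exact[j], nrow(sig)), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("external work balances strain energy in the impact solve", {
  mesh <- fix_bill_mesh()
  asg <- material_assignment("composite")
  K <- assemble_system(mesh, asg)
  fld <- solve_impact(mesh, asg, load_case("impact", F = 10), K = K)
  u <- as.vector(t(fld$displacements))
  w <- billmech:::patch_node_weights(mesh, mesh$node_sets$tip_patch)
  f <- numeric(length(u))
  f[3 * (seq_len(nrow(mesh$nodes)) - 1) + 3] <- -10 * w
  expect_equal(sum(f), -10, tolerance = 1e-12)   # exact load resultant
  W_ext <- 0.5 * sum(f * u)
  E_strain <- 0.5 * sum(u * as.vector(K %*% u))
  expect_equal(W_ext, E_strain, tolerance = 1e-8)
})

test_that("the solution is linear in the load and vanishes at zero twist", {
  mesh <- fix_bill_mesh()
  asg <- material_assignment("composite")
  K <- assemble_system(mesh, asg)
  f1 <- solve_impact(mesh, asg, load_case("impact", F = 10), K = K)
  f2 <- solve_impact(mesh, asg, load_case("impact", F = 20), K = K)
  expect_equal(f2$element_stress, 2 * f1$element_stress, tolerance = 1e-9)

  t1 <- solve_torsion(mesh, asg, load_case("torsion", theta = 1.75e-3), K = K)
  t2 <- solve_torsion(mesh, asg, load_case("torsion", theta = 3.5e-3), K = K)
  expect_equal(t2$element_stress, 2 * t1$element_stress, tolerance = 1e-9)

  t0 <- solve_torsion(mesh, asg, load_case("torsion", theta = 0), K = K)
  expect_equal(max(abs(t0$displacements)), 0)
  expect_equal(max(t0$nodal_vm), 0)
})

test_that("the von Mises field is invariant under a rigid rotation of the frame", {
  mesh <- make_bill_mesh(fix_spec(), n_axial = 8, n_circumferential = 8)
  asg <- material_assignment("composite")
  fld <- solve_impact(mesh, asg)
  rot <- mesh
  rot$nodes <- mesh$nodes %*% t(rot_z(pi / 7))   # -z load direction preserved
  fld_r <- solve_impact(rot, asg)
  expect_equal(fld_r$nodal_vm, fld$nodal_vm, tolerance = 1e-6)
})

test_that("axial stress partitions between core and shell by modulus ratio", {
  prism <- make_prism_mesh(0.012, 0.012, 0.05, 6, 6, 12, core_fraction = 0.5)
  fld <- solve_impact(prism, material_assignment("composite"),
                      load_case("impact", F = 10))
  zc <- rowMeans(matrix(prism$nodes[prism$tets, 3], nrow(prism$tets), 4))
  mid <- zc > 0.02 & zc < 0.03
  s_core <- mean(fld$element_stress[mid & prism$material == "bone", "szz"])
  s_shell <- mean(fld$element_stress[mid & prism$material == "rhamphotheca", "szz"])
  expect_equal(s_core / s_shell, 12.7 / 6.5, tolerance = 0.05)
  expect_lt(abs(s_shell), abs(s_core))
})

test_that("convergence_study validates its inputs", {
  asg <- material_assignment("composite")
  expect_error(convergence_study(fix_spec(), asg, load_case("impact"), 8),
               "at least 3")
  expect_error(convergence_study(fix_spec(), asg, load_case("impact"),
                                 c(8, 8, 16)), "strictly increasing")
})
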