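test_that("closed-form values match independent evaluation", {
  # I_x = pi a b^3 / 4
  expect_equal(second_moment(0.01, 0.005), pi * 0.01 * 0.005^3 / 4)
  expect_equal(second_moment(0.01, 0.005), 9.8175e-10, tolerance = 1e-4)

  # P_cr via the generic pi^2 E I / (K L)^2 route equals the elliptical form
  E <- 6.5e9; a <- 0.01; b <- 0.005; L <- 0.05
  expect_equal(euler_critical_load(E, a, b, L, K = 2),
               pi^3 * E * a * b^3 / (16 * L^2), tolerance = 1e-14)
  expect_equal(euler_critical_load(E, a, b, L, K = 2),
               pi^2 * E * second_moment(a, b) / (2 * L)^2, tolerance = 1e-14)

  expect_equal(critical_buckling_stress(6.5e9, 0.01, 0.05),
               pi^2 * 6.5e9 * 0.01^2 / (16 * 0.05^2), tolerance = 1e-14)
  expect_equal(critical_buckling_stress(6.5e9, 0.01, 0.05), 1.6038e8,
               tolerance = 1e-4)

  # circular-shaft oracle: T = G J theta / L with J = pi r^4 / 2
  G <- 6.5e9 / (2 * 1.4); th <- 1.75e-3; r <- 0.008
  J <- pi * r^4 / 2
  expect_equal(resultant_torque(G, th, r, r, 0.05), G * J * th / 0.05,
               tolerance = 1e-14)

  # tau_max: circular limit G theta r / L, and a flat-wide example
  expect_equal(max_shear_stress(6.5e9, 0.4, th, r, r, 0.05), G * th * r / 0.05,
               tolerance = 1e-12)
  expect_equal(max_shear_stress(6.5e9, 0.4, th, r, r, 0.05), 6.5e5,
               tolerance = 1e-4)
  expect_equal(max_shear_stress(6.5e9, 0.4, th, 0.005, 0.01, 0.05),
               2 * G * th * 0.005^2 * 0.01 / ((0.005^2 + 0.01^2) * 0.05),
               tolerance = 1e-14)
  expect_equal(max_shear_stress(6.5e9, 0.4, th, 0.005, 0.01, 0.05), 3.25e5,
               tolerance = 1e-4)
})

test_that("scaling laws and symmetries hold", {
  expect_equal(second_moment(0.01, 0.01) / second_moment(0.01, 0.005), 8)
  expect_equal(second_moment(0.007, 0.007), pi * 0.007^4 / 4)  # circle
  expect_equal(euler_critical_load(1e9, 0.01, 0.01, 0.05, K = 1),
               4 * euler_critical_load(1e9, 0.01, 0.01, 0.05, K = 2))
  expect_equal(euler_critical_load(1e9, 0.01, 0.01, 0.1),
               euler_critical_load(1e9, 0.01, 0.01, 0.05) / 4)
  expect_equal(resultant_torque(1e9, 1e-3, 0.004, 0.009, 0.05),
               resultant_torque(1e9, 1e-3, 0.009, 0.004, 0.05))
  expect_equal(max_shear_stress(1e9, 0.4, 2e-3, 0.01, 0.005, 0.05),
               2 * max_shear_stress(1e9, 0.4, 1e-3, 0.01, 0.005, 0.05))
})

test_that("algebraic identities hold to 1e-12 over 1000 random draws", {
  set.seed(7)
  n <- 1000
  a <- runif(n, 0.002, 0.02); b <- runif(n, 0.002, 0.02)
  E <- runif(n, 1e9, 2e10); L <- runif(n, 0.02, 0.1)
  nu <- runif(n, 0.1, 0.45); th <- runif(n, 1e-4, 1e-2)
  G <- E / (2 * (1 + nu))
  P <- euler_critical_load(E, a, b, L)
  s <- critical_buckling_stress(E, b, L)
  expect_equal(s * (pi * a * b), P, tolerance = 1e-12)
  Tq <- resultant_torque(G, th, a, b, L)
  tm <- max_shear_stress(E, nu, th, a, b, L)
  expect_equal(tm * pi * a * b^2 / 2, Tq, tolerance = 1e-12)
})

test_that("performance grids have the expected monotone structure", {
  g <- performance_grid(c(0.008, 0.03), c(0.008, 0.03), n_grid = 9)
  expect_equal(nrow(g), 81)

  # sigma_cr does not depend on width
  for (d in unique(g$depth))
    expect_equal(diff(range(g$sigma_cr[g$depth == d])), 0)
  # sigma_cr strictly increasing in depth
  sd1 <- g$sigma_cr[g$width == g$width[1]][order(unique(g$depth))]
  expect_true(all(diff(sd1) > 0))
  # tau_max strictly increasing in width at fixed depth
  for (d in unique(g$depth)) {
    tw <- g$tau_max[g$depth == d][order(g$width[g$depth == d])]
    expect_true(all(diff(tw) > 0))
  }
})

test_that("jointly growing sections trade impact against torsion performance", {
  # along a correlated morphospace path both sigma_cr (better impact) and
  # tau_max (worse torsion) increase: the geometric tradeoff
  sz <- seq(0.5, 2, length.out = 20)
  a <- 0.007 * sz
  b <- 0.009 * sz
  s <- critical_buckling_stress(6.5e9, b, 0.05)
  t <- max_shear_stress(6.5e9, 0.4, 1.75e-3, a, b, 0.05)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(t) > 0))
  expect_gt(stats::cor(s, t, method = "spearman"), 0.99)
})

test_that("beam_metrics wires the half-axis conversion and identities together", {
  bm <- beam_metrics(width = 0.016, depth = 0.020)
  expect_equal(bm$a, 0.008)
  expect_equal(bm$b, 0.010)
  expect_equal(bm$sigma_cr, bm$P_cr / bm$A, tolerance = 1e-12)
  expect_equal(bm$tau_max, 2 * bm$T / (pi * bm$a * bm$b^2), tolerance = 1e-12)
})
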