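test_that("bill_spec rejects invalid geometries by naming the violated invariant", {
  expect_error(bill_spec(base_width = 0.016, base_depth = 0.020,
                         shell_thickness = 0.011),
               "shell_thickness")
  expect_error(bill_spec(base_width = -0.01, base_depth = 0.02), "base_width")
  expect_error(bill_spec(base_width = 0.01, base_depth = 0.02, length = 0),
               "length")
  expect_error(bill_spec(base_width = 0.01, base_depth = 0.02,
                         section_exponent = 1.5), "section_exponent")
  expect_error(bill_spec(base_width = 0.01, base_depth = 0.02,
                         width_taper_exponent = 0), "taper")
})

test_that("meshes are valid (positive volumes, watertight, conformal) across the spec range", {
  set.seed(42)
  for (i in 1:6) {
    spec <- bill_spec(base_width = runif(1, 0.008, 0.022),
                      base_depth = runif(1, 0.008, 0.026),
                      shell_thickness = runif(1, 0.001, 0.002),
                      width_taper_exponent = runif(1, 0.7, 2),
                      depth_taper_exponent = runif(1, 0.7, 2),
                      section_exponent = runif(1, 2, 3.5))
    mesh <- make_bill_mesh(spec, n_axial = 6, n_circumferential = 8)
    expect_true(validate_mesh(mesh))
    expect_setequal(unique(mesh$material), c("bone", "rhamphotheca"))
    expect_true(all(lengths(mesh$node_sets) > 0))
  }
})

test_that("structured refinement multiplies the element count by roughly 8", {
  coarse <- make_bill_mesh(fix_spec(), n_axial = 24, n_circumferential = 16)
  fine <- make_bill_mesh(fix_spec(), n_axial = 48, n_circumferential = 32)
  ratio <- nrow(fine$tets) / nrow(coarse$tets)
  expect_gte(ratio, 6)
  expect_lte(ratio, 10)
})

test_that("base dimensions are recovered within 2% and scale with the mesh", {
  mesh <- make_bill_mesh(fix_spec(), n_axial = 8, n_circumferential = 16)
  d <- measure_base_dimensions(mesh)
  expect_equal(unname(d["width"]), 0.016, tolerance = 0.02)
  expect_equal(unname(d["depth"]), 0.020, tolerance = 0.02)

  # circular section: width = depth = 2r
  cyl <- make_bill_mesh(bill_spec(base_width = 0.016, base_depth = 0.016,
                                  shell_thickness = 0.002, tip_scale = 1),
                        n_axial = 8, n_circumferential = 16)
  dc <- measure_base_dimensions(cyl)
  expect_equal(unname(dc["width"]), unname(dc["depth"]), tolerance = 1e-10)

  scaled <- scale_mesh(mesh, "length", 0.1)
  expect_equal(unname(measure_base_dimensions(scaled)), unname(d) * 2,
               tolerance = 1e-10)
})

test_that("scale_mesh hits its target exactly for length and area modes", {
  mesh <- fix_bill_mesh()
  s <- scale_mesh(mesh, "length", 0.05)
  expect_identical(s$nodes, mesh$nodes)     # already at 5 cm: identity

  s2 <- scale_mesh(mesh, "length", 0.031)
  expect_equal(max(s2$nodes[, 3]) - min(s2$nodes[, 3]), 0.031, tolerance = 1e-12)

  a0 <- sum(billmech:::face_areas(mesh$nodes, billmech:::boundary_faces(mesh)))
  s3 <- scale_mesh(mesh, "surface_area", 2.5 * a0)
  a3 <- sum(billmech:::face_areas(s3$nodes, billmech:::boundary_faces(s3)))
  expect_equal(a3, 2.5 * a0, tolerance = 1e-3)
  expect_error(scale_mesh(mesh, "length", -1), "target")
})

test_that("node sets sit where the measurement protocol puts them", {
  mesh <- fix_bill_mesh()
  L <- 0.05
  z <- mesh$nodes[, 3]
  zone <- mesh$node_sets$measurement_zone
  expect_true(all(abs(z[zone] - 2 / 3 * L) <= 0.025 * L + 1e-9))
  expect_true(any(abs(z[zone] - 2 / 3 * L) < 1e-9))   # a station at 2L/3 itself
  expect_true(all(z[mesh$node_sets$tip_patch] >= 0.95 * L - 1e-9))
  expect_true(all(abs(z[mesh$node_sets$base]) <= 1e-6 * L))

  # degenerate zero-width band: no node plane exactly at 2L/3 on this grid
  prism <- make_prism_mesh(0.01, 0.01, 0.05, 2, 2, 10)
  expect_error(tag_node_sets(prism, zone_half_width_fraction = 0),
               "measurement_zone")
})
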