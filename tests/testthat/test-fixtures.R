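# synthetic defect fixture and analytic solver benchmarks

test_that("fixture meshes are watertight, closed and deterministic", {
  fx <- make_defect_fixture(40, 20, 10, curvature = 0, seed = 42)
  expect_true(is_watertight(fx$outer_surface))
  expect_true(is_watertight(fx$defect_region))
  expect_identical(euler_characteristic(fx$outer_surface), 2L)
  expect_identical(euler_characteristic(fx$defect_region), 2L)
  fx2 <- make_defect_fixture(40, 20, 10, curvature = 0, seed = 42)
  expect_identical(fx$outer_surface$vertices, fx2$outer_surface$vertices)
  expect_identical(fx$defect_region$faces, fx2$defect_region$faces)
})

test_that("fixture labeled node sets are populated and correctly placed", {
  fx <- make_defect_fixture(40, 20, 10, curvature = 0.15, seed = 42)
  v <- fx$outer_surface$vertices
  expect_true(all(lengths(fx$stump_faces) > 0))
  expect_true(all(abs(v[fx$stump_faces$neg, 1] + 20) < 1e-9))
  expect_true(all(abs(v[fx$stump_faces$pos, 1] - 20) < 1e-9))
  expect_gt(length(fx$occlusal_nodes), 0)
  expect_gt(length(fx$condyle_nodes), 0)
  expect_length(intersect(fx$occlusal_nodes, fx$condyle_nodes), 0)
  # eight muscles per side, names matching the force table
  ms <- fx$muscle_sites
  expect_identical(as.integer(table(ms$side)), c(8L, 8L))
  expect_setequal(unique(ms$name), unique(default_muscle_forces()$name))
  expect_equal(sqrt(ms$dx^2 + ms$dy^2 + ms$dz^2), rep(1, 16), tolerance = 1e-9)
})

test_that("curvature shears the prism without changing topology, and the
           enclosed volume matches a brute-force voxel fill", {
  f0 <- make_defect_fixture(15, 8, 6, curvature = 0, seed = 1, stump_mm = 3)
  f5 <- make_defect_fixture(15, 8, 6, curvature = 0.5, seed = 1, stump_mm = 3)
  expect_identical(nrow(f0$defect_region$vertices),
                   nrow(f5$defect_region$vertices))
  expect_false(isTRUE(all.equal(f0$defect_region$vertices,
                                f5$defect_region$vertices)))
  # divergence-theorem volume vs 0.2 mm voxel counting
  m <- f5$defect_region
  bb <- mesh_bbox(m)
  h <- 0.2
  gp <- as.matrix(expand.grid(seq(bb[1, 1] + h / 2, bb[2, 1], by = h),
                              seq(bb[1, 2] + h / 2, bb[2, 2], by = h),
                              seq(bb[1, 3] + h / 2, bb[2, 3], by = h)))
  vox_vol <- sum(points_in_mesh(gp, m)) * h^3
  expect_equal(mesh_volume(m), vox_vol, tolerance = 0.02)
})

test_that("degenerate fixture parameters are rejected", {
  expect_error(make_defect_fixture(40, 0, 10), class = "scaffem_invalid_parameter")
  expect_error(make_defect_fixture(-1, 20, 10), class = "scaffem_invalid_parameter")
  expect_error(make_defect_fixture(10, 20, 10), class = "scaffem_invalid_parameter")
  expect_error(make_defect_fixture(40, 20, 10, seed = -1),
               class = "scaffem_invalid_parameter")
})

test_that("cantilever benchmark matches Euler-Bernoulli and is linear", {
  cm <- make_cantilever_benchmark(100, 2, 110000, n_elems = 20)
  asm <- fe_assemble(cm)
  res <- fe_solve(asm)
  tip <- res$u[asm$beam_tdof[21, 3]]
  I <- pi * 2^4 / 64
  closed <- -100^3 / (3 * 110000 * I)
  expect_equal(tip, closed, tolerance = 0.01)
  # doubling E halves the deflection
  cm2 <- make_cantilever_benchmark(100, 2, 220000, n_elems = 20)
  asm2 <- fe_assemble(cm2)
  tip2 <- fe_solve(asm2)$u[asm2$beam_tdof[21, 3]]
  expect_equal(tip2, tip / 2, tolerance = 1e-10)
  # refinement: doubling the element count changes the tip by < 0.1 %
  cm3 <- make_cantilever_benchmark(100, 2, 110000, n_elems = 40)
  asm3 <- fe_assemble(cm3)
  tip3 <- fe_solve(asm3)$u[asm3$beam_tdof[41, 3]]
  expect_lt(abs(tip3 - tip) / abs(tip), 1e-3)
  expect_error(make_cantilever_benchmark(10, 2), class = "scaffem_invalid_parameter")
})

test_that("voxel patch test reproduces imposed constant strain states", {
  # uniaxial: exact strain tensor recovery to machine precision
  pm <- make_patch_test(3, 15000, 0.3, strain = c(1e-3, 0, 0, 0, 0, 0))
  res <- fe_solve(fe_assemble(pm))
  expect_equal(res$vox$strain6[, 1], rep(1e-3, nrow(res$vox$strain6)),
               tolerance = 1e-10)
  expect_equal(max(abs(res$vox$strain6[, 2:6])), 0, tolerance = 1e-13)
  eq <- equivalent_strain(c(1e-3, 0, 0, 0, 0, 0))
  expect_equal(res$vox$eq_strain_elem, rep(eq, 27), tolerance = 1e-10)

  # pure shear: von-Mises stress sqrt(3) * G * gamma everywhere
  gam <- 2e-3
  ps <- make_patch_test(2, 10000, 0.25, strain = c(0, 0, 0, gam, 0, 0))
  rs <- fe_solve(fe_assemble(ps))
  G <- 10000 / (2 * 1.25)
  expect_equal(rs$vox$vm_elem, rep(sqrt(3) * G * gam, 8), tolerance = 1e-10)

  # hydrostatic: zero deviatoric equivalent strain
  ph <- make_patch_test(2, 5000, 0.4, strain = c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  rh <- fe_solve(fe_assemble(ph))
  expect_equal(max(rh$vox$eq_strain_elem), 0, tolerance = 1e-7)

  expect_error(make_patch_test(2, 1000, 0.5), class = "scaffem_invalid_parameter")
  expect_error(make_patch_test(0, 1000, 0.3), class = "scaffem_invalid_parameter")
})
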