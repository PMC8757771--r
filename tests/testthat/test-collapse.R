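test_that("unit-cell meshes are conforming, labelled and of the expected scale", {
  m_free <- build_unit_cell_mesh(fx$cell, with_support = FALSE)
  m_bath <- build_unit_cell_mesh(fx$cell, with_support = TRUE)
  for (m in list(m_free, m_bath)) {
    areas <- gelprint:::triangle_areas(m)
    expect_true(all(areas > 0))                 # no inverted elements
    expect_false(anyNA(m$label))
    expect_equal(max(m$nodes[, 2]), fx$cell$n_layers * fx$cell$layer_height)
  }
  expect_true(all(m_free$label == "gel"))
  expect_gt(sum(m_bath$label == "support"), 0)
  # same gel geometry in both meshes
  expect_equal(sum(m_free$label == "gel"), sum(m_bath$label == "gel"))
  # element count at the reported mesh scale (order 500-1000)
  expect_gt(nrow(m_free$triangles), 400)
  expect_lt(nrow(m_free$triangles), 1200)
  # a one-layer cell collapses to a single rectangular slab
  slab <- build_unit_cell_mesh(scaffold_cell(n_layers = 1))
  expect_true(all(slab$label == "gel"))
  expect_equal(max(slab$nodes[, 2]), fx$cell$layer_height)
  expect_equal(diff(range(slab$nodes[, 1])), fx$cell$inter_fiber_distance)
  # degenerate slicing is rejected
  expect_error(scaffold_cell(strand_width = 0.4e-3, layer_height = 0.55e-3),
               "layer_height")
  expect_error(scaffold_cell(strand_width = 0.77e-3,
                             inter_fiber_distance = 0.5e-3), "exceed")
})

test_that("mesh export writes readable Gmsh ASCII", {
  m <- build_unit_cell_mesh(fx$cell, target_element_size = 4e-4)
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(m, path)
  lines <- readLines(path)
  expect_equal(lines[1], "$MeshFormat")
  expect_equal(as.integer(lines[5]), nrow(m$nodes))
  expect_true(sprintf("%d", nrow(m$triangles)) %in% lines)
})

test_that("analytic Kelvin-Voigt creep has the right limits and time constant", {
  expect_equal(analytic_kv_creep(30, 231.4, 60, Inf), 2)
  expect_equal(analytic_kv_creep(30, 231.4, 60, 0), 0)
  expect_equal(analytic_kv_creep(30, 0, 60, 5), 2)  # no dashpot: instantaneous
  tau <- 231.4 / 30
  expect_equal(tau, 7.713, tolerance = 1e-3)
  eps <- analytic_kv_creep(30, 231.4, 60, 200)
  expect_lt(abs(eps - 2) / 2, 1e-9)  # fully relaxed well before 200 s
  expect_equal(analytic_kv_creep(30, 231.4, 60, tau), 2 * (1 - exp(-1)))
})

test_that("single element under constant stress follows the lumped creep law", {
  mesh <- single_square_mesh()
  E <- 30; eta <- 231.4; sigma0 <- 12
  gel <- kelvin_voigt(E = E, eta0 = eta, nu = 0, rho = 1000)
  sol <- solve_collapse(mesh, gel, gravity = 0, top_traction = sigma0,
                        t_end = 40, dt = 0.05, bottom = "roller",
                        sides = "roller")
  eps_fe <- sol$point_a / mesh$height
  eps_ref <- analytic_kv_creep(E, eta, sigma0, sol$time)
  keep <- sol$time > 0
  expect_lt(max(abs(eps_fe[keep] - eps_ref[keep]) / eps_ref[keep]), 0.01)
})

test_that("uniform column matches analytic self-weight compression", {
  cell <- column_cell()
  mesh <- build_unit_cell_mesh(cell, target_element_size = 2e-4)
  H <- mesh$height
  # nu = 0: the constrained modulus equals E and the reference value is
  # rho g H^2 / (2 E); for E = 30 Pa and H = 3.3 mm that is ~1.78 mm
  gel0 <- kelvin_voigt(E = 30, eta0 = 231.4, nu = 0, rho = 1000)
  sol0 <- solve_collapse(mesh, gel0, t_end = 200, dt = 0.5)
  ref0 <- analytic_column_compression(30, 0, 1000, H)
  expect_equal(ref0, 1.78e-3, tolerance = 1e-2)
  expect_lt(abs(sol0$point_a[length(sol0$point_a)] - ref0) / ref0, 0.02)
  # near-incompressible: same test at nu = 0.49 against the constrained
  # modulus M = E (1 - nu) / ((1 + nu)(1 - 2 nu))
  gel49 <- kelvin_voigt(E = 30, eta0 = 231.4, nu = 0.49, rho = 1000)
  sol49 <- solve_collapse(mesh, gel49, t_end = 200, dt = 0.5)
  ref49 <- analytic_column_compression(30, 0.49, 1000, H)
  expect_lt(abs(sol49$point_a[length(sol49$point_a)] - ref49) / ref49, 0.02)
})

test_that("collapse solution honours basic physics invariants", {
  mesh <- build_unit_cell_mesh(fx$cell, target_element_size = 2.5e-4)
  gel <- fx$kv$C20_pH4.9
  sol <- solve_collapse(mesh, gel)
  # zero initial displacement, monotone in time, settled by the window end
  expect_equal(sol$point_a[1], 0)
  expect_true(all(diff(sol$point_a) >= -1e-15))
  n <- length(sol$point_a)
  tail_start <- floor(0.9 * n)
  expect_lt(abs(sol$point_a[n] - sol$point_a[tail_start]) / sol$point_a[n],
            1e-3)
  # no gravity, no displacement
  still <- solve_collapse(mesh, gel, gravity = 0, t_end = 5, dt = 1)
  expect_equal(max(abs(still$displacement)), 0)
  # linearity: doubling gravity doubles the settled displacement
  twice <- solve_collapse(mesh, gel, gravity = 2 * 9.81)
  expect_equal(twice$point_a[n] / sol$point_a[n], 2, tolerance = 1e-6)
  # time-step convergence: halving dt changes the final value < 1%
  half <- solve_collapse(mesh, gel, dt = 0.25)
  expect_lt(abs(half$point_a[length(half$point_a)] - sol$point_a[n]) /
              sol$point_a[n], 0.01)
  # support material demanded iff the mesh has support elements
  bath_mesh <- build_unit_cell_mesh(fx$cell, with_support = TRUE,
                                    target_element_size = 2.5e-4)
  expect_error(solve_collapse(bath_mesh, gel), "support")
  path <- withr::local_tempfile(fileext = ".csv")
  write_collapse_csv(sol, path)
  expect_equal(nrow(utils::read.csv(path)), n)
})

test_that("embedded printing stabilizes the scaffold; stiffness ranks strains", {
  coarse <- 2.5e-4
  cmp <- compare_strategies(fx$cell, fx$kv$C20_pH3.7, fx$kv$support,
                            target_element_size = coarse)
  expect_gt(attr(cmp$summary, "ratio"), 10)
  expect_lt(cmp$summary$final_strain[2], cmp$summary$final_strain[1])
  # equal materials, fully filled domain: filling the voids can only stiffen
  eq <- compare_strategies(fx$cell, fx$kv$support, fx$kv$support,
                           target_element_size = coarse)
  expect_lt(eq$summary$final_strain[2], eq$summary$final_strain[1])
  # final strain decreases monotonically with gel stiffness E
  gels <- fx$kv[setdiff(names(fx$kv), "support")]
  ord <- order(vapply(gels, `[[`, numeric(1), "E"))
  mesh <- build_unit_cell_mesh(fx$cell, target_element_size = coarse)
  strains <- vapply(gels[ord], function(kv) {
    solve_collapse(mesh, kv)$final_strain
  }, numeric(1))
  expect_true(all(diff(strains) < 0))
  # stiffest gel deforms over an order of magnitude less than the softest
  expect_gt(strains[1] / strains[length(strains)], 10)
})
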