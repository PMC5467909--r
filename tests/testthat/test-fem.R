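# Finite-element solver: assembly, potential solve, field recovery,
# electrode currents, rescaling and the solver's structural properties.

test_that("stiffness rows sum to zero and assembly is linear in sigma", {
  m <- two_layer_slab()
  f1 <- assign_isotropic(m, two_layer_table)
  sys1 <- assemble_system(m, f1)
  expect_lt(max(abs(Matrix::rowSums(sys1$K))), 1e-12)
  f3 <- ttfieldsim:::new_conductivity_field(3 * f1$tensor)
  sys3 <- assemble_system(m, f3)
  expect_equal(max(abs(sys3$K - 3 * sys1$K)), 0)
})

test_that("single-tetrahedron stiffness matches the hand formula", {
  # unit tet (mm coordinates), sigma = I: K_ij = vol * grad_i . grad_j with
  # grad_1 = -(1,1,1)/h, grad_2 = (1,0,0)/h, ... and h = 1 mm = 1e-3 m
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- tet_mesh(nodes, matrix(1:4, 1), "wm")
  sys <- assemble_system(m, assign_isotropic(m, c(wm = 1)))
  g <- rbind(c(-1, -1, -1), diag(3)) / 1e-3
  vol <- (1e-3)^3 / 6
  K_hand <- vol * g %*% t(g)
  expect_equal(as.matrix(sys$K), K_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate elements are rejected with their index", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(2, 0, 0), c(0, 2, 0), c(0.5, 0.5, 0))
  tets <- rbind(1:4, c(1, 5, 6, 7))  # second tet is coplanar
  expect_error(tet_mesh(nodes, tets, c("wm", "wm")), "2")
})

test_that("homogeneous slab reproduces the exact linear potential", {
  m <- build_slab_phantom(c(wm = 10), lateral_size = 20, resolution = 1)
  s <- solve_plates(m, assign_isotropic(m, c(wm = 1)), 0, 1, tol = 1e-12)
  expect_lt(max(abs(s$V - m$nodes[, 3] / 10)), 1e-8)
  # discrete maximum principle
  expect_true(all(s$V >= -1e-12 & s$V <= 1 + 1e-12))
  # E = -grad V is uniform at dV/d = 100 V/m
  expect_equal(range(s$normE), c(100, 100), tolerance = 1e-8)
})

test_that("two-layer slab matches the series-resistor oracle", {
  m <- two_layer_slab()
  s <- solve_plates(m, assign_isotropic(m, two_layer_table), 0, 1)
  # interface potential from the resistor divider: R_top/(R_top+R_bot)
  iz <- abs(m$nodes[, 3] - 5) < 1e-9
  expect_equal(unname(range(s$V[iz])), c(2 / 3, 2 / 3), tolerance = 1e-6)
  oracle <- slab_series_field(cbind(c(5, 5), c(1, 2)), delta_V = 1,
                              area_mm2 = 400)
  cz <- mesh_centroids(m)[, 3]
  expect_equal(max(abs(s$normE[cz < 5] - oracle$E_Vpm[1])) /
                 oracle$E_Vpm[1], 0, tolerance = 1e-3)
  expect_equal(max(abs(s$normE[cz > 5] - oracle$E_Vpm[2])) /
                 oracle$E_Vpm[2], 0, tolerance = 1e-3)
})

test_that("constant and linear potentials give exact element fields", {
  m <- two_layer_slab()
  x_m <- m$nodes[, 1] / 1000  # x in metres
  E <- element_field(m, x_m)  # V = x -> E = (-1, 0, 0)
  expect_equal(E, matrix(rep(c(-1, 0, 0), each = nrow(E)), ncol = 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  E0 <- element_field(m, rep(5, nrow(m$nodes)))
  expect_lt(max(abs(E0)), 1e-9)
})

test_that("current density applies the tensor point-wise", {
  f <- ttfieldsim:::new_conductivity_field(rbind(c(2, 2, 2, 0, 0, 0),
                                                 c(1, 2, 3, 0, 0, 0)))
  E <- rbind(c(100, 0, 0), c(1, 1, 1))
  J <- current_density(E, f)
  expect_identical(unname(J[1, ]), c(200, 0, 0))
  expect_identical(unname(J[2, ]), c(1, 2, 3))
})

test_that("electrode current matches the analytic slab current", {
  m <- build_slab_phantom(c(wm = 10), lateral_size = 20, resolution = 1)
  s <- solve_plates(m, assign_isotropic(m, c(wm = 1)), 1, 0, tol = 1e-12)
  I_lo <- electrode_current(s$system, s$V, s$lo)
  I_hi <- electrode_current(s$system, s$V, s$hi)
  expect_equal(I_lo, 0.04, tolerance = 1e-6)     # sigma * A * dV / d
  expect_lt(abs(I_lo + I_hi) / abs(I_lo), 1e-9)  # conservation
})

test_that("doubling the drive doubles potentials and currents exactly", {
  m <- two_layer_slab()
  f <- assign_isotropic(m, two_layer_table)
  s1 <- solve_plates(m, f, 1, 0)
  s2 <- solve_plates(m, f, 2, 0, system = s1$system)
  expect_identical(as.numeric(s2$V), 2 * as.numeric(s1$V))
  I1 <- electrode_current(s1$system, s1$V, s1$lo)
  I2 <- electrode_current(s2$system, s2$V, s2$lo)
  expect_identical(I2, 2 * I1)
})

test_that("swapping source and sink potentials negates the solution", {
  m <- two_layer_slab()
  f <- assign_isotropic(m, two_layer_table)
  s1 <- solve_plates(m, f, 0.5, -0.5)
  s2 <- solve_plates(m, f, -0.5, 0.5, system = s1$system)
  expect_identical(as.numeric(s2$V), -as.numeric(s1$V))
})

test_that("anisotropic tensors with equal eigenvalues match isotropic", {
  m <- build_slab_phantom(c(wm = 6), lateral_size = 10, resolution = 2)
  fib <- synth_fiber_field(m, "uniform", fa = 0, direction = c(1, 2, 3))
  s_iso <- solve_plates(m, assign_isotropic(m), 1, 0)
  s_ani <- solve_plates(m, direct_map_tensors(fib, m), 1, 0)
  expect_lt(max(abs(s_iso$V - s_ani$V)), 1e-9)
})

test_that("mirroring the phantom mirrors the field", {
  m <- build_slab_phantom(c(wm = 10), lateral_size = 16, resolution = 2)
  m <- add_box_region(m, c(2, -8, 2), c(8, 8, 6), "csf")  # off-centre in x
  mir <- m
  mir$nodes[, 1] <- -mir$nodes[, 1]
  mir <- tet_mesh(mir$nodes, mir$tets, mir$label, patches = mir$patches,
                  meta = mir$meta)
  f <- assign_isotropic(m)
  fm <- assign_isotropic(mir)
  s1 <- solve_plates(m, f, 1, 0, tol = 1e-11)
  pn <- plate_nodes(m)  # same node indexing in both meshes
  sys2 <- assemble_system(mir, fm)
  V2 <- solve_potential(sys2, c(pn$lo, pn$hi),
                        c(rep(1, length(pn$lo)), rep(0, length(pn$hi))),
                        tol = 1e-11)
  E2 <- element_field(mir, V2)
  expect_equal(as.numeric(V2), as.numeric(s1$V), tolerance = 1e-8)
  expect_equal(E2[, 1], -s1$E[, 1], tolerance = 1e-6)
  expect_equal(E2[, 2:3], s1$E[, 2:3], tolerance = 1e-6)
})

test_that("montage solve rescales to the target current idempotently", {
  h <- head_phantom()
  mons <- head_montages()
  tum <- embed_tumor(h, tumor_spec(c(40, 0, 0)))
  f <- assign_isotropic(tum)
  sol <- solve_tt_montage(tum, f, mons$LR)
  expect_equal(sol$source_current_A, 0.9, tolerance = 1e-12)
  expect_lt(abs(sol$source_current_A + sol$sink_current_A) / 0.9, 1e-6)
  sol2 <- rescale_to_target(sol, 0.9)
  expect_identical(sol2$V, sol$V)
  expect_identical(sol2$rescale_factor, sol$rescale_factor)
  # J = sigma E element-wise
  expect_equal(sol$J, current_density(sol$E, f), tolerance = 1e-12)
})

test_that("solver input validation catches misuse", {
  m <- two_layer_slab()
  sys <- assemble_system(m, assign_isotropic(m, two_layer_table))
  pn <- plate_nodes(m)
  expect_error(solve_potential(sys, pn$lo, rep(1, length(pn$lo))),
               "two distinct")
  expect_error(solve_potential(sys, c(1, 1), c(0, 1)), "duplicate")
  expect_error(solve_potential(sys, c(pn$lo, pn$hi),
                               c(rep(0, length(pn$lo)),
                                 rep(1, length(pn$hi))),
                               tol = 1e-14, maxit = 2), "converge")
})
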