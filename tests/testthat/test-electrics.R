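test_that("uniform conductivity gives the linear plate solution to machine precision", {
  mesh <- small_mesh(6, 9, R = 0.02, L = 0.05)
  bc <- electric_bc(100)
  V <- solve_potential(mesh, rep(2.5, mesh$ncell), bc)
  expect_equal(as.numeric(V), 100 * mesh$cell_z / 0.05, tolerance = 1e-12)
  # homogeneity: doubling sigma leaves the potential unchanged
  V2 <- solve_potential(mesh, rep(5.0, mesh$ncell), bc)
  expect_equal(as.numeric(V2), as.numeric(V), tolerance = 1e-12)
})

test_that("two-layer conductivity reproduces the series-resistor solution and the 1-D oracle", {
  L <- 0.06; V0 <- 90
  mesh <- build_mesh(cylinder_geometry(0.015, L), 4, 10)
  sigma_z <- ifelse(mesh$z < L / 2, 1.4, 2.8)   # sigma doubles in the top half
  V <- solve_potential(mesh, axial_profile(mesh, sigma_z), electric_bc(V0))
  # closed form: mid-plane potential V0 * s2/(s1+s2) = (2/3) V0, piecewise linear
  Vm <- V0 * 2 / 3
  exact <- ifelse(mesh$cell_z < L / 2, Vm * mesh$cell_z / (L / 2),
                  Vm + (V0 - Vm) * (mesh$cell_z - L / 2) / (L / 2))
  expect_equal(as.numeric(V), exact, tolerance = 1e-12)
  # independent dense 1-D finite-volume oracle
  oracle <- oracle_potential_1d(sigma_z, L, V0)
  expect_equal(as.numeric(V), axial_profile(mesh, oracle), tolerance = 1e-10)
})

test_that("arbitrary positive conductivity fields conserve current and obey the maximum principle", {
  set.seed(42)
  mesh <- small_mesh(7, 7)
  bc <- electric_bc(100)
  for (rep_i in 1:5) {
    sigma <- exp(stats::rnorm(mesh$ncell, sd = 0.5)) + 0.2
    V <- solve_potential(mesh, sigma, bc)
    expect_true(all(V >= -1e-9 & V <= 100 + 1e-9))
    I_top <- electrode_current(mesh, sigma, V, "top")
    I_bot <- electrode_current(mesh, sigma, V, "bottom")
    expect_equal(I_top, I_bot, tolerance = 1e-8)
    # energy identity: volume integral of Q equals V0 * I
    Q <- joule_source(mesh, sigma, V)
    expect_true(all(Q >= 0))
    expect_equal(total_power(mesh, Q), 100 * I_top, tolerance = 1e-8)
  }
})

test_that("Joule source matches the closed form for uniform fields", {
  L <- 0.03
  mesh <- build_mesh(cylinder_geometry(0.01, L), 5, 6)
  sigma <- rep(1.228, mesh$ncell)
  V <- solve_potential(mesh, sigma, electric_bc(100))
  Q <- joule_source(mesh, sigma, V)
  expect_equal(Q, rep(1.228 * (100 / L)^2, mesh$ncell), tolerance = 1e-10)
  # quarter power at half voltage
  Vh <- solve_potential(mesh, sigma, electric_bc(50))
  Qh <- joule_source(mesh, sigma, Vh)
  expect_equal(total_power(mesh, Qh), total_power(mesh, Q) / 4, tolerance = 1e-10)
})

test_that("Joule source is invariant under swapping the grounded electrode", {
  set.seed(7)
  mesh <- small_mesh(5, 6)
  sigma <- exp(stats::rnorm(mesh$ncell, sd = 0.3)) + 0.5
  V <- solve_potential(mesh, sigma, electric_bc(80))
  Q <- joule_source(mesh, sigma, V)
  # flip the mesh axially: same medium upside down, ground on the other side
  flip <- as.vector(field_matrix(mesh, seq_len(mesh$ncell))[, mesh$nz:1])
  Vf <- solve_potential(mesh, sigma[flip], electric_bc(80))
  Qf <- joule_source(mesh, sigma[flip], Vf)
  expect_equal(Qf[order(flip)], Q, tolerance = 1e-9)
  # and the flipped potential is the complement of the original
  expect_equal(Vf[order(flip)], 80 - as.numeric(V), tolerance = 1e-9)
})

test_that("total power integrates a uniform source exactly", {
  mesh <- build_mesh(cylinder_geometry(0.025, 0.05), 9, 4)
  expect_equal(total_power(mesh, rep(1e6, mesh$ncell)), 1e6 * pi * 0.025^2 * 0.05,
               tolerance = 1e-12)
})

test_that("degenerate conductivity is rejected", {
  mesh <- small_mesh(3, 3)
  expect_error(solve_potential(mesh, rep(0, mesh$ncell), electric_bc(100)),
               "positive")
  expect_error(solve_potential(mesh, rep(1, 5), electric_bc(100)), "mesh")
})

test_that("mid-plane potential converges to the two-layer closed form under refinement", {
  L <- 0.06; V0 <- 90
  err <- sapply(c(4, 8, 16), function(nz) {
    mesh <- build_mesh(cylinder_geometry(0.015, L), 3, nz)
    # smooth conductivity: linear in z, no longer nodally exact
    sigma <- 1 + 20 * mesh$cell_z
    V <- solve_potential(mesh, sigma, electric_bc(V0))
    # exact: V(z) = V0 * log(1 + 20 z)/log(1 + 20 L)
    max(abs(V - V0 * log(1 + 20 * mesh$cell_z) / log(1 + 20 * L)))
  })
  expect_true(all(diff(err) < 0))
})
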