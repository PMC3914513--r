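const_props <- function(mesh, lambda = 0.5, vhc = 3.4e6)
  list(thermal_conductivity = rep(lambda, mesh$ncell),
       volumetric_heat_capacity = rep(vhc, mesh$ncell))

test_that("equilibrium is exact: no source, no losses, uniform start", {
  mesh <- small_mesh(6, 6)
  T0 <- rep(300, mesh$ncell)
  Tn <- step_temperature(mesh, T0, rep(0, mesh$ncell), const_props(mesh),
                         thermal_bc(U = 0), dt = 1)
  expect_equal(Tn, T0, tolerance = 1e-13)
})

test_that("uniform source with insulated walls gives the lumped temperature rise exactly", {
  mesh <- small_mesh(5, 7)
  pr <- const_props(mesh, vhc = 3.4e6)
  T0 <- rep(280, mesh$ncell)
  Q <- rep(2e6, mesh$ncell)
  Tn <- step_temperature(mesh, T0, Q, pr, thermal_bc(U = 0), dt = 0.5)
  expect_equal(Tn, T0 + 2e6 * 0.5 / 3.4e6, tolerance = 1e-12)
})

test_that("pure cooling matches the small-Biot exponential and never undershoots", {
  # small sample, low U: Biot = U (R/2) / lambda ~ 0.02
  R <- 0.01; L <- 0.02
  mesh <- build_mesh(cylinder_geometry(R, L), 6, 6)
  lambda <- 0.5; vhc <- 3.4e6; U <- 2; T_inf <- 286.15; T0 <- 350
  pr <- const_props(mesh, lambda, vhc)
  bc <- thermal_bc(U = U, T_inf = T_inf)
  area <- sum(boundary_faces(mesh)$area_m2)
  vol <- sum(mesh$volume)
  dt <- 2; nsteps <- 200
  T <- rep(T0, mesh$ncell)
  mins <- maxs <- means <- numeric(nsteps)
  for (s in seq_len(nsteps)) {
    T <- step_temperature(mesh, T, rep(0, mesh$ncell), pr, bc, dt)
    mins[s] <- min(T); maxs[s] <- max(T); means[s] <- mean(T)
  }
  expect_true(all(diff(mins) < 0) && all(diff(maxs) < 0))
  expect_true(all(mins > T_inf))            # maximum principle
  lumped <- T_inf + (T0 - T_inf) * exp(-U * area * seq_len(nsteps) * dt / (vhc * vol))
  expect_lt(max(abs(means - lumped)) / (T0 - T_inf), 0.02)
})

test_that("insulated heating never lowers a cell below the running minimum", {
  set.seed(11)
  mesh <- small_mesh(5, 5)
  pr <- const_props(mesh)
  # from a uniform start, one step with any positive source raises every cell
  T <- rep(280, mesh$ncell)
  Q <- stats::runif(mesh$ncell, 0, 1e6)
  Tn <- step_temperature(mesh, T, Q, pr, thermal_bc(U = 0), dt = 0.5)
  expect_true(all(Tn > T))
  # thereafter the global minimum is nondecreasing (discrete maximum principle)
  for (s in 1:5) {
    T2 <- step_temperature(mesh, Tn, Q, pr, thermal_bc(U = 0), dt = 0.5)
    expect_gte(min(T2), min(Tn) - 1e-10)
    Tn <- T2
  }
})

test_that("per-step energy balance is exact for constant properties", {
  set.seed(3)
  mesh <- small_mesh(6, 6)
  pr <- const_props(mesh)
  Q <- stats::runif(mesh$ncell, 0, 2e6)
  # insulated, with source
  T0f <- rep(285, mesh$ncell)
  bc0 <- thermal_bc(U = 0)
  Tn <- step_temperature(mesh, T0f, Q, pr, bc0, 0.5)
  a <- energy_audit(mesh, T0f, Tn, Q, pr, bc0, 0.5)
  expect_lt(a$residual_W / a$source_W, 1e-10)
  # cooling, no source
  bc1 <- thermal_bc(U = 8, T_inf = 286.15)
  T1 <- rep(340, mesh$ncell)
  for (dt in c(1, 0.5)) {
    Tn <- step_temperature(mesh, T1, rep(0, mesh$ncell), pr, bc1, dt)
    a <- energy_audit(mesh, T1, Tn, rep(0, mesh$ncell), pr, bc1, dt)
    expect_lt(a$residual_W / abs(a$loss_W), 1e-6)
  }
})

test_that("disabling face families switches their losses off", {
  mesh <- small_mesh(4, 4)
  pr <- const_props(mesh)
  T0f <- rep(340, mesh$ncell)
  bc_none <- thermal_bc(U = 10, T_inf = 286.15, faces = "lateral")
  Tn <- step_temperature(mesh, T0f, rep(0, mesh$ncell), pr, bc_none, 1)
  # the outermost ring cools strongly; the implicit step lets a trace of the
  # deficit reach the axis, but orders of magnitude less
  M <- field_matrix(mesh, Tn)
  expect_true(all(M[mesh$nr, ] < 340 - 1e-3))
  expect_true(all(M[1, ] > 340 - 1e-4))
})

test_that("invalid steps are rejected", {
  mesh <- small_mesh(3, 3)
  pr <- const_props(mesh)
  T0f <- rep(300, mesh$ncell)
  expect_error(step_temperature(mesh, T0f, rep(0, mesh$ncell), pr,
                                thermal_bc(), dt = 0), "dt")
  expect_error(thermal_bc(U = -1), "U")
  expect_error(thermal_bc(faces = "side"), "unknown face tag")
})
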