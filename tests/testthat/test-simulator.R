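test_that("insulated runs stay spatially uniform and track the lumped ODE", {
  cfg <- process_config(nr = 8, nz = 8, duration = 60)
  tr <- run_simulation(cfg, tab5)
  expect_true(all(tr$T_max - tr$T_min < 0.01))
  ode <- lumped_ode(tab5, 100, cfg$geometry$length, 279.15, 60, times = tr$times)
  expect_lt(max(abs(tr$T_mean - ode$temperature_K)), 0.2)
  # trace invariants
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$T_min <= tr$T_mean + 1e-12 & tr$T_mean <= tr$T_max + 1e-12))
  # constant-voltage power grows as sigma(T) grows (row 1 repeats the t=0 fields)
  expect_true(all(diff(tr$power_W[-1]) > 0))
})

test_that("trace has one row per step including t = 0", {
  cfg <- process_config(nr = 6, nz = 6, duration = 10, dt = 0.5)
  tr <- run_simulation(cfg, tab5)
  expect_length(tr$times, 21L)
  expect_equal(tr$times[1], 0)
  expect_equal(tr$T_min[1], 279.15)
})

test_that("constant-power drive holds power and heats linearly with constant properties", {
  ctab <- const_table(sigma = 2, vhc = 3.4e6)
  cfg <- process_config(nr = 6, nz = 6, duration = 30, dt = 0.5,
                        drive_mode = "constant_power")
  tr <- run_simulation(cfg, ctab)
  expect_lt(diff(range(tr$power_W[-1])), 1e-8)
  # uniform constant source: exactly linear temperature rise
  rises <- diff(tr$T_mean)
  expect_lt(diff(range(rises)), 1e-10)
})

test_that("power rescaling follows the square law", {
  mesh <- small_mesh(4, 4)
  Q <- rep(1e6, mesh$ncell)
  P <- total_power(mesh, Q)
  rs <- rescale_for_constant_power(Q, mesh, P, 100)
  expect_equal(rs$Q, Q); expect_equal(rs$voltage, 100)
  rs2 <- rescale_for_constant_power(Q * 2, mesh, P, 100)
  expect_equal(rs2$Q, Q, tolerance = 1e-12)
  expect_equal(rs2$voltage, 100 / sqrt(2))
  expect_error(rescale_for_constant_power(Q * 0, mesh, P, 100), "power")
})

test_that("lumped ODE: closed form, convexity, and conductivity time-scaling", {
  # constant properties: T(t) = T0 + sigma (V0/L)^2 t / VHC
  ctab <- const_table(sigma = 2, vhc = 3.4e6)
  out <- lumped_ode(ctab, 100, 0.2, 280, 100)
  expect_equal(out$temperature_K,
               280 + 2 * (100 / 0.2)^2 * out$time_s / 3.4e6, tolerance = 1e-8)
  # sigma increasing with T: accelerating (convex) heating
  out2 <- lumped_ode(tab5, 100, 0.2, 279.15, 300)
  expect_true(all(diff(diff(out2$temperature_K)) > -1e-9))
  # scaling sigma by 1.1 scales the time to any temperature by 1/1.1
  out3 <- lumped_ode(scale_conductivity(tab5, 1.1), 100, 0.2, 279.15, 300)
  T_probe <- 320
  t_base <- stats::approx(out2$temperature_K, out2$time_s, T_probe)$y
  t_fast <- stats::approx(out3$temperature_K, out3$time_s, T_probe)$y
  expect_equal(t_fast / t_base, 1 / 1.1, tolerance = 1e-4)
})

test_that("the boiling guard aborts runs that leave the model's validity range", {
  cfg <- process_config(geometry = cylinder_geometry(0.01, 0.02),
                        nr = 6, nz = 6, duration = 120)
  expect_error(run_simulation(cfg, tab5), "boiling")
})

test_that("within-step property iteration refines but barely changes dt = 0.5 s results", {
  cfg <- process_config(nr = 6, nz = 6, duration = 20)
  tr0 <- run_simulation(cfg, tab5)
  tr1 <- run_simulation(cfg, tab5, picard_tol = 1e-3)
  expect_lt(max(abs(tr0$T - tr1$T)), 0.05)
})

test_that("with external cooling the coldest cell sits at an electrode/lateral corner", {
  # ambient below the initial temperature, so losses act from the first step
  cfg <- process_config(nr = 10, nz = 10, duration = 100,
                        thermal_bc = thermal_bc(U = 5, T_inf = 276.15))
  tr <- run_simulation(cfg, tab5, kinetics_params())
  ij <- mesh_ij(tr$mesh, which.min(tr$T))
  expect_equal(ij$i, 10L)
  expect_true(ij$j %in% c(1L, 10L))
  # accumulated-lethality cold cell agrees here
  expect_equal(which.min(tr$F), which.min(tr$T))
})

test_that("lethality tracking in a run matches standalone accumulation", {
  cfg <- process_config(nr = 5, nz = 5, duration = 40)
  kin <- kinetics_params()
  tr <- run_simulation(cfg, tab5, kin)
  # uniform insulated run: min-F history equals survivor-curve F on the mean path
  sc <- survivor_curve(1, tr$times, tr$T_mean, kin)
  expect_equal(tr$F_min, sc$F_s, tolerance = 1e-6)
  expect_true(all(diff(tr$F_min) >= 0))
})

test_that("halving dt and doubling the grid barely moves the cooled end state", {
  bc <- thermal_bc(U = 5, T_inf = 286.15)
  coarse <- run_simulation(process_config(thermal_bc = bc), tab5)
  fine <- run_simulation(process_config(nr = 32, nz = 32, dt = 0.25,
                                        thermal_bc = bc), tab5)
  expect_lt(abs(min(fine$T) - min(coarse$T)), 0.2)
})

test_that("configuration invariants are enforced", {
  expect_error(process_config(duration = 0), "duration")
  expect_error(process_config(dt = 2, duration = 1), "dt")
  expect_error(process_config(applied_voltage = -5), "applied_voltage")
  expect_error(run_simulation(process_config(), tab5, extend_to_target = TRUE),
               "kinetics")
})
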