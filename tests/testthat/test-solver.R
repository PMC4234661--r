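test_that("Courant bound reproduces hand-computed values", {
  expect_equal(max_stable_timestep(default_tissue_registry()) * 1e9, 122.97,
               tolerance = 1e-4)
  expect_equal(max_stable_timestep(347), 1.6638e-6, tolerance = 1e-4)
  expect_equal(max_stable_timestep(1540), 374.93e-9, tolerance = 1e-4)
  expect_equal(max_stable_timestep(1540, scheme = "yee24"),
               374.93e-9 * 6 / 7, tolerance = 1e-4)
  expect_error(max_stable_timestep(numeric(0)), "empty material set")
})

test_that("spatial sampling check flags under-resolved wavelengths", {
  s <- check_spatial_sampling(347, 40e3, 1e-3)
  expect_equal(s$wavelength, 8.675e-3)
  expect_equal(s$points_per_wavelength, 8.675)
  expect_equal(check_spatial_sampling(1540, 40e3)$wavelength, 38.5e-3)
  expect_warning(check_spatial_sampling(347, 100e3, 1e-3), "under-resolves")
})

test_that("velocity update: zero gradient, polynomial exactness, overdamping", {
  reg <- lossless_registry()
  dims <- c(12L, 8L, 8L)
  grid <- make_soft_tissue_phantom(dims)
  fields <- derive_material_fields(grid, reg)
  dt <- 1e-7
  # uniform pressure -> velocity stays zero
  st <- simulation_state(dims)
  st$p[] <- 3.3
  step_velocity(st, fields, dt)
  expect_true(all(st$vx == 0) && all(st$vy == 0) && all(st$vz == 0))
  # linear ramp in x -> uniform vx increment -dt*slope/rho at interior nodes
  st <- simulation_state(dims)
  slope <- 250  # Pa per metre
  for (i in seq_len(dims[1])) st$p[i, , ] <- slope * (i - 1) * 1e-3
  step_velocity(st, fields, dt)
  expect_equal(as.vector(st$vx), rep(-dt * slope / 1000, length(st$vx)),
               tolerance = 1e-12)
  expect_true(all(st$vy == 0) && all(st$vz == 0))
  # huge sigma drives velocity toward zero despite the gradient
  lossy <- tissue_registry(data.frame(id = 255L, name = "sponge",
                                      density_kg_m3 = 1000, speed_m_s = 1540,
                                      atten_db_cm_mhz = 1e6))
  fl <- derive_material_fields(grid, lossy)
  st2 <- simulation_state(dims)
  for (i in seq_len(dims[1])) st2$p[i, , ] <- slope * (i - 1) * 1e-3
  st2$vx[] <- 1e-3
  step_velocity(st2, fl, dt)
  expect_true(max(abs(st2$vx)) < 1e-3)
})

test_that("pressure update: divergence-free fields leave pressure unchanged", {
  reg <- lossless_registry()
  dims <- c(12L, 10L, 9L)
  grid <- make_soft_tissue_phantom(dims)
  fields <- derive_material_fields(grid, reg)
  dt <- 1e-7
  st <- simulation_state(dims)
  st$p[] <- 1.5
  step_pressure(st, fields, dt)  # v = 0 everywhere
  expect_true(all(st$p == 1.5))
  # uniform velocity: interior divergence is zero (boundaries see the walls)
  st <- simulation_state(dims)
  st$vx[] <- 1e-4
  step_pressure(st, fields, dt)
  interior <- st$p[3:(dims[1] - 2), 3:(dims[2] - 2), 3:(dims[3] - 2)]
  expect_true(all(interior == 0))
})

test_that("a pulse travels at the material sound speed", {
  reg <- default_tissue_registry()
  dims <- c(200L, 8L, 8L)
  grid <- make_soft_tissue_phantom(dims)
  dt <- max_stable_timestep(1540, 1e-3, "yee24") * 0.9
  n_steps <- 250L
  cfg <- simulation_config(dt, n_steps, output_rate = 1 / dt,
                           boundary = "rigid")
  p0 <- plane_pulse(dims, center = 50, width = 8)  # >= 8 voxels per wavelength
  res <- run_simulation(grid, reg, cfg, list(), list(), initial_pressure = p0)
  row <- res$state$p[, 4, 4]
  peak <- 100 + which.max(row[101:200])  # right-moving half of the split pulse
  travelled <- (peak - 50) * 1e-3
  expect_equal(travelled, 1540 * n_steps * dt, tolerance = 0.02)
})

test_that("hard sources overwrite the disc with the drive signal", {
  dims <- c(24L, 24L, 24L)
  st <- simulation_state(dims)
  st$p[] <- 0.5
  src <- source_spec(c(11, 5, 11), frequency = 40e3, phase_deg = 0,
                     level_db = 105, axis = "y")
  inject_sources(st, src, t = 0)
  a <- spl_to_pressure(105)
  disc <- st$p[, 6, ]
  expect_equal(sum(disc == 0), 113)  # voxelized 6 mm disc, sin(0) = 0
  expect_true(all(st$p[, 7, ] == 0.5))
  # 90 degrees -> exactly the amplitude
  st2 <- simulation_state(dims)
  src90 <- source_spec(c(11, 5, 11), frequency = 40e3, phase_deg = 90,
                       level_db = 105, axis = "y")
  inject_sources(st2, src90, t = 0)
  expect_equal(max(st2$p), a, tolerance = 1e-12)
  # periodicity of the drive: steps 0 and 50 carrier periods later agree
  dt <- 1 / (40e3 * 204.08)
  v0 <- a * sin(2 * pi * 40e3 * 0)
  v1 <- a * sin(2 * pi * 40e3 * 10204 * dt)
  expect_lt(abs(v1 - v0), 1e-6 * a)
  # disc outside the domain is refused
  bad <- source_spec(c(60, 5, 11), frequency = 40e3, axis = "y")
  expect_error(inject_sources(simulation_state(dims), bad, 0),
               "outside domain")
})

test_that("acoustic energy is conserved losslessly and dissipated with loss", {
  dims <- c(32L, 32L, 32L)
  grid <- make_soft_tissue_phantom(dims)
  # lossless closed box: windowed-mean energy drift under 1% over 1000 steps
  reg0 <- lossless_registry()
  fields <- derive_material_fields(grid, reg0)
  dt <- max_stable_timestep(1540, 1e-3, "yee24") * 0.5
  coef <- solver_coefficients(fields, dt)
  st <- simulation_state(dims)
  st$p[] <- gaussian_ball(dims)
  expect_identical(acoustic_energy(simulation_state(dims), fields), 0)
  E <- numeric(1000)
  for (n in 1:1000) {
    step_velocity(st, fields, dt, coef, check = FALSE)
    step_pressure(st, fields, dt, coef, check = FALSE)
    E[n] <- acoustic_energy(st, fields)
  }
  drift <- abs(mean(E[951:1000]) / mean(E[1:50]) - 1)
  expect_lt(drift, 0.01)
  # lossy box (muscle, alpha = 3.3): energy decays, window means monotone
  regl <- default_tissue_registry()
  fl <- derive_material_fields(voxel_grid(array(180L, dim = dims)), regl)
  cl <- solver_coefficients(fl, dt)
  st2 <- simulation_state(dims)
  st2$p[] <- gaussian_ball(dims)
  E2 <- numeric(400)
  for (n in 1:400) {
    step_velocity(st2, fl, dt, cl, check = FALSE)
    step_pressure(st2, fl, dt, cl, check = FALSE)
    E2[n] <- acoustic_energy(st2, fl)
  }
  m <- colMeans(matrix(E2, nrow = 50))
  expect_true(all(diff(m) < 0))
  expect_lt(E2[400], E[1000])
})

test_that("runs are stable just under the (2,4) bound and blow up at 1.2x", {
  reg <- default_tissue_registry()
  dims <- c(32L, 32L, 32L)
  grid <- make_soft_tissue_phantom(dims)
  p0 <- gaussian_ball(dims)
  ok <- simulation_config(max_stable_timestep(1540, 1e-3, "yee24") * 0.999,
                          n_steps = 1000L, boundary = "rigid")
  res <- run_simulation(grid, reg, ok, list(), list(), initial_pressure = p0)
  expect_true(all(is.finite(res$state$p)))
  bad <- simulation_config(max_stable_timestep(1540, 1e-3, "yee22") * 1.2,
                           n_steps = 2000L, boundary = "rigid")
  expect_warning(
    expect_error(
      run_simulation(grid, reg, bad, list(), list(), initial_pressure = p0),
      "instability: non-finite"),
    "Courant")
})

test_that("mirrored geometry yields mirrored (identical) traces", {
  reg <- default_tissue_registry()
  dims <- c(32L, 32L, 32L)
  labs <- array(255L, dim = dims)
  labs[6:12, 10:20, 8:24] <- 180L  # asymmetric muscle inclusion
  grid <- voxel_grid(labs)
  labs_m <- labs[dims[1]:1, , ]
  grid_m <- voxel_grid(labs_m)
  dt <- max_stable_timestep(1579, 1e-3, "yee24") * 0.9
  cfg <- simulation_config(dt, n_steps = 300L, output_rate = 1 / dt,
                           boundary = "mur")
  mirror_x <- function(x_mm) (dims[1] - 1) - x_mm
  src <- source_spec(c(8, 4, 15), frequency = 40e3, axis = "y",
                     radius_mm = 3, baffle_mm = 2)
  src_m <- source_spec(c(mirror_x(8), 4, 15), frequency = 40e3, axis = "y",
                       radius_mm = 3, baffle_mm = 2)
  mic <- microphone_spec(c(20, 25, 15))
  mic_m <- microphone_spec(c(mirror_x(20), 25, 15))
  r1 <- run_simulation(grid, reg, cfg, list(src), list(mic))
  r2 <- run_simulation(grid_m, reg, cfg, list(src_m), list(mic_m))
  expect_identical(r1$traces[[1]]$samples, r2$traces[[1]]$samples)
})

test_that("a single ultrasonic source produces its own carrier at the mic", {
  reg <- default_tissue_registry()
  dims <- c(48L, 48L, 48L)
  grid <- make_soft_tissue_phantom(dims)
  dt <- 1 / (96e3 * 35)
  cfg <- simulation_config(dt, n_steps = 35L * 96L, boundary = "mur")  # 1 ms
  src <- source_spec(c(23.5, 4, 23.5), frequency = 40e3, axis = "y")
  mic <- microphone_spec(c(23.5, 24, 23.5))
  res <- run_simulation(grid, reg, cfg, list(src), list(mic))
  f <- dominant_frequency(res$traces[[1]], 20e3, 47e3)
  expect_equal(f, 40e3, tolerance = 0.02)
  # zero-step runs return empty traces
  res0 <- run_simulation(grid, reg,
                         simulation_config(dt, 0L, boundary = "mur"),
                         list(src), list(mic))
  expect_length(res0$traces[[1]]$samples, 0L)
})

test_that("Mur boundaries absorb normally incident waves; rigid walls do not", {
  reg <- default_tissue_registry()
  dims <- c(256L, 8L, 8L)
  grid <- make_soft_tissue_phantom(dims)
  p0 <- plane_pulse(dims, center = 180, width = 10)
  dt <- max_stable_timestep(1540, 1e-3, "yee24") * 0.9
  mic <- microphone_spec(c(200, 3, 3))
  cfg <- simulation_config(dt, n_steps = 600L, output_rate = 1 / dt,
                           boundary = "mur", mur_faces = c("x0", "x1"))
  tr <- run_simulation(grid, reg, cfg, list(), list(mic),
                       initial_pressure = p0)$traces[[1]]$samples
  refl_mur <- max(abs(tr[300:600])) / max(abs(tr[1:200]))
  expect_lt(refl_mur, 0.02)
  cfg_rigid <- simulation_config(dt, n_steps = 600L, output_rate = 1 / dt,
                                 boundary = "rigid")
  tr2 <- run_simulation(grid, reg, cfg_rigid, list(), list(mic),
                        initial_pressure = p0)$traces[[1]]$samples
  expect_gt(max(abs(tr2[300:600])) / max(abs(tr2[1:200])), 0.5)
})

test_that("3D Mur box lets a pulse leave with little residual energy", {
  dims <- c(48L, 48L, 48L)
  grid <- make_soft_tissue_phantom(dims)
  fields <- derive_material_fields(grid, lossless_registry())
  dt <- max_stable_timestep(1540, 1e-3, "yee24") * 0.9
  coef <- solver_coefficients(fields, dt)
  st <- simulation_state(dims)
  st$p[] <- gaussian_ball(dims)
  E <- numeric(300)
  for (n in 1:300) {
    step_velocity(st, fields, dt, coef, check = FALSE)
    step_pressure(st, fields, dt, coef, check = FALSE)
    apply_mur_boundary(st, fields, dt, coef)
    E[n] <- acoustic_energy(st, fields)
  }
  expect_lt(E[300] / max(E), 0.05)
})

test_that("1D amplitude decay matches the attenuation coefficient", {
  reg <- default_tissue_registry()
  dims <- c(256L, 8L, 8L)
  grid <- voxel_grid(array(180L, dim = dims))  # muscle
  dt <- max_stable_timestep(1579, 1e-3, "yee24") * 0.9
  cfg <- simulation_config(dt, n_steps = 1400L, output_rate = 1 / dt,
                           boundary = "mur", mur_faces = c("x0", "x1"))
  src <- source_spec(c(5, 3, 3), frequency = 40e3, axis = "x",
                     baffle_mm = 0)
  xs <- seq(40, 200, by = 4)
  mics <- lapply(xs, function(x) microphone_spec(c(x, 3, 3)))
  res <- run_simulation(grid, reg, cfg, list(src), mics)
  per <- ceiling(1 / (40e3 * dt))
  amp <- vapply(res$traces, function(tr) {
    s <- tr$samples
    max(abs(s[(length(s) - 3 * per):length(s)]))
  }, numeric(1))
  fit <- stats::lm(log(amp) ~ I(xs / 1000))
  alpha_hat <- -unname(stats::coef(fit)[2])
  alpha_expect <- attenuation_to_sigma(3.3, 40e3, 1090, 1579) /
    (2 * 1090 * 1579)
  expect_equal(alpha_hat, alpha_expect, tolerance = 0.05)
})
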