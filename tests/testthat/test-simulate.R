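test_that("noiseless CTF-free micrograph equals the rendered projection", {
  lat <- mini_lattice()
  un <- mini_unit()
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 128, snr = Inf,
                           ctf = NULL, filaments_per_micrograph = 1, seed = 1)
  inst <- filament_instance(lat, 9, NULL, centre = c(0, 0),
                            direction_deg = 15, roll_deg = 40)
  sim <- simulate_micrograph(list(inst), un, cfg)
  # oracle: render the same instance in 3D and sum along z
  vol <- suppressWarnings(render_volume(un, inst$unit_poses, 128, 4))
  zsum <- apply(vol$values, c(1, 2), sum)
  expect_lt(max(abs(sim$micrograph$values - zsum)) / max(abs(zsum)), 1e-4)
})

test_that("empty instance list gives pure noise of the requested sd", {
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 2048, snr = 1,
                           noise_sd = 0.7, seed = 5)
  sim <- simulate_micrograph(list(), mini_unit(), cfg)
  v <- sim$micrograph$values
  expect_gt(length(v), 4e6)
  expect_lt(abs(mean(v)), 0.01)
  expect_lt(abs(stats::sd(v) - 0.7) / 0.7, 0.02)
  expect_equal(nrow(sim$truth$units), 0)
})

test_that("measured footprint SNR matches the requested value", {
  lat <- mini_lattice()
  un <- mini_unit()
  ratios <- vapply(1:50, function(r) {
    cfg <- simulation_config(pixel_size = 4, micrograph_shape = 192, snr = 1,
                             ctf = NULL, filaments_per_micrograph = 1,
                             seed = 1000 + r)
    inst <- filament_instance(lat, 12, NULL, centre = c(0, 0),
                              direction_deg = 5, roll_deg = 30 * r)
    sim <- simulate_micrograph(list(inst), un, cfg)
    noise <- sim$micrograph$values - sim$clean$values
    stats::var(sim$clean$values[sim$footprint]) /
      stats::var(noise[sim$footprint])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("identical config and seed give bit-identical output", {
  lat <- mini_lattice()
  un <- mini_unit()
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 128, snr = 0.5,
                           filaments_per_micrograph = 1, seed = 9)
  inst <- filament_instance(lat, 8, flex_params(seed = 3), centre = c(0, 0))
  a <- simulate_micrograph(list(inst), un, cfg)
  b <- simulate_micrograph(list(inst), un, cfg)
  expect_identical(a$micrograph$values, b$micrograph$values)
  expect_identical(a$truth, b$truth)
  ds1 <- simulate_dataset(lat, un, cfg, n_micrographs = 1, n_units = 8)
  ds2 <- simulate_dataset(lat, un, cfg, n_micrographs = 1, n_units = 8)
  expect_identical(ds1$micrographs[[1]]$micrograph$values,
                   ds2$micrographs[[1]]$micrograph$values)
})

test_that("truth tables record every unit with valid poses", {
  lat <- mini_lattice()
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 256,
                           filaments_per_micrograph = 2, seed = 2)
  ds <- simulate_dataset(lat, mini_unit(), cfg, n_micrographs = 2, n_units = 10)
  tu <- ds$truth$units
  expect_equal(nrow(tu), 2 * 2 * 10)
  expect_true(all(is.finite(as.matrix(tu[, c("rot", "tilt", "psi", "x", "y", "z")]))))
  # per-micrograph defocus variation within the configured range
  expect_true(all(tu$defocus_u >= 8000 & tu$defocus_u <= 16000))
  expect_gt(length(unique(tu$defocus_u)), 1)
})
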