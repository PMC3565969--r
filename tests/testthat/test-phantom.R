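test_that("rendered cells hit their target volume through the optics", {
  cfg <- optical_config()
  grid <- c(160L, 160L)
  for (shape in c("flat_disc", "spherocyte", "biconcave")) {
    sp <- cell_spec(center_xy = c(12, 12), shape = shape,
                    target_volume_fl = 90)
    ph <- make_rbc_phase(sp, grid, cfg)
    h <- phase_to_height(ph, cfg)
    vol <- sum(h$values) * cfg$pixel_pitch_um^2
    expect_equal(vol, 90, tolerance = 0.01)
  }
  # flat disc: uniform thickness, footprint close to pi r^2
  sp <- cell_spec(center_xy = c(12, 12), shape = "flat_disc",
                  target_volume_fl = 90)
  h <- phase_to_height(make_rbc_phase(sp, grid, cfg), cfg)$values
  fp <- sum(h > 0) * cfg$pixel_pitch_um^2
  expect_equal(fp, pi * sp$radius_um^2, tolerance = 0.03)
})

test_that("circularly symmetric cells are rotation invariant", {
  cfg <- optical_config()
  a <- make_rbc_phase(cell_spec(c(10, 10), "biconcave", 90, rotation = 0),
                      c(128L, 128L), cfg)
  b <- make_rbc_phase(cell_spec(c(10, 10), "biconcave", 90,
                                rotation = pi / 3), c(128L, 128L), cfg)
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("cell placement and spec validation raise clean errors", {
  cfg <- optical_config()
  sp <- cell_spec(center_xy = c(1, 10), shape = "biconcave",
                  target_volume_fl = 90)
  expect_error(make_rbc_phase(sp, c(128L, 128L), cfg), "outside")
  expect_error(cell_spec(shape = "platelet", target_volume_fl = 25),
               "20 fL")
  expect_error(cell_spec(target_volume_fl = -5), "> 0")
})

test_that("population sampling matches its statistical contract", {
  # zero width: every volume equals the mean
  pop <- sample_population(20, 90, 0, c(biconcave = 1), seed = 1)
  expect_true(all(vapply(pop, `[[`, 0, "target_volume_fl") == 90))
  # large draw: mean within 1%, CV within 0.5 percentage points
  pop <- sample_population(1e4, 90, 15, c(biconcave = 1), seed = 2)
  v <- vapply(pop, `[[`, 0, "target_volume_fl")
  expect_equal(mean(v), 90, tolerance = 0.01)
  expect_lt(abs(100 * sd(v) / mean(v) - 15), 0.5)
  expect_true(all(v > 20))
  # platelet fraction: binomial count within 4 sigma
  pop <- sample_population(2000, 90, 15,
                           c(biconcave = 0.9, platelet = 0.1), seed = 3)
  shapes <- vapply(pop, `[[`, "", "shape")
  n_plt <- sum(shapes == "platelet")
  expect_lt(abs(n_plt - 200), 4 * sqrt(2000 * 0.1 * 0.9))
  plt_v <- vapply(pop[shapes == "platelet"], `[[`, 0, "target_volume_fl")
  expect_true(all(plt_v < 20))
  # infeasible truncation: mean far below the 20 fL bound
  expect_error(sample_population(10, 15, 10, c(biconcave = 1), seed = 1),
               "infeasible|exceed")
  # determinism
  p1 <- sample_population(50, 90, 15, seed = 7)
  p2 <- sample_population(50, 90, 15, seed = 7)
  expect_identical(p1, p2)
})

test_that("interferogram model enforces the 3 px/fringe sampling rule", {
  expect_error(interferogram_model(carrier = c(0.4, 0)), "3 px")
  expect_error(interferogram_model(carrier = c(0.3, 0.2)), "3 px")
  expect_error(interferogram_model(fringe_contrast = 0), "contrast")
  expect_error(interferogram_model(fringe_contrast = 1.2), "contrast")
  m <- interferogram_model(carrier = c(1 / 3, 0))
  expect_equal(m$carrier[1], 1 / 3)
})

test_that("interferogram synthesis is deterministic and spectrally correct", {
  cfg <- optical_config()
  sc <- build_scene(list(), c(96L, 96L), cfg, seed = 1,
                    aberration_amplitude_rad = 0, n_dirt = 0)
  m <- interferogram_model(carrier = c(0.25, 0), noise_sd = 100)
  i1 <- synthesize_interferogram(sc, m, seed = 11)
  i2 <- synthesize_interferogram(sc, m, seed = 11)
  expect_identical(i1$values, i2$values)
  # flat-phase spectrum: dominant non-DC peak exactly at the carrier
  expect_equal(estimate_carrier(i1), c(0.25, 0), tolerance = 1 / 96)
  # conjugate first-order lobes present and symmetric
  F <- Mod(fft(i1$values))
  k <- 0.25 * 96 + 1
  expect_gt(F[1, k], 10 * median(F))
  expect_gt(F[1, 96 - 0.25 * 96 + 1], 10 * median(F))
})

test_that("background frames share the sample's dirt and aberration", {
  cfg <- optical_config()
  sc <- build_scene(list(cell_spec(c(8, 8), "biconcave", 90)),
                    c(128L, 128L), cfg, seed = 4,
                    aberration_amplitude_rad = 0.4, n_dirt = 5)
  m <- interferogram_model(noise_sd = 0)
  bg <- make_background_frame(sc, m)
  # removing the cells from the scene reproduces the background frame
  sc_empty <- sc
  sc_empty$true_phase <- sc$aberration + sc$dirt
  expect_identical(bg$values,
                   synthesize_interferogram(sc_empty, m)$values)
  expect_gt(max(sc$dirt), 0)
})

test_that("scenes reject overlapping cell placements", {
  cfg <- optical_config()
  cells <- list(cell_spec(c(10, 10), "biconcave", 90),
                cell_spec(c(11, 10), "biconcave", 90))
  expect_error(build_scene(cells, c(192L, 192L), cfg, seed = 1), "overlap")
})

test_that("scene ground truth records volume and quadrature surface area", {
  cfg <- optical_config()
  sc <- tiny_scene(volumes = c(80, 100), seed = 9)
  expect_equal(sc$truth$true_volume_fl, c(80, 100))
  # spherocyte dome (default radius makes the rescale ~1): half prolate
  # spheroid with semi-axes (R, R, 2R) plus its base, closed form
  sp <- cell_spec(c(10, 10), "spherocyte", 90)
  sc2 <- build_scene(list(sp), c(160L, 160L), cfg, seed = 2,
                     aberration_amplitude_rad = 0, n_dirt = 0)
  R <- sp$radius_um; e <- sqrt(1 - 1 / 4)
  closed <- pi * R^2 + pi * R * 2 * R / e * asin(e) + pi * R^2
  expect_equal(sc2$truth$true_surface_area_um2, closed, tolerance = 2e-3)
  # cylinder: top + base + side wall
  sp3 <- cell_spec(c(10, 10), "flat_disc", 90)
  sc3 <- build_scene(list(sp3), c(160L, 160L), cfg, seed = 2,
                     aberration_amplitude_rad = 0, n_dirt = 0)
  R3 <- sp3$radius_um
  expect_equal(sc3$truth$true_surface_area_um2,
               2 * pi * R3^2 + 2 * pi * R3 * 2, tolerance = 5e-3)
  # PSF preserves each cell's integrated volume on the grid
  vol_grid <- sum(sc2$cell_phase) * cfg$pixel_pitch_um^2 *
    (cfg$wavelength_nm / 1000) / (2 * pi * cfg$delta_n)
  expect_equal(vol_grid, 90, tolerance = 1e-6)
})
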