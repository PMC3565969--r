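carrier_field <- function(n, u, v = 0, phi = 0, A = 20000, m = 0.8) {
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  A * (1 + m * cos(2 * pi * (u * X + v * Y) + phi))
}

test_that("carrier estimation finds the first-order lobe", {
  n <- 256
  I <- carrier_field(n, 0.25)
  expect_equal(estimate_carrier(I), c(0.25, 0), tolerance = 1 / n)
  # rotated fringes: both components recovered
  I2 <- carrier_field(n, 0.22, 0.08)
  est <- estimate_carrier(I2)
  expect_lt(abs(est[1] - 0.22), 1 / n + 1e-12)
  expect_lt(abs(est[2] - 0.08), 1 / n + 1e-12)
  # uniform image carries no fringes
  expect_error(estimate_carrier(matrix(1000, n, n)), "no-fringe")
})

test_that("demodulation recovers phase from noiseless fringes", {
  n <- 256
  # flat phase: wrapped output is constant
  ph <- demodulate(carrier_field(n, 0.25), c(0.25, 0))
  expect_true(ph$wrapped)
  expect_lt(sd(ph$values), 1e-6)
  expect_true(all(ph$values >= -pi & ph$values < pi))
  # smooth in-band bump, peak 2 rad: round trip accurate away from border
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  phi <- 2 * exp(-((X - n / 2)^2 + (Y - n / 2)^2) / (2 * 12^2))
  rec <- unwrap_phase(demodulate(carrier_field(n, 0.25, phi = phi),
                                 c(0.25, 0)))
  core <- 17:(n - 16)
  err <- rec$values - phi
  err <- err - median(err[core, core])
  expect_lt(sqrt(mean(err[core, core]^2)), 0.02)
  # conjugate lobe: negated carrier yields negated phase
  neg <- unwrap_phase(demodulate(carrier_field(n, 0.25, phi = phi),
                                 c(-0.25, 0)))
  s <- neg$values + phi
  s <- s - median(s[core, core])
  expect_lt(sqrt(mean(s[core, core]^2)), 0.02)
})

test_that("demodulation rejects overlapping filter windows", {
  I <- carrier_field(64, 0.25)
  expect_error(demodulate(I, c(0.25, 0), filter_radius = 0.25),
               "lobe-overlap")
  expect_error(demodulate(I, c(0.25, 0), filter_radius = 0.3),
               "lobe-overlap")
})

test_that("unwrapping recovers a multi-cycle ramp and honours congruence", {
  n <- 128
  ramp <- matrix(seq(0, 6 * pi, length.out = n), n, n, byrow = TRUE)
  w <- wrap_phase(ramp)
  un <- unwrap_phase(phase_map(w, 0.16, wrapped = TRUE))
  err <- un$values - ramp
  err <- err - err[1, 1]  # global 2*pi*k offset allowed
  expect_lt(max(abs(err)), 1e-6)
  expect_equal(attr(un, "residues"), 0)
})

test_that("unwrap congruence holds on arbitrary random fields", {
  for (s in 1:8) {
    psi <- withr::with_seed(s, {
      base <- matrix(rnorm(48 * 48, sd = 2), 48, 48)
      wrap_phase(base)
    })
    un <- suppressMessages(unwrap_phase(psi))
    # wrap(unwrap(psi)) == psi: difference is an exact multiple of 2*pi
    k <- (un - psi) / (2 * pi)
    expect_lt(max(abs(k - round(k))), 1e-9)
    expect_equal(wrap_phase(un), psi, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # a smooth field already inside (-pi, pi) is returned unchanged up to
  # a global 2*pi*k
  sm <- outer(seq(-1, 1, length.out = 32), seq(-1, 1, length.out = 32),
              function(a, b) 1.5 * exp(-(a^2 + b^2)))
  un <- unwrap_phase(sm)
  d <- un - sm
  expect_lt(max(abs(d - d[1, 1])), 1e-9)
  expect_equal(d[1, 1] / (2 * pi), round(d[1, 1] / (2 * pi)),
               tolerance = 1e-9)
})

test_that("background subtraction removes dirt and aberrations", {
  # identity: sample equals background
  a <- phase_map(matrix(runif(64, 0, 2), 8, 8), 0.16)
  z <- subtract_background(a, a)
  expect_true(all(z$values == 0))
  expect_true(z$background_subtracted)
  # offset invariance
  b <- phase_map(a$values + 0.7, 0.16)
  s1 <- subtract_background(b, a)
  a2 <- phase_map(a$values + 1.3, 0.16)
  b2 <- phase_map(b$values + 1.3, 0.16)
  expect_equal(subtract_background(b2, a2)$values, s1$values,
               tolerance = 1e-9)
  # grid mismatch
  expect_error(
    subtract_background(a, phase_map(matrix(0, 4, 4), 0.16)),
    "grid mismatch")
  # phantom: corrected cell-free region is flat, uncorrected is not
  sc <- tiny_scene(volumes = c(85, 95), seed = 11, aberration = 0.5,
                   n_dirt = 5)
  m <- interferogram_model(noise_sd = 0)
  samp <- unwrap_phase(demodulate(synthesize_interferogram(sc, m),
                                  m$carrier))
  bg <- unwrap_phase(demodulate(make_background_frame(sc, m), m$carrier))
  corr <- subtract_background(samp, bg)
  free <- sc$cell_phase < 1e-3
  free[c(1:16, 177:192), ] <- FALSE
  free[, c(1:16, 177:192)] <- FALSE
  expect_lt(sqrt(mean(corr$values[free]^2)), 0.05)
  un_off <- samp$values - median(samp$values[free])
  expect_gt(sqrt(mean(un_off[free]^2)), 0.05)
})
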