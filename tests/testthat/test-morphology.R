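test_that("projected area and equivalent diameter are exact arithmetic", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(projected_area(m, 0.1), 1.00)
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(projected_area(m1, 0.16), 0.16^2)
  expect_error(projected_area(matrix(FALSE, 3, 3), 0.1), "degenerate")
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(4 * pi), 4)
  expect_error(equivalent_diameter(0), "> 0")
  # rasterized disc: area within a pixel ring of pi r^2
  d <- disc_mask(101, 51, 51, 30)
  pa <- projected_area(d, 1)
  expect_lt(abs(pa - pi * 900), 2 * pi * 30 * 1.5)
})

test_that("volume integration is the box sum and scales with 1/dn", {
  m <- matrix(FALSE, 10, 10); m[1:9, 1:5] <- TRUE  # 45 px
  h <- matrix(2, 10, 10)
  expect_equal(as.numeric(cell_volume(h, m, 1)), 90)  # 45 um^2 x 2 um
  # halving the index contrast doubles the reported volume
  cfg1 <- optical_config(mchc_g_dl = NULL, n_cell_override = 1.337 + 0.06)
  cfg2 <- optical_config(mchc_g_dl = NULL, n_cell_override = 1.337 + 0.03)
  ph <- matrix(1.2, 10, 10)
  v1 <- cell_volume(phase_to_height(ph, cfg1), m, 1)
  v2 <- cell_volume(phase_to_height(ph, cfg2), m, 1)
  expect_equal(as.numeric(v2) / as.numeric(v1), 2, tolerance = 1e-12)
  # clamping
  h[3, 3] <- -1
  v <- cell_volume(h, m, 1)
  expect_equal(attr(v, "n_clamped"), 1L)
  expect_equal(as.numeric(v), 88)
})

test_that("Monge surface area matches closed forms", {
  # flat patch: zero gradients, SA = 2 PA
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE
  h <- matrix(1.5, 12, 12)
  expect_equal(cell_surface_area(h, m, 0.5), 2 * projected_area(m, 0.5),
               tolerance = 1e-12)
  # tilted plane h = x: gradient (1, 0) everywhere (one-sided differences
  # are exact for a linear field), top = sqrt(2) A, total = (1 + sqrt(2)) A
  n <- 20
  hp <- matrix(rep((1:n) * 0.3, each = n), n, n)
  mp <- matrix(TRUE, n, n)
  A <- projected_area(mp, 0.3)
  expect_equal(cell_surface_area(hp, mp, 0.3), (1 + sqrt(2)) * A,
               tolerance = 1e-9)
  # discretized spherical cap vs closed form (cap height a, sphere R):
  # top = 2 pi R a, base = pi a (2R - a)
  R <- 4; a <- 2; p <- 0.16
  ax <- (1:61 - 31) * p
  hc <- pmax(sqrt(pmax(R^2 - outer(ax^2, ax^2, "+"), 0)) - (R - a), 0)
  mc <- hc > 0
  expect_gt(sum(mc[31, ]), 20)  # at least 20 px across
  expect_equal(cell_surface_area(hc, mc, p),
               2 * pi * R * a + pi * a * (2 * R - a), tolerance = 0.02)
})

test_that("sphericity attains 1 on a sphere and decreases with excess SA", {
  r <- 3
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1,
               tolerance = 1e-12)
  expect_equal(sphericity(90, 135), 0.71938, tolerance = 1e-4)
  sa <- seq(120, 200, by = 10)
  expect_true(all(diff(sphericity(90, sa)) < 0))
  expect_error(sphericity(0, 10), "> 0")
})

test_that("MCD solves the sphero-cylinder cubic", {
  # sphere identity: the cylinder degenerates and D = 2r
  for (r in c(0.8, 2, 3.5)) {
    V <- 4 / 3 * pi * r^3; SA <- 4 * pi * r^2
    expect_equal(minimum_cylindrical_diameter(V, SA), 2 * r,
                 tolerance = 1e-6)
  }
  # independent oracle: bisection on the cubic, smallest positive root
  V <- 90; SA <- 135
  f <- function(D) pi * D^3 - 3 * SA * D + 12 * V
  lo <- 1e-6; hi <- 2 * (3 * V / (4 * pi))^(1 / 3)  # below sphere diameter
  oracle <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  expect_equal(minimum_cylindrical_diameter(V, SA), oracle,
               tolerance = 1e-9)
  expect_equal(oracle, 2.8454, tolerance = 1e-4)
  # more surface at fixed volume -> smaller minimal capillary
  mcds <- vapply(seq(135, 175, by = 10),
                 function(s) minimum_cylindrical_diameter(90, s), 0)
  expect_true(all(diff(mcds) < 0))
  # infeasible: SA below the sphere bound (sphericity > 1)
  expect_error(minimum_cylindrical_diameter(90, 50), "infeasible")
})

test_that("extended parameters match analytic shapes", {
  # rasterized disc: eccentricity ~ 0, circularity ~ 1
  d <- disc_mask(101, 51, 51, 40)
  ex <- extended_parameters(matrix(1, 101, 101), d, NULL, 1)
  expect_lt(ex$eccentricity, 0.05)
  expect_equal(ex$circularity, 1, tolerance = 0.05)
  # circularity approaches 1 from a coarser disc
  d2 <- disc_mask(31, 16, 16, 10)
  ex2 <- extended_parameters(matrix(1, 31, 31), d2, NULL, 1)
  expect_lt(abs(ex$circularity - 1), abs(ex2$circularity - 1) + 0.02)
  # 2:1 ellipse: eccentricity sqrt(3)/2
  el <- outer(1:81, 1:81,
              function(i, j) ((j - 41) / 30)^2 + ((i - 41) / 15)^2 <= 1)
  exe <- extended_parameters(matrix(1, 81, 81), el, NULL, 1)
  expect_equal(exe$eccentricity, sqrt(3) / 2, tolerance = 0.01)
  # uniform height: zero variance, flagged degenerate moments
  expect_equal(ex$height_variance_um2, 0)
  expect_equal(ex$height_skewness, 0)
  expect_equal(ex$height_kurtosis, 0)
  expect_true(ex$degenerate_height)
  # integrated density sums phase over the mask
  ph <- matrix(0.5, 101, 101)
  exd <- extended_parameters(matrix(1, 101, 101), d, ph, 1)
  expect_equal(exd$integrated_density_rad_px, 0.5 * sum(d))
  # too-small mask
  tiny <- matrix(FALSE, 3, 3); tiny[1, 1] <- TRUE; tiny[2, 2] <- TRUE
  expect_error(extended_parameters(matrix(1, 3, 3), tiny, NULL, 1),
               "degenerate")
})

test_that("thickness statistics describe the height distribution", {
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  h <- matrix(0, 6, 6)
  h[2:5, 2:5] <- matrix(c(rep(1, 8), rep(3, 8)), 4, 4)
  ex <- extended_parameters(h, m, NULL, 1)
  expect_equal(ex$min_thickness_um, 1)
  expect_equal(ex$max_thickness_um, 3)
  expect_equal(ex$mean_thickness_um, 2)
  # population-normalised variance of {1,3} half-half is 1
  expect_equal(ex$height_variance_um2, 1)
  expect_equal(ex$height_skewness, 0)
  expect_equal(ex$height_kurtosis, 1)  # raw kurtosis of a symmetric 2-point law
  expect_false(ex$degenerate_height)
})

test_that("refinement moves volume and surface area toward truth", {
  # spherical cap measured at successively finer pitch
  R <- 4; a <- 2
  sa_true <- 2 * pi * R * a + pi * a * (2 * R - a)
  v_true <- pi * a^2 * (R - a / 3)
  errs <- sapply(c(0.4, 0.2, 0.1), function(p) {
    n <- 2 * ceiling(3.6 / p) + 5
    ax <- (1:n - (n + 1) / 2) * p
    h <- pmax(sqrt(pmax(R^2 - outer(ax^2, ax^2, "+"), 0)) - (R - a), 0)
    m <- h > 0
    c(abs(as.numeric(cell_volume(h, m, p)) - v_true) / v_true,
      abs(cell_surface_area(h, m, p) - sa_true) / sa_true)
  })
  expect_true(all(diff(errs[1, ]) < 0))
  expect_true(all(diff(errs[2, ]) < 0))
})
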