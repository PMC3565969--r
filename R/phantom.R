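#' Specification of one synthetic blood cell
#'
#' Describes a single phase object for the phantom generator: its position,
#' shape family, intended volume and in-plane radius. The rendered height
#' profile is rescaled so that its grid-integrated volume matches
#' `target_volume_fl` exactly; the profile shapes are:
#'
#' * `biconcave` — the classic Evans–Fung normal-RBC thickness profile
#'   `h(r) = sqrt(1 - (r/R)^2) * (C0 + C2 (r/R)^2 + C4 (r/R)^4)` with
#'   `C = (0.81, 7.83, -4.39)` um at `R = 3.91` um, scaled isotropically.
#' * `spherocyte` — the chord-length height field of a sphere,
#'   `h(r) = 2 sqrt(R^2 - r^2)`.
#' * `flat_disc` — a cylinder of uniform thickness (2 um before rescaling).
#' * `platelet` — a thin cylinder (1 um) with volume constrained `< 20` fL.
#'
#' @param center_xy Length-2 numeric, cell centre in micrometres (x, y), or
#'   `NA` to be assigned by [build_scene()].
#' @param shape One of `"biconcave"`, `"spherocyte"`, `"flat_disc"`,
#'   `"platelet"`.
#' @param target_volume_fl Intended cell volume (fL), > 0 (and < 20 for
#'   platelets).
#' @param radius_um In-plane radius (um); default derived from the shape and
#'   volume so that aspect ratios stay realistic.
#' @param rotation In-plane rotation (radians); shapes here are circularly
#'   symmetric so this only affects the sampling coordinates.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(center_xy = c(NA_real_, NA_real_),
                      shape = c("biconcave", "spherocyte", "flat_disc",
                                "platelet"),
                      target_volume_fl = 90,
                      radius_um = NULL,
                      rotation = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(target_volume_fl) || target_volume_fl <= 0)
    stop("`target_volume_fl` must be > 0", call. = FALSE)
  if (shape == "platelet" && target_volume_fl >= 20)
    stop("platelet volumes must be < 20 fL", call. = FALSE)
  if (is.null(radius_um)) radius_um <- default_cell_radius(shape, target_volume_fl)
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("`radius_um` must be > 0", call. = FALSE)
  structure(list(center_xy = as.numeric(center_xy), shape = shape,
                 target_volume_fl = target_volume_fl,
                 radius_um = radius_um, rotation = rotation),
            class = "cell_spec")
}

# Evans-Fung coefficients (um) for the normal biconcave disc of radius 3.91 um.
EVANS_FUNG <- list(R = 3.91, C0 = 0.81, C2 = 7.83, C4 = -4.39)

# Analytic volume of the unscaled Evans-Fung profile:
# V = 2 pi R^2 (C0/3 + 2 C2/15 + 8 C4/105).
evans_fung_volume <- function(R = EVANS_FUNG$R) {
  s <- R / EVANS_FUNG$R
  C0 <- EVANS_FUNG$C0 * s; C2 <- EVANS_FUNG$C2 * s; C4 <- EVANS_FUNG$C4 * s
  2 * pi * R^2 * (C0 / 3 + 2 * C2 / 15 + 8 * C4 / 105)
}

default_cell_radius <- function(shape, volume_fl) {
  switch(shape,
    biconcave  = EVANS_FUNG$R * (volume_fl / evans_fung_volume())^(1 / 3),
    spherocyte = (3 * volume_fl / (4 * pi))^(1 / 3),
    flat_disc  = sqrt(volume_fl / (pi * 2)),
    platelet   = sqrt(volume_fl / (pi * 1)))
}

# Height (um) of the unscaled profile at radial distance r_um from the centre.
cell_height_profile <- function(shape, r_um, radius_um) {
  rho <- r_um / radius_um
  inside <- rho < 1
  h <- numeric(length(r_um))
  if (shape == "biconcave") {
    s <- radius_um / EVANS_FUNG$R
    rr <- rho[inside]^2
    h[inside] <- sqrt(pmax(0, 1 - rr)) *
      s * (EVANS_FUNG$C0 + EVANS_FUNG$C2 * rr + EVANS_FUNG$C4 * rr^2)
  } else if (shape == "spherocyte") {
    h[inside] <- 2 * sqrt(pmax(0, radius_um^2 - r_um[inside]^2))
  } else { # flat_disc, platelet
    h0 <- if (shape == "platelet") 1 else 2
    h[inside] <- h0
  }
  h
}

# Render one cell's height field on a local bounding-box patch.
# Returns list(height, rows, cols, scale) with height rescaled so that
# sum(height) * pitch^2 == target volume.
render_cell_height <- function(spec, grid_dim, pixel_pitch_um) {
  nr <- grid_dim[1]; nc <- grid_dim[2]; p <- pixel_pitch_um
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]
  if (anyNA(c(cx, cy))) stop("cell has no centre; place it first", call. = FALSE)
  R <- spec$radius_um
  if (cx - R < 0 || cy - R < 0 ||
      cx + R > (nc - 1) * p || cy + R > (nr - 1) * p)
    stop("cell extends outside the grid", call. = FALSE)
  cols <- max(1L, floor(cx / p - R / p)):min(nc, ceiling(cx / p + R / p) + 1L)
  rows <- max(1L, floor(cy / p - R / p)):min(nr, ceiling(cy / p + R / p) + 1L)
  x <- (cols - 1) * p - cx
  y <- (rows - 1) * p - cy
  # rotate sampling coordinates (no-op for circularly symmetric profiles)
  co <- cos(spec$rotation); si <- sin(spec$rotation)
  X <- outer(rep(1, length(y)), x); Y <- outer(y, rep(1, length(x)))
  r <- sqrt((co * X + si * Y)^2 + (-si * X + co * Y)^2)
  h <- matrix(cell_height_profile(spec$shape, as.vector(r), R),
              nrow = length(rows))
  v_raw <- sum(h) * p^2
  if (v_raw <= 0) stop("cell footprint smaller than one pixel", call. = FALSE)
  scale <- spec$target_volume_fl / v_raw
  list(height = h * scale, rows = rows, cols = cols, scale = scale)
}

#' Render the phase imprint of a single cell
#'
#' Evaluates the cell's analytic height profile at the grid's pixel centres,
#' rescales it so the grid-integrated volume equals `target_volume_fl`, and
#' converts height to phase through the inverse of [phase_to_height()].
#'
#' @param spec A [cell_spec] with a concrete centre.
#' @param grid_dim Length-2 integer, image dimensions (rows, cols).
#' @param config An [optical_config].
#' @return A [phase_map] (unwrapped, non-negative) on the full grid.
#' @export
make_rbc_phase <- function(spec, grid_dim, config) {
  rc <- render_cell_height(spec, grid_dim, config$pixel_pitch_um)
  ph <- matrix(0, grid_dim[1], grid_dim[2])
  ph[rc$rows, rc$cols] <- height_to_phase(rc$height, config)
  phase_map(ph, config$pixel_pitch_um, wrapped = FALSE)
}

# Gaussian low-pass in the Fourier domain; kernel integrates to 1 so the
# field's integral (hence every cell's volume) is preserved exactly.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  K <- exp(-2 * pi^2 * sigma_px^2 *
             outer(fft_freq(nr)^2, fft_freq(nc)^2, "+"))
  Re(fft(fft(m) * K, inverse = TRUE)) / (nr * nc)
}

# Ground-truth surface area of a cell's realized (volume-rescaled) height
# profile: surface-of-revolution quadrature of the analytic profile plus
# the flat base, describing the physical cell before the instrument's
# optical blur. Domed profiles use the substitution r = R sin(t), which
# removes the rim singularity (the integrand
# 2 pi R sin(t) sqrt(R^2 cos^2(t) + g'(t)^2), g(t) = h(R sin t), is smooth
# even where h'(r) diverges); cylinders have a closed form.
cell_truth_surface_area <- function(spec, scale) {
  R <- spec$radius_um
  if (spec$shape %in% c("flat_disc", "platelet")) {
    h0 <- scale * if (spec$shape == "platelet") 1 else 2
    return(2 * pi * R^2 + 2 * pi * R * h0)  # top + base + side wall
  }
  g <- function(t) cell_height_profile(spec$shape, R * sin(t), R) * scale
  eps <- 1e-6
  f <- function(t) {
    dg <- (g(pmin(t + eps, pi / 2)) - g(pmax(t - eps, 0))) /
      (pmin(t + eps, pi / 2) - pmax(t - eps, 0))
    2 * pi * R * sin(t) * sqrt((R * cos(t))^2 + dg^2)
  }
  top <- stats::integrate(f, 0, pi / 2, rel.tol = 1e-8,
                          subdivisions = 400L)$value
  top + pi * R^2
}

#' Draw a synthetic cell population
#'
#' Samples cell volumes and shapes for a phantom blood smear. Red-cell
#' volumes follow a normal law with mean `mean_volume_fl` and standard
#' deviation `rdw_percent/100 * mean_volume_fl`, truncated to `> 20` fL
#' (the platelet-exclusion boundary). Platelets are drawn from a normal law
#' centred at 9 fL (sd 2.5), truncated to (3, 19.5) fL.
#'
#' @param n Number of cells, >= 1.
#' @param mean_volume_fl Target mean red-cell volume (fL).
#' @param rdw_percent Target red-cell distribution width (percent; the
#'   coefficient of variation of volume).
#' @param shape_mix Named numeric vector of shape fractions (normalised to
#'   sum to 1). Default 90% biconcave discs, 10% platelets.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A list of [cell_spec] objects with unplaced centres.
#' @examples
#' pop <- sample_population(5, seed = 1)
#' sapply(pop, function(s) s$target_volume_fl)
#' @export
sample_population <- function(n, mean_volume_fl = 90, rdw_percent = 15,
                              shape_mix = c(biconcave = 0.9, platelet = 0.1),
                              seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (rdw_percent < 0) stop("`rdw_percent` must be >= 0", call. = FALSE)
  shapes <- names(shape_mix)
  bad <- setdiff(shapes, c("biconcave", "spherocyte", "flat_disc", "platelet"))
  if (length(bad)) stop("unknown shapes in `shape_mix`: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  shape_mix <- shape_mix / sum(shape_mix)
  sd_fl <- rdw_percent / 100 * mean_volume_fl
  if (sd_fl > 0 && stats::pnorm(20, mean_volume_fl, sd_fl) > 0.5)
    stop("infeasible truncation: mean volume too close to the 20 fL bound",
         call. = FALSE)
  if (sd_fl == 0 && mean_volume_fl <= 20)
    stop("red-cell volumes must exceed 20 fL", call. = FALSE)
  draw <- function() {
    kind <- sample(shapes, n, replace = TRUE, prob = shape_mix)
    lapply(seq_len(n), function(i) {
      if (kind[i] == "platelet") {
        v <- rnorm(1, 9, 2.5)
        while (v <= 3 || v >= 19.5) v <- rnorm(1, 9, 2.5)
      } else {
        v <- if (sd_fl == 0) mean_volume_fl else rnorm(1, mean_volume_fl, sd_fl)
        while (v <= 20) v <- rnorm(1, mean_volume_fl, sd_fl)
      }
      cell_spec(shape = kind[i], target_volume_fl = v)
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Assemble a ground-truthed phantom scene
#'
#' Places cells on the grid without overlap, adds a smooth aberration phase
#' background and static dirt particles (present in both sample and
#' background frames), and records per-cell ground truth: true volume,
#' surface area from fine-grid quadrature of the analytic profile, centroid
#' and footprint.
#'
#' @param cells List of [cell_spec] (e.g. from [sample_population()]);
#'   cells with `NA` centres are placed by rejection sampling with a minimum
#'   gap, cells with concrete centres are kept (and checked for overlap).
#' @param grid_dim Image dimensions (rows, cols); default `c(512, 512)`.
#' @param config An [optical_config].
#' @param seed Optional integer seed controlling placement, aberration and
#'   dirt.
#' @param aberration_amplitude_rad Peak amplitude of the smooth background
#'   phase (radians); 0 disables it.
#' @param n_dirt Number of static dirt particles (Gaussian phase blobs).
#' @param dirt_amplitude_rad Range (min, max) of dirt peak phase (radians).
#' @param dirt_sigma_um Range (min, max) of dirt Gaussian width (um).
#' @param border_margin_px Cells are placed so their footprint stays at
#'   least this many pixels from the image border.
#' @param min_gap_um Minimum edge-to-edge distance between placed cells (um).
#' @param psf_sigma_um Gaussian width (um) of the instrument's effective
#'   point-spread function, applied to the cell and dirt phase. Band-limits
#'   the scene so the first-order spectral lobe stays separated from
#'   baseband (volume integrals are preserved exactly); 0 disables.
#' @return An object of class `rbc_scene` with fields `true_phase`,
#'   `cell_phase`, `aberration`, `dirt` (all as imaged, i.e. after the
#'   PSF), `cells`, `truth` (data frame describing the physical cells) and
#'   `cell_fields` (per-cell local height patches and masks before blur).
#' @export
build_scene <- function(cells, grid_dim = c(512L, 512L),
                        config = optical_config(), seed = NULL,
                        aberration_amplitude_rad = 0.5,
                        n_dirt = 8,
                        dirt_amplitude_rad = c(0.2, 0.8),
                        dirt_sigma_um = c(0.3, 0.8),
                        border_margin_px = 24,
                        min_gap_um = 1.5,
                        psf_sigma_um = 0.25) {
  force(cells)
  go <- function() {
    nr <- grid_dim[1]; nc <- grid_dim[2]; p <- config$pixel_pitch_um
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    for (i in seq_along(cells)) {
      sp <- cells[[i]]
      if (!anyNA(sp$center_xy)) {
        placed_x <- c(placed_x, sp$center_xy[1])
        placed_y <- c(placed_y, sp$center_xy[2])
        placed_r <- c(placed_r, sp$radius_um)
        next
      }
      R <- sp$radius_um
      lo_x <- (border_margin_px - 1) * p + R
      hi_x <- (nc - border_margin_px) * p - R
      lo_y <- (border_margin_px - 1) * p + R
      hi_y <- (nr - border_margin_px) * p - R
      if (lo_x >= hi_x || lo_y >= hi_y)
        stop("grid too small for cell of radius ", R, " um", call. = FALSE)
      ok <- FALSE
      for (try in seq_len(2000L)) {
        cx <- runif(1, lo_x, hi_x); cy <- runif(1, lo_y, hi_y)
        if (!length(placed_x) ||
            all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) >
                placed_r + R + min_gap_um)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place cell ", i,
                    " without overlap; reduce n or enlarge the grid",
                    call. = FALSE)
      cells[[i]]$center_xy <- c(cx, cy)
      placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
      placed_r <- c(placed_r, R)
    }
    if (length(placed_x) > 1) {
      d <- as.matrix(stats::dist(cbind(placed_x, placed_y)))
      sep <- outer(placed_r, placed_r, "+")
      diag(d) <- Inf
      if (any(d <= sep)) stop("cells overlap", call. = FALSE)
    }

    cell_phase <- matrix(0, nr, nc)
    fields <- vector("list", length(cells))
    truth <- data.frame()
    for (i in seq_along(cells)) {
      sp <- cells[[i]]
      rc <- render_cell_height(sp, grid_dim, p)
      cell_phase[rc$rows, rc$cols] <- cell_phase[rc$rows, rc$cols] +
        height_to_phase(rc$height, config)
      fields[[i]] <- list(rows = rc$rows, cols = rc$cols,
                          height = rc$height, mask = rc$height > 0)
      truth <- rbind(truth, data.frame(
        id = i, shape = sp$shape,
        center_x_um = sp$center_xy[1], center_y_um = sp$center_xy[2],
        centroid_x_px = sp$center_xy[1] / p + 1,
        centroid_y_px = sp$center_xy[2] / p + 1,
        true_volume_fl = sp$target_volume_fl,
        true_surface_area_um2 =
          cell_truth_surface_area(sp, rc$scale),
        radius_um = sp$radius_um,
        footprint_px = sum(rc$height > 0)))
    }

    X <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
    Y <- matrix(seq(-1, 1, length.out = nr), nr, nc)
    aberration <- matrix(0, nr, nc)
    if (aberration_amplitude_rad > 0) {
      a <- runif(6, -1, 1)
      f <- a[1] * X + a[2] * Y + a[3] * X * Y +
        a[4] * (2 * X^2 - 1) + a[5] * (2 * Y^2 - 1) + a[6] * X^2 * Y^2
      aberration <- f / max(abs(f)) * aberration_amplitude_rad
    }
    dirt <- matrix(0, nr, nc)
    if (n_dirt > 0) {
      for (k in seq_len(n_dirt)) {
        amp <- runif(1, dirt_amplitude_rad[1], dirt_amplitude_rad[2])
        sig <- runif(1, dirt_sigma_um[1], dirt_sigma_um[2]) / p  # px
        cx <- runif(1, 1, nc); cy <- runif(1, 1, nr)
        cols <- max(1L, floor(cx - 5 * sig)):min(nc, ceiling(cx + 5 * sig))
        rows <- max(1L, floor(cy - 5 * sig)):min(nr, ceiling(cy + 5 * sig))
        g <- amp * exp(-(outer((rows - cy)^2, (cols - cx)^2, "+")) /
                         (2 * sig^2))
        dirt[rows, cols] <- dirt[rows, cols] + g
      }
    }

    sig_px <- psf_sigma_um / p
    cell_phase <- gaussian_blur(cell_phase, sig_px)
    dirt <- gaussian_blur(dirt, sig_px)
    structure(list(
      grid_dim = grid_dim, pixel_pitch_um = p, config = config,
      cells = cells, cell_fields = fields,
      cell_phase = cell_phase, aberration = aberration, dirt = dirt,
      true_phase = cell_phase + aberration + dirt,
      psf_sigma_um = psf_sigma_um,
      truth = truth), class = "rbc_scene")
  }
  if (is.null(seed)) go() else withr::with_seed(seed, go())
}

#' @export
print.rbc_scene <- function(x, ...) {
  cat(sprintf("<rbc_scene> %d x %d px (pitch %g um), %d cells, %s\n",
              x$grid_dim[1], x$grid_dim[2], x$pixel_pitch_um,
              length(x$cells),
              sprintf("peak cell phase %.2f rad", max(x$cell_phase))))
  invisible(x)
}

#' Interferogram synthesis model
#'
#' Parameters of the simulated off-axis recording:
#' `I(x, y) = A * (1 + m * cos(2 pi (u0 x + v0 y) + phi(x, y))) + noise`,
#' quantised to the camera bit depth. The fringe period `1/|carrier|` must
#' be at least 3 pixels — the minimum sampling for off-axis demodulation.
#'
#' @param carrier Length-2 numeric, fringe frequency (cycles/pixel) along
#'   x and y. Default `c(0.32, 0)`: about 3.1 pixels per fringe along x,
#'   near the 3 px/fringe sampling minimum at which off-axis systems
#'   operate to save space-bandwidth.
#' @param fringe_contrast Modulation depth `m` in (0, 1].
#' @param mean_intensity Mean intensity `A` (counts).
#' @param noise_sd Additive Gaussian noise sd (counts).
#' @param bit_depth Quantisation depth (8 or 16).
#' @param poisson If `TRUE`, add shot noise (Poisson resampling of the
#'   clean intensity) before the Gaussian read noise.
#' @return An object of class `interferogram_model`.
#' @export
interferogram_model <- function(carrier = c(0.32, 0),
                                fringe_contrast = 0.8,
                                mean_intensity = 20000,
                                noise_sd = 200,
                                bit_depth = 16,
                                poisson = FALSE) {
  u <- sqrt(sum(carrier^2))
  if (u <= 0) stop("carrier frequency must be non-zero", call. = FALSE)
  if (u > 1 / 3 + 1e-12)
    stop(sprintf(
      "fringe-sampling error: |carrier| = %.3f cycles/px gives %.2f px/fringe; at least 3 px/fringe are required",
      u, 1 / u), call. = FALSE)
  if (fringe_contrast <= 0 || fringe_contrast > 1)
    stop("`fringe_contrast` must be in (0, 1]", call. = FALSE)
  if (mean_intensity <= 0) stop("`mean_intensity` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(list(carrier = carrier, fringe_contrast = fringe_contrast,
                 mean_intensity = mean_intensity, noise_sd = noise_sd,
                 bit_depth = bit_depth, poisson = poisson),
            class = "interferogram_model")
}

#' Synthesise an off-axis interferogram from a scene
#'
#' Renders `I = A (1 + m cos(2 pi (u0 x + v0 y) + phi))` from the scene's
#' total phase, adds noise, and quantises to the camera bit depth. The 2D
#' spectrum of the result contains a baseband lobe and two conjugate
#' first-order lobes at the carrier frequency.
#'
#' @param scene An `rbc_scene` from [build_scene()].
#' @param model An [interferogram_model].
#' @param seed Optional integer seed; output is bit-identical given it.
#' @param include_cells If `FALSE`, render the cell-free background frame
#'   (aberration + dirt only), as recorded at the start of a measurement.
#' @return An [interferogram].
#' @export
synthesize_interferogram <- function(scene, model = interferogram_model(),
                                     seed = NULL, include_cells = TRUE) {
  phi <- if (include_cells) scene$true_phase else
    scene$aberration + scene$dirt
  go <- function() {
    nr <- nrow(phi); nc <- ncol(phi)
    X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    Y <- matrix(0:(nr - 1), nr, nc)
    A <- model$mean_intensity
    I <- A * (1 + model$fringe_contrast *
                cos(2 * pi * (model$carrier[1] * X + model$carrier[2] * Y) +
                      phi))
    if (model$poisson)
      I <- matrix(stats::rpois(length(I), pmax(I, 0)), nr, nc)
    if (model$noise_sd > 0)
      I <- I + rnorm(length(I), 0, model$noise_sd)
    I <- round(pmin(pmax(I, 0), 2^model$bit_depth - 1))
    interferogram(I, scene$pixel_pitch_um, carrier = model$carrier)
  }
  if (is.null(seed)) go() else withr::with_seed(seed, go())
}

#' Render the cell-free background frame of a scene
#'
#' Same optics and noise model as [synthesize_interferogram()] but with the
#' cells removed: only the aberration background and the static dirt
#' particles remain, exactly as they appear in the sample frame.
#'
#' @inheritParams synthesize_interferogram
#' @return An [interferogram].
#' @export
make_background_frame <- function(scene, model = interferogram_model(),
                                  seed = NULL) {
  synthesize_interferogram(scene, model, seed = seed, include_cells = FALSE)
}
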