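#' Optical configuration
#'
#' Holds the optical constants of the imaging system and of the specimen
#' needed to convert between hemoglobin concentration, refractive index,
#' phase and physical thickness.
#'
#' The refractive index of a red blood cell depends linearly on its
#' hemoglobin concentration, `n_cell = n_water + beta * C`, where `beta` is
#' the refractive increment and `C` the mean cell hemoglobin concentration
#' (MCHC, g/dL). Exactly one of `mchc_g_dl` and `n_cell_override` must be
#' supplied; the derived index contrast `dn = n_cell - n_medium` must be
#' positive or every height is undefined.
#'
#' Defaults: `n_water = 1.334` and `beta_dl_per_g = 0.00196` are standard
#' values for hemoglobin at visible wavelengths; `n_medium = 1.337`
#' corresponds to PBS with 0.1% albumin; `wavelength_nm = 550` is a typical
#' effective centre wavelength for white-light illumination;
#' `pixel_pitch_um = 0.16` corresponds to a 6.5 um camera pitch behind 40x
#' magnification. All are overridable.
#'
#' @param wavelength_nm Centre illumination wavelength (nm), > 0.
#' @param pixel_pitch_um Pixel size at the sample plane (um), > 0.
#' @param n_medium Refractive index of the surrounding buffer.
#' @param n_water Refractive index of water.
#' @param beta_dl_per_g Refractive increment of hemoglobin (dL/g).
#' @param mchc_g_dl Mean cell hemoglobin concentration (g/dL), or `NULL` if
#'   `n_cell_override` is given.
#' @param n_cell_override Explicit cell refractive index, or `NULL`.
#' @return An object of class `optical_config` with derived fields `n_cell`
#'   and `delta_n`.
#' @examples
#' cfg <- optical_config(mchc_g_dl = 33)
#' cfg$n_cell   # 1.334 + 0.00196 * 33
#' cfg$delta_n
#' @export
optical_config <- function(wavelength_nm = 550,
                           pixel_pitch_um = 0.16,
                           n_medium = 1.337,
                           n_water = 1.334,
                           beta_dl_per_g = 0.00196,
                           mchc_g_dl = 33,
                           n_cell_override = NULL) {
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("`wavelength_nm` must be > 0", call. = FALSE)
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be > 0", call. = FALSE)
  if (!is.null(mchc_g_dl) && !is.null(n_cell_override))
    stop("supply exactly one of `mchc_g_dl` and `n_cell_override`",
         call. = FALSE)
  if (is.null(mchc_g_dl) && is.null(n_cell_override))
    stop("one of `mchc_g_dl` and `n_cell_override` is required",
         call. = FALSE)
  cfg <- structure(
    list(wavelength_nm = wavelength_nm,
         pixel_pitch_um = pixel_pitch_um,
         n_medium = n_medium, n_water = n_water,
         beta_dl_per_g = beta_dl_per_g,
         mchc_g_dl = mchc_g_dl, n_cell_override = n_cell_override),
    class = "optical_config")
  cfg$n_cell <- if (is.null(n_cell_override))
    refractive_index_from_mchc(mchc_g_dl, cfg) else n_cell_override
  cfg$delta_n <- cfg$n_cell - n_medium
  if (cfg$delta_n <= 0)
    stop(sprintf(
      "index contrast delta_n = n_cell - n_medium = %.5f must be > 0",
      cfg$delta_n), call. = FALSE)
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> lambda %g nm, pitch %g um\n  n_medium %.4f, n_cell %.5f (%s), delta_n %.5f\n",
    x$wavelength_nm, x$pixel_pitch_um, x$n_medium, x$n_cell,
    if (is.null(x$n_cell_override))
      sprintf("MCHC %g g/dL, beta %g dL/g", x$mchc_g_dl, x$beta_dl_per_g)
    else "override",
    x$delta_n))
  invisible(x)
}

#' Cell refractive index from hemoglobin concentration
#'
#' Evaluates the linear law `n = n_water + beta * C` relating the refractive
#' index of a red blood cell to its hemoglobin concentration `C` (MCHC).
#'
#' @param mchc Hemoglobin concentration (g/dL), >= 0.
#' @param config An [optical_config] supplying `n_water` and `beta_dl_per_g`.
#' @return Refractive index (dimensionless).
#' @examples
#' cfg <- optical_config()
#' refractive_index_from_mchc(0, cfg)   # pure water
#' refractive_index_from_mchc(33, cfg)  # 1.39868
#' @export
refractive_index_from_mchc <- function(mchc, config) {
  if (!is.numeric(mchc) || any(mchc < 0))
    stop("`mchc` must be >= 0 g/dL", call. = FALSE)
  config$n_water + config$beta_dl_per_g * mchc
}

#' Convert a phase map to a height map
#'
#' The optical pathlength delay of a cell of thickness `h` in a medium of
#' index contrast `dn = n_cell - n_medium` is `phi = 2*pi*dn*h/lambda`, so
#' thickness is recovered as `h = lambda * phi / (2*pi*dn)`. The map is a
#' pure linear rescaling: negative phase yields negative height here;
#' clamping is the morphology stage's concern.
#'
#' @param phase A [phase_map] (must be unwrapped) or numeric matrix of phase
#'   (radians).
#' @param config An [optical_config]; its `delta_n` must be positive.
#' @return A [height_map] in micrometres (a plain matrix if `phase` was one).
#' @examples
#' cfg <- optical_config(wavelength_nm = 550,
#'                       n_cell_override = 1.392, mchc_g_dl = NULL)
#' ph <- phase_map(matrix(2 * pi, 4, 4), pixel_pitch_um = 0.16)
#' phase_to_height(ph, cfg)  # 10 um everywhere: 0.55 / 0.055
#' @export
phase_to_height <- function(phase, config) {
  if (config$delta_n <= 0)
    stop("`delta_n` must be > 0 to convert phase to height", call. = FALSE)
  scale <- (config$wavelength_nm / 1000) / (2 * pi * config$delta_n)
  if (inherits(phase, "phase_map")) {
    if (phase$wrapped)
      stop("phase must be unwrapped before height conversion", call. = FALSE)
    height_map(phase$values * scale, phase$pixel_pitch_um)
  } else {
    phase * scale
  }
}

#' Convert a height map to a phase map
#'
#' Inverse of [phase_to_height()]; used by the phantom generator to induce
#' the phase a cell of given thickness would imprint.
#'
#' @param height A [height_map] or numeric matrix (micrometres).
#' @param config An [optical_config].
#' @return A [phase_map] in radians (a plain matrix if `height` was one).
#' @export
height_to_phase <- function(height, config) {
  if (config$delta_n <= 0)
    stop("`delta_n` must be > 0 to convert height to phase", call. = FALSE)
  scale <- 2 * pi * config$delta_n / (config$wavelength_nm / 1000)
  if (inherits(height, "height_map")) {
    phase_map(height$values * scale, height$pixel_pitch_um, wrapped = FALSE)
  } else {
    height * scale
  }
}
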