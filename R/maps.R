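#' Quantitative phase map
#'
#' Container for a 2D phase field (radians) on a regular pixel grid. Rows are
#' image y, columns image x; `pixel_pitch_um` is the physical size of one
#' pixel at the sample plane.
#'
#' @param values Numeric matrix of phase values (radians).
#' @param pixel_pitch_um Pixel size at the sample plane (micrometres).
#' @param wrapped Logical; `TRUE` if values are only known modulo `2*pi`
#'   (confined to `[-pi, pi)`).
#' @param background_subtracted Logical; `TRUE` once a cell-free reference
#'   has been subtracted.
#' @return An object of class `phase_map`.
#' @seealso [phase_to_height()], [demodulate()], [unwrap_phase()]
#' @export
phase_map <- function(values, pixel_pitch_um,
                      wrapped = FALSE, background_subtracted = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a single positive number", call. = FALSE)
  if (isTRUE(wrapped) && length(values) &&
      (min(values) < -pi || max(values) >= pi + 1e-12))
    stop("wrapped phase values must lie in [-pi, pi)", call. = FALSE)
  structure(
    list(values = values, pixel_pitch_um = pixel_pitch_um,
         wrapped = isTRUE(wrapped),
         background_subtracted = isTRUE(background_subtracted)),
    class = "phase_map"
  )
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf(
    "<phase_map> %d x %d px, pitch %.4g um, %s, background %ssubtracted\n",
    nrow(x$values), ncol(x$values), x$pixel_pitch_um,
    if (x$wrapped) "wrapped [-pi, pi)" else "unwrapped",
    if (x$background_subtracted) "" else "not "))
  cat(sprintf("  phase range [%.3f, %.3f] rad\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cell thickness (height) map
#'
#' A 2D field of physical specimen thickness in micrometres, on the same grid
#' as the phase map it was converted from.
#'
#' @param values Numeric matrix of heights (micrometres).
#' @param pixel_pitch_um Pixel size at the sample plane (micrometres).
#' @return An object of class `height_map`.
#' @seealso [phase_to_height()]
#' @export
height_map <- function(values, pixel_pitch_um) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a single positive number", call. = FALSE)
  structure(list(values = values, pixel_pitch_um = pixel_pitch_um),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, pitch %.4g um, range [%.3f, %.3f] um\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Off-axis interferogram
#'
#' A 2D intensity image (camera counts) carrying phase information as local
#' bending of carrier fringes. The optional `carrier` attribute records the
#' fringe spatial frequency used at synthesis time (cycles/pixel along x and
#' y); reconstruction does not rely on it.
#'
#' @param values Numeric matrix of intensities (counts, non-negative).
#' @param pixel_pitch_um Pixel size at the sample plane (micrometres).
#' @param carrier Optional length-2 numeric, fringe frequency (cycles/pixel).
#' @return An object of class `interferogram`.
#' @export
interferogram <- function(values, pixel_pitch_um, carrier = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(values < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(values = values, pixel_pitch_um = pixel_pitch_um,
                 carrier = carrier),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d x %d px, pitch %.4g um, counts [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch_um,
              min(x$values), max(x$values)))
  if (!is.null(x$carrier))
    cat(sprintf("  carrier (%.4f, %.4f) cycles/px\n",
                x$carrier[1], x$carrier[2]))
  invisible(x)
}

as_matrix <- function(x) {
  if (inherits(x, c("phase_map", "height_map", "interferogram"))) x$values
  else x
}
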