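# Signed FFT bin frequencies in cycles/pixel for an n-point transform.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

#' Estimate the carrier frequency of an off-axis interferogram
#'
#' Locates the dominant non-DC peak of the 2D power spectrum in the
#' half-plane `u > 0 | (u == 0 & v > 0)` — the first-order lobe produced by
#' the carrier fringes. A frequency disc around DC is excluded so the
#' baseband lobe (aberrations, cell envelope) cannot masquerade as the
#' carrier.
#'
#' @param x An [interferogram] or numeric matrix.
#' @param dc_exclude_cpp Radius (cycles/pixel) of the excluded DC disc.
#' @param min_peak_snr Minimum ratio of the peak amplitude to the spectral
#'   noise floor (median amplitude in the search region); below it a
#'   no-fringe error is raised.
#' @return Length-2 numeric `c(u, v)` in cycles/pixel.
#' @export
estimate_carrier <- function(x, dc_exclude_cpp = 0.08, min_peak_snr = 3) {
  I <- as_matrix(x)
  nr <- nrow(I); nc <- ncol(I)
  F <- fft(I)
  A <- Mod(F)
  fx <- fft_freq(nc); fy <- fft_freq(nr)
  U <- matrix(fx, nr, nc, byrow = TRUE)
  V <- matrix(fy, nr, nc)
  sel <- (U > 0 | (U == 0 & V > 0)) & (U^2 + V^2 > dc_exclude_cpp^2)
  amps <- A[sel]
  floor_amp <- median(amps)
  peak_amp <- max(amps)
  # absolute guard: a uniform image has only numerical dust off DC
  if (!is.finite(peak_amp) || peak_amp < min_peak_snr * floor_amp ||
      peak_amp < 1e-9 * A[1, 1])
    stop("no-fringe error: no spectral peak at least ", min_peak_snr,
         "x above the noise floor", call. = FALSE)
  k <- which(sel & A == peak_amp)[1]
  c(U[k], V[k])
}

#' Demodulate an interferogram to a wrapped phase map
#'
#' Spatial Hilbert-transform demodulation: the interferogram is multiplied
#' by `exp(-2i pi (u0 x + v0 y))`, which shifts the first-order spectral
#' lobe to baseband; a circular low-pass window of radius `filter_radius`
#' isolates it; the per-pixel argument of the filtered analytic signal is
#' the wrapped phase.
#'
#' @param x An [interferogram] or numeric matrix.
#' @param carrier Length-2 numeric (cycles/pixel), or `NULL` to call
#'   [estimate_carrier()].
#' @param filter_radius Low-pass radius in cycles/pixel; default
#'   `|carrier| / 2` (hard circular window). Must be `< |carrier|` or the
#'   baseband and first-order lobes overlap.
#' @param window `"hard"` (default) or `"gaussian"` (the radius becomes the
#'   1/e half-width, tapering ringing at the cost of resolution).
#' @return A [phase_map], wrapped in `[-pi, pi)`.
#' @export
demodulate <- function(x, carrier = NULL, filter_radius = NULL,
                       window = c("hard", "gaussian")) {
  window <- match.arg(window)
  I <- as_matrix(x)
  pitch <- if (inherits(x, "interferogram")) x$pixel_pitch_um else 1
  if (is.null(carrier)) carrier <- estimate_carrier(I)
  cu <- sqrt(sum(carrier^2))
  if (cu <= 0) stop("carrier must be non-zero", call. = FALSE)
  if (is.null(filter_radius)) filter_radius <- cu / 2
  if (filter_radius >= cu)
    stop(sprintf(
      "lobe-overlap error: filter_radius (%.3f) must be < |carrier| (%.3f) cycles/px",
      filter_radius, cu), call. = FALSE)
  nr <- nrow(I); nc <- ncol(I)
  X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  Y <- matrix(0:(nr - 1), nr, nc)
  z <- I * exp(-2i * pi * (carrier[1] * X + carrier[2] * Y))
  Z <- fft(z)
  R2 <- outer(fft_freq(nr)^2, fft_freq(nc)^2, "+")
  W <- if (window == "hard") (R2 <= filter_radius^2) * 1 else
    exp(-R2 / filter_radius^2)
  zb <- fft(Z * W, inverse = TRUE) / (nr * nc)
  phase_map(wrap_phase(Arg(zb)), pitch, wrapped = TRUE)
}

#' Unwrap a wrapped phase map
#'
#' Quality-guided flood-fill unwrapping: pixels are integrated outward from
#' the most reliable (locally smoothest) pixel in decreasing reliability
#' order, each receiving `wrapped + 2*pi*k` with `k` chosen against an
#' already-unwrapped neighbour. The congruence contract holds for every
#' input: output minus input is an integer multiple of `2*pi` per pixel;
#' on residue-free inputs the result has no adjacent-pixel jump above `pi`.
#' Residue-laden inputs are unwrapped best-effort and the residue count is
#' attached as attribute `"residues"` (with a message).
#'
#' @param phase A wrapped [phase_map] (or numeric matrix in `[-pi, pi)`).
#' @return An unwrapped [phase_map]; attribute `"residues"` carries the
#'   number of 2x2 plaquettes with non-zero wrapped-gradient curl.
#' @export
unwrap_phase <- function(phase) {
  pm <- inherits(phase, "phase_map")
  w <- as_matrix(phase)
  res <- cpp_unwrap(w)
  if (res$residues > 0)
    message("unwrap_phase: ", res$residues,
            " phase residues detected; result is best-effort")
  out <- if (pm)
    phase_map(res$values, phase$pixel_pitch_um, wrapped = FALSE,
              background_subtracted = phase$background_subtracted)
  else res$values
  attr(out, "residues") <- res$residues
  out
}

#' Subtract a cell-free background phase map
#'
#' Removes the static optical-path contribution (dust particles, field
#' aberrations) recorded in a cell-free reference frame: pixel-wise
#' difference followed by removal of a global offset, fixed as the mode of
#' a coarse histogram of the difference — in a dilute smear the cell-free
#' background dominates, so the modal phase is the true zero level.
#'
#' @param sample Unwrapped [phase_map] of the sample frame.
#' @param background Unwrapped [phase_map] of the cell-free frame, or
#'   `NULL` to proceed with a zero background (warns).
#' @param offset_bin_rad Histogram bin width (radians) used to locate the
#'   modal phase; the offset is refined as the median of the values in the
#'   modal bin and its neighbours.
#' @return A [phase_map] with `background_subtracted = TRUE`.
#' @export
subtract_background <- function(sample, background = NULL,
                                offset_bin_rad = 0.05) {
  if (!inherits(sample, "phase_map") || sample$wrapped)
    stop("`sample` must be an unwrapped phase_map", call. = FALSE)
  if (is.null(background)) {
    warning("no background frame supplied; proceeding with zero background")
    b <- 0
  } else {
    if (!inherits(background, "phase_map") || background$wrapped)
      stop("`background` must be an unwrapped phase_map", call. = FALSE)
    if (!identical(dim(background$values), dim(sample$values)))
      stop("grid mismatch between sample and background", call. = FALSE)
    b <- background$values
  }
  d <- sample$values - b
  rng <- range(d)
  brks <- seq(rng[1] - offset_bin_rad, rng[2] + offset_bin_rad,
              by = offset_bin_rad)
  cnt <- tabulate(findInterval(d, brks), nbins = length(brks))
  k <- which.max(cnt)
  inbin <- d >= brks[max(1, k - 1)] & d < brks[min(length(brks), k + 2)]
  offset <- median(d[inbin])
  phase_map(d - offset, sample$pixel_pitch_um, wrapped = FALSE,
            background_subtracted = TRUE)
}
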