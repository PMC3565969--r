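#' Projected area of a cell
#'
#' Number of mask pixels times the physical pixel area.
#'
#' @param mask Logical matrix (cell footprint).
#' @param pixel_pitch_um Pixel size (um).
#' @return Projected area (um^2).
#' @export
projected_area <- function(mask, pixel_pitch_um) {
  n <- sum(mask)
  if (n == 0) stop("degenerate cell: empty mask", call. = FALSE)
  n * pixel_pitch_um^2
}

#' Equivalent circular diameter
#'
#' Diameter of the circular disk with the cell's projected area.
#'
#' @param pa Projected area (um^2), > 0.
#' @return Diameter (um).
#' @export
equivalent_diameter <- function(pa) {
  if (any(pa <= 0)) stop("projected area must be > 0", call. = FALSE)
  2 * sqrt(pa / pi)
}

#' Cell volume by height integration
#'
#' Integrates the height map over the projected area:
#' `V = sum(h) * pitch^2`; 1 um^3 = 1 fL. Negative heights inside the mask
#' are clamped to zero (count available via attribute `"n_clamped"`).
#'
#' @param height Numeric matrix of heights (um), same grid as `mask`.
#' @param mask Logical matrix.
#' @param pixel_pitch_um Pixel size (um).
#' @return Volume (fL) with attribute `n_clamped`.
#' @export
cell_volume <- function(height, mask, pixel_pitch_um) {
  if (sum(mask) == 0) stop("degenerate cell: empty mask", call. = FALSE)
  h <- height[mask]
  ncl <- sum(h < 0)
  v <- sum(pmax(h, 0)) * pixel_pitch_um^2
  attr(v, "n_clamped") <- ncl
  v
}

# Masked gradient: central differences where both neighbours lie in the
# mask, one-sided at mask edges, zero when isolated along that axis.
masked_gradient <- function(h, mask, pixel_pitch_um) {
  p <- pixel_pitch_um
  gl <- shift_mat_num(h, 0, 1);  ml <- shift_mat_log(mask, 0, 1)
  gr <- shift_mat_num(h, 0, -1); mr <- shift_mat_log(mask, 0, -1)
  hx <- matrix(0, nrow(h), ncol(h))
  both <- ml & mr; hx[both] <- (gr[both] - gl[both]) / (2 * p)
  onlyr <- mr & !ml; hx[onlyr] <- (gr[onlyr] - h[onlyr]) / p
  onlyl <- ml & !mr; hx[onlyl] <- (h[onlyl] - gl[onlyl]) / p
  gu <- shift_mat_num(h, 1, 0);  mu <- shift_mat_log(mask, 1, 0)
  gd <- shift_mat_num(h, -1, 0); md <- shift_mat_log(mask, -1, 0)
  hy <- matrix(0, nrow(h), ncol(h))
  both <- mu & md; hy[both] <- (gd[both] - gu[both]) / (2 * p)
  onlyd <- md & !mu; hy[onlyd] <- (gd[onlyd] - h[onlyd]) / p
  onlyu <- mu & !md; hy[onlyu] <- (h[onlyu] - gu[onlyu]) / p
  list(hx = hx, hy = hy)
}

shift_mat_num <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

shift_mat_log <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

#' Cell surface area by Monge parameterisation
#'
#' Treats the cell's upper surface as a height function `h(x, y)`; each
#' pixel contributes an area element
#' `dA = sqrt(1 + hx^2 + hy^2) * dx * dy`. The total surface area is the
#' sum of the elements over the footprint plus the projected area once
#' more, since the cell lies flat on the coverslip. Gradients are central
#' differences inside the mask and one-sided at mask edges.
#'
#' @inheritParams cell_volume
#' @return Surface area (um^2).
#' @export
cell_surface_area <- function(height, mask, pixel_pitch_um) {
  if (sum(mask) == 0) stop("degenerate cell: empty mask", call. = FALSE)
  h <- height; h[!mask] <- 0; h <- pmax(h, 0)
  g <- masked_gradient(h, mask, pixel_pitch_um)
  top <- sum(sqrt(1 + g$hx[mask]^2 + g$hy[mask]^2)) * pixel_pitch_um^2
  top + projected_area(mask, pixel_pitch_um)
}

#' Sphericity index
#'
#' Ratio of the surface area of the sphere with the cell's volume to the
#' cell's actual surface area:
#' `Psi = pi^(1/3) * (6 V)^(2/3) / SA`. Equals 1 for a sphere and
#' decreases as the shape flattens.
#'
#' @param volume_fl Cell volume (fL), > 0.
#' @param surface_area_um2 Cell surface area (um^2), > 0.
#' @return Sphericity (dimensionless, in (0, 1] for physical shapes).
#' @export
sphericity <- function(volume_fl, surface_area_um2) {
  if (any(volume_fl <= 0) || any(surface_area_um2 <= 0))
    stop("volume and surface area must be > 0", call. = FALSE)
  pi^(1 / 3) * (6 * volume_fl)^(2 / 3) / surface_area_um2
}

#' Minimum cylindrical diameter
#'
#' The smallest capillary diameter a cell of given volume and surface area
#' can squeeze through, modelled as the diameter of the sphero-cylinder
#' (cylinder with hemispherical caps) with the same surface area and
#' volume. For a cap-ended cylinder of diameter `D` and total length
#' `L + D`, `SA = pi D L + pi D^2` and `V = pi D^2 L / 4 + pi D^3 / 6`;
#' eliminating `L` gives the cubic `pi D^3 - 3 SA D + 12 V = 0`, whose
#' smallest positive root is the MCD. A sphere (`SA = 4 pi r^2`,
#' `V = 4 pi r^3 / 3`) gives `D = 2 r` exactly.
#'
#' @inheritParams sphericity
#' @return Diameter (um).
#' @export
minimum_cylindrical_diameter <- function(volume_fl, surface_area_um2) {
  if (volume_fl <= 0 || surface_area_um2 <= 0)
    stop("volume and surface area must be > 0", call. = FALSE)
  r <- polyroot(c(12 * volume_fl, -3 * surface_area_um2, 0, pi))
  real <- Re(r)[abs(Im(r)) < 1e-8 * (abs(r) + 1)]
  pos <- real[real > 0]
  if (!length(pos))
    stop("infeasible shape: no positive real root (sphericity > 1)",
         call. = FALSE)
  min(pos)
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion.
# Returns counts of orthogonal and diagonal chain steps of the outer
# contour of the (single-object) mask.
trace_contour_steps <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # directions clockwise starting East: E SE S SW W NW N NE
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  start <- which(t(M))[1]  # raster order: topmost then leftmost
  sr <- ((start - 1L) %/% (nc + 2L)) + 1L
  sc <- ((start - 1L) %% (nc + 2L)) + 1L
  # backtrack: came from the West of the start pixel
  cr <- sr; cc <- sc; dir0 <- NA_integer_
  prev_dir <- 4L  # index of W (0-based: 4); search starts after backtrack
  n_ortho <- 0L; n_diag <- 0L
  first <- TRUE
  max_steps <- 4L * (nr + 2L) * (nc + 2L)
  steps <- 0L
  repeat {
    found <- FALSE
    s0 <- (prev_dir + 1L) %% 8L
    for (t in 0:7) {
      d <- (s0 + t) %% 8L
      ni <- cr + dr[d + 1L]; nj <- cc + dc[d + 1L]
      if (M[ni, nj]) { found <- TRUE; break }
    }
    if (!found) return(list(n_ortho = 0L, n_diag = 0L))  # isolated pixel
    # Jacob's criterion: back at the start and about to repeat the first
    # move -- the contour is closed, every step already counted.
    if (!first && cr == sr && cc == sc && d == dir0) break
    if (dr[d + 1L] != 0L && dc[d + 1L] != 0L) n_diag <- n_diag + 1L
    else n_ortho <- n_ortho + 1L
    cr <- ni; cc <- nj
    prev_dir <- (d + 4L) %% 8L  # backtrack direction
    if (first) { dir0 <- d; first <- FALSE }
    steps <- steps + 1L
    if (steps > max_steps) break
  }
  list(n_ortho = n_ortho, n_diag = n_diag)
}

#' Perimeter of a cell mask
#'
#' Length of the outer boundary contour obtained by Moore-neighbour
#' tracing. `"corrected"` (default) weights orthogonal and diagonal chain
#' steps by 0.948 and 1.340 respectively — a classical bias-corrected chain
#' estimator that converges to the true length for smooth shapes as
#' resolution grows; `"chain"` uses raw weights 1 and `sqrt(2)`; `"crack"`
#' counts exposed pixel edges (staircase length, always an overestimate
#' for smooth shapes).
#'
#' @param mask Logical matrix (single object).
#' @param pixel_pitch_um Pixel size (um).
#' @param method One of `"corrected"`, `"chain"`, `"crack"`.
#' @return Perimeter (um).
#' @export
mask_perimeter <- function(mask, pixel_pitch_um,
                           method = c("corrected", "chain", "crack")) {
  method <- match.arg(method)
  if (sum(mask) == 0) stop("degenerate cell: empty mask", call. = FALSE)
  if (method == "crack") {
    n <- sum(mask & !shift_mat_log(mask, 0, 1)) +
      sum(mask & !shift_mat_log(mask, 0, -1)) +
      sum(mask & !shift_mat_log(mask, 1, 0)) +
      sum(mask & !shift_mat_log(mask, -1, 0))
    return(n * pixel_pitch_um)
  }
  st <- trace_contour_steps(mask)
  if (st$n_ortho + st$n_diag == 0L)  # single pixel
    return(4 * pixel_pitch_um)
  w <- if (method == "corrected") c(0.948, 1.340) else c(1, sqrt(2))
  (w[1] * st$n_ortho + w[2] * st$n_diag) * pixel_pitch_um
}

#' Extended per-cell shape and height-distribution parameters
#'
#' Computes the remaining cell-record fields: perimeter and circularity
#' (`4 pi PA / perimeter^2`), eccentricity of the moment-equivalent
#' ellipse, thickness extrema and mean, integrated density (sum of phase
#' over the mask, radians x pixels), and population-normalised variance,
#' skewness and raw (non-excess) kurtosis of the height values over the
#' mask. For a constant height distribution skewness and kurtosis are
#' undefined and reported as 0 with `degenerate_height = TRUE`.
#'
#' @param height Numeric matrix of heights (um).
#' @param mask Logical matrix (>= 4 px).
#' @param phase Optional numeric matrix of phase (radians) on the same
#'   grid; `NA` integrated density if absent.
#' @param pixel_pitch_um Pixel size (um).
#' @return Named list of parameters.
#' @export
extended_parameters <- function(height, mask, phase = NULL, pixel_pitch_um) {
  n <- sum(mask)
  if (n < 4)
    stop("degenerate cell: fewer than 4 pixels", call. = FALSE)
  p <- pixel_pitch_um
  pa <- projected_area(mask, p)
  per <- mask_perimeter(mask, p)
  circ <- 4 * pi * pa / per^2
  idx <- which(mask)
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  x <- cols - mean(cols); y <- rows - mean(rows)
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - det))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - det))
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  h <- pmax(height[mask], 0)
  m <- mean(h)
  m2 <- mean((h - m)^2)
  degenerate <- m2 < 1e-12
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((h - m)^3) / m2^1.5
    kurt <- mean((h - m)^4) / m2^2
  }
  list(perimeter_um = per,
       circularity = circ,
       eccentricity = ecc,
       min_thickness_um = min(h),
       max_thickness_um = max(h),
       mean_thickness_um = m,
       integrated_density_rad_px =
         if (is.null(phase)) NA_real_ else sum(phase[mask]),
       height_variance_um2 = m2,
       height_skewness = skew,
       height_kurtosis = kurt,
       degenerate_height = degenerate)
}

#' Full morphological record for one cell patch
#'
#' Applies every per-cell measurement to a `cell_patch` from
#' [extract_cells()] and returns a one-row data frame (a `CellRecord`).
#' The minimum cylindrical diameter is `NA` (with a warning) when the
#' discretised sphericity exceeds 1 and the sphero-cylinder cubic has no
#' positive real root.
#'
#' @param cell A `cell_patch`.
#' @return One-row data frame.
#' @export
measure_cell <- function(cell) {
  p <- cell$pixel_pitch_um
  pa <- projected_area(cell$mask, p)
  vol <- cell_volume(cell$height, cell$mask, p)
  sa <- cell_surface_area(cell$height, cell$mask, p)
  psi <- sphericity(as.numeric(vol), sa)
  mcd <- tryCatch(minimum_cylindrical_diameter(as.numeric(vol), sa),
                  error = function(e) {
                    warning("cell ", cell$id, ": ", conditionMessage(e),
                            call. = FALSE)
                    NA_real_
                  })
  ext <- extended_parameters(cell$height, cell$mask, cell$phase, p)
  data.frame(
    id = cell$id,
    centroid_x_px = cell$centroid_px[["x"]],
    centroid_y_px = cell$centroid_px[["y"]],
    projected_area_um2 = pa,
    equivalent_diameter_um = equivalent_diameter(pa),
    volume_fl = as.numeric(vol),
    surface_area_um2 = sa,
    sphericity = psi,
    mcd_um = mcd,
    perimeter_um = ext$perimeter_um,
    circularity = ext$circularity,
    eccentricity = ext$eccentricity,
    min_thickness_um = ext$min_thickness_um,
    max_thickness_um = ext$max_thickness_um,
    mean_thickness_um = ext$mean_thickness_um,
    integrated_density_rad_px = ext$integrated_density_rad_px,
    height_variance_um2 = ext$height_variance_um2,
    height_skewness = ext$height_skewness,
    height_kurtosis = ext$height_kurtosis,
    degenerate_height = ext$degenerate_height,
    n_pixels = cell$n_px,
    n_clamped_px = cell$n_clamped)
}

#' Morphological records for a list of cells
#'
#' @param cells List of `cell_patch` objects from [extract_cells()].
#' @return Data frame, one row per cell (zero rows if no cells).
#' @export
analyze_cells <- function(cells) {
  if (!length(cells)) return(empty_cell_records())
  do.call(rbind, lapply(cells, measure_cell))
}

empty_cell_records <- function() {
  measure_cell(structure(list(
    id = 0L, mask = matrix(TRUE, 2, 2),
    height = matrix(1, 2, 2), phase = NULL,
    offset = c(row = 1L, col = 1L), centroid_px = c(x = 1, y = 1),
    n_px = 4L, volume_fl = 4, n_clamped = 0L,
    pixel_pitch_um = 1), class = "cell_patch"))[0, ]
}
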