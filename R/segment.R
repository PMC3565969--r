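#' Global threshold mask
#'
#' Separates objects from background in an unwrapped, background-corrected
#' phase image: a pixel is foreground iff its phase is at least `tau`.
#'
#' @param phase A [phase_map] (unwrapped; a warning is issued if the
#'   background has not been subtracted) or numeric matrix.
#' @param tau Threshold (radians). Default 0.3 rad.
#' @return Logical matrix, `TRUE` for foreground.
#' @export
threshold_mask <- function(phase, tau = 0.3) {
  if (inherits(phase, "phase_map")) {
    if (phase$wrapped)
      stop("phase must be unwrapped before thresholding", call. = FALSE)
    if (!phase$background_subtracted)
      warning("thresholding a phase map without background subtraction")
  }
  as_matrix(phase) >= tau
}

shift_mat <- function(L, dr, dc) {
  nr <- nrow(L); nc <- ncol(L)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- L[rs - dr, cs - dc]
  out
}

conn_offsets <- function(connectivity) {
  o4 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4) return(o4)
  c(o4, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

#' Label connected components by label equivalence
#'
#' Implements the iterative label-equivalence scheme used for massively
#' parallel connected-component labelling: every foreground pixel starts
#' with its own linear index as label; a *scanning* pass lets each pixel
#' adopt the minimum label among itself and its foreground neighbours,
#' recording the implied equivalence in a reference array; an *analysis*
#' pass resolves every label to the root of its equivalence chain (pointer
#' jumping); the two passes alternate until a scanning pass changes
#' nothing. Labels are then compacted to `1..K`. The resulting partition is
#' identical, up to relabelling, to classical flood-fill connected
#' components.
#'
#' @param mask Logical (or strictly 0/1 numeric) matrix.
#' @param connectivity 4 or 8 (default 8: blob-like cells may touch
#'   diagonally).
#' @return An object of class `label_map`: integer matrix `labels`
#'   (0 background, `1..K` objects), `connectivity`, `n_components`, and
#'   `tau` provenance (filled by [segment_phase()]).
#' @export
label_components <- function(mask, connectivity = 8) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("`mask` must be binary (logical or 0/1)", call. = FALSE)
    mask <- mask == 1
  }
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop("`mask` contains NA", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  L <- matrix(0L, nr, nc)
  if (length(fg)) {
    L[fg] <- fg  # initial label = own linear index
    offs <- conn_offsets(connectivity)
    ref <- seq_len(nr * nc)
    repeat {
      # Scanning: minimum label among self and foreground neighbours
      M <- L
      for (o in offs) {
        S <- shift_mat(L, o[1], o[2])
        hit <- S > 0L & S < M & M > 0L
        if (any(hit)) M[hit] <- S[hit]
      }
      ch <- which(M < L)
      if (!length(ch)) break
      # record equivalences: each old label points to the smallest label seen
      agg <- tapply(M[ch], L[ch], min)
      ids <- as.integer(names(agg))
      ref[ids] <- pmin(ref[ids], as.integer(agg))
      # Analysis: resolve chains to their roots by pointer jumping
      repeat {
        r2 <- ref[ref]
        if (identical(r2, ref)) break
        ref <- r2
      }
      L[fg] <- ref[L[fg]]
    }
    labs <- sort(unique(L[fg]))
    L[fg] <- match(L[fg], labs)
  }
  structure(list(labels = L, connectivity = connectivity,
                 n_components = if (length(fg)) max(L) else 0L,
                 tau = NA_real_),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d components, %d-connectivity%s\n",
              nrow(x$labels), ncol(x$labels), x$n_components,
              x$connectivity,
              if (is.na(x$tau)) "" else sprintf(", tau = %.3g rad", x$tau)))
  invisible(x)
}

#' Threshold and label a phase map in one step
#'
#' @param phase A [phase_map] (unwrapped, background-subtracted).
#' @param tau Threshold (radians).
#' @param connectivity 4 or 8.
#' @return A `label_map` with `tau` provenance recorded.
#' @export
segment_phase <- function(phase, tau = 0.3, connectivity = 8) {
  lm <- label_components(threshold_mask(phase, tau), connectivity)
  lm$tau <- tau
  lm
}

#' Extract per-cell patches, applying the platelet-exclusion filter
#'
#' Collects each labelled object's mask and cropped height (and optionally
#' phase) patch, discards objects whose integrated volume is below
#' `min_volume_fl` (20 fL by default, excluding platelets from red-cell
#' analysis) and objects touching the image border (partial cells would
#' corrupt volume statistics). Negative heights inside a mask are clamped
#' to zero for the volume test and the clamp count recorded.
#'
#' @param labelmap A `label_map` (or integer matrix of labels).
#' @param height A [height_map] on the same grid.
#' @param phase Optional [phase_map] on the same grid, stored per cell for
#'   integrated-density computation.
#' @param min_volume_fl Minimum integrated volume (fL); 0 disables.
#' @param exclude_border Drop objects touching the image border.
#' @param min_px Drop objects smaller than this many pixels (noise specks);
#'   default 1 (off).
#' @return List of `cell_patch` objects: `id`, `mask`, `height`, `phase`,
#'   `offset` (top-left row/col of the crop), `centroid_px` (x, y),
#'   `n_px`, `volume_fl`, `n_clamped`, `pixel_pitch_um`.
#' @export
extract_cells <- function(labelmap, height, phase = NULL,
                          min_volume_fl = 20, exclude_border = TRUE,
                          min_px = 1) {
  L <- if (inherits(labelmap, "label_map")) labelmap$labels else labelmap
  if (!inherits(height, "height_map"))
    stop("`height` must be a height_map", call. = FALSE)
  H <- height$values
  if (!identical(dim(L), dim(H)))
    stop("label map and height map grids differ", call. = FALSE)
  P <- if (is.null(phase)) NULL else as_matrix(phase)
  p <- height$pixel_pitch_um
  nr <- nrow(L); nc <- ncol(L)
  fg <- which(L > 0L)
  out <- list()
  if (!length(fg)) return(out)
  by_label <- split(fg, L[fg])
  id <- 0L
  for (k in names(by_label)) {
    idx <- by_label[[k]]
    if (length(idx) < min_px) next
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    if (exclude_border &&
        (any(rows == 1L | rows == nr | cols == 1L | cols == nc))) next
    h <- H[idx]
    n_clamped <- sum(h < 0)
    h <- pmax(h, 0)
    vol <- sum(h) * p^2
    if (vol < min_volume_fl) next
    r0 <- max(1L, min(rows) - 1L); r1 <- min(nr, max(rows) + 1L)
    c0 <- max(1L, min(cols) - 1L); c1 <- min(nc, max(cols) + 1L)
    m <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    m[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    hp <- H[r0:r1, c0:c1]; hp[!m] <- 0
    id <- id + 1L
    out[[id]] <- structure(list(
      id = id, mask = m, height = hp,
      phase = if (is.null(P)) NULL else P[r0:r1, c0:c1],
      offset = c(row = r0, col = c0),
      centroid_px = c(x = mean(cols), y = mean(rows)),
      n_px = length(idx), volume_fl = vol, n_clamped = n_clamped,
      pixel_pitch_um = p), class = "cell_patch")
  }
  out
}
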