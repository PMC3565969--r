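# TIFF plumbing. Interferograms and label maps are 16-bit integer TIFFs.
# Phase maps are 32-bit float TIFFs; because float TIFF storage is defined
# only on [0, 1] here, phase values are affinely rescaled into that range
# and the range recorded in a `<path>.range.txt` sidecar so reading is an
# exact inverse.

#' Write an interferogram as a 16-bit grayscale TIFF
#'
#' @param x An [interferogram].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interferogram_tiff <- function(x, path) {
  v <- as_matrix(x)
  if (max(v) > 65535) stop("counts exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF interferogram
#'
#' @param path Input path.
#' @param pixel_pitch_um Pixel size at the sample plane (um).
#' @param carrier Optional known carrier (cycles/pixel).
#' @return An [interferogram].
#' @export
read_interferogram_tiff <- function(path, pixel_pitch_um = 0.16,
                                    carrier = NULL) {
  v <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e)
                  stop("failed to read TIFF '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  if (length(dim(v)) == 3L) v <- v[, , 1]
  storage.mode(v) <- "double"
  interferogram(v, pixel_pitch_um, carrier = carrier)
}

range_sidecar <- function(path) paste0(path, ".range.txt")

#' Write a phase map as a rescaled 32-bit float TIFF
#'
#' The phase values are mapped affinely onto `[0, 1]`; `phase_min` and
#' `phase_max` (plus grid metadata) go to a `<path>.range.txt` sidecar.
#'
#' @param x A [phase_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(x, path) {
  v <- x$values
  lo <- min(v); hi <- max(v)
  s <- if (hi > lo) (v - lo) / (hi - lo) else v * 0 + 0.5
  tiff::writeTIFF(s, path, bits.per.sample = 32L, compression = "none")
  write_config_file(list(phase_min = lo, phase_max = hi,
                         pixel_pitch_um = x$pixel_pitch_um,
                         wrapped = as.integer(x$wrapped),
                         background_subtracted =
                           as.integer(x$background_subtracted)),
                    range_sidecar(path))
  invisible(path)
}

#' Read a phase map written by [write_phase_tiff()]
#'
#' @param path Input path (sidecar `<path>.range.txt` must exist).
#' @return A [phase_map].
#' @export
read_phase_tiff <- function(path) {
  meta <- read_config_file(range_sidecar(path))
  s <- tiff::readTIFF(path)
  if (length(dim(s)) == 3L) s <- s[, , 1]
  v <- if (meta$phase_max > meta$phase_min)
    s * (meta$phase_max - meta$phase_min) + meta$phase_min
  else matrix(meta$phase_min, nrow(s), ncol(s))
  phase_map(v, meta$pixel_pitch_um,
            wrapped = meta$wrapped == 1,
            background_subtracted = meta$background_subtracted == 1)
}

#' Write a label map as a 16-bit TIFF
#'
#' @param x A `label_map` from [label_components()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(x, path) {
  L <- if (inherits(x, "label_map")) x$labels else x
  if (max(L) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(L / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a label map written by [write_label_tiff()]
#'
#' @param path Input path.
#' @param connectivity Connectivity to record (4 or 8).
#' @return A `label_map`.
#' @export
read_label_tiff <- function(path, connectivity = 8) {
  L <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(L)) == 3L) L <- L[, , 1]
  storage.mode(L) <- "integer"
  structure(list(labels = L, connectivity = connectivity,
                 n_components = max(L), tau = NA_real_),
            class = "label_map")
}

#' Write a flat key-value configuration file
#'
#' One `key = value` pair per line; `NULL` entries are skipped; lines
#' starting with `#` are comments.
#'
#' @param config Named list of scalars.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_file <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  config <- config[keep]
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1))
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' @param path Input path.
#' @return Named list; values are numeric where they parse as numbers
#'   (comma-separated values become numeric vectors).
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Write a scene's ground-truth table as CSV
#'
#' @param scene An `rbc_scene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(scene, path) {
  write.csv(scene$truth, path, row.names = FALSE)
  invisible(path)
}
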