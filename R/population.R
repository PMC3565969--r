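get_volumes <- function(records) {
  if (is.data.frame(records)) records$volume_fl else as.numeric(records)
}

#' Mean corpuscular volume (MCV)
#'
#' Arithmetic mean of the cell volumes, in fL, over cells that passed the
#' 20 fL platelet-exclusion filter.
#'
#' @param records Data frame of cell records (column `volume_fl`) or a
#'   numeric vector of volumes.
#' @return MCV (fL).
#' @export
mcv <- function(records) {
  v <- get_volumes(records)
  if (!length(v)) stop("no cells: MCV undefined", call. = FALSE)
  mean(v)
}

#' Red cell distribution width (RDW)
#'
#' Coefficient of variation of the cell volumes in percent:
#' `100 * sd(V) / mean(V)`, with the sample (n - 1) standard deviation.
#' Scale-invariant: multiplying every volume by a constant leaves RDW
#' unchanged.
#'
#' @inheritParams mcv
#' @return RDW (percent).
#' @export
rdw <- function(records) {
  v <- get_volumes(records)
  if (length(v) < 2)
    stop("insufficient data: RDW needs at least 2 cells", call. = FALSE)
  100 * sd(v) / mean(v)
}

default_bin_width <- function(parameter, v) {
  switch(parameter,
         volume_fl = 1,
         surface_area_um2 = 5,
         max(diff(range(v)) / 30, .Machine$double.eps))
}

#' Histogram and quartile summary of a cell parameter
#'
#' Bins one morphological parameter over the population and summarises it
#' with linear-interpolation quartiles (the convention used for
#' interquartile-range boxes), mean and standard deviation. Default bin
#' widths: 1 fL for volume, 5 um^2 for surface area, range/30 otherwise.
#'
#' @param records Data frame of cell records.
#' @param parameter Column name to summarise (default `"volume_fl"`).
#' @param bin_width Bin width in the parameter's units; `NULL` for the
#'   default.
#' @param breaks Explicit bin edges (overrides `bin_width`).
#' @return List with `parameter`, `histogram` (data frame `lower`,
#'   `upper`, `count`), `quartiles` (q1, median, q3), `mean`, `sd`, `n`.
#' @export
distributions <- function(records, parameter = "volume_fl",
                          bin_width = NULL, breaks = NULL) {
  if (!is.data.frame(records) || !parameter %in% names(records))
    stop("unknown parameter: ", parameter, call. = FALSE)
  v <- records[[parameter]]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values for ", parameter, call. = FALSE)
  if (is.null(breaks)) {
    if (is.null(bin_width)) bin_width <- default_bin_width(parameter, v)
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  }
  cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)  # linear interpolation
  list(parameter = parameter,
       histogram = data.frame(lower = breaks[-length(breaks)],
                              upper = breaks[-1], count = cnt),
       quartiles = c(q1 = q[1], median = q[2], q3 = q[3]),
       mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n = length(v))
}

#' Sample-level hematology summary
#'
#' Aggregates per-cell records into the sample indices reported by a blood
#' test: MCV, RDW, mean surface area, mean sphericity and mean MCD, plus
#' histograms and quartile summaries of the main parameters. Assumes the
#' records already passed the 20 fL filter in [extract_cells()].
#'
#' @param records Data frame of cell records from [analyze_cells()].
#' @param histogram_parameters Character vector of columns to bin.
#' @return An object of class `population_stats`.
#' @export
population_stats <- function(records,
                             histogram_parameters = c(
                               "volume_fl", "surface_area_um2",
                               "sphericity", "mcd_um",
                               "equivalent_diameter_um",
                               "mean_thickness_um")) {
  if (!is.data.frame(records) || !nrow(records))
    stop("no cells: population statistics undefined", call. = FALSE)
  dists <- lapply(histogram_parameters, function(p)
    tryCatch(distributions(records, p), error = function(e) NULL))
  names(dists) <- histogram_parameters
  dists <- dists[!vapply(dists, is.null, logical(1))]
  structure(list(
    n_cells = nrow(records),
    mcv_fl = mcv(records),
    rdw_percent = if (nrow(records) >= 2) rdw(records) else NA_real_,
    msa_um2 = mean(records$surface_area_um2),
    mean_sphericity = mean(records$sphericity),
    mean_mcd_um = mean(records$mcd_um, na.rm = TRUE),
    distributions = dists), class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("<population_stats> n = %d cells\n", x$n_cells))
  cat(sprintf("  MCV  %.1f fL    RDW  %.1f %%\n", x$mcv_fl, x$rdw_percent))
  cat(sprintf("  mean SA %.1f um^2   mean sphericity %.3f   mean MCD %.2f um\n",
              x$msa_um2, x$mean_sphericity, x$mean_mcd_um))
  invisible(x)
}

#' Write the population summary as a compact text file
#'
#' Key-value header followed by per-parameter quartile and histogram
#' tables — the kilobyte-scale "arrays of numbers" a sample distils to.
#'
#' @param stats A `population_stats` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("n_cells = %d", stats$n_cells)
  w("mcv_fl = %.6g", stats$mcv_fl)
  w("rdw_percent = %.6g", stats$rdw_percent)
  w("msa_um2 = %.6g", stats$msa_um2)
  w("mean_sphericity = %.6g", stats$mean_sphericity)
  w("mean_mcd_um = %.6g", stats$mean_mcd_um)
  for (d in stats$distributions) {
    w("")
    w("[distribution %s]", d$parameter)
    w("mean = %.6g", d$mean)
    w("sd = %.6g", d$sd)
    w("q1 = %.6g", d$quartiles[["q1"]])
    w("median = %.6g", d$quartiles[["median"]])
    w("q3 = %.6g", d$quartiles[["q3"]])
    keep <- d$histogram$count > 0
    hh <- d$histogram[keep, , drop = FALSE]
    w("histogram = %s", paste(sprintf("%.6g:%.6g:%d", hh$lower, hh$upper,
                                      hh$count), collapse = " "))
  }
  invisible(path)
}
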