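#' Construct a calibration curve
#'
#' A calibration curve is the fitted linear map between the number of cells in
#' a well and the optical signal it emits (photon flux for bioluminescence,
#' radiant efficiency for fluorescence). It is the bridge used everywhere else
#' in the package to convert measured signal into an inferred cell number.
#'
#' @param slope Signal per cell; must be positive for a usable curve.
#' @param intercept Background signal at zero cells.
#' @param pearson_r Sample Pearson correlation of the points the curve was
#'   fitted to; `NA` for a curve constructed directly rather than fitted.
#' @param n_points Number of calibration points behind the fit.
#' @param modality `"fluorescence"` or `"luminescence"`.
#' @return An object of class `calibration_curve`.
#' @examples
#' calibration_curve(slope = 100, intercept = 0, modality = "fluorescence")
#' @export
calibration_curve <- function(slope, intercept = 0, pearson_r = NA_real_,
                              n_points = NA_integer_,
                              modality = c("fluorescence", "luminescence")) {
  modality <- match.arg(modality)
  assert_scalar_number(slope, "slope", lower = 0, strict_lower = TRUE)
  if (!is.na(pearson_r)) assert_scalar_number(pearson_r, "pearson_r", -1, 1)
  structure(
    list(modality = modality, slope = slope, intercept = intercept,
         pearson_r = pearson_r, n_points = n_points),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s\n", x$modality))
  cat(sprintf("  signal = %.6g * cells + %.6g\n", x$slope, x$intercept))
  if (!is.na(x$pearson_r))
    cat(sprintf("  Pearson R = %.2f over %d points\n", x$pearson_r, x$n_points))
  invisible(x)
}

#' Fit a signal-vs-cell-number calibration curve
#'
#' Ordinary least squares of signal on plated cell number, intercept included
#' (real wells carry background signal; the zero-cell wells of the plated
#' design anchor it). Replicates are pooled, not averaged, so the triplicate
#' variance structure enters the reported Pearson R.
#'
#' @param points Data frame with columns `cell_count`, `signal` and optionally
#'   `modality` (single value) and `replicate`, as produced by
#'   [generate_calibration_plate()] or read from a calibration CSV.
#' @param modality Modality of the curve; taken from the data when present.
#' @return A [calibration_curve()].
#' @examples
#' pts <- data.frame(cell_count = c(0, 1e3, 1e4, 1e5),
#'                   signal = 100 * c(0, 1e3, 1e4, 1e5))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, modality = NULL) {
  if (!is.data.frame(points) || !all(c("cell_count", "signal") %in% names(points)))
    stop_input("points must be a data frame with cell_count and signal columns")
  if (nrow(points) < 3L)
    stop_input("need at least 3 calibration points, got ", nrow(points))
  if (any(points$cell_count < 0) || any(points$signal < 0))
    stop_domain("cell counts and signals must be nonnegative")
  if ("modality" %in% names(points)) {
    mods <- unique(points$modality)
    if (length(mods) > 1L)
      stop_input("calibration points mix modalities: ", paste(mods, collapse = ", "))
    modality <- modality %||% mods
  }
  modality <- modality %||% "fluorescence"
  if (length(unique(points$cell_count)) < 2L)
    stop_input("degenerate design: need at least 2 distinct cell counts")

  fit <- stats::lm(signal ~ cell_count, data = points)
  slope <- unname(stats::coef(fit)["cell_count"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  if (slope <= 0)
    stop_domain("non-monotone calibration: fitted slope ", signif(slope, 4),
                " is not positive")
  r <- pearson_correlation(points$cell_count, points$signal)
  calibration_curve(slope = slope, intercept = intercept, pearson_r = r,
                    n_points = nrow(points), modality = modality)
}

#' Invert a calibration curve: signal to cell number
#'
#' Returns `(signal - intercept) / slope`, clamped at zero. A signal below the
#' fitted background is physically a non-detection, so it maps to zero cells
#' with a warning rather than an error.
#'
#' @param curve A [calibration_curve()].
#' @param signal Nonnegative signal value(s).
#' @return Inferred cell number(s), `>= 0`.
#' @examples
#' cv <- calibration_curve(slope = 250, intercept = 500)
#' cells_from_signal(cv, 10500) # 40
#' @export
cells_from_signal <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(signal)) || any(signal < 0))
    stop_domain("signal must be finite and nonnegative")
  cells <- (signal - curve$intercept) / curve$slope
  below <- cells < 0
  if (any(below)) {
    warning(sprintf("%d signal value(s) below the curve intercept; clamped to 0 cells",
                    sum(below)), call. = FALSE)
    cells[below] <- 0
  }
  cells
}

#' Forward calibration: cell number to expected signal
#'
#' @param curve A [calibration_curve()].
#' @param cells Nonnegative cell number(s).
#' @return Expected signal `slope * cells + intercept`.
#' @export
predict_signal <- function(curve, cells) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(cells)) || any(cells < 0))
    stop_domain("cells must be finite and nonnegative")
  curve$slope * cells + curve$intercept
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around the sample Pearson coefficient, the
#' association statistic used for all signal-vs-cells and modality-vs-modality
#' comparisons in this package.
#'
#' @param x,y Equal-length numeric vectors, each of length `>= 3` and
#'   non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop_input("x and y must have equal length")
  if (length(x) < 3L)
    stop_input("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("undefined correlation: constant input vector")
  stats::cor(x, y, method = "pearson")
}

#' Read calibration points from CSV
#'
#' Expected columns: `modality,cell_count,signal,replicate` (header required).
#'
#' @param path Path to the CSV file.
#' @return Data frame of calibration points.
#' @export
read_calibration <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "cell_count", "signal", "replicate")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop_input("calibration CSV ", path, " missing column(s): ",
               paste(miss, collapse = ", "))
  pts
}

#' Write / read a calibration curve as JSON
#'
#' The JSON carries keys `slope`, `intercept`, `pearson_r`, `n_points`,
#' `modality`.
#'
#' @param curve A [calibration_curve()].
#' @param path Destination / source path.
#' @return `write_curve` returns `path` invisibly; `read_curve` the curve.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(slope = x$slope, intercept = x$intercept,
                    pearson_r = x$pearson_r %||% NA_real_,
                    n_points = as.integer(x$n_points %||% NA_integer_),
                    modality = x$modality)
}
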