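#' Construct a 2D dose grid
#'
#' A dose grid is a regular 2D scalar field of absorbed dose (cGy) with
#' known pixel spacing (mm) and origin (mm).  It is the common currency of
#' every operation in the package: reference (measured) and evaluated
#' (calculated) distributions are both dose grids.
#'
#' The x axis runs along matrix dimension 1 (rows), y along dimension 2
#' (columns); `values[i, j]` is the dose at the pixel center
#' `(origin[1] + (i-1)*spacing[1], origin[2] + (j-1)*spacing[2])`.
#'
#' @param values numeric matrix of dose in cGy; all entries finite and
#'   non-negative.
#' @param spacing numeric pair `(dx, dy)` in mm per pixel, both strictly
#'   positive.  A scalar is recycled to both axes.
#' @param origin numeric pair `(x0, y0)` in mm: physical position of the
#'   center of pixel `[1, 1]`.
#' @return An object of class `dose_grid` with elements `values`,
#'   `spacing`, `origin`.
#' @examples
#' g <- dose_grid(matrix(100, 5, 5), spacing = c(1, 1))
#' pixel_to_physical(g, c(3, 3))
#' @export
dose_grid <- function(values, spacing = c(1, 1), origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("'values' contains non-finite dose (NA/NaN/Inf)", call. = FALSE)
  if (any(values < 0))
    stop("'values' contains negative dose", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be two strictly positive finite values (mm)",
         call. = FALSE)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("'origin' must be two finite values (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' @rdname dose_grid
#' @param x object to test or print.
#' @export
is_dose_grid <- function(x) inherits(x, "dose_grid")

stopifnot_dose_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_dose_grid(x))
    stop(sprintf("'%s' must be a dose_grid", arg), call. = FALSE)
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d pixels, spacing (%g, %g) mm, origin (%g, %g) mm\n",
    d[1], d[2], x$spacing[1], x$spacing[2], x$origin[1], x$origin[2]))
  cat(sprintf("  dose range [%.6g, %.6g] cGy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.dose_grid <- function(x) dim(x$values)

#' Physical coordinates of a pixel center
#'
#' @param grid a [dose_grid()].
#' @param index integer pair `(i, j)`, 1-based, within the grid shape.
#' @return numeric `(x, y)` position in mm of the pixel center.
#' @export
pixel_to_physical <- function(grid, index) {
  stopifnot_dose_grid(grid)
  index <- as.integer(index)
  d <- dim(grid$values)
  if (length(index) != 2L || any(index < 1L) || index[1] > d[1] ||
      index[2] > d[2])
    stop(sprintf("index (%s) out of range for a %d x %d grid",
                 paste(index, collapse = ", "), d[1], d[2]), call. = FALSE)
  c(grid$origin[1] + (index[1] - 1L) * grid$spacing[1],
    grid$origin[2] + (index[2] - 1L) * grid$spacing[2])
}

#' Pixel-center coordinate axes of a grid
#'
#' @param grid a [dose_grid()].
#' @return list with numeric vectors `x` and `y` (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot_dose_grid(grid)
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2])
}

#' Comparison criteria for dose-distribution evaluation
#'
#' Bundles the two acceptance tolerances shared by the gamma and MDdiff
#' methods: the dose-difference criterion \eqn{\delta D^0} (cGy) and the
#' distance-to-agreement criterion \eqn{DTA^0} (mm), plus the prescribed
#' dose used to convert a percentage dose criterion to absolute cGy.  The
#' clinical standard for photon IMRT QA is 3% of the prescribed dose and
#' 3 mm.
#'
#' @param dose_diff dose-difference criterion.  Either a number in cGy, or
#'   a percentage string such as `"3%"`, converted once to
#'   `pct/100 * prescribed`.
#' @param dta distance-to-agreement criterion, mm.
#' @param prescribed prescribed dose, cGy.
#' @return An object of class `dose_criteria` with numeric fields
#'   `dose_diff` (cGy), `dta` (mm), `prescribed` (cGy).
#' @examples
#' dose_criteria("3%", dta = 3, prescribed = 200)  # dose_diff = 6 cGy
#' dose_criteria(6, 3, 200)
#' @export
dose_criteria <- function(dose_diff, dta, prescribed) {
  prescribed <- as.numeric(prescribed)
  if (!isTRUE(is.finite(prescribed)) || prescribed <= 0)
    stop("'prescribed' must be a strictly positive dose in cGy",
         call. = FALSE)
  if (is.character(dose_diff)) {
    if (!grepl("^\\s*[0-9.]+\\s*%\\s*$", dose_diff))
      stop("percentage 'dose_diff' must look like \"3%\"", call. = FALSE)
    pct <- as.numeric(sub("%.*$", "", trimws(dose_diff)))
    dose_diff <- pct / 100 * prescribed
  }
  dose_diff <- as.numeric(dose_diff)
  dta <- as.numeric(dta)
  if (!isTRUE(is.finite(dose_diff)) || dose_diff <= 0)
    stop("'dose_diff' criterion must be strictly positive (cGy)",
         call. = FALSE)
  if (!isTRUE(is.finite(dta)) || dta <= 0)
    stop("'dta' criterion must be strictly positive (mm)", call. = FALSE)
  structure(list(dose_diff = dose_diff, dta = dta, prescribed = prescribed),
            class = "dose_criteria")
}

stopifnot_criteria <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "dose_criteria"))
    stop(sprintf("'%s' must be a dose_criteria object", arg), call. = FALSE)
  invisible(x)
}

#' @export
print.dose_criteria <- function(x, ...) {
  cat(sprintf(
    "<dose_criteria> deltaD0 = %g cGy (%.3g%% of %g cGy), DTA0 = %g mm\n",
    x$dose_diff, 100 * x$dose_diff / x$prescribed, x$prescribed, x$dta))
  invisible(x)
}

#' Per-point metric map
#'
#' Holds per-point metric values on the reference grid: signed MDdiff in
#' cGy, or unitless gamma (>= 0), together with a validity mask marking
#' reference points where the metric could be computed (e.g. points whose
#' evaluated-dose counterpart lies inside the evaluated extent).
#'
#' @param values numeric matrix of metric values (NA allowed where
#'   invalid).
#' @param metric metric label: `"mddiff"` or `"gamma"`.
#' @param valid logical matrix of the same shape; defaults to
#'   `is.finite(values)`.
#' @param reference the reference [dose_grid()] the map lives on
#'   (optional; carries geometry for printing and reporting).
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(values, metric, valid = NULL, reference = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  metric <- match.arg(metric, c("mddiff", "gamma"))
  if (is.null(valid)) valid <- is.finite(values)
  if (!is.logical(valid) || !identical(dim(valid), dim(values)))
    stop("'valid' must be a logical matrix of the same shape", call. = FALSE)
  if (any(valid & !is.finite(values)))
    stop("valid points must carry finite metric values", call. = FALSE)
  if (metric == "gamma" && any(values[valid] < 0))
    stop("gamma values must be non-negative", call. = FALSE)
  if (!is.null(reference)) {
    stopifnot_dose_grid(reference)
    if (!identical(dim(reference$values), dim(values)))
      stop("metric map shape must equal the reference grid shape",
           call. = FALSE)
  }
  structure(list(values = values, valid = valid, metric = metric,
                 reference = reference),
            class = "metric_map")
}

stopifnot_metric <- function(map, metric, arg = deparse(substitute(map))) {
  if (!inherits(map, "metric_map"))
    stop(sprintf("'%s' must be a metric_map", arg), call. = FALSE)
  if (!identical(map$metric, metric))
    stop(sprintf("'%s' is a %s map; a %s map is required",
                 arg, map$metric, metric), call. = FALSE)
  invisible(map)
}

#' @export
print.metric_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$valid]
  unit <- if (x$metric == "mddiff") " cGy" else ""
  cat(sprintf("<metric_map> %s, %d x %d (%d valid points)\n",
              x$metric, d[1], d[2], sum(x$valid)))
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g]%s, mean %.4g%s\n",
                min(v), max(v), unit, mean(v), unit))
  invisible(x)
}
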