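#' Write a dose grid to a plain-text file
#'
#' The self-describing `dgrid-text` format: `key=value` header lines
#' (format version, shape, spacing in mm, origin in mm, dose unit)
#' followed by one whitespace-delimited line of doses per grid row
#' (matrix dimension 1, the x axis).  Values round-trip to better than
#' 1e-6 cGy and the geometry round-trips exactly.  Alternatively a bare
#' CSV of dose values (geometry supplied by the reader).
#'
#' @param grid a [dose_grid()].
#' @param path output file.
#' @param format `"dgrid"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path, format = c("dgrid", "csv")) {
  stopifnot_dose_grid(grid)
  format <- match.arg(format)
  d <- dim(grid$values)
  if (format == "csv") {
    utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "format=dgrid-text-1",
    sprintf("shape=%d %d", d[1], d[2]),
    sprintf("spacing=%.17g %.17g", grid$spacing[1], grid$spacing[2]),
    sprintf("origin=%.17g %.17g", grid$origin[1], grid$origin[2]),
    "unit=cGy"), con)
  for (i in seq_len(d[1]))
    writeLines(paste(sprintf("%.10g", grid$values[i, ]), collapse = " "),
               con)
  invisible(path)
}

#' Read a dose grid from a plain-text file
#'
#' @param path input file.
#' @param format `"dgrid"` (self-describing header, see
#'   [write_dose_grid()]) or `"csv"` (bare dose values; `spacing` must
#'   then be supplied).
#' @param spacing pixel spacing in mm, required for `"csv"` input.
#' @param origin grid origin in mm for `"csv"` input (default `(0, 0)`).
#' @return a validated [dose_grid()]; parse failures report the
#'   offending line and column.
#' @export
read_dose_grid <- function(path, format = c("dgrid", "csv"),
                           spacing = NULL, origin = c(0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    if (is.null(spacing))
      stop("csv input carries no geometry: supply 'spacing' (mm)",
           call. = FALSE)
    vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(vals) <- NULL
    return(dose_grid(vals, spacing = spacing, origin = origin))
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("=", lines[i], fixed = TRUE)) {
    kv <- sub("=.*$", "", lines[i])
    hdr[[kv]] <- sub("^[^=]*=", "", lines[i])
    i <- i + 1L
  }
  for (key in c("format", "shape", "spacing", "origin", "unit"))
    if (is.null(hdr[[key]]))
      stop(sprintf("missing header key '%s' in %s", key, path),
           call. = FALSE)
  if (hdr$format != "dgrid-text-1")
    stop(sprintf("unsupported format '%s' (line 1)", hdr$format),
         call. = FALSE)
  num_pair <- function(key) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(hdr[[key]]),
                                              "\\s+")[[1]]))
    if (length(v) != 2L || any(is.na(v)))
      stop(sprintf("header key '%s' must hold two numbers", key),
           call. = FALSE)
    v
  }
  shape <- as.integer(num_pair("shape"))
  spacing <- num_pair("spacing")
  origin <- num_pair("origin")
  data_lines <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != shape[1])
    stop(sprintf("header shape declares %d rows but %d data lines found",
                 shape[1], length(data_lines)), call. = FALSE)
  vals <- matrix(NA_real_, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    row <- suppressWarnings(
      as.numeric(strsplit(trimws(data_lines[r]), "\\s+")[[1]]))
    lineno <- i + r - 1L
    if (length(row) != shape[2])
      stop(sprintf("line %d: %d values, expected %d",
                   lineno, length(row), shape[2]), call. = FALSE)
    if (any(is.na(row)))
      stop(sprintf("line %d, column %d: unparseable dose value",
                   lineno, which(is.na(row))[1]), call. = FALSE)
    if (any(row < 0))
      stop(sprintf("line %d, column %d: negative dose",
                   lineno, which(row < 0)[1]), call. = FALSE)
    vals[r, ] <- row
  }
  dose_grid(vals, spacing = spacing, origin = origin)
}
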