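#' Options controlling the gamma-index search
#'
#' @param search_radius maximum spatial search distance in mm; must be at
#'   least the DTA criterion.  `NULL` (default) picks
#'   `max(3 * DTA0, DTA0 + 2 * max(spacing))` at evaluation time, large
#'   enough that the spatial term alone exceeds 3 at the cut-off.
#' @param subsample integer >= 1: the evaluated grid is bilinearly
#'   refined by this factor before the search, reducing the gamma
#'   index's well-known sensitivity to dose grid resolution.
#' @return an object of class `gamma_options`.
#' @export
gamma_options <- function(search_radius = NULL, subsample = 4L) {
  subsample <- as.integer(subsample)
  if (is.na(subsample) || subsample < 1L)
    stop("'subsample' must be an integer >= 1", call. = FALSE)
  if (!is.null(search_radius)) {
    search_radius <- as.numeric(search_radius)
    if (!isTRUE(is.finite(search_radius)) || search_radius <= 0)
      stop("'search_radius' must be a positive distance in mm",
           call. = FALSE)
  }
  structure(list(search_radius = search_radius, subsample = subsample),
            class = "gamma_options")
}

# Bilinearly refined copy of the evaluated grid: axes at spacing/k over
# the same physical extent.  k = 1 returns the grid's own nodes.
refine_grid <- function(grid, k) {
  a <- grid_axes(grid)
  xs <- if (length(a$x) > 1L)
    seq(a$x[1], a$x[length(a$x)], by = grid$spacing[1] / k) else a$x
  ys <- if (length(a$y) > 1L)
    seq(a$y[1], a$y[length(a$y)], by = grid$spacing[2] / k) else a$y
  xy <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  vals <- matrix(bilinear_sample(grid, xy$x, xy$y),
                 length(xs), length(ys))
  list(x = xs, y = ys, values = vals)
}

resolve_gamma_options <- function(options, criteria, evaluated) {
  if (is.null(options)) options <- gamma_options()
  if (!inherits(options, "gamma_options"))
    stop("'options' must come from gamma_options()", call. = FALSE)
  r <- options$search_radius
  if (is.null(r))
    r <- max(3 * criteria$dta, criteria$dta + 2 * max(evaluated$spacing))
  if (r < criteria$dta)
    stop("'search_radius' must be at least the DTA criterion",
         call. = FALSE)
  list(search_radius = r, subsample = options$subsample)
}

# Shared per-point machinery for both gamma implementations.  `prune`
# selects the accelerated exact search (gamma_map) or the exhaustive
# enumeration (gamma_bruteforce); both minimize over the identical
# candidate set (refined evaluated points within the circular search
# disc) and therefore agree to floating-point precision.
gamma_engine <- function(evaluated, reference, criteria, options, prune) {
  stopifnot_dose_grid(evaluated)
  stopifnot_dose_grid(reference)
  stopifnot_criteria(criteria)
  opt <- resolve_gamma_options(options, criteria, evaluated)
  R <- opt$search_radius
  R2 <- R^2 * (1 + 1e-12) + 1e-12
  dta2 <- criteria$dta^2
  dd2 <- criteria$dose_diff^2
  ref <- refine_grid(evaluated, opt$subsample)
  ra <- grid_axes(reference)
  d <- dim(reference$values)
  out <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  n_candidates <- 0
  ex <- ref$x; ey <- ref$y; ev <- ref$values
  nX <- length(ex); nY <- length(ey)
  for (j in seq_len(d[2])) {
    yr <- ra$y[j]
    jwin <- which(abs(ey - yr) <= R)
    if (!length(jwin)) next
    dy2_all <- (ey[jwin] - yr)^2
    for (i in seq_len(d[1])) {
      xr <- ra$x[i]
      iwin <- which(abs(ex - xr) <= R)
      if (!length(iwin)) next
      dr <- reference$values[i, j]
      dx2_all <- (ex[iwin] - xr)^2
      best2 <- Inf
      ii <- iwin; jj <- jwin
      dx2 <- dx2_all; dy2 <- dy2_all
      if (prune) {
        # exact pruning: seed a bound from the candidate nearest the
        # reference point, then shrink the window to the radius within
        # which the spatial term alone could still beat the bound
        i0 <- ii[which.min(dx2)]; j0 <- jj[which.min(dy2)]
        d2n <- min(dx2) + min(dy2)
        if (d2n <= R2) {
          best2 <- d2n / dta2 + (ev[i0, j0] - dr)^2 / dd2
          reff2 <- min(R2, dta2 * best2)
          keep_i <- dx2 <= reff2; keep_j <- dy2 <= reff2
          ii <- ii[keep_i]; dx2 <- dx2[keep_i]
          jj <- jj[keep_j]; dy2 <- dy2[keep_j]
        }
      }
      if (length(ii) && length(jj)) {
        d2 <- outer(dx2, dy2, "+")
        disc <- d2 <= R2
        if (any(disc)) {
          g2 <- d2 / dta2 + (ev[ii, jj, drop = FALSE] - dr)^2 / dd2
          best2 <- min(best2, min(g2[disc]))
          n_candidates <- n_candidates + sum(disc)
        }
      }
      if (is.finite(best2)) {
        out[i, j] <- sqrt(best2)
        # flagged invalid when the search square is clipped by the
        # evaluated extent (edge points lack the full candidate disc)
        valid[i, j] <- xr - R >= ex[1] - 1e-9 && xr + R <= ex[nX] + 1e-9 &&
                       yr - R >= ey[1] - 1e-9 && yr + R <= ey[nY] + 1e-9
      }
    }
  }
  map <- metric_map(out, "gamma", valid = valid & is.finite(out),
                    reference = reference)
  attr(map, "n_candidates") <- n_candidates
  attr(map, "search_radius") <- R
  attr(map, "subsample") <- opt$subsample
  map
}

#' Gamma-index map
#'
#' Classic gamma evaluation: for every reference point \eqn{r_r},
#' \deqn{\gamma(r_r) = \min_{r_e} \sqrt{\frac{|r_e - r_r|^2}{DTA^{0\,2}}
#'   + \frac{(D_e(r_e) - D_r(r_r))^2}{\delta D^{0\,2}}}}
#' over evaluated positions \eqn{r_e} within `search_radius`, with the
#' evaluated field bilinearly refined by the subsample factor.  Global
#' absolute-dose normalization (\eqn{\delta D^0} in cGy).  A point
#' conventionally fails at \eqn{\gamma \ge 1}.
#'
#' The search is exact over the candidate set but accelerated: once a
#' candidate bounds \eqn{\gamma}, positions whose spatial term alone
#' exceeds the bound are skipped.  [gamma_bruteforce()] performs the same
#' minimization by exhaustive enumeration and is used as a verification
#' oracle.
#'
#' Reference points whose full search disc is not covered by the
#' evaluated extent still receive a gamma value from the available
#' candidates but are flagged `FALSE` in the validity mask, so summary
#' statistics are not biased by artificial edge failures.
#'
#' @param evaluated evaluated [dose_grid()]; it shares the physical
#'   coordinate frame with the reference but need not share its geometry.
#' @param reference reference [dose_grid()].
#' @param criteria a [dose_criteria()].
#' @param options a [gamma_options()], or `NULL` for defaults.
#' @return a [metric_map()] (metric `"gamma"`).  Attribute
#'   `n_candidates` counts the candidate evaluations performed.
#' @examples
#' ref <- dose_grid(matrix(100, 9, 9))
#' ev <- dose_grid(matrix(106, 9, 9))
#' crit <- dose_criteria(6, 3, 200)
#' g <- gamma_map(ev, ref, crit)   # gamma = 1 everywhere
#' @export
gamma_map <- function(evaluated, reference, criteria, options = NULL) {
  gamma_engine(evaluated, reference, criteria, options, prune = TRUE)
}

#' Brute-force gamma oracle
#'
#' Identical contract to [gamma_map()], computed by exhaustively
#' enumerating every refined evaluated point within the search radius of
#' each reference point, with no pruning or shortcuts.  Intended for
#' verification on small grids; its cost grows as the number of
#' reference points times the search-disc size.
#'
#' @inheritParams gamma_map
#' @return a [metric_map()] (metric `"gamma"`) with attribute
#'   `n_candidates` equal to the full candidate count enumerated.
#' @export
gamma_bruteforce <- function(evaluated, reference, criteria,
                             options = NULL) {
  gamma_engine(evaluated, reference, criteria, options, prune = FALSE)
}

#' Pass/fail mask for a gamma map
#'
#' A point fails when \eqn{\gamma \ge 1}.
#'
#' @param map a gamma [metric_map()].
#' @return list with `mask` (logical, `TRUE` = failing, `NA` at invalid
#'   points), `failing`, `total` (valid points), `ratio`.
#' @export
gamma_pass_mask <- function(map) {
  stopifnot_metric(map, "gamma")
  mask <- map$values >= 1
  mask[!map$valid] <- NA
  failing <- sum(mask, na.rm = TRUE)
  total <- sum(map$valid)
  list(mask = mask, failing = failing, total = total,
       ratio = if (total > 0) failing / total else NA_real_)
}
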