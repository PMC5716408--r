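#' Linear ramp dose field
#'
#' A field varying linearly along x, `D(x, y) = base_dose + slope * x`
#' (clipped at 0), on a square extent.  Ramps exercise the two regimes
#' the metrics distinguish: their constant, exactly-known gradient makes
#' closed-form predictions possible for shift-induced dose differences.
#'
#' @param slope dose gradient along x, cGy/mm (>= 0).
#' @param extent side length of the square field, mm.
#' @param spacing pixel spacing, mm (scalar or pair).
#' @param base_dose dose at x = 0, cGy.
#' @return a [dose_grid()] with origin (0, 0).
#' @export
ramp_field <- function(slope, extent = 50, spacing = 1, base_dose = 0) {
  if (slope < 0) stop("'slope' must be >= 0", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  x <- seq(0, extent, by = spacing[1])
  y <- seq(0, extent, by = spacing[2])
  vals <- matrix(pmax(base_dose + slope * x, 0), length(x), length(y))
  dose_grid(vals, spacing = spacing, origin = c(0, 0))
}

# Gaussian-blurred indicator of [a, b]: the convolution of a rectangular
# aperture edge with a normal penumbra of width sigma.
erf_profile <- function(t, a, b, sigma) {
  pnorm((t - a) / sigma) - pnorm((t - b) / sigma)
}

#' IMRT-like planar dose field
#'
#' Emulates a modulated planar dose distribution as a sum of rectangular
#' apertures convolved with a Gaussian penumbra (products of
#' error-function edge profiles along x and y).  This surrogate contains
#' the regimes an IMRT QA plane presents to a comparison metric: flat
#' plateaus (zero gradient, where MDdiff equals the plain dose
#' difference), steep penumbrae of several cGy/mm at the aperture edges
#' (where gradient suppression acts), and low-dose background.  The peak
#' edge gradient of an isolated aperture is `dose / (sigma * sqrt(2*pi))`.
#'
#' @param apertures list of apertures, each a list/vector with elements
#'   `center` (mm, scalar or `(cx, cy)` pair), `width` (mm, scalar or
#'   `(wx, wy)` pair) and `dose` (cGy).
#' @param penumbra_sigma Gaussian penumbra width, mm (> 0).
#' @param spacing pixel spacing, mm.
#' @param extent side length of the square field, mm.
#' @return a [dose_grid()] with origin (0, 0).
#' @examples
#' f <- imrt_like_field(list(list(center = 30, width = 30, dose = 200)),
#'                      penumbra_sigma = 3, spacing = 1, extent = 60)
#' @export
imrt_like_field <- function(apertures, penumbra_sigma = 3, spacing = 1,
                            extent = 60) {
  if (penumbra_sigma <= 0)
    stop("'penumbra_sigma' must be > 0", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  x <- seq(0, extent, by = spacing[1])
  y <- seq(0, extent, by = spacing[2])
  vals <- matrix(0, length(x), length(y))
  for (ap in apertures) {
    ap <- as.list(ap)
    ctr <- rep(as.numeric(ap$center), length.out = 2L)
    wid <- rep(as.numeric(ap$width), length.out = 2L)
    px <- erf_profile(x, ctr[1] - wid[1] / 2, ctr[1] + wid[1] / 2,
                      penumbra_sigma)
    py <- erf_profile(y, ctr[2] - wid[2] / 2, ctr[2] + wid[2] / 2,
                      penumbra_sigma)
    vals <- vals + as.numeric(ap$dose) * outer(px, py)
  }
  dose_grid(pmax(vals, 0), spacing = spacing, origin = c(0, 0))
}

#' Specification of a controlled discrepancy
#'
#' Parameters of a synthetic discrepancy between an evaluated and a
#' reference distribution: a rigid spatial shift (the alignment errors
#' that dominate penumbra disagreement), a multiplicative dose scaling
#' (output/calibration error), and additive Gaussian noise (detector
#' noise).
#'
#' @param shift `(sx, sy)` shift in mm applied to the dose pattern.
#' @param dose_scale multiplicative factor (> 0).
#' @param noise_sigma standard deviation of additive Gaussian noise, cGy
#'   (>= 0).
#' @param seed integer seed making the noise reproducible; required when
#'   `noise_sigma > 0`.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(shift = c(0, 0), dose_scale = 1,
                              noise_sigma = 0, seed = NULL) {
  shift <- rep(as.numeric(shift), length.out = 2L)
  if (any(!is.finite(shift)))
    stop("'shift' must be finite (mm)", call. = FALSE)
  if (!isTRUE(is.finite(dose_scale)) || dose_scale <= 0)
    stop("'dose_scale' must be > 0", call. = FALSE)
  if (!isTRUE(is.finite(noise_sigma)) || noise_sigma < 0)
    stop("'noise_sigma' must be >= 0 (cGy)", call. = FALSE)
  if (noise_sigma > 0 && is.null(seed))
    stop("'seed' is required when noise_sigma > 0", call. = FALSE)
  structure(list(shift = shift, dose_scale = dose_scale,
                 noise_sigma = noise_sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply a controlled discrepancy to a dose grid
#'
#' Produces an "evaluated" distribution with known ground-truth
#' discrepancy: the dose pattern is rigidly shifted by `(sx, sy)` mm
#' (bilinear resampling; positions sampling beyond the original extent
#' take the clamped edge value), multiplied by `dose_scale`, and
#' perturbed by seeded Gaussian noise of sd `noise_sigma`; the result is
#' clipped at 0.  Shift and scale commute when `noise_sigma = 0`.
#'
#' @param grid a [dose_grid()].
#' @param spec a [perturbation_spec()].
#' @return a [dose_grid()] on the same geometry.
#' @export
apply_perturbation <- function(grid, spec) {
  stopifnot_dose_grid(grid)
  if (!inherits(spec, "perturbation_spec"))
    stop("'spec' must come from perturbation_spec()", call. = FALSE)
  vals <- grid$values
  if (any(spec$shift != 0)) {
    a <- grid_axes(grid)
    # shifting the pattern by +s means sampling the original at x - s;
    # clamp sample positions to the extent (no dose invented outside)
    xs <- pmin(pmax(a$x - spec$shift[1], a$x[1]), a$x[length(a$x)])
    ys <- pmin(pmax(a$y - spec$shift[2], a$y[1]), a$y[length(a$y)])
    xy <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
    vals <- matrix(bilinear_sample(grid, xy$x, xy$y),
                   length(xs), length(ys))
  }
  vals <- vals * spec$dose_scale
  if (spec$noise_sigma > 0) {
    noise <- withr::with_seed(spec$seed,
      matrix(rnorm(length(vals), sd = spec$noise_sigma),
             nrow(vals), ncol(vals)))
    vals <- vals + noise
  }
  dose_grid(pmax(vals, 0), spacing = grid$spacing, origin = grid$origin)
}

#' Base IMRT-like plan of the synthetic cohort
#'
#' Four square apertures at graded dose levels (200, 150, 100, 60 cGy)
#' plus their penumbrae, giving flat plateaus, edge gradients of roughly
#' 25 cGy/mm, and low-dose background on a single plane — the dose
#' regimes a clinical IMRT QA plane presents.
#'
#' @param spacing pixel spacing, mm.
#' @param extent side length, mm.
#' @return a [dose_grid()].
#' @export
cohort_base_field <- function(spacing = 1, extent = 79) {
  imrt_like_field(
    apertures = list(
      list(center = c(24, 24), width = c(26, 26), dose = 200),
      list(center = c(56, 24), width = c(22, 22), dose = 150),
      list(center = c(24, 56), width = c(22, 22), dose = 100),
      list(center = c(56, 56), width = c(18, 18), dose = 60)),
    penumbra_sigma = 2.5, spacing = spacing, extent = extent)
}

#' Synthetic QA cohort with graded discrepancy severity
#'
#' A reproducible cohort of reference/evaluated pairs standing in for a
#' set of patient-specific QA cases.  Every case shares the same
#' IMRT-like reference plane; the evaluated plane of case k carries a
#' perturbation of strictly increasing severity: case 1 is the identity
#' (perfect agreement), and subsequent cases combine a growing dose
#' scaling (4% to 10%), a growing rigid shift (1 to 4 mm) and mild
#' detector noise (0.3 cGy), spanning near-perfect to clearly failing
#' QA outcomes.
#'
#' @param n_cases number of cases (>= 2).
#' @param seed integer seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @param spacing pixel spacing of the generated planes, mm.
#' @param extent side length of the planes, mm.
#' @return list of cases; each case is a list with `reference`,
#'   `evaluated` (dose grids), `severity` (strictly increasing, 0 for
#'   the identity case) and `spec` (the [perturbation_spec()] used).
#' @export
synthetic_cohort <- function(n_cases = 9, seed = 1, spacing = 1,
                             extent = 79) {
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 2L)
    stop("'n_cases' must be >= 2", call. = FALSE)
  ref <- cohort_base_field(spacing = spacing, extent = extent)
  lapply(seq_len(n_cases), function(k) {
    if (k == 1L) {
      spec <- perturbation_spec()
      ev <- ref
      sev <- 0
    } else {
      t <- (k - 2L) / max(n_cases - 2L, 1L)
      spec <- perturbation_spec(
        shift = c(1 + 3 * t, 0.5 + 1.5 * t),
        dose_scale = 1.04 + 0.06 * t,
        noise_sigma = 0.3,
        seed = as.integer((seed %% 100000L) * 1000L + k))
      ev <- apply_perturbation(ref, spec)
      sev <- k - 1
    }
    list(case_id = sprintf("QA%d", k), reference = ref, evaluated = ev,
         severity = sev, spec = spec)
  })
}
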