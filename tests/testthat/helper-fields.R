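# Shared fixtures: every test grid is generated in code.

# A random smooth-ish dose grid (uniform noise dose field is fine for
# metric algebra; smoothness only matters where a test says so).
random_grid <- function(nx = sample(8:40, 1), ny = sample(8:40, 1),
                        spacing = round(runif(1, 0.5, 2), 2),
                        max_dose = 200, origin = c(0, 0)) {
  dose_grid(matrix(runif(nx * ny, 0, max_dose), nx, ny),
            spacing = c(spacing, spacing), origin = origin)
}

# A random reference/evaluated pair on a shared geometry, with a random
# smooth discrepancy, plus random criteria.
random_pair <- function(nx = sample(10:30, 1), ny = sample(10:30, 1)) {
  ref <- imrt_like_field(
    apertures = list(list(center = c(nx / 2, ny / 2),
                          width = c(nx / 2, ny / 2),
                          dose = runif(1, 80, 220))),
    penumbra_sigma = runif(1, 1.5, 4),
    spacing = 1, extent = max(nx, ny))
  spec <- perturbation_spec(shift = runif(2, -2, 2),
                            dose_scale = runif(1, 0.93, 1.07),
                            noise_sigma = runif(1, 0, 1),
                            seed = sample.int(1e6, 1))
  list(reference = ref, evaluated = apply_perturbation(ref, spec),
       criteria = dose_criteria(runif(1, 3, 9), runif(1, 1.5, 4),
                                prescribed = 200))
}

# Run the CLI script in a child R process with the current library paths.
run_doseqa <- function(args) {
  cli <- system.file("cli", "doseqa", package = "mddiff")
  stopifnot(nzchar(cli))
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(shQuote(cli), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
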