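crit633 <- dose_criteria(6, 3, 200)

test_that("gradient magnitude matches analytic fields", {
  expect_equal(gradient_magnitude(dose_grid(matrix(100, 10, 10))),
               matrix(0, 10, 10))

  ramp <- ramp_field(slope = 2, extent = 20, spacing = 1)
  g <- gradient_magnitude(ramp)
  expect_equal(g[2:19, ], matrix(2, 18, 21), tolerance = 1e-12)

  plane <- dose_grid(outer(0:10, 0:10, function(i, j) 3 * i + 4 * j),
                     spacing = c(1, 1))
  g <- gradient_magnitude(plane)
  expect_equal(g[2:10, 2:10], matrix(5, 9, 9), tolerance = 1e-12)

  # anisotropic spacing enters the mm-denominator
  plane2 <- dose_grid(outer(0:10, 0:10, function(i, j) 6 * i + 4 * j),
                      spacing = c(2, 1))
  g2 <- gradient_magnitude(plane2)
  expect_equal(g2[5, 5], 5, tolerance = 1e-12)

  expect_error(gradient_magnitude(dose_grid(matrix(1, 1, 5))), "2 x 2")
})

test_that("beta_dg scales the gradient by DTA0/deltaD0", {
  z <- matrix(0, 4, 4)
  expect_equal(beta_dg(z, crit633), z)
  g <- matrix(2, 4, 4)
  expect_equal(beta_dg(g, crit633), matrix(1, 4, 4))
  crit_dta6 <- dose_criteria(6, 6, 200)
  expect_equal(beta_dg(g, crit_dta6), 2 * beta_dg(g, crit633))
  withr::local_seed(3)
  gr <- matrix(runif(16, 0, 10), 4, 4)
  expect_equal(beta_dg(gr, crit633), gr * 3 / 6)
})

test_that("dose difference is signed evaluated-minus-reference", {
  withr::local_seed(5)
  ref <- random_grid(12, 12)
  expect_equal(dose_difference(ref, ref)$values, matrix(0, 12, 12))

  ev <- dose_grid(ref$values + 6, ref$spacing, ref$origin)
  expect_equal(dose_difference(ev, ref)$values, matrix(6, 12, 12))

  ramp <- ramp_field(slope = 2, extent = 30, spacing = 1, base_dose = 10)
  shifted <- apply_perturbation(ramp, perturbation_spec(shift = c(3, 0)))
  dd <- dose_difference(shifted, ramp)
  expect_equal(dd$values[5:27, ], matrix(-6, 23, 31), tolerance = 1e-9)

  expect_error(dose_difference(dose_grid(matrix(0, 3, 3)), ref), "shape")
})

test_that("mddiff reduces to the dose difference on flat fields", {
  ref <- dose_grid(matrix(100, 15, 15))
  ev <- dose_grid(matrix(106, 15, 15))
  md <- mddiff_map(ev, ref, crit633)
  expect_equal(md$values, matrix(6, 15, 15))

  # zero-gradient equivalence with arbitrary evaluated dose
  withr::local_seed(7)
  ev2 <- random_grid(15, 15)
  expect_identical(mddiff_map(ev2, ref, crit633)$values,
                   dose_difference(ev2, ref)$values)
})

test_that("mddiff follows the closed-form ramp/shift law", {
  # slope g, shift s: deltaD = -g*s, beta = g*DTA0/deltaD0, so
  # MDdiff = -g*s*deltaD0 / (deltaD0 + g*DTA0)
  for (g in c(1, 2, 4)) {
    for (s in c(1, 3)) {
      ramp <- ramp_field(slope = g, extent = 40, spacing = 1,
                         base_dose = 20)
      ev <- apply_perturbation(ramp, perturbation_spec(shift = c(s, 0)))
      md <- mddiff_map(ev, ramp, crit633)
      expected <- -g * s * 6 / (6 + g * 3)
      interior <- md$values[(s + 2):39, ]
      expect_equal(interior, matrix(expected, nrow(interior), 41),
                   tolerance = 1e-6)
    }
  }
})

test_that("mddiff shrinks, preserves sign, and suppresses monotonically", {
  withr::local_seed(41)
  for (rep in 1:20) {
    pr <- random_pair()
    rs <- resample_to_reference(pr$evaluated, pr$reference)
    dd <- dose_difference(rs$grid, pr$reference, valid = rs$valid)
    md <- mddiff_map(rs$grid, pr$reference, pr$criteria, valid = rs$valid)
    v <- md$valid
    expect_true(all(abs(md$values[v]) <= abs(dd$values[v]) + 1e-12))
    expect_true(all(sign(md$values[v]) == sign(dd$values[v])))
    # where beta vanishes MDdiff equals the dose difference exactly;
    # where beta is appreciable the shrinkage is strict
    beta <- beta_dg(gradient_magnitude(pr$reference), pr$criteria)
    expect_identical(md$values[beta == 0 & v], dd$values[beta == 0 & v])
    strict <- v & beta > 1e-9 & abs(dd$values) > 1e-9
    expect_true(all(abs(md$values[strict]) < abs(dd$values[strict])))
  }

  # fixed deltaD, growing gradient: |MDdiff| strictly decreases
  vals <- sapply(c(0, 1, 2, 4, 8), function(g) {
    ramp <- ramp_field(slope = g, extent = 20, spacing = 1, base_dose = 50)
    ev <- dose_grid(ramp$values + 6, ramp$spacing, ramp$origin)
    mddiff_map(ev, ramp, crit633)$values[10, 10]
  })
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 6)
})

test_that("mddiff evaluates each reference point exactly once", {
  for (n in c(10, 25)) {
    ref <- dose_grid(matrix(100, n, n))
    md <- mddiff_map(ref, ref, crit633)
    expect_identical(attr(md, "n_evaluations"), as.integer(n * n))
  }
})

test_that("mddiff pass rule fails points at half the dose criterion", {
  vals <- matrix(c(-3.1, 2.9, 3.0, -0.5), 2, 2)
  map <- metric_map(vals, "mddiff")
  pm <- mddiff_pass_mask(map, crit633)
  expect_equal(pm$failing, 2L)
  expect_equal(pm$total, 4L)
  expect_equal(pm$ratio, 0.5)
  expect_identical(pm$mask, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))

  # boundary is inclusive
  bdy <- metric_map(matrix(3, 5, 5), "mddiff")
  expect_equal(mddiff_pass_mask(bdy, crit633)$failing, 25L)

  # all-zero map passes everywhere
  expect_equal(mddiff_pass_mask(metric_map(matrix(0, 4, 4), "mddiff"),
                                crit633)$failing, 0L)

  # literal signed rule ignores under-dosed points
  under <- metric_map(matrix(-5, 3, 3), "mddiff")
  expect_equal(mddiff_pass_mask(under, crit633)$failing, 9L)
  expect_equal(mddiff_pass_mask(under, crit633, signed = TRUE)$failing, 0L)

  # configurable critical value
  expect_equal(mddiff_pass_mask(under, crit633,
                                threshold_factor = 1)$failing, 0L)

  gm <- metric_map(matrix(0.5, 2, 2), "gamma")
  expect_error(mddiff_pass_mask(gm, crit633), "mddiff map is required")
})
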