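crit633 <- dose_criteria(6, 3, 200)

test_that("summary statistics match hand-enumerated maps", {
  md <- metric_map(matrix(c(3, -3, 0, 0), 2, 2), "mddiff")
  s <- summarize_metric(md, crit633)
  expect_equal(s$failing, 2L)
  expect_equal(s$ratio, 0.5)
  expect_equal(s$mean, 0)
  expect_equal(s$mean_abs, 1.5)
  expect_equal(s$max_abs, 3)

  gm <- metric_map(matrix(c(0.5, 1.5), 1, 2), "gamma")
  s <- summarize_metric(gm, crit633)
  expect_equal(s$failing, 1L)
  expect_equal(s$ratio, 0.5)
  expect_equal(s$mean, 1.0)
  expect_equal(s$max_abs, 1.5)

  z <- summarize_metric(metric_map(matrix(0, 10, 10), "mddiff"), crit633)
  expect_equal(z$failing, 0L)
  expect_equal(z$mean, 0)
  expect_equal(z$max_abs, 0)

  none <- metric_map(matrix(NA_real_, 2, 2), "mddiff",
                     valid = matrix(FALSE, 2, 2))
  expect_error(summarize_metric(none, crit633), "no valid points")
})

test_that("summary invariants hold on random maps", {
  withr::local_seed(31)
  for (rep in 1:20) {
    vals <- matrix(rnorm(100, sd = 4), 10, 10)
    s <- summarize_metric(metric_map(vals, "mddiff"), crit633)
    expect_gte(s$mean_abs, abs(s$mean))
    expect_gte(s$max_abs, s$mean_abs)
    expect_true(s$failing >= 0 && s$failing <= s$total)
    expect_equal(s$ratio, s$failing / s$total)
  }
})

test_that("criteria sweeps are monotone and validated", {
  withr::local_seed(37)
  opt <- gamma_options(subsample = 2)
  ref <- imrt_like_field(list(list(center = 15, width = 14, dose = 200)),
                         penumbra_sigma = 2.5, spacing = 1, extent = 30)
  ev <- apply_perturbation(ref, perturbation_spec(shift = c(1.5, 0.5),
                                                  dose_scale = 1.05))
  dd_list <- lapply(c(2, 4, 6, 9, 12),
                    function(v) dose_criteria(v, 3, 200))
  tab <- criteria_sweep(ev, ref, dd_list, which = "dd", options = opt)
  expect_equal(nrow(tab), 5L)
  expect_true(all(diff(tab$gamma_failing) <= 0))
  expect_true(all(diff(tab$mddiff_failing) <= 0))

  dta_list <- lapply(c(1, 2, 3, 5), function(v) dose_criteria(6, v, 200))
  tab2 <- criteria_sweep(ev, ref, dta_list, which = "dta", options = opt)
  expect_true(all(diff(tab2$gamma_failing) <= 0))
  expect_true(all(diff(tab2$mddiff_failing) <= 0))

  # identical pair: no failures at any criteria
  tab3 <- criteria_sweep(ref, ref, dd_list, which = "dd", options = opt)
  expect_true(all(tab3$gamma_failing == 0))
  expect_true(all(tab3$mddiff_failing == 0))

  # flat pair offset 6 cGy: gamma failures vanish once deltaD0 > 6
  flat <- dose_grid(matrix(100, 25, 25))
  off <- dose_grid(matrix(106, 25, 25))
  tab4 <- criteria_sweep(off, flat,
                         lapply(c(3, 9), function(v) dose_criteria(v, 3, 200)),
                         which = "dd", options = opt)
  g <- gamma_map(off, flat, dose_criteria(3, 3, 200), opt)
  expect_equal(tab4$gamma_failing[1], sum(g$valid))  # gamma = 2 everywhere
  expect_equal(tab4$gamma_failing[2], 0L)            # gamma = 2/3

  expect_error(criteria_sweep(ev, ref, rev(dd_list), which = "dd"),
               "ascending")
  mixed <- list(dose_criteria(3, 3, 200), dose_criteria(6, 5, 200))
  expect_error(criteria_sweep(ev, ref, mixed, which = "dd"), "fixed")
})

test_that("cohort trends rank cases concordantly across methods", {
  base <- imrt_like_field(list(list(center = 15, width = 14, dose = 200)),
                          penumbra_sigma = 2.5, spacing = 1, extent = 30)
  perfect <- list(reference = base, evaluated = base)
  shifted <- list(reference = base,
                  evaluated = apply_perturbation(
                    base, perturbation_spec(shift = c(4, 0),
                                            dose_scale = 1.08)))
  tr <- cohort_trend(list(perfect, shifted), crit633,
                     options = gamma_options(subsample = 2))
  expect_equal(tr$table$gamma_ratio[1], 0)
  expect_equal(tr$table$mddiff_ratio[1], 0)
  expect_gt(tr$table$gamma_ratio[2], 0)
  expect_gt(tr$table$mddiff_ratio[2], 0)

  # degenerate all-perfect cohort: correlation not applicable
  tr0 <- cohort_trend(list(perfect, perfect), crit633,
                      options = gamma_options(subsample = 2))
  expect_true(all(tr0$table$gamma_ratio == 0))
  expect_true(is.na(tr0$spearman))

  expect_error(cohort_trend(list(perfect), crit633), "at least 2")
})

test_that("reports round-trip through JSON and render both methods", {
  withr::local_seed(43)
  ref <- cohort_base_field(spacing = 2, extent = 60)
  ev <- apply_perturbation(ref, perturbation_spec(dose_scale = 1.05))
  res <- compare_distributions(ev, ref, crit633,
                               options = gamma_options(subsample = 2))
  stats <- list(gamma = res$gamma$stats, mddiff = res$mddiff$stats)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(stats, path, case_id = "QA-demo", criteria = crit633)
  rt <- read_report(path)
  expect_equal(rt$case_id, "QA-demo")
  expect_equal(rt$criteria$dd_cGy, 6)
  expect_equal(rt$gamma$failing, stats$gamma$failing)
  expect_equal(rt$gamma$avg, stats$gamma$mean, tolerance = 1e-12)
  expect_equal(rt$mddiff$avg_abs, stats$mddiff$mean_abs, tolerance = 1e-12)
  expect_equal(rt$mddiff$max_abs, stats$mddiff$max_abs, tolerance = 1e-12)

  txt <- format_report(stats, crit633)
  expect_match(txt, "Total # of Data Points")
  expect_match(txt, "gamma >= 1")
  expect_match(txt, "MDdiff >= \\(1/2\\)deltaD0")
})
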