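#' Summary statistics for a metric map
#'
#' The per-case summary a QA report tabulates: number and ratio of
#' failing points (gamma: \eqn{\gamma \ge 1}; MDdiff:
#' \eqn{|MDdiff| \ge \frac{1}{2}\delta D^0}), the mean over valid points
#' (signed for MDdiff, plain average gamma), the mean of absolute
#' values, and the maximum absolute value.  Means and maxima are taken
#' over all valid points, not only failing ones.
#'
#' @param map a [metric_map()] from [mddiff_map()] or [gamma_map()].
#' @param criteria a [dose_criteria()] (needed for the MDdiff critical
#'   value; ignored for gamma).
#' @param signed for MDdiff maps, use the one-sided signed failing rule
#'   (see [mddiff_pass_mask()]).
#' @return an object of class `summary_stats`: list with `metric`,
#'   `total`, `failing`, `ratio`, `mean`, `mean_abs`, `max_abs`.
#' @export
summarize_metric <- function(map, criteria, signed = FALSE) {
  if (!inherits(map, "metric_map"))
    stop("'map' must be a metric_map", call. = FALSE)
  if (!any(map$valid))
    stop("metric map has no valid points to summarize", call. = FALSE)
  pm <- if (map$metric == "mddiff")
    mddiff_pass_mask(map, criteria, signed = signed)
  else
    gamma_pass_mask(map)
  v <- map$values[map$valid]
  structure(list(metric = map$metric,
                 total = pm$total,
                 failing = pm$failing,
                 ratio = pm$ratio,
                 mean = mean(v),
                 mean_abs = mean(abs(v)),
                 max_abs = max(abs(v))),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  unit <- if (x$metric == "mddiff") " cGy" else ""
  cat(sprintf("<summary_stats> %s\n", x$metric))
  cat(sprintf("  points: %d valid, %d failing (%.2f%%)\n",
              x$total, x$failing, 100 * x$ratio))
  cat(sprintf("  mean %.4g%s, mean|.| %.4g%s, max|.| %.4g%s\n",
              x$mean, unit, x$mean_abs, unit, x$max_abs, unit))
  invisible(x)
}

#' Failing-point counts across a sweep of criteria
#'
#' Recomputes both metrics' failing counts for a sequence of criteria in
#' which one parameter (the dose-difference criterion or the DTA
#' criterion) increases while the other stays fixed.  Enlarging either
#' tolerance can only remove failures, so both count columns are
#' non-increasing along the sweep.
#'
#' @param evaluated evaluated [dose_grid()].
#' @param reference reference [dose_grid()].
#' @param criteria_list list of [dose_criteria()], sorted strictly
#'   ascending in the swept parameter; the other parameter and the
#'   prescribed dose must be identical across the list.
#' @param which which parameter the list sweeps: `"dd"` (dose-difference
#'   criterion, cGy) or `"dta"` (DTA criterion, mm).
#' @param options [gamma_options()] for the gamma evaluations, or `NULL`
#'   for defaults.
#' @return data.frame with columns `value` (the swept criterion),
#'   `gamma_failing`, `mddiff_failing`.
#' @export
criteria_sweep <- function(evaluated, reference, criteria_list,
                           which = c("dd", "dta"), options = NULL) {
  which <- match.arg(which)
  if (length(criteria_list) < 1L ||
      !all(vapply(criteria_list, inherits, TRUE, "dose_criteria")))
    stop("'criteria_list' must be a list of dose_criteria objects",
         call. = FALSE)
  swept <- vapply(criteria_list,
                  function(cr) if (which == "dd") cr$dose_diff else cr$dta,
                  numeric(1))
  fixed <- vapply(criteria_list,
                  function(cr) if (which == "dd") cr$dta else cr$dose_diff,
                  numeric(1))
  if (any(diff(swept) <= 0))
    stop("'criteria_list' must be strictly ascending in the swept ",
         "parameter", call. = FALSE)
  if (length(unique(fixed)) != 1L)
    stop("the non-swept criterion must be fixed across the sweep",
         call. = FALSE)
  rs <- resample_to_reference(evaluated, reference)
  rows <- lapply(criteria_list, function(cr) {
    md <- mddiff_map(rs$grid, reference, cr, valid = rs$valid)
    gm <- gamma_map(evaluated, reference, cr, options = options)
    data.frame(value = if (which == "dd") cr$dose_diff else cr$dta,
               gamma_failing = gamma_pass_mask(gm)$failing,
               mddiff_failing = mddiff_pass_mask(md, cr)$failing)
  })
  do.call(rbind, rows)
}

#' Cross-method agreement over a cohort of QA cases
#'
#' Computes, for every case of a cohort, the failing-point ratio under
#' both the gamma and the MDdiff rule, and the Spearman rank correlation
#' between the two ratio vectors.  Concordant rankings (correlation near
#' 1) mean the two evaluation methods order QA cases from best to worst
#' agreement in the same way.
#'
#' @param cases list of cases as produced by [synthetic_cohort()] (each
#'   a list with `reference` and `evaluated` dose grids; `case_id` and
#'   `severity` are carried through when present).
#' @param criteria a [dose_criteria()].
#' @param options [gamma_options()] for the gamma evaluations, or `NULL`
#'   for defaults.
#' @return list with `table` (data.frame: `case_id`, `severity`,
#'   `gamma_failing`, `gamma_ratio`, `mddiff_failing`, `mddiff_ratio`)
#'   and `spearman` (rank correlation of the two ratio vectors; ties use
#'   average ranks; `NA` when either vector is constant, e.g. an
#'   all-perfect cohort).
#' @export
cohort_trend <- function(cases, criteria, options = NULL) {
  if (!is.list(cases) || length(cases) < 2L)
    stop("'cases' must be a list of at least 2 QA cases", call. = FALSE)
  stopifnot_criteria(criteria)
  rows <- lapply(seq_along(cases), function(k) {
    cs <- cases[[k]]
    rs <- resample_to_reference(cs$evaluated, cs$reference)
    md <- mddiff_map(rs$grid, cs$reference, criteria, valid = rs$valid)
    gm <- gamma_map(cs$evaluated, cs$reference, criteria,
                    options = options)
    mp <- mddiff_pass_mask(md, criteria)
    gp <- gamma_pass_mask(gm)
    data.frame(
      case_id = if (!is.null(cs$case_id)) cs$case_id else sprintf("case%d", k),
      severity = if (!is.null(cs$severity)) cs$severity else NA_real_,
      gamma_failing = gp$failing, gamma_ratio = gp$ratio,
      mddiff_failing = mp$failing, mddiff_ratio = mp$ratio)
  })
  tab <- do.call(rbind, rows)
  rho <- if (stats::sd(tab$gamma_ratio) == 0 ||
             stats::sd(tab$mddiff_ratio) == 0)
    NA_real_
  else
    stats::cor(tab$gamma_ratio, tab$mddiff_ratio, method = "spearman")
  list(table = tab, spearman = rho)
}

#' Write / read a QA comparison report
#'
#' Serializes one QA case's summary statistics for both methods as JSON
#' (machine readable) and renders the familiar row-labelled table
#' (human readable).
#'
#' @param stats list with elements `gamma` and `mddiff`, each a
#'   [summarize_metric()] result.
#' @param path file to write the JSON report to.
#' @param case_id case identifier stored in the report.
#' @param criteria the [dose_criteria()] the statistics were computed
#'   under.
#' @return (invisibly) the report list that was serialized.
#' @export
write_report <- function(stats, path, case_id = "case1", criteria) {
  if (!is.list(stats) || is.null(stats$gamma) || is.null(stats$mddiff))
    stop("'stats' must be a list with 'gamma' and 'mddiff' summaries",
         call. = FALSE)
  stopifnot_criteria(criteria)
  rep <- list(
    case_id = case_id,
    criteria = list(dd_cGy = criteria$dose_diff, dta_mm = criteria$dta,
                    prescribed_cGy = criteria$prescribed),
    gamma = list(total = stats$gamma$total, failing = stats$gamma$failing,
                 ratio = stats$gamma$ratio, avg = stats$gamma$mean,
                 max = stats$gamma$max_abs),
    mddiff = list(total = stats$mddiff$total,
                  failing = stats$mddiff$failing,
                  ratio = stats$mddiff$ratio, avg = stats$mddiff$mean,
                  avg_abs = stats$mddiff$mean_abs,
                  max_abs = stats$mddiff$max_abs))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_report
#' @export
format_report <- function(stats, criteria) {
  g <- stats$gamma; m <- stats$mddiff
  paste0(sprintf("Criteria: deltaD0 = %g cGy, DTA0 = %g mm, prescribed %g cGy\n",
                 criteria$dose_diff, criteria$dta, criteria$prescribed),
         sprintf("%-28s %10d\n", "Total # of Data Points", g$total),
         sprintf("%-28s %10d\n", "gamma >= 1", g$failing),
         sprintf("%-28s %9.2f%%\n", "  (ratio)", 100 * g$ratio),
         sprintf("%-28s %10.2f\n", "gamma avg", g$mean),
         sprintf("%-28s %10.2f\n", "gamma max", g$max_abs),
         sprintf("%-28s %10d\n", "MDdiff >= (1/2)deltaD0", m$failing),
         sprintf("%-28s %9.2f%%\n", "  (ratio)", 100 * m$ratio),
         sprintf("%-28s %10.2f\n", "MDdiff avg (cGy)", m$mean),
         sprintf("%-28s %10.2f\n", "MDdiff |avg| (cGy)", m$mean_abs),
         sprintf("%-28s %10.2f\n", "MDdiff max (cGy)", m$max_abs))
}
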