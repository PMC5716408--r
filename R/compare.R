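#' Full two-method comparison of a QA case
#'
#' The end-to-end workflow behind the command-line tool: resample the
#' evaluated distribution onto the reference geometry, compute the
#' requested metric maps, and summarize each.  Exit judgment (pass or
#' fail of the whole plan) is left to the user; the function only
#' quantifies the disagreement.
#'
#' @param evaluated evaluated [dose_grid()].
#' @param reference reference [dose_grid()].
#' @param criteria a [dose_criteria()].
#' @param methods character vector among `"gamma"`, `"mddiff"`.
#' @param options [gamma_options()] or `NULL`.
#' @param signed use the one-sided signed MDdiff failing rule.
#' @return list with (per requested method) `map` and `stats`, plus the
#'   shared `criteria`.
#' @examples
#' ref <- cohort_base_field()
#' ev <- apply_perturbation(ref, perturbation_spec(dose_scale = 1.05))
#' res <- compare_distributions(ev, ref, dose_criteria("3%", 3, 200))
#' res$mddiff$stats
#' @export
compare_distributions <- function(evaluated, reference, criteria,
                                  methods = c("gamma", "mddiff"),
                                  options = NULL, signed = FALSE) {
  methods <- match.arg(methods, c("gamma", "mddiff"), several.ok = TRUE)
  stopifnot_criteria(criteria)
  out <- list(criteria = criteria)
  if ("mddiff" %in% methods) {
    rs <- resample_to_reference(evaluated, reference)
    map <- mddiff_map(rs$grid, reference, criteria, valid = rs$valid)
    out$mddiff <- list(map = map,
                       stats = summarize_metric(map, criteria,
                                                signed = signed))
  }
  if ("gamma" %in% methods) {
    map <- gamma_map(evaluated, reference, criteria, options = options)
    out$gamma <- list(map = map, stats = summarize_metric(map, criteria))
  }
  out
}
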