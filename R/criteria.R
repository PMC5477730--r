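#' Target-volume dose objectives (three-level protocol rules)
#'
#' The default objective set reproduces the institutional target coverage
#' protocol used throughout this package, in percent of prescription:
#'
#' * `d95` — per protocol exactly 100% (evaluated with a 0.05-point
#'   tolerance to absorb rounding of one-decimal inputs), variation
#'   acceptable within +/-2%, deviation unacceptable beyond.
#' * `d5` — per protocol <= 107%, acceptable <= 110%, unacceptable above.
#' * `d98` — per protocol >= 95%, acceptable >= 90%, unacceptable below.
#' * `hotspot_outside` — per protocol <= 107%, acceptable <= 110%,
#'   unacceptable above.
#'
#' Boundary values classify into the better level (the printed
#' inequalities are non-strict). The three levels partition the metric
#' axis for every objective.
#'
#' @return an object of class `objective_set`: a named list of objectives,
#'   each with a `kind` (`"target"`, `"upper"`, `"lower"`) and bounds.
#' @export
default_objectives <- function() {
  structure(list(
    d95 = list(kind = "target", target = 100, per_protocol_tol = 0.05,
               acceptable_tol = 2),
    d5 = list(kind = "upper", per_protocol = 107, acceptable = 110),
    d98 = list(kind = "lower", per_protocol = 95, acceptable = 90),
    hotspot_outside = list(kind = "upper", per_protocol = 107,
                           acceptable = 110)
  ), class = "objective_set")
}

#' Read an objective set from a JSON configuration file
#'
#' The file holds one entry per objective keyed by metric name, with the
#' same fields as [default_objectives()] (`kind` plus bounds, in percent
#' of prescription). The packaged default configuration is available via
#' `system.file("extdata", "objectives_default.json", package =
#' "ctvdelta")`.
#'
#' @param path JSON file path.
#' @return an `objective_set`.
#' @export
read_objectives <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj <- lapply(obj, as.list)
  for (nm in names(obj)) {
    kind <- obj[[nm]]$kind
    if (!kind %in% c("target", "upper", "lower")) {
      stop("read_objectives: unknown objective kind: ", kind)
    }
  }
  structure(obj, class = "objective_set")
}

.levels <- c("per_protocol", "variation_acceptable", "deviation_unacceptable")

#' Classify one metric value against its objective
#'
#' Returns the tightest satisfied level of the three-level protocol rule
#' for this metric.
#'
#' @param value metric value in percent of prescription.
#' @param metric metric name (must exist in the objective set).
#' @param objectives an `objective_set`.
#' @return one of `"per_protocol"`, `"variation_acceptable"`,
#'   `"deviation_unacceptable"`.
#' @examples
#' classify_metric(99.8, "d95")   # variation_acceptable
#' classify_metric(97.5, "d95")   # deviation_unacceptable
#' classify_metric(90, "d98")     # variation_acceptable (boundary inclusive)
#' @export
classify_metric <- function(value, metric, objectives = default_objectives()) {
  o <- objectives[[metric]]
  if (is.null(o)) stop("classify_metric: unknown metric: ", metric)
  if (!is.finite(value)) stop("classify_metric: value must be finite")
  lv <- switch(o$kind,
    target = {
      dev <- abs(value - o$target)
      if (dev <= o$per_protocol_tol) 1L
      else if (dev <= o$acceptable_tol) 2L
      else 3L
    },
    upper = {
      if (value <= o$per_protocol) 1L
      else if (value <= o$acceptable) 2L
      else 3L
    },
    lower = {
      if (value >= o$per_protocol) 1L
      else if (value >= o$acceptable) 2L
      else 3L
    },
    stop("classify_metric: unknown objective kind"))
  .levels[lv]
}

#' Evaluate a plan against an objective set
#'
#' Classifies every objective metric present in `metrics`; objectives
#' whose metric is absent (e.g. D5 or the hot spot when only printed
#' coverage tables are available) are skipped and recorded as
#' not-evaluated. The plan is accepted iff no evaluated metric is a
#' deviation-unacceptable: a variation-acceptable result still passes.
#'
#' @param metrics a [extract_metrics()] object or named numeric vector of
#'   percent-of-prescription values.
#' @param objectives an `objective_set`.
#' @return an object of class `plan_verdict`: `classifications` (named
#'   character), `accepted` (logical), `not_evaluated` (character).
#' @export
evaluate_plan <- function(metrics, objectives = default_objectives()) {
  if (inherits(metrics, "dose_metrics")) {
    metrics <- unlist(metrics[c("d2", "d5", "d95", "d98", "hotspot_outside")])
  }
  metrics <- metrics[!is.na(metrics)]
  have <- intersect(names(objectives), names(metrics))
  missing_ <- setdiff(names(objectives), names(metrics))
  cls <- vapply(have, function(m) classify_metric(metrics[[m]], m, objectives),
                character(1L))
  structure(list(
    classifications = cls,
    accepted = !any(cls == "deviation_unacceptable"),
    not_evaluated = missing_
  ), class = "plan_verdict")
}

#' @export
print.plan_verdict <- function(x, ...) {
  cat(sprintf("plan %s\n", if (x$accepted) "ACCEPTED" else "NOT ACCEPTED"))
  for (m in names(x$classifications)) {
    cat(sprintf("  %-16s %s\n", m, x$classifications[[m]]))
  }
  if (length(x$not_evaluated)) {
    cat("  not evaluated:", paste(x$not_evaluated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag target under-coverage from D98%
#'
#' A structure counts as under-covered when its D98% falls below the
#' per-protocol coverage level (strictly below 95% of prescription by
#' default); D98% exactly at the threshold is adequate coverage.
#'
#' @param d98 D98% in percent of prescription.
#' @param threshold per-protocol coverage level (percent).
#' @param structure_id optional identifier carried into the flag.
#' @return an object of class `coverage_flag` with `structure_id`, `d98`
#'   and `under_covered`.
#' @export
flag_under_coverage <- function(d98, threshold = 95, structure_id = NULL) {
  if (!is.finite(d98) || d98 < 0) stop("flag_under_coverage: invalid d98")
  structure(list(structure_id = structure_id, d98 = d98,
                 under_covered = d98 < threshold),
            class = "coverage_flag")
}

#' Coverage analysis of the packaged per-case plan table
#'
#' Applies the plan-acceptance engine to the packaged per-case coverage
#' table: 14 cases with CTV_L D2/D95%/D98% and CTV_delta D98% measured on
#' the soft-tissue-window plan. Each CTV_L row is evaluated against the
#' default objectives (D2 carries no objective and is recorded as
#' not-evaluated) and each CTV_delta D98% is tested for under-coverage.
#'
#' @param path fixture CSV with columns `case`, `ctvl_d2`, `ctvl_d95`,
#'   `ctvl_d98`, `delta_d98`; defaults to the packaged table.
#' @param objectives an `objective_set`.
#' @return list with `per_case` (data frame: case, levels, acceptance and
#'   under-coverage flags) and `counts` (`accepted_ctvl`,
#'   `under_covered_delta`).
#' @examples
#' res <- run_table4_analysis()
#' res$counts   # 13 of 14 accepted, 8 delta volumes under-covered
#' @export
run_table4_analysis <- function(path = NULL,
                                objectives = default_objectives()) {
  if (is.null(path)) {
    path <- system.file("extdata", "table4_plan_s_coverage.csv",
                        package = "ctvdelta")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "ctvl_d2", "ctvl_d95", "ctvl_d98", "delta_d98")
  if (!all(need %in% names(tab)) || !nrow(tab) ||
      !all(vapply(tab[need[-1L]], is.numeric, logical(1L)))) {
    stop("run_table4_analysis: malformed fixture (need numeric columns ",
         paste(need, collapse = ", "), ")")
  }
  per <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    v <- evaluate_plan(c(d95 = tab$ctvl_d95[i], d98 = tab$ctvl_d98[i]),
                       objectives)
    data.frame(
      case = tab$case[i],
      ctvl_d95_level = v$classifications[["d95"]],
      ctvl_d98_level = v$classifications[["d98"]],
      accepted = v$accepted,
      ctvl_under_covered = flag_under_coverage(tab$ctvl_d98[i])$under_covered,
      delta_under_covered = flag_under_coverage(tab$delta_d98[i])$under_covered,
      stringsAsFactors = FALSE)
  }))
  list(per_case = per,
       counts = list(accepted_ctvl = sum(per$accepted),
                     n_cases = nrow(per),
                     under_covered_delta = sum(per$delta_under_covered)))
}
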