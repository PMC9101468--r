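#' Summarize one ICATUS division for one method
#'
#' Population summary mirroring the inter-method comparison table: median
#' minutes with 25th/75th percentiles over all participants,
#' non-participation (participants with zero credited minutes), the
#' partaker-only median (over participants with positive minutes), and the
#' Wilcoxon signed-rank p-value of the method against the criterion.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' Non-participation is judged on the criterion table's credits by default
#' (one non-participation column for all methods); set
#' `nonparticipation_on = "method"` to judge it on the summarized method
#' instead. Partaker medians are restricted the same way.
#'
#' @param credits A [credit_table()] for the method being summarized.
#' @param division A division identifier (`"MD1"`..`"MD9"`).
#' @param criterion_credits A [credit_table()] for the criterion method,
#'   same participant set.
#' @param nonparticipation_on `"criterion"` (default) or `"method"`.
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return One-row data frame with columns `division`, `method`, `n`,
#'   `nonparticipation_n`, `nonparticipation_pct`, `p25`, `median`, `p75`,
#'   `partaker_median`, `wilcoxon_p`.
#' @export
summarize_division <- function(credits, division, criterion_credits,
                               nonparticipation_on = c("criterion", "method"),
                               ...) {
  nonparticipation_on <- match.arg(nonparticipation_on)
  stopifnot(inherits(credits, "credit_table"),
            inherits(criterion_credits, "credit_table"))
  ids <- rownames(credits)
  if (!setequal(ids, rownames(criterion_credits))) {
    diff_ids <- c(setdiff(ids, rownames(criterion_credits)),
                  setdiff(rownames(criterion_credits), ids))
    stop("summarize_division: participant sets differ: ",
         paste(diff_ids, collapse = ", "))
  }
  x <- unclass(credits)[ids, division]
  crit <- unclass(criterion_credits)[ids, division]
  ref <- if (nonparticipation_on == "criterion") crit else x
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  partakers <- ref > 0
  wt <- wilcoxon_signed_rank(crit, x, ...)
  data.frame(division = division, method = attr(credits, "method"),
             n = length(x),
             nonparticipation_n = sum(!partakers),
             nonparticipation_pct = 100 * mean(!partakers),
             p25 = q[1], median = q[2], p75 = q[3],
             partaker_median = if (any(partakers))
               stats::median(x[partakers]) else NA_real_,
             wilcoxon_p = wt$p_value,
             stringsAsFactors = FALSE)
}

#' Division summary table across methods
#'
#' Stacks [summarize_division()] over every division and every supplied
#' method table, producing the full population descriptives report (one row
#' per division x method).
#'
#' @param tables Named list of [credit_table()]s, one per method; must
#'   include the criterion table.
#' @param criterion Name of the criterion method in `tables`
#'   (default `"OBS"`).
#' @param divisions Divisions to report (default: all nine).
#' @inheritParams summarize_division
#' @return Data frame of class `"division_summary_table"`.
#' @export
division_summary_table <- function(tables, criterion = "OBS",
                                   divisions = names(icatus_divisions()),
                                   nonparticipation_on = "criterion", ...) {
  stopifnot(criterion %in% names(tables))
  crit <- tables[[criterion]]
  rows <- list()
  for (dv in divisions) {
    for (m in names(tables)) {
      rows[[paste(dv, m)]] <-
        summarize_division(tables[[m]], dv, crit,
                           nonparticipation_on = nonparticipation_on, ...)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("division_summary_table", "data.frame")
  out
}

#' Compare observation-day and non-observation-day estimates
#'
#' For one recall method assessed on both day types, computes per-division
#' medians for each day type and the paired Wilcoxon signed-rank test --
#' the check used to probe reactivity (e.g. more caregiving reported on the
#' observation day). Participants lacking either day type are dropped with
#' a message stating how many.
#'
#' @param records List of [method_record()]s containing both day types for
#'   `method`.
#' @param method The method to compare (e.g. `"IAR"`).
#' @param catalog An [activity_catalog()].
#' @param grid A [timeslot_grid()].
#' @param mode Crediting mode passed to [credit_table()].
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return Data frame with one row per division: `division`, `method`, `n`,
#'   `median_observation`, `median_non_observation`, `wilcoxon_p`.
#' @export
compare_day_types <- function(records, method, catalog, grid,
                              mode = "simultaneous_aware", ...) {
  recs <- Filter(function(r) r$method == method, records)
  obs <- Filter(function(r) r$day_type == "observation", recs)
  non <- Filter(function(r) r$day_type == "non_observation", recs)
  ids_obs <- vapply(obs, `[[`, character(1), "participant_id")
  ids_non <- vapply(non, `[[`, character(1), "participant_id")
  ids <- intersect(ids_obs, ids_non)
  dropped <- length(union(ids_obs, ids_non)) - length(ids)
  if (dropped > 0)
    message("compare_day_types: dropped ", dropped,
            " participant(s) without both day types")
  if (!length(ids))
    stop("compare_day_types: no participants with both day types for ", method)
  t_obs <- credit_table(obs[match(ids, ids_obs)], catalog, grid, mode)
  t_non <- credit_table(non[match(ids, ids_non)], catalog, grid, mode)
  rows <- lapply(colnames(t_obs), function(dv) {
    wo <- unclass(t_obs)[, dv]; wn <- unclass(t_non)[, dv]
    wt <- wilcoxon_signed_rank(wo, wn, ...)
    data.frame(division = dv, method = method, n = length(ids),
               median_observation = stats::median(wo),
               median_non_observation = stats::median(wn),
               wilcoxon_p = wt$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
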