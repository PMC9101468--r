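#' Assessment methods recognised by the pipeline
#' @keywords internal
METHODS <- c("OBS", "R24H", "IAR", "EII")
DAY_TYPES <- c("observation", "non_observation")

#' Construct a participant-day method record
#'
#' One participant-day's per-slot activity sets for one assessment method
#' (direct observation `OBS`, 24-hour recall `R24H`, image-assisted recall
#' `IAR`, or enumerator image interpretation `EII`). `slots` holds one
#' element per grid slot: a character vector of activity codes present in
#' that slot (possibly empty), or `NA` for a missing slot. A record is
#' complete iff no slot is missing; incomplete records are excluded from
#' analysis under the complete-case rule.
#'
#' @param participant_id Participant identifier (string).
#' @param method One of `"OBS"`, `"R24H"`, `"IAR"`, `"EII"`.
#' @param day_type `"observation"` or `"non_observation"`.
#' @param slots List of length `grid$n_slots`: character vectors of codes,
#'   or `NA` for missing slots.
#' @param grid A [timeslot_grid()].
#' @param catalog An [activity_catalog()]; every code must be in it.
#'
#' @return An object of class `"method_record"`.
#' @export
method_record <- function(participant_id, method, day_type = "observation",
                          slots, grid, catalog) {
  method <- match.arg(method, METHODS)
  day_type <- match.arg(day_type, DAY_TYPES)
  if (length(slots) != grid$n_slots)
    stop(sprintf("record %s/%s: %d slots supplied but grid has %d",
                 participant_id, method, length(slots), grid$n_slots))
  slots <- lapply(slots, function(x) {
    if (length(x) == 1 && is.na(x)) return(NA_character_)
    as.character(x[!is.na(x)])
  })
  missing_slot <- vapply(slots, function(x) length(x) == 1 && is.na(x), logical(1))
  codes <- unlist(slots[!missing_slot], use.names = FALSE)
  bad <- setdiff(codes, catalog$code)
  if (length(bad))
    stop(sprintf("record %s/%s: unknown activity codes: %s",
                 participant_id, method, paste(bad, collapse = ", ")))
  structure(list(participant_id = as.character(participant_id),
                 method = method, day_type = day_type,
                 slots = slots, missing = missing_slot),
            class = "method_record")
}

#' Is a record complete (no missing slots)?
#' @param record A [method_record()].
#' @return Logical scalar.
#' @export
is_complete <- function(record) {
  stopifnot(inherits(record, "method_record"))
  !any(record$missing)
}

#' @export
print.method_record <- function(x, ...) {
  cat(sprintf("Method record: participant %s, %s (%s day), %d slots%s\n",
              x$participant_id, x$method, x$day_type, length(x$slots),
              if (is_complete(x)) "" else sprintf(" [%d missing]", sum(x$missing))))
  invisible(x)
}

#' Concurrency profile of a record
#'
#' Per-slot counts of distinct recorded activities, their median across all
#' slots, and the proportion of slots with more than one activity. By
#' default all recorded activities count toward concurrency, including
#' activities excluded from time aggregation; set `count_excluded = FALSE`
#' (with a catalog) to drop them first.
#'
#' @param record A complete [method_record()].
#' @param catalog Optional [activity_catalog()], required when
#'   `count_excluded = FALSE`.
#' @param count_excluded Count activities flagged `excluded` toward
#'   concurrency? Default `TRUE`.
#' @return List with `counts` (integer vector, one per slot), `median`, and
#'   `prop_multi` (proportion of slots with >1 activity).
#' @export
concurrency_profile <- function(record, catalog = NULL, count_excluded = TRUE) {
  if (!is_complete(record))
    stop("concurrency_profile: record is incomplete (complete-case rule)")
  slots <- record$slots
  if (!count_excluded) {
    if (is.null(catalog))
      stop("concurrency_profile: catalog required when count_excluded = FALSE")
    keep <- catalog$code[!catalog$excluded]
    slots <- lapply(slots, function(s) s[s %in% keep])
  }
  counts <- vapply(slots, length, integer(1))
  list(counts = counts,
       median = stats::median(counts),
       prop_multi = mean(counts > 1))
}
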