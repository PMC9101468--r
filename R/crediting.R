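#' Credit one timeslot's activities with minutes
#'
#' Implements the simultaneous-aware crediting rule for a single timeslot:
#' every simultaneous activity present is credited the full slot length,
#' while the non-simultaneous activities present split the slot length
#' equally among themselves. A slot containing exactly one activity (of
#' either kind) credits it the full slot. In `"sequential"` mode -- the
#' traditional convention that treats concurrent activities as if performed
#' one after another -- all activities present split the slot equally,
#' regardless of the simultaneity flag.
#'
#' Activities flagged `excluded` in the catalog are removed before
#' crediting: they neither receive credit nor shrink the splitting pool
#' (switch with `drop_excluded = FALSE` to credit them like any other
#' activity).
#'
#' @param activities Character vector (set) of activity codes present in
#'   the slot; an empty set yields an empty result.
#' @param catalog An [activity_catalog()].
#' @param slot_minutes Slot length in minutes (default 15).
#' @param mode `"simultaneous_aware"` (default) or `"sequential"`.
#' @param drop_excluded Remove catalog-excluded activities before crediting?
#'
#' @return Named numeric vector of credited minutes, one element per
#'   credited activity code.
#' @export
#' @examples
#' cat44 <- default_catalog()
#' # worked example: snacking + food preparation + care of the index child
#' credit_timeslot(c("snacking", "food_preparation", "care_index_child"), cat44)
#' # -> care_index_child 15, snacking 7.5, food_preparation 7.5
credit_timeslot <- function(activities, catalog, slot_minutes = 15,
                            mode = c("simultaneous_aware", "sequential"),
                            drop_excluded = TRUE) {
  mode <- match.arg(mode)
  stopifnot(slot_minutes > 0)
  activities <- unique(as.character(activities))
  if (!length(activities)) return(stats::setNames(numeric(0), character(0)))
  idx <- match(activities, catalog$code)
  if (anyNA(idx))
    stop("credit_timeslot: unknown activity code(s): ",
         paste(activities[is.na(idx)], collapse = ", "))
  if (drop_excluded) {
    keep <- !catalog$excluded[idx]
    activities <- activities[keep]
    idx <- idx[keep]
    if (!length(activities)) return(stats::setNames(numeric(0), character(0)))
  }
  sim <- catalog$simultaneous[idx]
  credits <- numeric(length(activities))
  if (mode == "sequential") {
    credits[] <- slot_minutes / length(activities)
  } else {
    credits[sim] <- slot_minutes
    n_ns <- sum(!sim)
    if (n_ns > 0) credits[!sim] <- slot_minutes / n_ns
  }
  stats::setNames(credits, activities)
}

#' Aggregate a record's credited minutes into ICATUS divisions
#'
#' Applies [credit_timeslot()] to every slot of a complete record and sums
#' the credited minutes within each ICATUS-2016 major division, returning a
#' 9-vector (MD1..MD9) of minutes. Excluded activities are dropped before
#' crediting.
#'
#' @inheritParams credit_timeslot
#' @param record A complete [method_record()].
#' @param grid The [timeslot_grid()] the record was coded on.
#' @return Named numeric vector of length 9 (`MD1`..`MD9`).
#' @export
aggregate_divisions <- function(record, catalog, grid,
                                mode = c("simultaneous_aware", "sequential"),
                                drop_excluded = TRUE) {
  mode <- match.arg(mode)
  if (!is_complete(record))
    stop(sprintf("aggregate_divisions: record %s/%s is incomplete (complete-case rule)",
                 record$participant_id, record$method))
  divs <- names(icatus_divisions())
  out <- stats::setNames(numeric(9), divs)
  act_div <- stats::setNames(catalog$division, catalog$code)
  for (s in record$slots) {
    cr <- credit_timeslot(s, catalog, grid$slot_minutes, mode, drop_excluded)
    if (length(cr)) {
      d <- act_div[names(cr)]
      for (k in seq_along(cr)) out[[d[k]]] <- out[[d[k]]] + cr[k]
    }
  }
  out
}

#' Build a participant-by-division credit table
#'
#' Aggregates a collection of records (all for one method and day type)
#' into a matrix of credited minutes: one row per participant, one column
#' per ICATUS division.
#'
#' @inheritParams aggregate_divisions
#' @param records List of complete [method_record()]s sharing one method.
#' @return A matrix of class `"credit_table"` (participants x 9 divisions)
#'   with attributes `method` and `mode`.
#' @export
credit_table <- function(records, catalog, grid,
                         mode = c("simultaneous_aware", "sequential"),
                         drop_excluded = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(records) > 0)
  methods <- unique(vapply(records, `[[`, character(1), "method"))
  if (length(methods) != 1)
    stop("credit_table: records mix methods: ", paste(methods, collapse = ", "))
  m <- t(vapply(records, aggregate_divisions, numeric(9),
                catalog = catalog, grid = grid, mode = mode,
                drop_excluded = drop_excluded))
  rownames(m) <- vapply(records, `[[`, character(1), "participant_id")
  structure(m, method = methods, mode = mode, class = c("credit_table", "matrix", "array"))
}

#' @export
print.credit_table <- function(x, ...) {
  cat(sprintf("Credit table: %d participants x %d divisions, method %s, %s crediting\n",
              nrow(x), ncol(x), attr(x, "method"), attr(x, "mode")))
  cat("Division medians (min):\n")
  print(round(apply(unclass(x), 2, stats::median), 1))
  invisible(x)
}

#' Write a credit table as tidy CSV
#'
#' Long format with columns `participant_id,method,mode,division,minutes`.
#'
#' @param table A [credit_table()].
#' @param path Output CSV path.
#' @export
write_credit_table <- function(table, path) {
  stopifnot(inherits(table, "credit_table"))
  df <- data.frame(participant_id = rep(rownames(table), times = ncol(table)),
                   method = attr(table, "method"),
                   mode = attr(table, "mode"),
                   division = rep(colnames(table), each = nrow(table)),
                   minutes = round(as.vector(unclass(table)), 1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
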