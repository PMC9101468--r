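#' Reserved activity code marking an observed-empty slot
#'
#' In the long activity-log CSV a slot with no activities is written as one
#' row with this code, so it can be distinguished from a missing
#' (unobserved) slot, which has no rows at all.
#' @keywords internal
EMPTY_CODE <- "NONE"

#' Write method records as a long activity-log CSV
#'
#' One row per participant x method x day type x slot x activity, columns
#' `participant_id,method,day_type,slot_start,activity_code`. Slots with no
#' activities are written with the reserved code `"NONE"`; missing slots
#' are omitted entirely (so completeness survives a round trip).
#'
#' @param records List of [method_record()]s.
#' @param path Output CSV path.
#' @param grid The [timeslot_grid()] the records are coded on.
#' @return Invisibly, `path`.
#' @export
write_activity_log <- function(records, path, grid) {
  starts <- slot_starts(grid)
  rows <- lapply(records, function(r) {
    ks <- which(!r$missing)
    do.call(rbind, lapply(ks, function(k) {
      codes <- r$slots[[k]]
      if (!length(codes)) codes <- EMPTY_CODE
      data.frame(participant_id = r$participant_id, method = r$method,
                 day_type = r$day_type, slot_start = starts[k],
                 activity_code = codes, stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long activity-log CSV into method records
#'
#' Parses the long CSV format written by [write_activity_log()], grouping
#' rows by participant x method x day type. Slots of the grid with no rows
#' for a record are treated as missing (the record is then incomplete);
#' rows with the reserved code `"NONE"` mark observed-empty slots. Unknown
#' activity codes and slot starts not on the grid are rejected with their
#' row numbers; exact duplicate rows are deduplicated with a warning.
#'
#' @param path Input CSV path.
#' @param catalog An [activity_catalog()].
#' @param grid A [timeslot_grid()].
#' @return List of [method_record()]s.
#' @export
read_activity_log <- function(path, catalog, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "method", "day_type", "slot_start", "activity_code")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("activity log ", path, " missing columns: ", paste(miss, collapse = ", "))
  rowno <- seq_len(nrow(df)) + 1L   # +1 for the header line
  bad_m <- !df$method %in% METHODS
  if (any(bad_m))
    stop("activity log: unknown method at row(s) ",
         paste(utils::head(rowno[bad_m], 5), collapse = ", "))
  bad_d <- !df$day_type %in% DAY_TYPES
  if (any(bad_d))
    stop("activity log: unknown day_type at row(s) ",
         paste(utils::head(rowno[bad_d], 5), collapse = ", "))
  starts <- slot_starts(grid)
  slot_idx <- match(df$slot_start, starts)
  if (anyNA(slot_idx))
    stop("activity log: slot_start not on the grid at row(s) ",
         paste(utils::head(rowno[is.na(slot_idx)], 5), collapse = ", "),
         " (values: ",
         paste(utils::head(unique(df$slot_start[is.na(slot_idx)]), 5), collapse = ", "), ")")
  bad_c <- !(df$activity_code %in% catalog$code | df$activity_code == EMPTY_CODE)
  if (any(bad_c))
    stop("activity log: unknown activity code(s) ",
         paste(utils::head(unique(df$activity_code[bad_c]), 5), collapse = ", "),
         " at row(s) ", paste(utils::head(rowno[bad_c], 5), collapse = ", "))
  key <- paste(df$participant_id, df$method, df$day_type, df$slot_start,
               df$activity_code, sep = "\r")
  if (anyDuplicated(key)) {
    warning("activity log: ", sum(duplicated(key)), " duplicate row(s) removed")
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    slot_idx <- slot_idx[keep]
  }
  grp <- paste(df$participant_id, df$method, df$day_type, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), grp), function(ix) {
    slots <- replicate(grid$n_slots, NA_character_, simplify = FALSE)
    for (k in unique(slot_idx[ix])) {
      codes <- df$activity_code[ix][slot_idx[ix] == k]
      codes <- setdiff(codes, EMPTY_CODE)
      slots[[k]] <- codes   # character(0) for observed-empty slots
    }
    method_record(df$participant_id[ix[1]], df$method[ix[1]],
                  df$day_type[ix[1]], slots, grid, catalog)
  })
  names(out) <- NULL
  out
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Reads simulation and analysis settings from a YAML (`.yml`/`.yaml`) or
#' JSON file and builds a [simulation_config()]; unknown keys are rejected.
#' Recognized top-level keys are the arguments of [simulation_config()]
#' (except `grid` and `catalog`, configured via `window_start`,
#' `window_end`, `slot_minutes` and `catalog_file`) plus the analysis
#' options `mode`, `loa_multiplier` and `kappa_weights`.
#'
#' @param path Path to the configuration file.
#' @return List with elements `config` (a [simulation_config()]), `mode`,
#'   `loa_multiplier`, `kappa_weights`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_participants", "seed", "window_start", "window_end",
             "slot_minutes", "catalog_file", "p_sim", "division_weights",
             "persistence", "p_second_foreground", "methods", "reactivity",
             "missing_slot_rate", "mode", "loa_multiplier", "kappa_weights")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config file: unknown keys: ", paste(bad, collapse = ", "))
  grid <- timeslot_grid(raw$window_start %||% "08:00",
                        raw$window_end %||% "20:00",
                        raw$slot_minutes %||% 15)
  catalog <- if (!is.null(raw$catalog_file)) read_catalog(raw$catalog_file)
             else default_catalog()
  args <- raw[intersect(names(raw),
                        c("n_participants", "seed", "persistence",
                          "p_second_foreground", "missing_slot_rate"))]
  if (!is.null(raw$p_sim)) args$p_sim <- unlist(raw$p_sim)
  if (!is.null(raw$division_weights))
    args$division_weights <- unlist(raw$division_weights)
  if (!is.null(raw$methods)) args$methods <- raw$methods
  if (!is.null(raw$reactivity)) args$reactivity <- raw$reactivity
  args$grid <- grid
  args$catalog <- catalog
  list(config = do.call(simulation_config, args),
       mode = raw$mode %||% "simultaneous_aware",
       loa_multiplier = raw$loa_multiplier %||% 2,
       kappa_weights = raw$kappa_weights %||% "linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full validation pipeline
#'
#' Orchestrates simulate -> credit -> agree -> report. Simulates a cohort
#' from `config` (or consumes pre-built records via `records`), credits
#' every method under the chosen mode, and writes the report bundle to
#' `output_dir`: a division summary table (`summary_table.csv`), a
#' bias/LOA agreement table per recall method (`agreement_table.csv`), a
#' reliability table (`reliability_table.csv`), a concurrency report with
#' Bland-Altman and weighted-kappa agreement on per-participant median
#' concurrency (`concurrency_table.csv`), per-division plot-data files
#' (`plotdata_<method>_<division>.csv` with columns `mean,difference`), and
#' a JSON manifest recording the configuration, seed, package version and
#' input digests. Minutes are written with one decimal, statistics with
#' four. Any stage failure aborts with a stage-labeled message.
#'
#' @param config A [simulation_config()].
#' @param output_dir Directory for the report bundle (created if needed);
#'   `NULL` skips writing files.
#' @param records Optional list of [method_record()]s to analyze instead of
#'   simulating (e.g. from [read_activity_log()]).
#' @param mode Crediting mode.
#' @param loa_multiplier LOA multiplier (default 2).
#' @param kappa_weights Weight scheme for the concurrency kappa.
#' @param seed Optional seed overriding `config$seed`.
#' @return Object of class `"timeagree_report"`: list with `summary`,
#'   `agreement` (per method), `concurrency`, `tables` (credit tables) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, records = NULL,
                         mode = c("simultaneous_aware", "sequential"),
                         loa_multiplier = 2, kappa_weights = "linear",
                         seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  if (is.null(records)) {
    records <- tryCatch(simulate_cohort(config)$records,
                        error = function(e) stop("simulate: ", conditionMessage(e),
                                                 call. = FALSE))
  }
  records <- Filter(is_complete, records)
  if (!length(records)) stop("credit: no complete records to analyze")

  methods_present <- unique(vapply(records, `[[`, character(1), "method"))
  if (!"OBS" %in% methods_present)
    stop("credit: no criterion (OBS) records present")

  obs_day <- Filter(function(r) r$day_type == "observation", records)
  by_method <- split(obs_day, vapply(obs_day, `[[`, character(1), "method"))
  # complete-case across methods: keep participants present for every method
  ids_by_m <- lapply(by_method, function(rs)
    vapply(rs, `[[`, character(1), "participant_id"))
  ids <- Reduce(intersect, ids_by_m)
  if (!length(ids)) stop("credit: no participants complete for all methods")
  tables <- tryCatch(
    lapply(names(by_method), function(m) {
      rs <- by_method[[m]][match(ids, ids_by_m[[m]])]
      credit_table(rs, config$catalog, config$grid, mode)
    }),
    error = function(e) stop("credit: ", conditionMessage(e), call. = FALSE))
  names(tables) <- names(by_method)

  recall_methods <- setdiff(names(tables), "OBS")
  agreement <- tryCatch(
    lapply(recall_methods, function(m)
      compare_methods(tables$OBS, tables[[m]], multiplier = loa_multiplier)),
    error = function(e) stop("agree: ", conditionMessage(e), call. = FALSE))
  names(agreement) <- recall_methods

  summary_tab <- tryCatch(
    division_summary_table(tables, criterion = "OBS"),
    error = function(e) stop("agree: ", conditionMessage(e), call. = FALSE))

  # concurrency: per-participant median concurrent-activity count per method
  conc <- lapply(names(by_method), function(m) {
    rs <- by_method[[m]][match(ids, ids_by_m[[m]])]
    vapply(rs, function(r) concurrency_profile(r)$median, numeric(1))
  })
  names(conc) <- names(by_method)
  concurrency <- do.call(rbind, lapply(recall_methods, function(m) {
    ba <- bland_altman(conc$OBS, conc[[m]], multiplier = loa_multiplier,
                       label = "concurrency")
    kp <- weighted_kappa(conc$OBS, conc[[m]], scheme = kappa_weights)
    data.frame(measure = "median_concurrency", method = m, n = ba$n,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               kappa = kp$kappa, kappa_scheme = kp$scheme,
               kappa_label = kp$label, stringsAsFactors = FALSE)
  }))

  manifest <- list(package = "timeagree",
                   version = as.character(utils::packageVersion("timeagree")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed, mode = mode,
                   loa_multiplier = loa_multiplier,
                   kappa_weights = kappa_weights,
                   n_participants_analyzed = length(ids),
                   methods = names(tables))

  out <- structure(list(summary = summary_tab, agreement = agreement,
                        concurrency = concurrency, tables = tables,
                        manifest = manifest),
                   class = "timeagree_report")

  if (!is.null(output_dir)) {
    tryCatch({
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      fmt_min <- function(x) round(x, 1)
      fmt_stat <- function(x) round(x, 4)
      s <- summary_tab
      for (cc in c("p25", "median", "p75", "partaker_median",
                   "nonparticipation_pct"))
        s[[cc]] <- fmt_min(s[[cc]])
      s$wilcoxon_p <- fmt_stat(s$wilcoxon_p)
      utils::write.csv(s, file.path(output_dir, "summary_table.csv"),
                       row.names = FALSE)
      ag <- do.call(rbind, lapply(agreement, as.data.frame))
      for (cc in c("bias", "sd_diff", "loa_low", "loa_high"))
        ag[[cc]] <- fmt_min(ag[[cc]])
      for (cc in c("wilcoxon_p", "alpha")) ag[[cc]] <- fmt_stat(ag[[cc]])
      utils::write.csv(ag, file.path(output_dir, "agreement_table.csv"),
                       row.names = FALSE)
      rel <- ag[, c("division", "method", "alpha", "alpha_label")]
      utils::write.csv(rel, file.path(output_dir, "reliability_table.csv"),
                       row.names = FALSE)
      cn <- concurrency
      for (cc in c("bias", "loa_low", "loa_high")) cn[[cc]] <- fmt_stat(cn[[cc]])
      cn$kappa <- fmt_stat(cn$kappa)
      utils::write.csv(cn, file.path(output_dir, "concurrency_table.csv"),
                       row.names = FALSE)
      for (m in recall_methods) {
        det <- attr(agreement[[m]], "detail")
        for (dv in names(det)) {
          pd <- det[[dv]]$pairs
          pd$mean <- fmt_min(pd$mean); pd$difference <- fmt_min(pd$difference)
          utils::write.csv(pd,
            file.path(output_dir, sprintf("plotdata_%s_%s.csv", m, dv)),
            row.names = FALSE)
        }
      }
      jsonlite::write_json(manifest,
                           file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }, error = function(e) stop("report: ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' @export
print.timeagree_report <- function(x, ...) {
  cat(sprintf("timeagree report: %d participants, methods %s, %s crediting\n",
              x$manifest$n_participants_analyzed,
              paste(x$manifest$methods, collapse = "/"),
              x$manifest$mode))
  for (m in names(x$agreement)) print(x$agreement[[m]])
  cat("Concurrency agreement:\n")
  cn <- x$concurrency
  cn$bias <- round(cn$bias, 2); cn$loa_low <- round(cn$loa_low, 2)
  cn$loa_high <- round(cn$loa_high, 2); cn$kappa <- round(cn$kappa, 4)
  print(cn, row.names = FALSE)
  invisible(x)
}
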