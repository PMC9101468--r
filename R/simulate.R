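#' Simulation configuration for synthetic time-use cohorts
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort size,
#' seed, grid and catalog, the truth model (per-slot presence probabilities
#' of the simultaneous activities, foreground-activity division weights,
#' Markov dwell persistence, probability of a second concurrent foreground
#' activity), per-method recall-error models (episode omission
#' probabilities for simultaneous and non-simultaneous activities, episode
#' time-shift probability), and observation-day reactivity effects.
#'
#' The defaults emulate the structure of a rural women's time-use day:
#' heavy multitasking (most timeslots hold more than one activity, median
#' around three concurrent activities), caregiving present in most slots as
#' a passive simultaneous activity, domestic chores dominating the
#' foreground, and recall methods that omit simultaneous/background
#' activities more often than image-assisted methods
#' (`q_sim(R24H) >= q_sim(EII) >= q_sim(IAR)`).
#'
#' @param n_participants Cohort size (default 175).
#' @param seed Integer seed; identical configs give identical cohorts.
#' @param grid A [timeslot_grid()].
#' @param catalog An [activity_catalog()].
#' @param p_sim Named vector of per-slot presence probabilities for the
#'   simultaneous activities (names must be simultaneous codes in the
#'   catalog).
#' @param division_weights Named vector of probabilities (summing to 1)
#'   that the foreground activity falls in each division with
#'   non-simultaneous activities; the activity within a division is drawn
#'   uniformly.
#' @param persistence Probability a foreground activity continues into the
#'   next slot (Markov dwell; default 0.7).
#' @param p_second_foreground Probability a slot carries a second,
#'   different foreground activity (default 0.1).
#' @param methods Named list of per-method error models, each a list with
#'   `q_sim` (episode omission probability for simultaneous activities),
#'   `q_act` (for non-simultaneous episodes) and `p_shift` (probability a
#'   surviving non-simultaneous episode is shifted by one slot).
#' @param reactivity List with `caregiving_inflation` (multiplier on
#'   simultaneous-care presence probabilities on observation days) and
#'   `own_production_deflation` (multiplier on the MD2 foreground weight on
#'   observation days).
#' @param missing_slot_rate Probability a slot is missing from a record
#'   (default 0; positive values create incomplete records).
#'
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_participants = 175,
                              seed = 1L,
                              grid = timeslot_grid(),
                              catalog = default_catalog(),
                              p_sim = c(care_index_child = 0.65,
                                        care_other_members = 0.30,
                                        chatting = 0.40,
                                        tv_radio = 0.10),
                              division_weights = c(MD1 = 0.02, MD2 = 0.07,
                                                   MD3 = 0.50, MD4 = 0.18,
                                                   MD7 = 0.08, MD8 = 0.03,
                                                   MD9 = 0.12),
                              persistence = 0.7,
                              p_second_foreground = 0.10,
                              methods = list(
                                R24H = list(q_sim = 0.50, q_act = 0.12, p_shift = 0.05),
                                IAR  = list(q_sim = 0.15, q_act = 0.06, p_shift = 0.03),
                                EII  = list(q_sim = 0.35, q_act = 0.15, p_shift = 0.03)),
                              reactivity = list(caregiving_inflation = 1.15,
                                                own_production_deflation = 0.80),
                              missing_slot_rate = 0) {
  cfg <- list(n_participants = as.integer(n_participants), seed = as.integer(seed),
              grid = grid, catalog = catalog, p_sim = p_sim,
              division_weights = division_weights, persistence = persistence,
              p_second_foreground = p_second_foreground, methods = methods,
              reactivity = reactivity, missing_slot_rate = missing_slot_rate)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_participants < 1) stop("config: n_participants must be >= 1")
  probs <- c(cfg$p_sim, cfg$persistence, cfg$p_second_foreground,
             cfg$missing_slot_rate,
             unlist(lapply(cfg$methods, function(m) c(m$q_sim, m$q_act, m$p_shift))))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("config: all probabilities must lie in [0, 1]")
  sim_codes <- cfg$catalog$code[cfg$catalog$simultaneous]
  bad <- setdiff(names(cfg$p_sim), sim_codes)
  if (length(bad))
    stop("config: p_sim names are not simultaneous catalog codes: ",
         paste(bad, collapse = ", "))
  w <- cfg$division_weights
  if (abs(sum(w) - 1) > 1e-8) stop("config: division_weights must sum to 1")
  nonsim_divs <- unique(cfg$catalog$division[!cfg$catalog$simultaneous &
                                               !cfg$catalog$excluded])
  bad <- setdiff(names(w)[w > 0], nonsim_divs)
  if (length(bad))
    stop("config: division_weights name divisions without non-simultaneous activities: ",
         paste(bad, collapse = ", "))
  bad_m <- setdiff(names(cfg$methods), c("R24H", "IAR", "EII"))
  if (length(bad_m))
    stop("config: unknown methods in error model: ", paste(bad_m, collapse = ", "))
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d participants, seed %d, %d slots\n",
              x$n_participants, x$seed, x$grid$n_slots))
  cat("  simultaneous presence:", paste(sprintf("%s=%.2f", names(x$p_sim), x$p_sim),
                                        collapse = ", "), "\n")
  for (m in names(x$methods))
    cat(sprintf("  %s: q_sim=%.2f q_act=%.2f p_shift=%.2f\n", m,
                x$methods[[m]]$q_sim, x$methods[[m]]$q_act, x$methods[[m]]$p_shift))
  invisible(x)
}

# Effective truth parameters for a day type (observation-day reactivity).
effective_truth_params <- function(config, day_type) {
  p_sim <- config$p_sim
  w <- config$division_weights
  if (day_type == "observation") {
    care <- names(p_sim) %in%
      config$catalog$code[config$catalog$division == "MD4"]
    p_sim[care] <- pmin(1, p_sim[care] * config$reactivity$caregiving_inflation)
    if ("MD2" %in% names(w)) {
      w[["MD2"]] <- w[["MD2"]] * config$reactivity$own_production_deflation
      w <- w / sum(w)
    }
  }
  list(p_sim = p_sim, division_weights = w)
}

#' Simulate one participant-day's true activity schedule
#'
#' Generates the criterion ("truth") record for one participant-day: each
#' simultaneous activity is present in each slot independently with its
#' configured probability; exactly one non-simultaneous foreground activity
#' is always present, drawn from the division weights (uniform within
#' division) and continued from slot to slot with the dwell persistence; an
#' optional second foreground activity appears per slot with its configured
#' probability. Observation-day reactivity (caregiving inflation,
#' own-production deflation) is applied when `day_type = "observation"`.
#'
#' Uses the current RNG state; seed management (stream per participant) is
#' done by [simulate_cohort()].
#'
#' @param config A [simulation_config()].
#' @param participant_id Participant identifier.
#' @param day_type `"observation"` or `"non_observation"`.
#' @return A complete [method_record()] with method `"OBS"`.
#' @export
simulate_truth <- function(config, participant_id = "P1",
                           day_type = "observation") {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  catalog <- config$catalog
  n <- grid$n_slots
  par <- effective_truth_params(config, day_type)
  # non-simultaneous, non-excluded foreground pool by division
  pool <- split(catalog$code[!catalog$simultaneous & !catalog$excluded],
                catalog$division[!catalog$simultaneous & !catalog$excluded])
  w <- par$division_weights
  draw_fg <- function() {
    dv <- sample(names(w), 1, prob = w)
    cand <- pool[[dv]]
    if (length(cand) == 1) cand else sample(cand, 1)
  }
  # simultaneous presence, iid per slot
  sim_present <- lapply(names(par$p_sim), function(a)
    stats::runif(n) < par$p_sim[[a]])
  names(sim_present) <- names(par$p_sim)
  # foreground Markov chain
  fg <- character(n)
  fg[1] <- draw_fg()
  for (k in seq_len(n)[-1])
    fg[k] <- if (stats::runif(1) < config$persistence) fg[k - 1] else draw_fg()
  second <- stats::runif(n) < config$p_second_foreground
  slots <- vector("list", n)
  for (k in seq_len(n)) {
    acts <- fg[k]
    if (second[k]) {
      alt <- draw_fg()
      while (alt == fg[k]) alt <- draw_fg()
      acts <- c(acts, alt)
    }
    acts <- c(acts, names(sim_present)[vapply(sim_present, `[`, logical(1), k)])
    slots[[k]] <- acts
  }
  if (config$missing_slot_rate > 0) {
    miss <- stats::runif(n) < config$missing_slot_rate
    slots[miss] <- list(NA_character_)
  }
  method_record(participant_id, "OBS", day_type, slots, grid, catalog)
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end).
presence_runs <- function(present) {
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Degrade a truth record with a method's recall-error model
#'
#' Applies the configured error model of a recall method to a truth record.
#' Errors operate on episodes -- maximal runs of consecutive slots in which
#' an activity is present -- because recall omission plausibly affects
#' whole activity bouts: each simultaneous-activity episode is dropped with
#' probability `q_sim`; each non-simultaneous episode is dropped with
#' `q_act`, and surviving non-simultaneous episodes are shifted by one slot
#' (direction equiprobable, clipped at the window) with probability
#' `p_shift`. No activities are invented: apart from shifts, every activity
#' in the degraded record is present in the truth for the same slot.
#'
#' @param truth A complete [method_record()] (the criterion schedule).
#' @param method `"R24H"`, `"IAR"` or `"EII"`.
#' @param config A [simulation_config()] supplying the error model.
#' @return A complete [method_record()] for `method`.
#' @export
degrade <- function(truth, method, config) {
  method <- match.arg(method, c("R24H", "IAR", "EII"))
  stopifnot(inherits(truth, "method_record"))
  if (!is_complete(truth)) stop("degrade: truth record must be complete")
  em <- config$methods[[method]]
  if (is.null(em)) stop("degrade: no error model configured for ", method)
  catalog <- config$catalog
  n <- length(truth$slots)
  codes <- unique(unlist(truth$slots, use.names = FALSE))
  out <- replicate(n, character(0), simplify = FALSE)
  for (a in codes) {
    sim <- catalog$simultaneous[match(a, catalog$code)]
    present <- vapply(truth$slots, function(s) a %in% s, logical(1))
    runs <- presence_runs(present)
    new_present <- logical(n)
    for (i in seq_len(nrow(runs))) {
      q <- if (sim) em$q_sim else em$q_act
      if (stats::runif(1) < q) next                    # episode omitted
      s <- runs$start[i]; e <- runs$end[i]
      if (!sim && em$p_shift > 0 && stats::runif(1) < em$p_shift) {
        off <- sample(c(-1L, 1L), 1)
        s <- max(1L, s + off); e <- min(n, e + off)
        if (s > e) next
      }
      new_present[s:e] <- TRUE
    }
    for (k in which(new_present)) out[[k]] <- c(out[[k]], a)
  }
  method_record(truth$participant_id, method, truth$day_type, out,
                config$grid, catalog)
}

#' Simulate a full synthetic cohort
#'
#' Generates, for each participant, the observation-day truth record
#' (method `OBS`) and degraded records for every configured recall method,
#' plus -- when `both_day_types = TRUE` -- a non-observation-day truth and
#' degraded `IAR`/`EII` records for it, mirroring the study design (24-hour
#' recall covers only the observation day; the image-based methods were
#' also administered for a non-observation day).
#'
#' Random numbers are drawn from one stream per participant (sub-seeds
#' derived from `config$seed`), so participant `i`'s data are unchanged
#' when `n_participants` grows.
#'
#' @param config A [simulation_config()].
#' @param both_day_types Also simulate the non-observation day for
#'   image-based methods? Default `FALSE`.
#' @return Object of class `"synthetic_cohort"`: list with `records` (flat
#'   list of [method_record()]s) and `config`.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(n_participants = 3, seed = 42))
#' length(co$records)   # 3 participants x (OBS + 3 recall methods)
simulate_cohort <- function(config, both_day_types = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
  records <- list()
  for (i in seq_len(config$n_participants)) {
    set.seed(sub_seeds[i])
    pid <- sprintf("P%04d", i)
    truth_obs <- simulate_truth(config, pid, "observation")
    records[[length(records) + 1L]] <- truth_obs
    for (m in names(config$methods))
      records[[length(records) + 1L]] <- degrade(truth_obs, m, config)
    if (both_day_types) {
      truth_non <- simulate_truth(config, pid, "non_observation")
      for (m in intersect(c("IAR", "EII"), names(config$methods)))
        records[[length(records) + 1L]] <- degrade(truth_non, m, config)
    }
  }
  structure(list(records = records, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  meth <- vapply(x$records, `[[`, character(1), "method")
  cat(sprintf("Synthetic cohort: %d participants, %d records (seed %d)\n",
              x$config$n_participants, length(x$records), x$config$seed))
  print(table(method = meth,
              day = vapply(x$records, `[[`, character(1), "day_type")))
  invisible(x)
}

#' Extract one method/day's records from a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param method Method identifier.
#' @param day_type Day type (default `"observation"`).
#' @return List of [method_record()]s ordered by participant.
#' @export
cohort_records <- function(cohort, method, day_type = "observation") {
  Filter(function(r) r$method == method && r$day_type == day_type,
         cohort$records)
}

#' Analytic expected Bland-Altman bias for a division
#'
#' Closed-form expectation of the criterion-minus-degraded credited minutes
#' for one division under the episode-omission error model, valid in the
#' analytically tractable regime: no time shifts (`p_shift = 0`), no second
#' foreground activity (`p_second_foreground = 0`) and no missing slots.
#' Then every slot carries exactly one non-simultaneous foreground activity
#' credited the full slot, each simultaneous activity credits the full slot
#' wherever present, and dropping an episode independently with probability
#' q removes its minutes in expectation linearly, so
#' `E(bias) = T (q_sim * sum of simultaneous presence probabilities in the
#' division + q_act * foreground division weight)` with `T` the total
#' window minutes. The dwell persistence does not enter the expectation
#' (episodes are dropped independently, so each slot's marginal omission
#' probability is q regardless of episode lengths).
#'
#' @param config A [simulation_config()] in the tractable regime.
#' @param method `"R24H"`, `"IAR"` or `"EII"`.
#' @param division A division identifier.
#' @param day_type Day type whose reactivity-adjusted truth parameters to
#'   use (default `"observation"`, matching criterion-vs-recall pipelines).
#' @return Expected bias in minutes (non-negative).
#' @export
expected_bias <- function(config, method, division,
                          day_type = "observation") {
  stopifnot(inherits(config, "simulation_config"))
  method <- match.arg(method, c("R24H", "IAR", "EII"))
  em <- config$methods[[method]]
  offending <- character(0)
  if (!is.null(em$p_shift) && em$p_shift > 0)
    offending <- c(offending, sprintf("p_shift(%s) = %g", method, em$p_shift))
  if (config$p_second_foreground > 0)
    offending <- c(offending, sprintf("p_second_foreground = %g",
                                      config$p_second_foreground))
  if (config$missing_slot_rate > 0)
    offending <- c(offending, sprintf("missing_slot_rate = %g",
                                      config$missing_slot_rate))
  if (length(offending))
    stop("expected_bias: config outside the tractable regime (",
         paste(offending, collapse = "; "), ")")
  par <- effective_truth_params(config, day_type)
  total_min <- config$grid$n_slots * config$grid$slot_minutes
  sim_codes <- names(par$p_sim)
  sim_divs <- config$catalog$division[match(sim_codes, config$catalog$code)]
  p_div <- sum(par$p_sim[sim_divs == division])
  w_div <- if (division %in% names(par$division_weights))
    par$division_weights[[division]] else 0
  total_min * (em$q_sim * p_div + em$q_act * w_div)
}
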