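# Shared fixtures: small catalogs, record builders, and independent oracles.

# 6-activity toy catalog: 2 simultaneous, 4 foreground, across 4 divisions.
toy_catalog <- function() {
  activity_catalog(
    code = c("simA", "simB", "ns1", "ns2", "ns3", "ns4"),
    label = c("passive care", "chatting", "cooking", "washing",
              "eating", "farming"),
    simultaneous = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    division = c("MD4", "MD7", "MD3", "MD3", "MD9", "MD2"),
    excluded = FALSE)
}

# One-foreground catalog for deterministic simulation corners.
mono_catalog <- function() {
  activity_catalog(
    code = c("care", "cooking"),
    label = c("passive care", "cooking"),
    simultaneous = c(TRUE, FALSE),
    division = c("MD4", "MD3"),
    excluded = FALSE)
}

# Build a complete record from a list of per-slot code vectors, recycling
# to the grid length.
make_record <- function(slots, catalog, grid = timeslot_grid(),
                        participant = "P1", method = "OBS",
                        day_type = "observation") {
  slots <- rep(slots, length.out = grid$n_slots)
  method_record(participant, method, day_type, slots, grid, catalog)
}

# Independent brute-force interpreter of the crediting rule, written as a
# direct transliteration of the rule text (no shared code with
# credit_timeslot).
oracle_credit <- function(activities, catalog, slot_minutes, mode) {
  activities <- unique(activities)
  keep <- !catalog$excluded[match(activities, catalog$code)]
  activities <- activities[keep]
  if (length(activities) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- numeric(0)
  if (mode == "sequential") {
    for (a in activities) out[a] <- slot_minutes / length(activities)
    return(out)
  }
  is_sim <- function(a) catalog$simultaneous[catalog$code == a]
  nonsim <- Filter(function(a) !is_sim(a), activities)
  for (a in activities) {
    out[a] <- if (is_sim(a)) slot_minutes else slot_minutes / length(nonsim)
  }
  out
}

# Brute-force minute enumeration: which slots does an episode occupy?
oracle_rasterize_slots <- function(start_min, end_min, grid) {
  # enumerate the episode minute-by-minute on a fine lattice
  eps <- 1e-6
  pts <- seq(start_min, end_min - eps, by = 0.5)
  slot_of <- floor((pts - grid$window_start) / grid$slot_minutes) + 1
  sort(unique(slot_of[slot_of >= 1 & slot_of <= grid$n_slots]))
}

# Exhaustive sign-flip enumeration oracle for the Wilcoxon exact p-value
# (two-sided, symmetric-distance definition; midranks for tied |d|).
oracle_wilcoxon_exact <- function(d, zero_rule = "drop") {
  if (zero_rule == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0) return(NA_real_)
  W_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}
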