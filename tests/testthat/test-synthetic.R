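test_that("configs validate probabilities and catalog consistency", {
  expect_error(simulation_config(n_participants = 0), "n_participants")
  expect_error(simulation_config(persistence = 1.2), "probabilities")
  expect_error(simulation_config(p_sim = c(cooking = 0.5)), "simultaneous")
  expect_error(simulation_config(division_weights = c(MD3 = 0.5, MD9 = 0.4)),
               "sum to 1")
  expect_error(simulation_config(
    methods = list(XYZ = list(q_sim = 0, q_act = 0, p_shift = 0))),
    "unknown methods")
})

test_that("identical configs give bit-identical cohorts", {
  cfg <- simulation_config(n_participants = 5, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  # stream per participant: growing n leaves earlier participants unchanged
  big <- simulate_cohort(simulation_config(n_participants = 8, seed = 123))
  for (i in seq_along(a$records))
    expect_identical(big$records[[i]], a$records[[i]])
})

test_that("deterministic truth corners", {
  toy <- mono_catalog()
  # passive care always present, cooking always the foreground
  cfg <- simulation_config(n_participants = 1, seed = 1, catalog = toy,
                           p_sim = c(care = 1),
                           division_weights = c(MD3 = 1),
                           persistence = 1, p_second_foreground = 0)
  r <- simulate_truth(cfg)
  expect_true(all(vapply(r$slots, function(s)
    setequal(s, c("cooking", "care")), logical(1))))
  expect_equal(concurrency_profile(r)$median, 2)
  # no simultaneous activity at all: one activity per slot
  cfg0 <- simulation_config(n_participants = 1, seed = 1, catalog = toy,
                            p_sim = c(care = 0),
                            division_weights = c(MD3 = 1),
                            p_second_foreground = 0)
  r0 <- simulate_truth(cfg0)
  expect_equal(concurrency_profile(r0)$median, 1)
  expect_equal(concurrency_profile(r0)$prop_multi, 0)
})

test_that("degradation with zero error rates is the identity", {
  cfg <- simulation_config(
    n_participants = 1, seed = 5,
    methods = list(R24H = list(q_sim = 0, q_act = 0, p_shift = 0)))
  truth <- simulate_truth(cfg, "P1")
  deg <- degrade(truth, "R24H", cfg)
  expect_equal(lapply(deg$slots, sort), lapply(truth$slots, sort))
})

test_that("certain omission of a simultaneous activity empties its division", {
  toy <- toy_catalog()
  cfg <- simulation_config(
    n_participants = 1, seed = 6, catalog = toy,
    p_sim = c(simA = 0.7, simB = 0.6),
    division_weights = c(MD3 = 0.8, MD9 = 0.2),   # no MD7 foreground
    methods = list(R24H = list(q_sim = 1, q_act = 0, p_shift = 0)))
  truth <- simulate_truth(cfg, "P1")
  deg <- degrade(truth, "R24H", cfg)
  v <- aggregate_divisions(deg, toy, cfg$grid)
  expect_equal(v[["MD7"]], 0)   # simB (chatting) is MD7's only source
  expect_equal(v[["MD4"]], 0)
  # non-simultaneous minutes survive untouched
  vt <- aggregate_divisions(truth, toy, cfg$grid)
  expect_equal(v[["MD3"]] + v[["MD9"]], vt[["MD3"]] + vt[["MD9"]])
})

test_that("degraded records contain no hallucinated activities (no shifts)", {
  cfg <- simulation_config(
    n_participants = 1, seed = 8,
    methods = list(IAR = list(q_sim = 0.3, q_act = 0.2, p_shift = 0)))
  truth <- simulate_truth(cfg, "P1")
  deg <- degrade(truth, "IAR", cfg)
  for (k in seq_along(deg$slots))
    expect_true(all(deg$slots[[k]] %in% truth$slots[[k]]))
})

test_that("analytic expected bias: closed form and tractability guard", {
  toy <- mono_catalog()
  base <- function(q_sim, q_act = 0, p_shift = 0, p_care = 1,
                   persistence = 1)
    simulation_config(n_participants = 1, seed = 1, catalog = toy,
                      p_sim = c(care = p_care),
                      division_weights = c(MD3 = 1),
                      persistence = persistence, p_second_foreground = 0,
                      methods = list(R24H = list(q_sim = q_sim, q_act = q_act,
                                                 p_shift = p_shift)),
                      reactivity = list(caregiving_inflation = 1,
                                        own_production_deflation = 1))
  # all omission rates zero -> zero bias
  expect_equal(expected_bias(base(0), "R24H", "MD4"), 0)
  # one 48-slot episode, q_sim = 0.5 -> 0.5 x 720 = 360
  expect_equal(expected_bias(base(0.5), "R24H", "MD4"), 360)
  # foreground omission drives the foreground division
  expect_equal(expected_bias(base(0, q_act = 0.25), "R24H", "MD3"), 180)
  # intractable features are listed in the rejection
  expect_error(expected_bias(base(0.5, p_shift = 0.1), "R24H", "MD4"),
               "p_shift")
  cfg2 <- simulation_config(p_second_foreground = 0.2,
                            methods = list(R24H = list(q_sim = 0, q_act = 0,
                                                       p_shift = 0)))
  expect_error(expected_bias(cfg2, "R24H", "MD4"), "p_second_foreground")
})

test_that("expected bias matches brute-force enumeration on a 4-slot grid", {
  # single simultaneous activity on 4 slots: enumerate all 2^4 presence
  # patterns and, within each, all episode drop subsets
  toy <- mono_catalog()
  g4 <- timeslot_grid("08:00", "09:00", 15)
  p <- 0.6; q <- 0.35
  cfg <- simulation_config(n_participants = 1, seed = 1, catalog = toy,
                           grid = g4, p_sim = c(care = p),
                           division_weights = c(MD3 = 1),
                           persistence = 0.5, p_second_foreground = 0,
                           methods = list(R24H = list(q_sim = q, q_act = 0,
                                                      p_shift = 0)),
                           reactivity = list(caregiving_inflation = 1,
                                             own_production_deflation = 1))
  exp_enum <- 0
  for (mask in 0:15) {
    pattern <- as.logical(bitwAnd(mask, 2^(0:3)))
    prob <- prod(ifelse(pattern, p, 1 - p))
    # each episode dropped independently with q; expected dropped minutes
    r <- rle(pattern)
    ep_len <- r$lengths[r$values]
    exp_enum <- exp_enum + prob * sum(q * ep_len * 15)
  }
  expect_equal(expected_bias(cfg, "R24H", "MD4"), exp_enum, tolerance = 1e-12)
  expect_equal(exp_enum, q * p * 4 * 15, tolerance = 1e-12)  # linearity
})

test_that("pipeline-estimated bias tracks the analytic expectation", {
  # moderate n Monte-Carlo check; the acceptance suite runs the full-size one
  cfg <- simulation_config(
    n_participants = 120, seed = 37,
    p_second_foreground = 0,
    methods = list(R24H = list(q_sim = 0.4, q_act = 0.1, p_shift = 0)),
    reactivity = list(caregiving_inflation = 1, own_production_deflation = 1))
  co <- simulate_cohort(cfg)
  obs <- credit_table(cohort_records(co, "OBS"), cfg$catalog, cfg$grid)
  rec <- credit_table(cohort_records(co, "R24H"), cfg$catalog, cfg$grid)
  d <- unclass(obs)[, "MD4"] - unclass(rec)[, "MD4"]
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected_bias(cfg, "R24H", "MD4")), 3 * se)
})

test_that("the default preset produces heavy multitasking", {
  cfg <- simulation_config(n_participants = 80, seed = 55)
  co <- simulate_cohort(cfg)
  pm <- vapply(cohort_records(co, "OBS"),
               function(r) concurrency_profile(r)$prop_multi, numeric(1))
  expect_gt(mean(pm), 0.80)
  expect_lt(mean(pm), 0.95)
  med <- vapply(cohort_records(co, "OBS"),
                function(r) concurrency_profile(r)$median, numeric(1))
  expect_gte(stats::median(med), 2)
  expect_lte(stats::median(med), 3.5)
})
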