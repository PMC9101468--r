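test_that("Bland-Altman bias, SD and LOA follow criterion - test", {
  # identity
  ba <- bland_altman(c(3, 8, 12), c(3, 8, 12))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  expect_equal(ba$ties, 3)
  # constant offset: SD of differences is zero, LOA collapse on the bias
  ba <- bland_altman(c(10, 20, 30), c(0, 10, 20))
  expect_equal(ba$bias, 10)
  expect_equal(c(ba$loa_low, ba$loa_high), c(10, 10))
  expect_equal(ba$counts_above_zero, 3)
  # hand-computed n = 2 case: sd = |d1 - d2| / sqrt(2)
  ba <- bland_altman(c(0, 10), c(10, 0), multiplier = 2)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2 * 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -ba$loa_high)
  # plot pairs
  expect_equal(ba$pairs$mean, c(5, 5))
  expect_equal(ba$pairs$difference, c(-10, 10))
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman is antisymmetric and translation invariant", {
  set.seed(3)
  a <- rnorm(20, 100, 30); b <- rnorm(20, 80, 25)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa_low, -f$loa_high)
  expect_equal(g$loa_high, -f$loa_low)
  h <- bland_altman(a + 57, b + 57)
  expect_equal(h$bias, f$bias)
  expect_equal(h$sd_diff, f$sd_diff)
  expect_equal(c(h$loa_low, h$loa_high), c(f$loa_low, f$loa_high))
})

test_that("threshold exceedance counts use |d| <= t at the boundary", {
  tc <- threshold_counts(c(0, 0, 0), 30)
  expect_equal(tc$pct_within, 100)
  tc <- threshold_counts(c(29, 31, -29), 30)
  expect_equal(tc$n_within, 2)
  tc <- threshold_counts(c(121, -121, 119), 120)
  expect_equal(tc$n_beyond, 2)
  tc <- threshold_counts(c(30, -30, 31), 30)   # boundary inclusive
  expect_equal(tc$n_within, 2)
  expect_error(threshold_counts(1:3, -5), "positive")
})

test_that("Cronbach's alpha matches the two-item formula and benchmarks", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  r <- cronbach_alpha(x, x)
  expect_equal(r$alpha, 1)
  expect_equal(r$label, "suspect")   # > 0.95
  # degenerate: sums constant -> zero total variance
  r <- cronbach_alpha(x, -x)
  expect_true(r$undefined)
  expect_true(is.na(r$alpha))
  # independent methods: alpha near 0 at large n
  set.seed(42)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(cronbach_alpha(a, b)$alpha), 0.05)
  # alpha agrees with the standardized two-item identity 2r_s/(1+r_s) on
  # equal-variance items (r_s = Pearson correlation)
  set.seed(8)
  u <- rnorm(200); v <- 0.6 * u + sqrt(1 - 0.36) * rnorm(200)
  v <- (v - mean(v)) / stats::sd(v) * stats::sd(u)  # match variances
  r_uv <- stats::cor(u, v)
  expect_equal(cronbach_alpha(u, v)$alpha, 2 * r_uv / (1 + r_uv),
               tolerance = 1e-10)
})

test_that("alpha is invariant to shifts and joint positive rescaling", {
  set.seed(5)
  a <- rnorm(50, 10, 3); b <- a + rnorm(50, 0, 2)
  base <- cronbach_alpha(a, b)$alpha
  expect_equal(cronbach_alpha(a + 100, b)$alpha, base)
  expect_equal(cronbach_alpha(a, b - 31)$alpha, base)
  expect_equal(cronbach_alpha(3.7 * a, 3.7 * b)$alpha, base)
})

test_that("weighted kappa reproduces hand-computed tables", {
  # perfect agreement with >= 2 categories
  expect_equal(weighted_kappa(c(1, 1, 2, 2), c(1, 1, 2, 2))$kappa, 1)
  # uniform 2x2 table -> independence -> kappa 0
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(weighted_kappa(a, b)$kappa, 0)
  # hand computation for counts ((5,1),(1,5)), linear weights: kappa = 2/3
  a <- c(rep(1, 6), rep(2, 6))
  b <- c(rep(1, 5), 2, 1, rep(2, 5))
  k <- weighted_kappa(a, b, "linear")
  expect_equal(k$kappa, 2 / 3, tolerance = 1e-12)
  expect_equal(k$label, "substantial")
  # quadratic equals linear when there are only 2 categories
  expect_equal(weighted_kappa(a, b, "quadratic")$kappa, k$kappa)
  # half-integer medians are doubled, preserving order
  kh <- weighted_kappa(c(1, 1.5, 2, 3), c(1, 1.5, 2, 3))
  expect_equal(kh$kappa, 1)
  expect_equal(kh$categories, 2:6)
  # single category overall -> undefined
  expect_true(weighted_kappa(c(2, 2), c(2, 2))$undefined)
  expect_error(weighted_kappa(1:3, 1:4), "equal length")
})

test_that("shape diagnostics classify simulated structures", {
  set.seed(9)
  n <- 120
  mkba <- function(mean, diff) {
    # assemble a bland_altman object from target (mean, difference) pairs
    crit <- mean + diff / 2
    test <- mean - diff / 2
    bland_altman(crit, test)
  }
  m <- runif(n, 0, 400)
  # cloud: homoscedastic noise, no slope
  cl <- shape_diagnostics(mkba(m, rnorm(n, 0, 20)))
  expect_type(cl$classification, "character")
  # sloped: difference proportional to the mean
  sl <- shape_diagnostics(mkba(m, -0.5 * m + rnorm(n, 0, 10)))
  expect_true(sl$classification %in% c("sloped", "fan+sloped"))
  expect_lt(sl$slope_p, 0.05)
  expect_lt(sl$slope, 0)
  # fan: spread proportional to the mean, no slope
  fan <- shape_diagnostics(mkba(m, rnorm(n, 0, 1 + 0.3 * m)))
  expect_true(fan$classification %in% c("fan", "fan+sloped"))
  expect_lt(fan$spread_p, 0.05)
  # constant means -> undefined
  und <- shape_diagnostics(mkba(rep(100, 10), rnorm(10)))
  expect_true(und$undefined)
  expect_error(shape_diagnostics(bland_altman(1:3, 3:1)), "at least 4")
})

test_that("compare_methods assembles the per-division agreement table", {
  toy <- toy_catalog()
  g <- timeslot_grid()
  set.seed(21)
  mk <- function(method, drop_sim) {
    lapply(1:8, function(i) {
      set.seed(100 + i)
      slots <- replicate(48, {
        acts <- "ns1"
        if (runif(1) < 0.7 && !drop_sim) acts <- c(acts, "simA")
        if (runif(1) < 0.3) acts <- c(acts, "ns3")
        acts
      }, simplify = FALSE)
      make_record(slots, toy, g, participant = paste0("P", i), method = method)
    })
  }
  crit <- credit_table(mk("OBS", FALSE), toy, g)
  test <- credit_table(mk("R24H", TRUE), toy, g)
  tab <- compare_methods(crit, test)
  expect_s3_class(tab, "agreement_table")
  expect_true("MD4" %in% tab$division)
  md4 <- tab[tab$division == "MD4", ]
  expect_gt(md4$bias, 0)           # dropping simA underestimates caregiving
  expect_true(md4$alpha_label %in% c("unacceptable", "acceptable",
                                     "moderate", "high", "suspect"))
  # MD9 schedules are identical by construction of the per-participant seed
  md9 <- tab[tab$division == "MD9", ]
  expect_equal(md9$bias, 0)
  # mismatched participant sets are rejected with the symmetric difference
  test2 <- test
  rownames(test2)[1] <- "ZZ"
  expect_error(compare_methods(crit, test2), "ZZ")
})
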