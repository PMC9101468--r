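#' Bland-Altman bias and limits of agreement
#'
#' Computes the mean difference (bias), the standard deviation of the paired
#' differences, and the limits of agreement (bias +/- multiplier x SD) for a
#' criterion method against a test method. The sign convention is fixed
#' project-wide as criterion minus test, so a positive bias means the test
#' (recall) method underestimates the criterion on average, and a negative
#' bias means it overestimates. The default multiplier is 2, following the
#' "mean difference +/- 2 SD" formulation; set `multiplier = 1.96` for
#' exact normal 95% limits.
#'
#' @param criterion Numeric vector of criterion-method values, one per
#'   participant.
#' @param test Numeric vector of test-method values, paired by position.
#' @param multiplier Positive LOA multiplier (default 2).
#' @param label Optional label (e.g. the division) carried in the result.
#'
#' @return Object of class `"bland_altman"`: list with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `multiplier`, `pairs` (data frame
#'   with `mean`, `difference` per participant), `counts_above_zero`,
#'   `counts_below_zero`, `ties`, `label`.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(0, 10, 20))
#' ba$bias      # 10: the test method underestimates by 10 min on average
#' c(ba$loa_low, ba$loa_high)
bland_altman <- function(criterion, test, multiplier = 2, label = NULL) {
  if (length(criterion) != length(test))
    stop("bland_altman: criterion and test must have equal length")
  if (length(criterion) < 2)
    stop("bland_altman: need at least 2 pairs (SD undefined otherwise)")
  if (multiplier <= 0)
    stop("bland_altman: multiplier must be positive")
  d <- criterion - test
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(n = length(d), bias = bias, sd_diff = sdd,
                 loa_low = bias - multiplier * sdd,
                 loa_high = bias + multiplier * sdd,
                 multiplier = multiplier,
                 pairs = data.frame(mean = (criterion + test) / 2,
                                    difference = d),
                 counts_above_zero = sum(d > 0),
                 counts_below_zero = sum(d < 0),
                 ties = sum(d == 0),
                 label = label),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman agreement%s (n = %d)\n",
              if (!is.null(x$label)) paste0(": ", x$label) else "", x$n))
  cat(sprintf("  bias (criterion - test): %.*f\n", digits, x$bias))
  cat(sprintf("  SD of differences:       %.*f\n", digits, x$sd_diff))
  cat(sprintf("  LOA (+/- %g SD):         [%.*f, %.*f]\n",
              x$multiplier, digits, x$loa_low, digits, x$loa_high))
  cat(sprintf("  differences > 0: %d, < 0: %d, ties: %d\n",
              x$counts_above_zero, x$counts_below_zero, x$ties))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$difference,
                 xlab = "Mean of methods", ylab = "Difference (criterion - test)",
                 main = if (!is.null(x$label)) x$label else "Bland-Altman plot", ...)
  graphics::abline(h = x$bias, lty = 3)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Threshold-exceedance counts for paired differences
#'
#' For each threshold t (minutes), counts participants whose absolute
#' difference is within t (`|d| <= t`) and beyond t (`|d| > t`), with
#' percentages -- e.g. the share of participants whose estimate was within
#' 30 min of the criterion, or erred by more than two hours.
#'
#' @param differences Numeric vector of paired differences.
#' @param thresholds Positive thresholds in minutes (default `c(30, 120)`).
#' @return Data frame with columns `threshold`, `n`, `n_within`,
#'   `pct_within`, `n_beyond`, `pct_beyond`.
#' @export
threshold_counts <- function(differences, thresholds = c(30, 120)) {
  if (any(thresholds <= 0)) stop("threshold_counts: thresholds must be positive")
  n <- length(differences)
  within <- vapply(thresholds, function(t) sum(abs(differences) <= t), integer(1))
  data.frame(threshold = thresholds, n = n,
             n_within = within, pct_within = 100 * within / n,
             n_beyond = n - within, pct_beyond = 100 * (n - within) / n)
}

#' Cronbach's coefficient alpha for two methods
#'
#' Treats the two methods as a two-item scale:
#' `alpha = (k/(k-1)) (1 - sum(Var_i) / Var_total)` with `k = 2` items and
#' `Var_total` the variance of per-participant sums (sample variances,
#' n - 1 denominator). The interpretation label follows the Nunnally /
#' Peterson benchmarks: <0.70 unacceptable; >0.70 acceptable; >0.80
#' moderate; 0.90-0.95 high; >0.95 suspect.
#'
#' @param method_a,method_b Paired numeric vectors (length >= 3).
#' @return Object of class `"reliability_result"`: list with `alpha`,
#'   `label`, `n`, `undefined` (TRUE when the total variance is zero, in
#'   which case `alpha` is `NA`).
#' @export
#' @examples
#' cronbach_alpha(1:10, 1:10)$alpha   # 1 (label "suspect": > 0.95)
cronbach_alpha <- function(method_a, method_b) {
  if (length(method_a) != length(method_b))
    stop("cronbach_alpha: inputs must have equal length")
  if (length(method_a) < 3)
    stop("cronbach_alpha: need at least 3 pairs")
  vt <- stats::var(method_a + method_b)
  if (!is.finite(vt) || vt <= 0) {
    return(structure(list(alpha = NA_real_, label = "undefined (zero total variance)",
                          n = length(method_a), undefined = TRUE),
                     class = "reliability_result"))
  }
  alpha <- 2 * (1 - (stats::var(method_a) + stats::var(method_b)) / vt)
  structure(list(alpha = alpha, label = alpha_label(alpha),
                 n = length(method_a), undefined = FALSE),
            class = "reliability_result")
}

alpha_label <- function(alpha) {
  if (alpha > 0.95) "suspect"
  else if (alpha >= 0.90) "high"
  else if (alpha > 0.80) "moderate"
  else if (alpha > 0.70) "acceptable"
  else "unacceptable"
}

#' @export
print.reliability_result <- function(x, ...) {
  if (x$undefined) cat("Cronbach's alpha: undefined (zero total variance), n =", x$n, "\n")
  else cat(sprintf("Cronbach's alpha: %.4f (%s), n = %d\n", x$alpha, x$label, x$n))
  invisible(x)
}

#' Weighted Cohen's kappa for ordinal paired ratings
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` over the R x R joint category
#' table, with disagreement weights `w_ij = |i-j|/(R-1)` (linear, default)
#' or `((i-j)/(R-1))^2` (quadratic), observed joint proportions `O`, and
#' expected proportions `E` from the outer product of the marginals. The
#' shared category range is the integer span of the union of both raters'
#' observed values. Half-integer values (e.g. median concurrency over an
#' even number of slots) are doubled to integers internally so category
#' order is preserved without binning. The interpretation label follows the
#' Landis-Koch benchmarks.
#'
#' @param ratings_a,ratings_b Paired numeric vectors of ordinal values
#'   (integers or half-integers).
#' @param scheme `"linear"` (default) or `"quadratic"` weights.
#' @return Object of class `"kappa_result"`: list with `kappa`, `scheme`,
#'   `categories` (the shared ordinal range used), `label`, `n`,
#'   `undefined`.
#' @export
#' @examples
#' weighted_kappa(c(1, 1, 2, 2), c(1, 1, 2, 2))$kappa  # 1
weighted_kappa <- function(ratings_a, ratings_b, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  if (length(ratings_a) != length(ratings_b))
    stop("weighted_kappa: inputs must have equal length")
  a <- as.numeric(ratings_a); b <- as.numeric(ratings_b)
  if (anyNA(a) || anyNA(b)) stop("weighted_kappa: missing values not allowed")
  # double half-integers to an integer scale
  if (any(abs(c(a, b) - round(c(a, b))) > 1e-9)) { a <- 2 * a; b <- 2 * b }
  if (any(abs(c(a, b) - round(c(a, b))) > 1e-9))
    stop("weighted_kappa: values must be integers or half-integers")
  a <- as.integer(round(a)); b <- as.integer(round(b))
  lo <- min(a, b); hi <- max(a, b)
  cats <- lo:hi
  R <- length(cats)
  if (R < 2) {
    return(structure(list(kappa = NA_real_, scheme = scheme, categories = cats,
                          label = "undefined (fewer than 2 categories)",
                          n = length(a), undefined = TRUE),
                     class = "kappa_result"))
  }
  fa <- factor(a, levels = cats); fb <- factor(b, levels = cats)
  O <- table(fa, fb) / length(a)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(R)
  w <- abs(outer(idx, idx, "-")) / (R - 1)
  if (scheme == "quadratic") w <- w^2
  kappa <- 1 - sum(w * O) / sum(w * E)
  structure(list(kappa = kappa, scheme = scheme, categories = cats,
                 label = kappa_label(kappa), n = length(a), undefined = FALSE),
            class = "kappa_result")
}

kappa_label <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) cat("Weighted kappa: undefined,", x$label, "\n")
  else cat(sprintf("Weighted kappa (%s weights, %d categories): %.4f (%s), n = %d\n",
                   x$scheme, length(x$categories), x$kappa, x$label, x$n))
  invisible(x)
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Paired signed-rank test with midranks for tied absolute differences.
#' Zero differences are handled by the configured rule: `"drop"` (classic
#' Wilcoxon; zeros discarded before ranking, the default) or `"pratt"`
#' (zeros ranked with the rest, then their ranks discarded). The exact null
#' distribution of the positive-rank sum is enumerated (via its generating
#' function over the signed ranks) whenever the effective sample size is at
#' most `exact_max_n`; otherwise a normal approximation with tie correction
#' and continuity correction is used. When every difference is zero the
#' test is flagged not testable and the p-value is `NA`.
#'
#' @param x,y Paired numeric vectors.
#' @param zero_rule `"drop"` (default) or `"pratt"`.
#' @param p_mode `"exact_when_small"` (default: exact iff effective n <=
#'   `exact_max_n`) or `"normal_approx"`.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends to
#'   exceed y) or `"less"`.
#' @param exact_max_n Largest effective n for exact enumeration (default 12).
#' @return Object of class `"wilcoxon_result"`: list with `statistic`
#'   (positive-rank sum W+), `p_value`, `n_eff`, `method` (`"exact"` or
#'   `"normal_approx"`), `zero_rule`, `alternative`, `not_testable`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))$p_value   # 0.25 (exact)
wilcoxon_signed_rank <- function(x, y,
                                 zero_rule = c("drop", "pratt"),
                                 p_mode = c("exact_when_small", "normal_approx"),
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max_n = 12) {
  zero_rule <- match.arg(zero_rule)
  p_mode <- match.arg(p_mode)
  alternative <- match.arg(alternative)
  if (length(x) != length(y))
    stop("wilcoxon_signed_rank: inputs must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  if (!length(d) || all(d == 0)) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_, n_eff = 0L,
                          method = "none", zero_rule = zero_rule,
                          alternative = alternative, not_testable = TRUE),
                     class = "wilcoxon_result"))
  }
  if (zero_rule == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n_eff <- length(d)
  W <- sum(r[d > 0])
  tot <- sum(r)
  mu <- tot / 2
  use_exact <- (p_mode == "exact_when_small") && n_eff <= exact_max_n
  if (use_exact) {
    # exact null: each rank signed + with prob 1/2; distribution of W+ by DP
    # on doubled ranks (midranks may be half-integers)
    r2 <- as.integer(round(2 * r))
    dist <- signed_rank_distribution(r2)        # over values 0 .. sum(r2)
    vals <- seq(0, sum(r2))                     # doubled W+ support
    w2 <- round(2 * W)
    mu2 <- sum(r2) / 2
    p_ge <- sum(dist[vals >= w2 - 1e-9])
    p_le <- sum(dist[vals <= w2 + 1e-9])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, sum(dist[abs(vals - mu2) >= abs(w2 - mu2) - 1e-9])))
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)                 # tie-corrected via midranks
    cc <- 0.5
    z_ge <- (W - mu - cc) / sigma
    z_le <- (W - mu + cc) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z_ge, lower.tail = FALSE),
                less = stats::pnorm(z_le),
                two.sided = {
                  z <- if (W > mu) z_ge else if (W < mu) z_le else 0
                  min(1, 2 * stats::pnorm(-abs(z)))
                })
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_value = p, n_eff = n_eff, method = method,
                 zero_rule = zero_rule, alternative = alternative,
                 not_testable = FALSE),
            class = "wilcoxon_result")
}

# Exact distribution of the positive-rank sum over integer ranks r2
# (doubled midranks): probability vector over 0:sum(r2).
signed_rank_distribution <- function(r2) {
  tot <- sum(r2)
  f <- numeric(tot + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f / 2
    shifted <- c(numeric(ri), g[seq_len(tot + 1 - ri)])
    f <- g + shifted
  }
  f
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$not_testable) {
    cat("Wilcoxon signed-rank: not testable (all differences zero)\n")
  } else {
    cat(sprintf("Wilcoxon signed-rank: W+ = %g, n_eff = %d, p = %.4g (%s, %s, zeros: %s)\n",
                x$statistic, x$n_eff, x$p_value, x$method, x$alternative, x$zero_rule))
  }
  invisible(x)
}

#' Bland-Altman plot-shape diagnostics
#'
#' Operationalizes the visual classification of Bland-Altman plots:
#' a least-squares fit of difference on mean tests for a slope
#' (proportional bias), and a fit of absolute residuals on mean tests for
#' spread increasing with the mean (heteroscedastic, "fan" shape).
#' Classification at the configured significance level: neither significant
#' -> `"cloud"`; spread only -> `"fan"`; slope only -> `"sloped"`; both ->
#' `"fan+sloped"`.
#'
#' @param result A [bland_altman()] result with at least 4 pairs.
#' @param alpha_level Significance level for both component tests
#'   (default 0.05).
#' @return Object of class `"shape_diagnostic"`: list with `slope`,
#'   `slope_p`, `spread_slope`, `spread_p`, `classification`, `alpha_level`,
#'   `undefined` (TRUE with constant means).
#' @export
shape_diagnostics <- function(result, alpha_level = 0.05) {
  stopifnot(inherits(result, "bland_altman"))
  m <- result$pairs$mean
  d <- result$pairs$difference
  if (length(m) < 4)
    stop("shape_diagnostics: need at least 4 pairs")
  if (stats::sd(m) == 0) {
    return(structure(list(slope = NA_real_, slope_p = NA_real_,
                          spread_slope = NA_real_, spread_p = NA_real_,
                          classification = "undefined (constant means)",
                          alpha_level = alpha_level, undefined = TRUE),
                     class = "shape_diagnostic"))
  }
  fit <- stats::lm(d ~ m)
  sl <- stats::coef(fit)[2]
  res <- abs(stats::residuals(fit))
  perfect <- sqrt(mean(res^2)) < 1e-8 * (stats::sd(d) + 1e-12)
  if (perfect) {
    # exact linear relation: slope verdict is unambiguous, spread is flat
    sl_p <- if (abs(sl) > 1e-12) 0 else 1
    sp <- 0; sp_p <- 1
  } else {
    sl_p <- summary(fit)$coefficients[2, 4]
    fit2 <- stats::lm(res ~ m)
    sp <- stats::coef(fit2)[2]
    sp_p <- summary(fit2)$coefficients[2, 4]
  }
  sig_slope <- sl_p < alpha_level
  sig_spread <- sp_p < alpha_level
  cls <- if (sig_slope && sig_spread) "fan+sloped"
         else if (sig_slope) "sloped"
         else if (sig_spread) "fan"
         else "cloud"
  structure(list(slope = unname(sl), slope_p = unname(sl_p),
                 spread_slope = unname(sp), spread_p = unname(sp_p),
                 classification = cls, alpha_level = alpha_level,
                 undefined = FALSE),
            class = "shape_diagnostic")
}

#' @export
print.shape_diagnostic <- function(x, ...) {
  cat(sprintf("Plot shape: %s (slope %.4g, p = %.3g; spread slope %.4g, p = %.3g; alpha = %g)\n",
              x$classification, x$slope, x$slope_p, x$spread_slope, x$spread_p,
              x$alpha_level))
  invisible(x)
}

#' Division-level agreement table for one method pair
#'
#' Runs the full agreement suite for every requested ICATUS division of two
#' credit tables: Bland-Altman bias and LOA, Wilcoxon signed-rank p,
#' Cronbach's alpha with its benchmark label, and plot-shape
#' classification. Participants are matched by row name; both tables must
#' cover the same participant set.
#'
#' @param criterion,test [credit_table()]s for the criterion and test
#'   methods.
#' @param divisions Division identifiers to compare (default: all with any
#'   non-zero minutes in either table).
#' @param multiplier LOA multiplier (default 2).
#' @param alpha_level Significance level for shape diagnostics.
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return Object of class `"agreement_table"`: data frame with one row per
#'   division (`division`, `method`, `n`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `wilcoxon_p`, `alpha`, `alpha_label`, `shape`), plus the
#'   per-division [bland_altman()] objects in attribute `"detail"`.
#' @export
compare_methods <- function(criterion, test, divisions = NULL,
                            multiplier = 2, alpha_level = 0.05, ...) {
  stopifnot(inherits(criterion, "credit_table"), inherits(test, "credit_table"))
  ids <- rownames(criterion)
  if (!setequal(ids, rownames(test))) {
    diff_ids <- c(setdiff(ids, rownames(test)), setdiff(rownames(test), ids))
    stop("compare_methods: participant sets differ: ", paste(diff_ids, collapse = ", "))
  }
  test_method <- attr(test, "method")
  test <- unclass(test)[ids, , drop = FALSE]
  if (is.null(divisions)) {
    tot <- colSums(unclass(criterion)) + colSums(unclass(test))
    divisions <- colnames(criterion)[tot > 0]
  }
  detail <- list()
  rows <- lapply(divisions, function(dv) {
    ba <- bland_altman(unclass(criterion)[, dv], unclass(test)[, dv],
                       multiplier = multiplier, label = dv)
    detail[[dv]] <<- ba
    wt <- wilcoxon_signed_rank(unclass(criterion)[, dv], unclass(test)[, dv], ...)
    ca <- cronbach_alpha(unclass(criterion)[, dv], unclass(test)[, dv])
    shp <- if (ba$sd_diff > 0 && stats::sd(ba$pairs$mean) > 0 && ba$n >= 4)
    shape_diagnostics(ba, alpha_level)$classification else NA_character_
    data.frame(division = dv, method = test_method, n = ba$n,
               bias = ba$bias, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               wilcoxon_p = wt$p_value, alpha = ca$alpha,
               alpha_label = ca$label, shape = shp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  attr(out, "multiplier") <- multiplier
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("Agreement vs criterion, method %s (LOA multiplier %g):\n",
              x$method[1], attr(x, "multiplier")))
  df <- data.frame(division = x$division, n = x$n,
                   bias = round(x$bias, 1),
                   loa_low = round(x$loa_low, 1), loa_high = round(x$loa_high, 1),
                   wilcoxon_p = signif(x$wilcoxon_p, 4),
                   alpha = round(x$alpha, 4), label = x$alpha_label,
                   shape = x$shape)
  print(df, row.names = FALSE)
  invisible(x)
}
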