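#' Filter paired samples for clinical-validation eligibility
#'
#' Retains paired plasma/DBS samples whose hematocrit lies inside the
#' validated range (closed interval) and whose Hct determination is recent
#' enough; everything else is excluded with a logged reason, so the
#' reduction from collected to analysed samples is auditable.
#'
#' @param samples Data.frame of paired samples with columns `c_pla`, `c_dbs`,
#'   `hct_pct` and optionally `days_since_hct` (missing column or NA values
#'   are treated as within the limit), `subject_id`, `analyte`.
#' @param hct_range Closed validated Hct interval, percent (default c(29, 45)).
#' @param max_days_since_hct Maximum age of the Hct determination, days
#'   (default 14).
#' @return List: `eligible` (data.frame subset), `exclusions` (data.frame of
#'   excluded rows with a `reason` column).
#' @export
filter_eligible <- function(samples, hct_range = c(29, 45),
                            max_days_since_hct = 14) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0) {
    return(list(eligible = samples,
                exclusions = cbind(samples, reason = character(0))))
  }
  need <- c("c_pla", "c_dbs", "hct_pct")
  if (!all(need %in% names(samples))) {
    stop("`samples` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(samples))
  bad_conc <- !is.finite(samples$c_pla) | !is.finite(samples$c_dbs) |
    samples$c_pla <= 0 | samples$c_dbs <= 0
  reason[bad_conc] <- "invalid-concentration"
  bad_hct <- is.na(reason) &
    (is.na(samples$hct_pct) | samples$hct_pct < hct_range[1] |
       samples$hct_pct > hct_range[2])
  reason[bad_hct] <- "hct-out-of-range"
  if ("days_since_hct" %in% names(samples)) {
    stale <- is.na(reason) & !is.na(samples$days_since_hct) &
      samples$days_since_hct > max_days_since_hct
    reason[stale] <- "hct-determination-too-old"
  }
  keep <- is.na(reason)
  excl <- samples[!keep, , drop = FALSE]
  if (nrow(excl)) excl$reason <- reason[!keep] else excl$reason <- character(0)
  list(eligible = samples[keep, , drop = FALSE], exclusions = excl)
}

#' Average DBS-to-plasma conversion factor
#'
#' The conversion factor CF is the average of the per-sample ratios
#' C_DBS / C_pla for one analyte (arithmetic mean by default; this is the
#' bare-number conversion deliberately free of Hct or plasma-fraction
#' parameters). Also records whether the data meet the recommended minimum
#' of 40 samples from at least 25 subjects for establishing a conversion.
#'
#' @param samples Eligible paired samples of a single analyte: data.frame
#'   with `c_pla`, `c_dbs`, optional `subject_id`, `analyte`.
#' @param method `"mean"` (default), `"geometric"` (geometric mean of the
#'   ratios) or `"regression"` (least-squares slope through the origin).
#' @param min_samples,min_subjects Sample-size recommendation thresholds.
#' @return List of class `conversion_model`: `cf`, `method`, `n_samples`,
#'   `n_subjects`, `meets_sample_size`, `ratios`.
#' @export
conversion_factor <- function(samples, method = c("mean", "geometric", "regression"),
                              min_samples = 40, min_subjects = 25) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples), all(c("c_pla", "c_dbs") %in% names(samples)))
  if (nrow(samples) < 1L) stop("need at least one paired sample", call. = FALSE)
  if ("analyte" %in% names(samples) && length(unique(samples$analyte)) > 1L) {
    stop("mixed analytes: compute one conversion factor per analyte", call. = FALSE)
  }
  if (any(samples$c_pla <= 0) || any(samples$c_dbs <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  ratios <- samples$c_dbs / samples$c_pla
  cf <- switch(method,
    mean = mean(ratios),
    geometric = exp(mean(log(ratios))),
    regression = sum(samples$c_pla * samples$c_dbs) / sum(samples$c_pla^2)
  )
  n_subj <- if ("subject_id" %in% names(samples)) {
    length(unique(samples$subject_id))
  } else {
    NA_integer_
  }
  structure(
    list(
      cf = cf, method = method, n_samples = nrow(samples), n_subjects = n_subj,
      meets_sample_size = isTRUE(nrow(samples) >= min_samples && n_subj >= min_subjects),
      ratios = ratios
    ),
    class = "conversion_model"
  )
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf(
    "<conversion_model> CF = %.3f (%s of %d DBS/plasma ratios%s)%s\n",
    x$cf, x$method, x$n_samples,
    if (is.na(x$n_subjects)) "" else sprintf(", %d subjects", x$n_subjects),
    if (x$meets_sample_size) "" else " [below recommended 40 samples / 25 subjects]"
  ))
  invisible(x)
}

#' Estimate plasma concentration from a DBS measurement
#'
#' EC_pla = C_DBS / CF. No truncation to the validated range is applied.
#'
#' @param c_dbs DBS concentration(s), ng/mL.
#' @param model A `conversion_model`, or a bare positive CF.
#' @return Estimated plasma concentration(s), ng/mL.
#' @export
estimate_plasma <- function(c_dbs, model) {
  cf <- if (inherits(model, "conversion_model")) model$cf else model
  if (!is.numeric(cf) || length(cf) != 1L || !is.finite(cf) || cf <= 0) {
    stop("invalid conversion model: CF must be a single positive number",
      call. = FALSE)
  }
  c_dbs / cf
}

# All pairwise slopes (y_j - y_i)/(x_j - x_i), i < j, following the
# Passing-Bablok conventions: 0/0 pairs dropped, vertical pairs contribute
# +/-Inf by the sign of dy, slopes exactly -1 dropped.
pb_pairwise_slopes <- function(x, y) {
  n <- length(x)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  dx <- x[j] - x[i]
  dy <- y[j] - y[i]
  s <- ifelse(dx == 0 & dy == 0, NA_real_,
    ifelse(dx == 0, sign(dy) * Inf, dy / dx))
  s <- s[!is.na(s) & s != -1]
  sort(s)
}

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression robust to measurement error in
#' both variables. The slope is the shifted median of all pairwise slopes
#' (y_j - y_i)/(x_j - x_i): with K the number of slopes below -1, the
#' estimate is the (N+1)/2 + K order statistic (mean of the two straddling
#' order statistics for even N). Identical-x pairs contribute infinite
#' slopes signed by dy; 0/0 pairs and slopes exactly equal to -1 are
#' omitted. Confidence bounds come from the rank-based normal approximation
#' with w = z * sqrt(n(n-1)(2n+5)/18); the intercept is median(y - b x),
#' with its CI obtained from the slope bounds (upper slope gives the lower
#' intercept bound). The cusum linearity test is attached when n >= 5.
#'
#' @param x,y Paired measurements (reference method in `x`), n >= 3 with at
#'   least two distinct `x`.
#' @param conf_level Confidence level for the CIs (default 0.95).
#' @return Object of class `pb_result`: `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `n`, `n_slopes`, `k_offset`, `cusum` (a `cusum_test` or
#'   `NULL`), `conf_level`.
#' @examples
#' passing_bablok(1:5, 2 * (1:5) + 1)
#' @export
passing_bablok <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate input: all x values identical", call. = FALSE)
  }
  s <- pb_pairwise_slopes(x, y)
  ns <- length(s)
  k <- sum(s < -1)
  slope <- shifted_median(s, k)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((ns - w) / 2)
  m2 <- ns - m1 + 1
  slope_ci <- c(
    s[clamp_index(m1 + k, ns)],
    s[clamp_index(m2 + k, ns)]
  )
  intercept <- stats::median(y - slope * x)
  intercept_ci <- c(
    stats::median(y - slope_ci[2] * x),
    stats::median(y - slope_ci[1] * x)
  )
  cusum <- if (n >= 5 && is.finite(slope) && slope != 0) {
    cusum_linearity_test(x, y, slope, intercept)
  }
  structure(
    list(
      slope = slope, slope_ci = slope_ci,
      intercept = intercept, intercept_ci = intercept_ci,
      n = n, n_slopes = ns, k_offset = k,
      cusum = cusum, conf_level = conf_level
    ),
    class = "pb_result"
  )
}

shifted_median <- function(s_sorted, k) {
  ns <- length(s_sorted)
  if (ns == 0L) stop("no valid pairwise slopes", call. = FALSE)
  if (ns %% 2L == 1L) {
    s_sorted[clamp_index((ns + 1L) / 2L + k, ns)]
  } else {
    lo <- s_sorted[clamp_index(ns / 2L + k, ns)]
    hi <- s_sorted[clamp_index(ns / 2L + 1L + k, ns)]
    (lo + hi) / 2
  }
}

clamp_index <- function(i, n) min(max(i, 1L), n)

#' @export
print.pb_result <- function(x, ...) {
  cat(sprintf(
    "<pb_result> Passing-Bablok (n = %d):\n  slope %.4g (%g%% CI %.4g to %.4g)\n  intercept %.4g (CI %.4g to %.4g)\n",
    x$n, x$slope, 100 * x$conf_level, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2]
  ))
  if (!is.null(x$cusum)) {
    cat(sprintf("  cusum linearity: %s (H = %.3f)\n", x$cusum$band, x$cusum$statistic))
  }
  invisible(x)
}

#' Cusum test for linearity of a Passing-Bablok fit
#'
#' Scores each point by its side of the fitted line (above: sqrt(n_below /
#' n_above), below: -sqrt(n_above / n_below), on the line: 0), accumulates
#' the scores in ascending order of the projection x + y / slope along the
#' fitted direction, and compares the normalized maximum excursion
#' H = max|cusum| / sqrt(n_below + 1) against Kolmogorov-Smirnov critical
#' values (1.36 at the 5% level, 1.63 at 1%). Reported as a band, matching
#' how the test is used in method-comparison reporting.
#'
#' @param x,y Paired measurements (n >= 5).
#' @param slope,intercept Fitted Passing-Bablok line.
#' @return Object of class `cusum_test`: `statistic` (H), `band` (one of
#'   `"p > 0.05"`, `"p <= 0.05"`, `"p <= 0.01"`), `significant` (at 5%),
#'   `max_cusum`, `n_above`, `n_below`.
#' @export
cusum_linearity_test <- function(x, y, slope, intercept) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) {
    stop("insufficient data for the cusum linearity test (n < 5)", call. = FALSE)
  }
  if (!is.finite(slope) || slope == 0) {
    stop("cusum test needs a finite nonzero slope", call. = FALSE)
  }
  d <- y - (intercept + slope * x)
  n_above <- sum(d > 0)
  n_below <- sum(d < 0)
  score <- numeric(length(d))
  if (n_above > 0 && n_below > 0) {
    score[d > 0] <- sqrt(n_below / n_above)
    score[d < 0] <- -sqrt(n_above / n_below)
  }
  ord <- order(x + y / slope)
  cs <- cumsum(score[ord])
  max_cusum <- max(abs(cs))
  h <- max_cusum / sqrt(n_below + 1)
  band <- if (h > 1.63) "p <= 0.01" else if (h > 1.36) "p <= 0.05" else "p > 0.05"
  structure(
    list(
      statistic = h, band = band, significant = h > 1.36,
      max_cusum = max_cusum, n_above = n_above, n_below = n_below
    ),
    class = "cusum_test"
  )
}

#' @export
print.cusum_test <- function(x, ...) {
  cat(sprintf(
    "<cusum_test> H = %.3f: %s (%d above / %d below the line)\n",
    x$statistic, x$band, x$n_above, x$n_below
  ))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences d = y - x are summarized by their mean (bias) with a
#' t-based confidence interval, the sample SD, and the limits of agreement
#' bias +/- 1.96 SD. A Spearman rank correlation between the differences
#' and the pairwise means (x + y)/2 probes for a trend of disagreement with
#' concentration (r_S near zero means none).
#'
#' @param x,y Paired measurements, n >= 2 (reference in `x`).
#' @param conf_level Confidence level for the bias CI (default 0.95).
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @return Object of class `ba_result`: `bias`, `bias_ci`, `sd`, `loa_low`,
#'   `loa_high`, `spearman_r`, `spearman_p`, `mean_concentration`, `n`.
#' @export
bland_altman <- function(x, y, conf_level = 0.95, loa_mult = 1.96) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
  sp <- spearman_trend(d, m)
  structure(
    list(
      bias = bias, bias_ci = c(bias - half, bias + half), sd = s,
      loa_low = bias - loa_mult * s, loa_high = bias + loa_mult * s,
      spearman_r = sp$estimate, spearman_p = sp$p_value,
      mean_concentration = mean(m), n = n
    ),
    class = "ba_result"
  )
}

# Spearman correlation of differences vs means: exact null distribution for
# small untied samples, t approximation with average ranks otherwise.
spearman_trend <- function(d, m) {
  if (stats::sd(d) == 0 || stats::sd(m) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_))
  }
  n <- length(d)
  ties <- anyDuplicated(d) > 0 || anyDuplicated(m) > 0
  ct <- suppressWarnings(stats::cor.test(
    m, d,
    method = "spearman", exact = (n <= 10 && !ties)
  ))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf(
    "<ba_result> Bland-Altman (n = %d): bias %.4g ng/mL (CI %.4g to %.4g), SD %.4g\n  limits of agreement %.4g to %.4g; r_S = %.4f (p = %.2g)\n",
    x$n, x$bias, x$bias_ci[1], x$bias_ci[2], x$sd,
    x$loa_low, x$loa_high, x$spearman_r, x$spearman_p
  ))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with population
#' (1/n) moments. Penalizes both poor correlation and departure from the
#' identity line; 1 means perfect concordance.
#'
#' @param x,y Paired measurements, n >= 2.
#' @return The concordance coefficient in [-1, 1].
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4)) # 4/7
#' @export
lins_ccc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) {
    stop("undefined concordance: zero variances and zero mean difference",
      call. = FALSE)
  }
  2 * sxy / den
}

#' Percent-difference agreement rule
#'
#' Per-sample percent difference against the pairwise mean,
#' %diff = (a - b) / mean(a, b) x 100, with the regulatory pass rule: at
#' least `required_fraction` of samples (default 2/3) must lie within
#' `tol` percent (default +/-20, boundary inclusive).
#'
#' @param a,b Paired positive concentration series of equal length; for the
#'   bridging use `a` = EC_pla and `b` = C_pla.
#' @param tol Tolerance, percent.
#' @param required_fraction Minimum fraction of samples within tolerance.
#' @return List of class `pct_diff_result`: `pct_diff`, `within`,
#'   `frac_within`, `n_outside`, `pass`, `tol`, `required_fraction`.
#' @export
percent_diff_rule <- function(a, b, tol = 20, required_fraction = 2 / 3) {
  if (length(a) != length(b)) {
    stop("length mismatch between the two series", call. = FALSE)
  }
  stopifnot(length(a) >= 1L, tol > 0)
  if (any(a <= 0) || any(b <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  pd <- (a - b) / ((a + b) / 2) * 100
  within <- abs(pd) <= tol
  frac <- mean(within)
  structure(
    list(
      pct_diff = pd, within = within, frac_within = frac,
      n_outside = sum(!within), pass = frac >= required_fraction,
      tol = tol, required_fraction = required_fraction
    ),
    class = "pct_diff_result"
  )
}

#' @export
print.pct_diff_result <- function(x, ...) {
  cat(sprintf(
    "<pct_diff_result> %d/%d within +/-%g%% (%.1f%%; need >= %.1f%%): %s\n",
    sum(x$within), length(x$within), x$tol, 100 * x$frac_within,
    100 * x$required_fraction, if (x$pass) "PASS" else "FAIL"
  ))
  invisible(x)
}

#' Incurred sample reanalysis assessment
#'
#' Applies the percent-difference rule with the ISR orientation:
#' %diff = (repeat - original) / mean(repeat, original) x 100, passing when
#' at least 67% of pairs are within +/-20%.
#'
#' @param original,repeated Concentrations from the first and second
#'   analytical run, aligned pairs.
#' @inheritParams percent_diff_rule
#' @return A `pct_diff_result` (differences oriented repeat minus original).
#' @export
isr_assess <- function(original, repeated, tol = 20, required_fraction = 2 / 3) {
  percent_diff_rule(repeated, original, tol = tol,
    required_fraction = required_fraction)
}

#' Full plasma/DBS agreement report for one analyte
#'
#' Runs the complete bridging analysis on eligible paired samples of one
#' analyte: conversion-factor estimation, plasma estimation from DBS,
#' Passing-Bablok regression with cusum linearity test, Bland-Altman
#' analysis with Spearman trend test, Lin's CCC, and the +/-20% / 67%
#' percent-difference rule.
#'
#' @param samples Eligible paired samples (single analyte): data.frame with
#'   `c_pla`, `c_dbs`, optional `subject_id`, `analyte`.
#' @param cf_method Conversion-factor method, see [conversion_factor()].
#' @param conf_level Confidence level for interval estimates.
#' @return Object of class `agreement_report`: `analyte`, `conversion`
#'   (`conversion_model`), `pb` (`pb_result`), `ba` (`ba_result`),
#'   `lins_ccc`, `pct_diff` (`pct_diff_result`), `ema_fda_pass`, `data`
#'   (per-sample table with `ec_pla`, `diff`, `mean_conc`, `pct_diff`).
#' @export
agreement_report <- function(samples, cf_method = "mean", conf_level = 0.95) {
  conv <- conversion_factor(samples, method = cf_method)
  ec <- estimate_plasma(samples$c_dbs, conv)
  pb <- passing_bablok(samples$c_pla, ec, conf_level = conf_level)
  ba <- bland_altman(samples$c_pla, ec, conf_level = conf_level)
  ccc <- lins_ccc(samples$c_pla, ec)
  pd <- percent_diff_rule(ec, samples$c_pla)
  per_sample <- data.frame(
    c_pla = samples$c_pla, c_dbs = samples$c_dbs, ec_pla = ec,
    diff = ec - samples$c_pla, mean_conc = (ec + samples$c_pla) / 2,
    pct_diff = pd$pct_diff
  )
  if ("subject_id" %in% names(samples)) {
    per_sample <- cbind(subject_id = samples$subject_id, per_sample)
  }
  structure(
    list(
      analyte = if ("analyte" %in% names(samples)) samples$analyte[1] else NA_character_,
      conversion = conv, pb = pb, ba = ba, lins_ccc = ccc,
      pct_diff = pd, ema_fda_pass = pd$pass, data = per_sample
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n",
    x$analyte, x$conversion$n_samples))
  cat(sprintf("  CF = %.3f%s\n", x$conversion$cf,
    if (x$conversion$meets_sample_size) "" else " [sample-size recommendation not met]"))
  cat(sprintf("  Passing-Bablok: slope %.2f (%.2f to %.2f), intercept %.0f (%.0f to %.0f), cusum %s\n",
    x$pb$slope, x$pb$slope_ci[1], x$pb$slope_ci[2],
    x$pb$intercept, x$pb$intercept_ci[1], x$pb$intercept_ci[2],
    if (is.null(x$pb$cusum)) "n/a" else x$pb$cusum$band))
  cat(sprintf("  Lin's CCC = %.3f\n", x$lins_ccc))
  cat(sprintf("  Bland-Altman: bias %.0f (%.0f to %.0f) ng/mL, SD %.0f, r_S = %.4f (p = %.2g)\n",
    x$ba$bias, x$ba$bias_ci[1], x$ba$bias_ci[2], x$ba$sd,
    x$ba$spearman_r, x$ba$spearman_p))
  cat(sprintf("  %%diff rule: %d/%d outside +/-%g%% -> %s\n",
    x$pct_diff$n_outside, length(x$pct_diff$within), x$pct_diff$tol,
    if (x$ema_fda_pass) "PASS" else "FAIL"))
  invisible(x)
}
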