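#' Percent relative error of a back-calculated concentration
#'
#' Signed relative deviation of a found concentration from its nominal value,
#' %RE = (C_found - C_nom) / C_nom x 100. Vectorised over `found` and
#' `nominal`.
#'
#' @param found Back-calculated concentration(s), ng/mL.
#' @param nominal Nominal concentration(s), ng/mL; must be positive.
#' @return Signed percent relative error.
#' @examples
#' percent_re(87, 100)  # -13
#' @export
percent_re <- function(found, nominal) {
  if (!is.numeric(found) || !is.numeric(nominal)) {
    stop("`found` and `nominal` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(nominal)) || any(nominal <= 0)) {
    stop("`nominal` must be positive and finite", call. = FALSE)
  }
  (found - nominal) / nominal * 100
}

weighting_levels <- c("1", "1/x", "1/x^2")

weighting_weights <- function(weighting, x) {
  switch(weighting,
    "1"     = rep(1, length(x)),
    "1/x"   = 1 / x,
    "1/x^2" = 1 / x^2,
    stop("unknown weighting factor: ", weighting, call. = FALSE)
  )
}

#' Fit a weighted linear calibration line
#'
#' Fits response = intercept + slope x nominal by weighted least squares with
#' one of the standard calibration weighting factors w = 1, 1/x or 1/x^2, and
#' computes the statistics used for weighting-factor selection: the weighted
#' residual sum of squares (SS), the weighted correlation coefficient (r)
#' between observed and fitted responses, Akaike's information criterion
#' (AIC = n log(SS/n) + 2k with k = 2 fitted parameters), and the percent
#' relative error (%RE) of every back-calculated concentration.
#'
#' Duplicate calibrators are fitted as individual points (no averaging).
#'
#' @param points A data.frame with numeric columns `nominal` (ng/mL, > 0) and
#'   `response` (analyte/IS area ratio, >= 0); optional `level_label`.
#' @param weighting One of `"1"`, `"1/x"`, `"1/x^2"`.
#' @return An object of class `weighted_fit`: list with `weighting`, `slope`,
#'   `intercept`, `r`, `ss`, `aic`, `sum_abs_re`, `re_by_point`, `n`, and the
#'   fitted `points`.
#' @examples
#' pts <- data.frame(nominal = c(60, 120, 300, 600), response = 0.002 * c(60, 120, 300, 600))
#' fit_weighted_line(pts, "1/x^2")
#' @export
fit_weighted_line <- function(points, weighting = c("1", "1/x", "1/x^2")) {
  weighting <- match.arg(weighting)
  points <- validate_calibration_points(points)
  if (nrow(points) < 3L) {
    stop("need at least 3 calibration points", call. = FALSE)
  }
  if (length(unique(points$nominal)) < 2L) {
    stop("degenerate design: all nominal concentrations identical", call. = FALSE)
  }
  x <- points$nominal
  y <- points$response
  w <- weighting_weights(weighting, x)
  fit <- stats::lm(y ~ x, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  yhat <- unname(stats::fitted(fit))
  ss <- sum(w * (y - yhat)^2)
  n <- length(y)
  aic <- n * log(ss / n) + 2 * 2
  r <- weighted_pearson(y, yhat, w)
  found <- (y - intercept) / slope
  re <- percent_re(found, x)
  structure(
    list(
      weighting = weighting, slope = slope, intercept = intercept,
      r = r, ss = ss, aic = aic,
      sum_abs_re = sum(abs(re)), re_by_point = re,
      n = n, points = points
    ),
    class = "weighted_fit"
  )
}

validate_calibration_points <- function(points) {
  if (!is.data.frame(points) || !all(c("nominal", "response") %in% names(points))) {
    stop("`points` must be a data.frame with columns `nominal` and `response`",
      call. = FALSE)
  }
  if (any(!is.finite(points$nominal)) || any(points$nominal <= 0)) {
    stop("nominal concentrations must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(points$response)) || any(points$response < 0)) {
    stop("responses must be non-negative and finite", call. = FALSE)
  }
  points
}

# Weighted Pearson correlation; collapses to 1 for an exact fit.
weighted_pearson <- function(a, b, w) {
  wm <- function(v) sum(w * v) / sum(w)
  ca <- a - wm(a)
  cb <- b - wm(b)
  den <- sqrt(sum(w * ca^2) * sum(w * cb^2))
  if (den == 0) {
    return(NA_real_)
  }
  sum(w * ca * cb) / den
}

#' @export
print.weighted_fit <- function(x, ...) {
  cat(sprintf(
    "<weighted_fit> w = %s: y = %.6g + %.6g x (n = %d)\n  r = %.6f, SS = %.4g, AIC = %.4g, sum|%%RE| = %.3f\n",
    x$weighting, x$intercept, x$slope, x$n, x$r, x$ss, x$aic, x$sum_abs_re
  ))
  invisible(x)
}

#' Back-calculate a concentration from an instrument response
#'
#' Inverts the calibration line: C_found = (response - intercept) / slope.
#' Values outside the validated range are returned as-is; range flagging is
#' the caller's responsibility.
#'
#' @param fit A `weighted_fit`.
#' @param response Instrument response(s) (analyte/IS area ratio).
#' @return Concentration(s), ng/mL.
#' @export
back_calculate <- function(fit, response) {
  stopifnot(inherits(fit, "weighted_fit"))
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop("degenerate fit: zero slope", call. = FALSE)
  }
  (response - fit$intercept) / fit$slope
}

#' F-test for heteroscedasticity of calibration responses
#'
#' Two-sided variance-ratio test comparing replicate response variances at
#' the two ends of the calibration range. The statistic is the ratio of the
#' larger to the smaller sample variance; significance is declared when it
#' exceeds the upper `1 - alpha/2` quantile of the F distribution with the
#' corresponding degrees of freedom. A significant result motivates a
#' non-unit weighting factor in the calibration fit.
#'
#' @param reps_low Replicate responses at the LLOQ.
#' @param reps_high Replicate responses at the ULOQ.
#' @param alpha Significance level (default 0.01).
#' @return List of class `hetero_ftest`: `f` (variance ratio), `df` (numerator,
#'   denominator degrees of freedom), `critical`, `p_value` (two-sided),
#'   `significant`, `alpha`.
#' @examples
#' heteroscedasticity_ftest(c(1, 2, 3), c(10, 20, 30))
#' @export
heteroscedasticity_ftest <- function(reps_low, reps_high, alpha = 0.01) {
  if (length(reps_low) < 2L || length(reps_high) < 2L) {
    stop("need at least 2 replicates at each range end", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  v_low <- stats::var(reps_low)
  v_high <- stats::var(reps_high)
  if (v_low == 0 || v_high == 0) {
    stop("undefined variance ratio: zero replicate variance", call. = FALSE)
  }
  if (v_high >= v_low) {
    f <- v_high / v_low
    df <- c(length(reps_high) - 1L, length(reps_low) - 1L)
  } else {
    f <- v_low / v_high
    df <- c(length(reps_low) - 1L, length(reps_high) - 1L)
  }
  critical <- stats::qf(1 - alpha / 2, df[1], df[2])
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  structure(
    list(
      f = f, df = df, critical = critical, p_value = p,
      significant = f > critical, alpha = alpha
    ),
    class = "hetero_ftest"
  )
}

#' @export
print.hetero_ftest <- function(x, ...) {
  cat(sprintf(
    "<hetero_ftest> F(%d, %d) = %.4g, critical = %.4g (alpha = %g, two-sided): %s\n",
    x$df[1], x$df[2], x$f, x$critical, x$alpha,
    if (x$significant) "heteroscedastic" else "homoscedastic"
  ))
  invisible(x)
}

#' Select the calibration weighting factor
#'
#' Implements the formal weighting-factor selection procedure: the
#' calibration is fitted with each candidate weighting (w = 1, 1/x, 1/x^2)
#' and the heteroscedasticity of replicate responses at the range ends is
#' tested with [heteroscedasticity_ftest()]. If the F-test is not
#' significant the unweighted fit (w = 1) is kept. Otherwise the weighting
#' with the best selection metrics wins, with the priority AIC, then SS,
#' then sum of absolute %RE, then r closest to 1; exact ties are broken
#' toward the stronger weighting.
#'
#' @param points Calibration points as for [fit_weighted_line()].
#' @param reps_low,reps_high Replicate responses at LLOQ and ULOQ for the
#'   F-test (typically the duplicate calibrators across runs).
#' @param alpha Significance level of the F-test.
#' @return Object of class `weighting_selection`: `chosen` (the weighting),
#'   `fits` (named list of `weighted_fit`), `metrics_table` (data.frame with
#'   one row per weighting: ss, r, aic, sum_abs_re), `ftest`
#'   (`hetero_ftest`), `ftest_significant`, `rationale`.
#' @export
select_weighting <- function(points, reps_low, reps_high, alpha = 0.01) {
  fits <- lapply(weighting_levels, function(w) fit_weighted_line(points, w))
  names(fits) <- weighting_levels
  metrics <- data.frame(
    weighting = weighting_levels,
    ss = vapply(fits, `[[`, numeric(1), "ss"),
    r = vapply(fits, `[[`, numeric(1), "r"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    sum_abs_re = vapply(fits, `[[`, numeric(1), "sum_abs_re"),
    row.names = NULL
  )
  ftest <- heteroscedasticity_ftest(reps_low, reps_high, alpha)
  if (!ftest$significant) {
    chosen <- "1"
    rationale <- sprintf(
      "F-test not significant (F = %.3g <= critical %.3g): unweighted regression retained",
      ftest$f, ftest$critical
    )
  } else {
    pick <- pick_by_priority(metrics)
    chosen <- pick$weighting
    rationale <- sprintf(
      "F-test significant (F = %.3g > critical %.3g); %s",
      ftest$f, ftest$critical, pick$reason
    )
  }
  structure(
    list(
      chosen = chosen, fits = fits, metrics_table = metrics,
      ftest = ftest, ftest_significant = ftest$significant,
      rationale = rationale
    ),
    class = "weighting_selection"
  )
}

# Lexicographic selection: AIC, SS, sum|%RE|, |1 - r|; exact ties fall
# through to the next criterion, and a full tie picks the strongest
# weighting (largest index in weighting_levels).
pick_by_priority <- function(metrics) {
  crit <- list(
    aic = metrics$aic,
    ss = metrics$ss,
    sum_abs_re = metrics$sum_abs_re,
    r_dist = abs(1 - metrics$r)
  )
  alive <- rep(TRUE, nrow(metrics))
  for (nm in names(crit)) {
    v <- crit[[nm]]
    v[!alive] <- Inf
    best <- min(v)
    keep <- alive & (v == best)
    if (sum(keep) == 1L) {
      return(list(
        weighting = metrics$weighting[keep],
        reason = sprintf("chosen %s by smallest %s", metrics$weighting[keep], nm)
      ))
    }
    alive <- keep
  }
  idx <- max(which(alive))
  list(
    weighting = metrics$weighting[idx],
    reason = sprintf(
      "all criteria tied among {%s}; stronger weighting %s preferred",
      paste(metrics$weighting[alive], collapse = ", "), metrics$weighting[idx]
    )
  )
}

#' @export
print.weighting_selection <- function(x, ...) {
  cat(sprintf("<weighting_selection> chosen w = %s\n  %s\n", x$chosen, x$rationale))
  print(x$metrics_table, row.names = FALSE, digits = 6)
  invisible(x)
}
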