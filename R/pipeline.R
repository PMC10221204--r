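#' Study configuration
#'
#' Bundles the file paths, acceptance rules and eligibility thresholds for
#' a validation / bridging run. All regulatory thresholds carry their
#' guideline defaults and are overridable here.
#'
#' @param calibration_csv,qc_csv,areas_csv,paired_csv,isr_csv File paths
#'   (any may be `NULL` when the corresponding stage is not run).
#' @param rule,rule_lloq Acceptance rules (defaults [standard_rule()],
#'   [lloq_rule()]).
#' @param hct_range,max_days_since_hct Eligibility thresholds for
#'   [filter_eligible()].
#' @param weighting_alpha Significance level of the heteroscedasticity
#'   F-test in [select_weighting()].
#' @param r_min Linearity check threshold on the correlation coefficient
#'   (default 0.997).
#' @param cf_method Conversion-factor method (default `"mean"`).
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic; only the synthetic generators draw random numbers).
#' @return List of class `study_config`.
#' @export
study_config <- function(calibration_csv = NULL, qc_csv = NULL, areas_csv = NULL,
                         paired_csv = NULL, isr_csv = NULL,
                         rule = standard_rule(), rule_lloq = lloq_rule(),
                         hct_range = c(29, 45), max_days_since_hct = 14,
                         weighting_alpha = 0.01, r_min = 0.997,
                         cf_method = "mean", seed = NULL) {
  structure(
    list(
      calibration_csv = calibration_csv, qc_csv = qc_csv, areas_csv = areas_csv,
      paired_csv = paired_csv, isr_csv = isr_csv,
      rule = rule, rule_lloq = rule_lloq,
      hct_range = hct_range, max_days_since_hct = max_days_since_hct,
      weighting_alpha = weighting_alpha, r_min = r_min,
      cf_method = cf_method, seed = seed
    ),
    class = "study_config"
  )
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

provenance_block <- function(config) {
  list(
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dbsbridge")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

# Per-analyte, per-run weighting selection over a calibration table.
# Replicate responses at the lowest/highest calibrator (pooled across runs)
# feed the heteroscedasticity F-test.
calibration_stage <- function(cal, alpha, r_min) {
  fits <- list()
  re_rows <- list()
  for (an in unique(cal$analyte)) {
    sub_a <- cal[cal$analyte == an, , drop = FALSE]
    reps_low <- sub_a$response[sub_a$nominal == min(sub_a$nominal)]
    reps_high <- sub_a$response[sub_a$nominal == max(sub_a$nominal)]
    for (run in unique(sub_a$run_id)) {
      sub <- sub_a[sub_a$run_id == run, , drop = FALSE]
      sel <- select_weighting(sub, reps_low, reps_high, alpha = alpha)
      fit <- sel$fits[[sel$chosen]]
      fits[[length(fits) + 1]] <- data.frame(
        analyte = an, run_id = run, weighting = sel$chosen,
        slope = fit$slope, intercept = fit$intercept, r = fit$r,
        ss = fit$ss, aic = fit$aic, sum_abs_re = fit$sum_abs_re,
        r_ok = fit$r >= r_min,
        ftest_significant = sel$ftest_significant
      )
      re_rows[[length(re_rows) + 1]] <- data.frame(
        analyte = an, run_id = run, level_label = sub$level_label,
        nominal = sub$nominal, re = fit$re_by_point
      )
    }
  }
  list(fits = do.call(rbind, fits), re = do.call(rbind, re_rows))
}

ap_stage <- function(qc, rule, rule_lloq) {
  groups <- split(qc, list(qc$analyte, qc$condition, qc$nominal), drop = TRUE)
  rows <- lapply(groups, function(g) {
    row <- summarize_qc(g$measured, g$nominal[1], is_lloq = g$is_lloq[1])
    row <- check_acceptance(row, rule = rule, rule_lloq = rule_lloq)
    cbind(data.frame(analyte = g$analyte[1], condition = g$condition[1]), row)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$analyte, tab$condition, tab$nominal), ]
  rownames(tab) <- NULL
  tab
}

recovery_stage <- function(areas) {
  rows <- list()
  for (an in unique(areas$analyte)) {
    sub <- areas[areas$analyte == an, , drop = FALSE]
    for (lv in unique(sub$level)) {
      rec <- recovery(sub, lv)
      mf <- tryCatch(isn_matrix_factor(sub, lv), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        analyte = an, level = lv, rec = rec$rec, rec_cv = rec$cv,
        isn_mf = if (is.null(mf)) NA_real_ else mf$isn_mf,
        isn_mf_cv = if (is.null(mf)) NA_real_ else mf$cv,
        isn_mf_ok = if (is.null(mf)) NA else !mf$cv_exceeds
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the validation stage of the pipeline
#'
#' Executes, per analyte: calibration fitting with weighting-factor
#' selection for every run; accuracy-and-precision summaries with
#' acceptance verdicts for all QC conditions (within-run, between-run,
#' stability, dilution); recovery and IS-normalized matrix factor when an
#' area file is supplied; and — for the DBS matrix — the hematocrit-effect
#' assessment on `hct:<value>` QC conditions.
#'
#' @param config A [study_config()] with at least `calibration_csv` and
#'   `qc_csv` set.
#' @param matrix `"plasma"` or `"dbs"`.
#' @return Object of class `report_bundle` with elements `matrix`,
#'   `calibration` (fit summary + per-point %RE), `ap_table`,
#'   `recovery_table` (or `NULL`), `hct` (`hct_assessment` or `NULL`),
#'   `pass` (overall verdict), `provenance`.
#' @export
run_validation <- function(config, matrix = c("plasma", "dbs")) {
  matrix <- match.arg(matrix)
  stopifnot(inherits(config, "study_config"))
  if (is.null(config$calibration_csv) || is.null(config$qc_csv)) {
    stop("config must provide `calibration_csv` and `qc_csv`", call. = FALSE)
  }
  cal <- read_calibration_csv(config$calibration_csv)
  qc <- read_qc_csv(config$qc_csv)

  calres <- calibration_stage(cal, config$weighting_alpha, config$r_min)

  is_hct <- startsWith(qc$condition, "hct:")
  ap <- ap_stage(qc[!is_hct, , drop = FALSE], config$rule, config$rule_lloq)

  hct <- NULL
  if (matrix == "dbs" && any(is_hct)) {
    hq <- qc[is_hct, , drop = FALSE]
    if (!"hct_pct" %in% names(hq) || anyNA(hq$hct_pct)) {
      hq$hct_pct <- as.numeric(sub("^hct:", "", hq$condition))
    }
    hct_tabs <- lapply(split(hq, hq$analyte), hct_effect_assess,
      rule = config$rule, rule_lloq = config$rule_lloq)
    hct_table <- do.call(rbind, lapply(names(hct_tabs), function(an) {
      cbind(analyte = an, hct_tabs[[an]]$table)
    }))
    rownames(hct_table) <- NULL
    hct <- list(table = hct_table, pass = all(vapply(hct_tabs, `[[`, logical(1), "pass")))
  }

  rec <- NULL
  if (!is.null(config$areas_csv)) {
    rec <- recovery_stage(read_areas_csv(config$areas_csv))
  }

  pass <- all(ap$pass) && all(calres$fits$r_ok) &&
    (is.null(hct) || hct$pass) &&
    (is.null(rec) || all(rec$isn_mf_ok, na.rm = TRUE))

  structure(
    list(
      matrix = matrix, calibration = calres, ap_table = ap,
      recovery_table = rec, hct = hct, pass = pass,
      provenance = provenance_block(config)
    ),
    class = "report_bundle"
  )
}

#' Run the bridging stage of the pipeline
#'
#' Filters paired samples for eligibility (Hct range, Hct-determination
#' age), then computes per analyte the conversion factor, estimated plasma
#' concentrations and the full agreement suite ([agreement_report()]).
#' Analytes left with no eligible samples are skipped with a warning. When
#' an ISR file is supplied, [isr_assess()] runs per (analyte, matrix).
#'
#' @param config A [study_config()] with `paired_csv` set (and optionally
#'   `isr_csv`).
#' @return Object of class `report_bundle` with elements `agreement` (named
#'   list of `agreement_report`), `agreement_table` (one summary row per
#'   analyte), `exclusions`, `filter_counts`, `isr_table` (or `NULL`),
#'   `pass`, `provenance`.
#' @export
run_bridging <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(config$paired_csv)) {
    stop("config must provide `paired_csv`", call. = FALSE)
  }
  paired <- read_paired_csv(config$paired_csv)
  flt <- filter_eligible(paired, hct_range = config$hct_range,
    max_days_since_hct = config$max_days_since_hct)
  counts <- data.frame(
    n_in = nrow(paired), n_eligible = nrow(flt$eligible),
    n_excluded = nrow(flt$exclusions)
  )

  reports <- list()
  rows <- list()
  for (an in unique(paired$analyte)) {
    sub <- flt$eligible[flt$eligible$analyte == an, , drop = FALSE]
    if (nrow(sub) < 3L) {
      warning("analyte ", an, " skipped: fewer than 3 eligible samples",
        call. = FALSE)
      next
    }
    rep <- agreement_report(sub, cf_method = config$cf_method)
    reports[[an]] <- rep
    rows[[an]] <- data.frame(
      analyte = an, n = rep$conversion$n_samples,
      n_subjects = rep$conversion$n_subjects,
      meets_sample_size = rep$conversion$meets_sample_size,
      cf = rep$conversion$cf,
      pb_slope = rep$pb$slope, pb_slope_lo = rep$pb$slope_ci[1],
      pb_slope_hi = rep$pb$slope_ci[2],
      pb_intercept = rep$pb$intercept,
      pb_intercept_lo = rep$pb$intercept_ci[1],
      pb_intercept_hi = rep$pb$intercept_ci[2],
      cusum = if (is.null(rep$pb$cusum)) NA_character_ else rep$pb$cusum$band,
      lins_ccc = rep$lins_ccc,
      bias = rep$ba$bias, bias_lo = rep$ba$bias_ci[1], bias_hi = rep$ba$bias_ci[2],
      ba_sd = rep$ba$sd, spearman_r = rep$ba$spearman_r,
      spearman_p = rep$ba$spearman_p,
      n_outside_20 = rep$pct_diff$n_outside,
      frac_within_20 = rep$pct_diff$frac_within,
      pct_diff_pass = rep$pct_diff$pass
    )
  }
  agreement_table <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(agreement_table)) rownames(agreement_table) <- NULL

  isr_table <- NULL
  if (!is.null(config$isr_csv)) {
    isr <- read_isr_csv(config$isr_csv)
    isr_rows <- lapply(split(isr, list(isr$analyte, isr$matrix), drop = TRUE),
      function(g) {
        res <- isr_assess(g$original, g$repeated)
        data.frame(
          analyte = g$analyte[1], matrix = g$matrix[1], n = nrow(g),
          frac_within = res$frac_within, max_abs_diff = max(abs(res$pct_diff)),
          pass = res$pass
        )
      })
    isr_table <- do.call(rbind, isr_rows)
    rownames(isr_table) <- NULL
  }

  pass <- length(reports) > 0 &&
    all(vapply(reports, `[[`, logical(1), "ema_fda_pass")) &&
    (is.null(isr_table) || all(isr_table$pass))

  structure(
    list(
      agreement = reports, agreement_table = agreement_table,
      exclusions = flt$exclusions, filter_counts = counts,
      isr_table = isr_table, pass = pass,
      provenance = provenance_block(config)
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  if (!is.null(x$calibration)) {
    cat("\nCalibration fits (selected weighting per run):\n")
    print(round_df(x$calibration$fits), row.names = FALSE)
  }
  if (!is.null(x$ap_table)) {
    cat("\nAccuracy & precision:\n")
    print(round_df(x$ap_table), row.names = FALSE)
  }
  if (!is.null(x$recovery_table)) {
    cat("\nRecovery / ISN-MF:\n")
    print(round_df(x$recovery_table), row.names = FALSE)
  }
  if (!is.null(x$hct)) {
    cat(sprintf("\nHct effect (overall %s):\n", if (x$hct$pass) "PASS" else "FAIL"))
    print(round_df(x$hct$table), row.names = FALSE)
  }
  if (!is.null(x$agreement_table)) {
    cat(sprintf("\nEligibility: %d in, %d eligible, %d excluded\n",
      x$filter_counts$n_in, x$filter_counts$n_eligible, x$filter_counts$n_excluded))
    cat("\nAgreement summary:\n")
    print(round_df(x$agreement_table), row.names = FALSE)
  }
  if (!is.null(x$isr_table)) {
    cat("\nIncurred sample reanalysis:\n")
    print(round_df(x$isr_table), row.names = FALSE)
  }
  invisible(x)
}

# Reporting-layer rounding only; underlying tables keep full precision.
round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits + 1))
  df
}

#' Write a report bundle to CSV files
#'
#' Serializes every table in the bundle (full precision) plus a provenance
#' file into `dir`.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(bundle$calibration)) {
    emit(bundle$calibration$fits, "calibration_fits")
    emit(bundle$calibration$re, "calibration_re")
  }
  emit(bundle$ap_table, "accuracy_precision")
  emit(bundle$recovery_table, "recovery_matrix_factor")
  if (!is.null(bundle$hct)) emit(bundle$hct$table, "hct_effect")
  emit(bundle$agreement_table, "agreement")
  if (!is.null(bundle$agreement)) {
    per_sample <- do.call(rbind, lapply(names(bundle$agreement), function(an) {
      cbind(analyte = an, bundle$agreement[[an]]$data)
    }))
    emit(per_sample, "agreement_per_sample")
  }
  emit(bundle$exclusions, "exclusions")
  emit(bundle$isr_table, "isr")
  prov <- data.frame(
    key = names(bundle$provenance),
    value = vapply(bundle$provenance, function(v) {
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  )
  emit(prov, "provenance")
  invisible(written)
}
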