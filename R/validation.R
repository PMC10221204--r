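#' Acceptance rules for accuracy and precision
#'
#' An acceptance rule bundles the accuracy band (percent of nominal) and the
#' imprecision cap (CV%) applied to a QC summary. The regulatory defaults
#' are 85-115% accuracy with CV <= 15% for ordinary QC levels and 80-120%
#' with CV <= 20% at the LLOQ.
#'
#' @param acc_low,acc_high Accuracy band bounds, percent of nominal.
#' @param cv_max Maximum allowed CV%.
#' @param name Label for reporting.
#' @return A list of class `acceptance_rule`.
#' @examples
#' standard_rule()
#' lloq_rule()
#' @export
acceptance_rule <- function(acc_low, acc_high, cv_max, name = "custom") {
  stopifnot(is.numeric(acc_low), is.numeric(acc_high), is.numeric(cv_max))
  if (acc_low >= acc_high) stop("acc_low must be < acc_high", call. = FALSE)
  if (cv_max <= 0) stop("cv_max must be positive", call. = FALSE)
  structure(
    list(acc_low = acc_low, acc_high = acc_high, cv_max = cv_max, name = name),
    class = "acceptance_rule"
  )
}

#' @rdname acceptance_rule
#' @export
standard_rule <- function() acceptance_rule(85, 115, 15, "standard +/-15%")

#' @rdname acceptance_rule
#' @export
lloq_rule <- function() acceptance_rule(80, 120, 20, "LLOQ +/-20%")

#' @export
print.acceptance_rule <- function(x, ...) {
  cat(sprintf(
    "<acceptance_rule> %s: accuracy %g-%g%%, CV <= %g%%\n",
    x$name, x$acc_low, x$acc_high, x$cv_max
  ))
  invisible(x)
}

#' Summarize a QC replicate set
#'
#' Computes the accuracy-and-precision row for one QC level: mean measured
#' concentration, accuracy (mean/nominal x 100) and imprecision as CV%
#' (sample n-1 standard deviation over the mean x 100). The pass flag is
#' left `NA` until [check_acceptance()] applies a rule.
#'
#' @param measured Replicate measured concentrations, ng/mL (>= 2 values).
#' @param nominal Nominal concentration, ng/mL (> 0).
#' @param is_lloq Whether this set sits at the LLOQ (wider acceptance band).
#' @return One-row data.frame of class `ap_row`: `nominal`, `mean_conc`,
#'   `cv`, `acc`, `n`, `is_lloq`, `pass`.
#' @examples
#' summarize_qc(c(90, 100, 110), 100)
#' @export
summarize_qc <- function(measured, nominal, is_lloq = FALSE) {
  if (length(measured) < 2L) {
    stop("insufficient replicates: need at least 2 measured values", call. = FALSE)
  }
  if (!is.numeric(nominal) || length(nominal) != 1L || is.na(nominal) || nominal <= 0) {
    stop("`nominal` must be a single positive number", call. = FALSE)
  }
  m <- mean(measured)
  row <- data.frame(
    nominal = nominal,
    mean_conc = m,
    cv = 100 * stats::sd(measured) / m,
    acc = 100 * m / nominal,
    n = length(measured),
    is_lloq = is_lloq,
    pass = NA
  )
  class(row) <- c("ap_row", class(row))
  row
}

#' Apply an acceptance rule to an accuracy-and-precision row
#'
#' Sets the pass flag: pass iff accuracy lies inside the applicable band
#' (inclusive at the boundary) and CV% does not exceed the cap. At the LLOQ
#' the wider `lloq` rule applies.
#'
#' @param row An `ap_row` from [summarize_qc()] (or any data.frame with
#'   `acc` and `cv` columns; multi-row input is handled rowwise).
#' @param rule Rule for non-LLOQ rows (default [standard_rule()]).
#' @param is_lloq Logical, recycled along rows; defaults to the row's own
#'   `is_lloq` column when present.
#' @param rule_lloq Rule applied where `is_lloq` (default [lloq_rule()]).
#' @return The row(s) with `pass` filled in.
#' @export
check_acceptance <- function(row, rule = standard_rule(), is_lloq = NULL,
                             rule_lloq = lloq_rule()) {
  stopifnot(is.data.frame(row), all(c("acc", "cv") %in% names(row)))
  if (is.null(is_lloq)) {
    is_lloq <- if ("is_lloq" %in% names(row)) row$is_lloq else FALSE
  }
  is_lloq <- rep_len(is_lloq, nrow(row))
  pass <- logical(nrow(row))
  for (i in seq_len(nrow(row))) {
    r <- if (is_lloq[i]) rule_lloq else rule
    pass[i] <- row$acc[i] >= r$acc_low && row$acc[i] <= r$acc_high &&
      row$cv[i] <= r$cv_max
  }
  row$pass <- pass
  row
}

validate_area_panel <- function(panel) {
  need <- c("technique", "analyte_area", "is_area")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    stop("area panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(panel$technique), c("normal", "post", "neat"))
  if (length(bad)) {
    stop("unknown technique(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(panel$analyte_area < 0) || any(panel$is_area < 0)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  panel
}

#' Extraction recovery at one QC level
#'
#' Recovery compares the signal obtained with the normal extraction against
#' the post-extraction technique (blank matrix spiked after extraction).
#' Each normal-extraction replicate yields a per-replicate recovery against
#' the mean post-extraction signal (unpaired design); the reported recovery
#' is their mean, with the CV% across replicates. The signal is the
#' analyte/IS area ratio by default so that IS variability cancels; set
#' `signal = "area"` to use the raw analyte area.
#'
#' @param panel Area panel data.frame with columns `technique` (one of
#'   `"normal"`, `"post"`, `"neat"`), `analyte_area`, `is_area`, `level`, and
#'   optionally `donor_id`, `hct_pct`.
#' @param level QC level to evaluate (matched against `panel$level`).
#' @param signal `"ratio"` (analyte/IS, default) or `"area"`.
#' @return List: `rec` (percent), `cv` (percent), `n` (normal-extraction
#'   replicates).
#' @export
recovery <- function(panel, level, signal = c("ratio", "area")) {
  signal <- match.arg(signal)
  panel <- validate_area_panel(panel)
  sub <- panel[panel$level == level, , drop = FALSE]
  sig <- if (signal == "ratio") sub$analyte_area / sub$is_area else sub$analyte_area
  normal <- sig[sub$technique == "normal"]
  post <- sig[sub$technique == "post"]
  if (length(normal) < 2L || length(post) < 2L) {
    stop("need at least 2 replicates per technique at level ", level, call. = FALSE)
  }
  ref <- mean(post)
  if (ref == 0) stop("undefined recovery: zero post-extraction mean", call. = FALSE)
  rec_i <- 100 * normal / ref
  list(rec = mean(rec_i), cv = 100 * stats::sd(rec_i) / mean(rec_i), n = length(rec_i))
}

#' IS-normalized matrix factor at one QC level
#'
#' Per donor, the matrix factor (MF) of the analyte is the post-extraction
#' area divided by the mean neat-solution area, and likewise for the internal
#' standard; the IS-normalized matrix factor is their ratio,
#' ISN-MF = MF_analyte / MF_IS. Reported as the mean and CV% across donors;
#' a CV above 15% flags a relevant residual matrix effect.
#'
#' @inheritParams recovery
#' @param cv_limit CV% limit for the flag (default 15).
#' @return List: `isn_mf` (mean across donors), `cv`, `n_donors`, `per_donor`
#'   (data.frame), `cv_exceeds`.
#' @export
isn_matrix_factor <- function(panel, level, cv_limit = 15) {
  panel <- validate_area_panel(panel)
  if (!"donor_id" %in% names(panel)) {
    stop("panel needs a `donor_id` column for matrix-factor evaluation", call. = FALSE)
  }
  sub <- panel[panel$level == level, , drop = FALSE]
  neat <- sub[sub$technique == "neat", , drop = FALSE]
  post <- sub[sub$technique == "post", , drop = FALSE]
  if (nrow(neat) == 0 || nrow(post) == 0) {
    stop("need post-extraction and neat-solution areas at level ", level, call. = FALSE)
  }
  neat_a <- mean(neat$analyte_area)
  neat_is <- mean(neat$is_area)
  if (neat_a == 0 || neat_is == 0) {
    stop("undefined matrix factor: zero neat-solution area", call. = FALSE)
  }
  donors <- split(post, post$donor_id)
  per_donor <- data.frame(
    donor_id = names(donors),
    mf_analyte = vapply(donors, function(d) mean(d$analyte_area) / neat_a, numeric(1)),
    mf_is = vapply(donors, function(d) mean(d$is_area) / neat_is, numeric(1)),
    row.names = NULL
  )
  per_donor$isn_mf <- per_donor$mf_analyte / per_donor$mf_is
  m <- mean(per_donor$isn_mf)
  cv <- 100 * stats::sd(per_donor$isn_mf) / m
  list(
    isn_mf = m, cv = cv, n_donors = nrow(per_donor),
    per_donor = per_donor, cv_exceeds = cv > cv_limit
  )
}

#' Hematocrit-effect assessment
#'
#' Assesses whether DBS QC samples prepared at the extremes of the validated
#' hematocrit range and read on a mid-Hct calibration curve still meet the
#' accuracy-and-precision acceptance rules. One row per (Hct, level) cell;
#' the overall verdict requires every cell to pass.
#'
#' @param qc Data.frame with columns `hct_pct`, `nominal`, `measured`,
#'   optional `is_lloq` (lowest nominal defaults to LLOQ when absent).
#' @param rule,rule_lloq Acceptance rules (defaults [standard_rule()],
#'   [lloq_rule()]).
#' @return List of class `hct_assessment`: `table` (one `ap_row` per cell
#'   with `hct_pct`), `pass` (overall).
#' @export
hct_effect_assess <- function(qc, rule = standard_rule(), rule_lloq = lloq_rule()) {
  need <- c("hct_pct", "nominal", "measured")
  if (!is.data.frame(qc) || !all(need %in% names(qc))) {
    stop("`qc` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"is_lloq" %in% names(qc)) qc$is_lloq <- qc$nominal == min(qc$nominal)
  cells <- split(qc, list(qc$hct_pct, qc$nominal), drop = TRUE)
  n_levels <- length(unique(qc$nominal))
  for (h in unique(qc$hct_pct)) {
    if (length(unique(qc$nominal[qc$hct_pct == h])) < n_levels) {
      stop("incomplete design: Hct ", h, "% is missing QC levels", call. = FALSE)
    }
  }
  rows <- lapply(cells, function(cell) {
    row <- summarize_qc(cell$measured, cell$nominal[1], is_lloq = cell$is_lloq[1])
    row <- check_acceptance(row, rule = rule, rule_lloq = rule_lloq)
    row$hct_pct <- cell$hct_pct[1]
    row
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$hct_pct, tab$nominal), c("hct_pct", setdiff(names(tab), "hct_pct"))]
  rownames(tab) <- NULL
  structure(list(table = tab, pass = all(tab$pass)), class = "hct_assessment")
}

#' @export
print.hct_assessment <- function(x, ...) {
  cat(sprintf("<hct_assessment> overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

interference_limits <- c(
  "selectivity-analyte" = 20, "selectivity-IS" = 5,
  "carryover-analyte" = 20, "carryover-IS" = 5
)

#' Selectivity / carryover interference check
#'
#' Compares a blank-sample response at the analyte (or IS) retention time
#' against the reference response — the LLOQ sample for the analyte, the
#' working-level IS response for the IS. The blank must stay below 20% of
#' the reference for the analyte and below 5% for the IS.
#'
#' @param blank_response Blank peak area at the retention time of interest.
#' @param reference_response Reference peak area (> 0).
#' @param context One of `"selectivity-analyte"`, `"selectivity-IS"`,
#'   `"carryover-analyte"`, `"carryover-IS"`.
#' @return List of class `threshold_check`: `observed_fraction` (percent of
#'   reference), `limit`, `pass`, `context`.
#' @export
interference_check <- function(blank_response, reference_response,
                               context = names(interference_limits)) {
  context <- match.arg(context)
  if (!is.numeric(reference_response) || reference_response <= 0) {
    stop("undefined fraction: reference response must be positive", call. = FALSE)
  }
  frac <- 100 * blank_response / reference_response
  limit <- interference_limits[[context]]
  structure(
    list(observed_fraction = frac, limit = limit, pass = frac < limit,
         context = context),
    class = "threshold_check"
  )
}

#' Sensitivity check at the LLOQ
#'
#' The LLOQ response must be at least `min_ratio` times the zero-sample
#' (blank + IS) response, and — when a signal-to-noise estimate from the
#' acquisition software is supplied — S/N must also reach `min_ratio`.
#'
#' @param lloq_response Mean LLOQ analyte response.
#' @param zero_response Mean zero-sample response at the analyte retention
#'   time (> 0).
#' @param sn Optional signal-to-noise ratio (taken as an input, not computed
#'   from chromatograms).
#' @param min_ratio Required ratio (default 5).
#' @return List of `threshold_check`s: `response_ratio` and, if `sn` given,
#'   `signal_to_noise`.
#' @export
sensitivity_check <- function(lloq_response, zero_response, sn = NULL,
                              min_ratio = 5) {
  if (!is.numeric(zero_response) || zero_response <= 0) {
    stop("undefined ratio: zero-sample response must be positive", call. = FALSE)
  }
  ratio <- lloq_response / zero_response
  out <- list(response_ratio = structure(
    list(observed_fraction = ratio, limit = min_ratio, pass = ratio >= min_ratio,
         context = "sensitivity"),
    class = "threshold_check"
  ))
  if (!is.null(sn)) {
    out$signal_to_noise <- structure(
      list(observed_fraction = sn, limit = min_ratio, pass = sn >= min_ratio,
           context = "sensitivity"),
      class = "threshold_check"
    )
  }
  out
}

#' @export
print.threshold_check <- function(x, ...) {
  unit <- if (x$context == "sensitivity") "x" else "% of reference"
  cat(sprintf(
    "<threshold_check> %s: observed %.3g%s vs limit %g: %s\n",
    x$context, x$observed_fraction, unit, x$limit,
    if (x$pass) "PASS" else "FAIL"
  ))
  invisible(x)
}

#' Stability / dilution-integrity assessment
#'
#' Summarizes each (analyte, condition, nominal) replicate group with
#' [summarize_qc()] and applies the standard acceptance rule (LLOQ groups
#' get the LLOQ rule). Dilution-integrity sets enter with measured values
#' already multiplied by the dilution factor; the factor, when supplied, is
#' carried through for reporting.
#'
#' @param qc Data.frame with columns `condition`, `nominal`, `measured`, and
#'   optionally `analyte`, `is_lloq`, `dilution_factor`.
#' @param rule,rule_lloq Acceptance rules.
#' @return Data.frame: one checked `ap_row` per group, with `condition` (and
#'   `analyte`, `dilution_factor` when present).
#' @export
stability_or_dilution_assess <- function(qc, rule = standard_rule(),
                                         rule_lloq = lloq_rule()) {
  need <- c("condition", "nominal", "measured")
  if (!is.data.frame(qc) || !all(need %in% names(qc))) {
    stop("`qc` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"analyte" %in% names(qc)) qc$analyte <- "analyte"
  if (!"is_lloq" %in% names(qc)) qc$is_lloq <- FALSE
  groups <- split(qc, list(qc$analyte, qc$condition, qc$nominal), drop = TRUE)
  rows <- lapply(groups, function(g) {
    row <- summarize_qc(g$measured, g$nominal[1], is_lloq = g$is_lloq[1])
    row <- check_acceptance(row, rule = rule, rule_lloq = rule_lloq)
    row$analyte <- g$analyte[1]
    row$condition <- g$condition[1]
    if ("dilution_factor" %in% names(g)) row$dilution_factor <- g$dilution_factor[1]
    row
  })
  tab <- do.call(rbind, rows)
  front <- intersect(c("analyte", "condition"), names(tab))
  tab <- tab[order(tab$analyte, tab$condition, tab$nominal),
             c(front, setdiff(names(tab), front))]
  rownames(tab) <- NULL
  tab
}
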