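# Seeded generators emulating the validation-study designs. All take an
# integer `seed`; when non-NULL the RNG state is set locally so callers'
# streams are untouched.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a calibration run
#'
#' Generates duplicate (or `replicates_per_level`) responses at the
#' eight-level calibrator series of an analyte from the forward model
#' response = intercept + slope x nominal, perturbed by either additive
#' constant-SD noise or proportional constant-CV noise. Proportional noise
#' reproduces the heteroscedastic behaviour of LC-MS/MS area ratios across a
#' 50-fold concentration span, for which the 1/x^2 weighting is expected to
#' win the selection.
#'
#' @param analyte Analyte name or an `analyte_range`.
#' @param slope,intercept Forward-model parameters (response units; default
#'   slope 2e-3 per ng/mL, intercept 0).
#' @param noise_model `"proportional"` (constant CV, default) or
#'   `"additive"` (constant SD).
#' @param noise_param CV% for proportional noise (default 5), SD in response
#'   units for additive.
#' @param replicates_per_level Calibrators per level (default 2, the
#'   duplicate-calibrator design).
#' @param seed Integer seed; `NULL` for the current RNG stream.
#' @return Data.frame of calibration points: `level_label`, `nominal`,
#'   `response`, `replicate`.
#' @export
gen_calibration_run <- function(analyte = "olaparib", slope = 2e-3, intercept = 0,
                                noise_model = c("proportional", "additive"),
                                noise_param = 5, replicates_per_level = 2,
                                seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(noise_param >= 0, replicates_per_level >= 1)
  levels <- calibrator_levels(analyte)
  with_seed(seed, {
    pts <- levels[rep(seq_len(nrow(levels)), each = replicates_per_level), ]
    pts$replicate <- rep(seq_len(replicates_per_level), times = nrow(levels))
    mu <- intercept + slope * pts$nominal
    pts$response <- switch(noise_model,
      proportional = mu * (1 + stats::rnorm(nrow(pts), 0, noise_param / 100)),
      additive = mu + stats::rnorm(nrow(pts), 0, noise_param)
    )
    pts$response <- pmax(pts$response, 0)
    rownames(pts) <- NULL
    pts[, c("level_label", "nominal", "response", "replicate")]
  })
}

#' Simulate a QC replicate set
#'
#' measured = nominal x (1 + bias/100) x (1 + N(0, cv/100)).
#'
#' @param nominal Nominal concentration, ng/mL.
#' @param bias Systematic bias, percent.
#' @param cv Replicate CV, percent.
#' @param n Number of replicates (>= 2).
#' @param seed Integer seed; `NULL` for the current RNG stream.
#' @return Numeric vector of measured concentrations.
#' @export
gen_qc_panel <- function(nominal, bias = 0, cv = 5, n = 5, seed = NULL) {
  stopifnot(nominal > 0, cv >= 0, n >= 2)
  with_seed(seed,
    nominal * (1 + bias / 100) * (1 + stats::rnorm(n, 0, cv / 100))
  )
}

# Trough-concentration summaries (mean, SD in ng/mL) used to parameterize
# the plasma model, and the observed DBS-to-plasma conversion factors.
clinical_defaults <- list(
  olaparib  = list(mean = 1290, sd = 0.76 * 1290, cf = 0.718),
  rucaparib = list(mean = 1754, sd = 805, cf = 1.427),
  niraparib = list(mean = 649, sd = 135, cf = 1.440)
)

lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate paired plasma/DBS clinical samples
#'
#' Per subject, plasma concentrations are drawn from a lognormal
#' distribution moment-matched to the reported steady-state trough mean and
#' SD of the analyte; the DBS concentration is C_DBS = cf_true x C_pla x
#' (1 + N(0, ratio_cv/100)) (multiplicative ratio noise, so the conversion
#' is scale-free); hematocrit is uniform over the validated range, and the
#' Hct-determination age is uniform over 0-14 days.
#'
#' @param analyte Analyte name; sets the default plasma distribution and
#'   `cf_true`.
#' @param n_subjects Number of subjects (default 25).
#' @param samples_per_subject Samples per subject (default 2).
#' @param cf_true True DBS-to-plasma ratio (default: the analyte's observed
#'   conversion factor).
#' @param plasma_mean,plasma_sd Plasma trough mean and SD, ng/mL (defaults:
#'   the analyte's reported values).
#' @param ratio_cv CV% of the multiplicative noise on the DBS/plasma ratio
#'   (default 8).
#' @param hct_range Hct sampling range, percent (default c(29, 45)).
#' @param hct_bias_slope Optional robustness hook: percent bias on C_DBS per
#'   Hct percentage point away from 36% (default 0 — the bridging premise is
#'   that a bare conversion factor suffices without Hct dependence).
#' @param seed Integer seed; `NULL` for the current RNG stream.
#' @return Data.frame of paired samples: `subject_id`, `analyte`, `c_pla`,
#'   `c_dbs`, `hct_pct`, `days_since_hct`, `hours_since_dose`.
#' @export
gen_paired_clinical <- function(analyte = "olaparib", n_subjects = 25,
                                samples_per_subject = 2, cf_true = NULL,
                                plasma_mean = NULL, plasma_sd = NULL,
                                ratio_cv = 8, hct_range = c(29, 45),
                                hct_bias_slope = 0, seed = NULL) {
  analyte <- match.arg(tolower(analyte), names(clinical_defaults))
  def <- clinical_defaults[[analyte]]
  if (is.null(cf_true)) cf_true <- def$cf
  if (is.null(plasma_mean)) plasma_mean <- def$mean
  if (is.null(plasma_sd)) plasma_sd <- def$sd
  stopifnot(cf_true > 0, ratio_cv >= 0, n_subjects >= 1, samples_per_subject >= 1,
            hct_range[1] > 0, hct_range[2] < 100, hct_range[1] <= hct_range[2])
  n <- n_subjects * samples_per_subject
  lp <- lognormal_params(plasma_mean, plasma_sd)
  with_seed(seed, {
    c_pla <- stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
    hct <- stats::runif(n, hct_range[1], hct_range[2])
    c_dbs <- cf_true * c_pla * (1 + stats::rnorm(n, 0, ratio_cv / 100)) *
      (1 + hct_bias_slope / 100 * (hct - 36))
    data.frame(
      subject_id = sprintf("S%03d", rep(seq_len(n_subjects), each = samples_per_subject)),
      analyte = analyte,
      c_pla = c_pla,
      c_dbs = pmax(c_dbs, .Machine$double.eps),
      hct_pct = hct,
      days_since_hct = sample(0:14, n, replace = TRUE),
      hours_since_dose = stats::runif(n, 9, 15)
    )
  })
}

#' Simulate incurred-sample-reanalysis pairs
#'
#' repeat = original x (1 + N(0, cv/100)); originals are lognormal around
#' 1000 ng/mL unless supplied.
#'
#' @param n Number of pairs.
#' @param cv Between-run CV, percent (default 5).
#' @param original Optional vector of original-run concentrations (length n).
#' @param seed Integer seed; `NULL` for the current RNG stream.
#' @return Data.frame with columns `original` and `repeated`, ng/mL.
#' @export
gen_isr_pairs <- function(n, cv = 5, original = NULL, seed = NULL) {
  stopifnot(n >= 1, cv >= 0)
  with_seed(seed, {
    if (is.null(original)) original <- stats::rlnorm(n, log(1000), 0.5)
    stopifnot(length(original) == n)
    data.frame(
      original = original,
      repeated = pmax(original * (1 + stats::rnorm(n, 0, cv / 100)),
                      .Machine$double.eps)
    )
  })
}
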