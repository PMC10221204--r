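#' Analytical ranges for the supported PARP inhibitors
#'
#' Validated calibration ranges and quality-control placements for olaparib,
#' rucaparib and niraparib in both human plasma and dried blood spot (DBS).
#' The QC placements follow the regulatory convention implemented by
#' [derive_qc_levels()]: QC low at 2.55 x LLOQ, QC mid at 0.34 x ULOQ and
#' QC high at 0.85 x ULOQ.
#'
#' @param analyte Analyte name, one of `"olaparib"`, `"rucaparib"`,
#'   `"niraparib"`. Case-insensitive.
#' @return A list of class `analyte_range` with elements `analyte`, `lloq`,
#'   `uloq`, `qc_low`, `qc_mid`, `qc_high` (all concentrations in ng/mL).
#' @examples
#' analyte_range("olaparib")
#' @export
analyte_range <- function(analyte) {
  analyte <- match.arg(tolower(analyte), c("olaparib", "rucaparib", "niraparib"))
  lims <- switch(analyte,
    olaparib  = c(140, 7000),
    rucaparib = c(100, 5000),
    niraparib = c(60, 3000)
  )
  qc <- derive_qc_levels(lims[1], lims[2])
  structure(
    list(
      analyte = analyte, lloq = lims[1], uloq = lims[2],
      qc_low = qc[["qc_low"]], qc_mid = qc[["qc_mid"]], qc_high = qc[["qc_high"]]
    ),
    class = "analyte_range"
  )
}

#' @export
print.analyte_range <- function(x, ...) {
  cat(sprintf(
    "<analyte_range> %s: LLOQ %g - ULOQ %g ng/mL; QC L/M/H = %g/%g/%g ng/mL\n",
    x$analyte, x$lloq, x$uloq, x$qc_low, x$qc_mid, x$qc_high
  ))
  invisible(x)
}

#' Calibrator concentrations for an analyte
#'
#' The eight-level calibrator series spans the validated range with the
#' level multipliers 1, 2, 5, 10, 20, 30, 40 and 50 x LLOQ (level labels
#' H down to A, lowest to highest concentration).
#'
#' @param range An `analyte_range`, or an analyte name passed on to
#'   [analyte_range()].
#' @return A data.frame with columns `level_label` and `nominal` (ng/mL).
#' @examples
#' calibrator_levels("niraparib")
#' @export
calibrator_levels <- function(range) {
  if (is.character(range)) range <- analyte_range(range)
  stopifnot(inherits(range, "analyte_range"))
  mult <- c(1, 2, 5, 10, 20, 30, 40, 50)
  data.frame(
    level_label = rev(LETTERS[1:8]),
    nominal = range$lloq * mult
  )
}

#' Derive quality-control placements from a calibration range
#'
#' Places the three QC levels inside the validated range following the
#' convention used throughout the validation: QC low at `low_mult` x LLOQ
#' (default 2.55), QC mid at `mid_frac` of the ULOQ (default 0.34, the exact
#' placement behind the nominal "about 35% of the range") and QC high at
#' `high_frac` of the ULOQ (default 0.85).
#'
#' @param lloq,uloq Lower/upper limit of quantification, ng/mL.
#' @param low_mult Multiplier on the LLOQ for QC low.
#' @param mid_frac,high_frac Fractions of the ULOQ for QC mid and QC high.
#' @return Named numeric vector with `qc_low`, `qc_mid`, `qc_high` (ng/mL).
#' @examples
#' derive_qc_levels(140, 7000) # 357, 2380, 5950
#' @export
derive_qc_levels <- function(lloq, uloq, low_mult = 2.55, mid_frac = 0.34,
                             high_frac = 0.85) {
  if (!is.numeric(lloq) || !is.numeric(uloq) || length(lloq) != 1L ||
      length(uloq) != 1L || is.na(lloq) || is.na(uloq)) {
    stop("`lloq` and `uloq` must be single non-missing numbers", call. = FALSE)
  }
  if (lloq <= 0 || uloq <= lloq) {
    stop("invalid range: need 0 < lloq < uloq", call. = FALSE)
  }
  c(qc_low = low_mult * lloq, qc_mid = mid_frac * uloq, qc_high = high_frac * uloq)
}
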