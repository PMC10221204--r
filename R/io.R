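# CSV readers for the tabular interchange schemas. Plain utils::read.csv
# with explicit schema validation; errors name the file and the missing
# columns so malformed inputs fail loudly at the boundary.

read_checked_csv <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(label, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    stop(label, " file is empty: ", path, call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(label, " file ", path, " is missing column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read the tabular interchange files
#'
#' Schema-checked readers for the CSV formats consumed by the pipeline:
#'
#' * calibration: `analyte, run_id, level_label, nominal_ng_ml, response`
#' * QC replicates: `analyte, condition, nominal_ng_ml, measured_ng_ml`
#'   (optional `run_id, replicate_id, is_lloq, hct_pct, dilution_factor`)
#' * peak areas: `analyte, technique, donor_id, level, analyte_area, is_area`
#'   (optional `hct_pct`)
#' * paired clinical samples: `subject_id, analyte, c_pla_ng_ml, c_dbs_ng_ml,
#'   hct_pct` (optional `days_since_hct, hours_since_dose`)
#' * ISR: `sample_id, analyte, matrix, original_ng_ml, repeat_ng_ml`
#'
#' Concentration columns are renamed to the internal short names (`nominal`,
#' `measured`, `c_pla`, `c_dbs`, ...) on read.
#'
#' @param path Path to the CSV file.
#' @return A data.frame in the internal column naming.
#' @name read_study_csv
NULL

#' @rdname read_study_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read_checked_csv(
    path, c("analyte", "run_id", "level_label", "nominal_ng_ml", "response"),
    "calibration"
  )
  names(df)[names(df) == "nominal_ng_ml"] <- "nominal"
  validate_calibration_points(df)
}

#' @rdname read_study_csv
#' @export
read_qc_csv <- function(path) {
  df <- read_checked_csv(
    path, c("analyte", "condition", "nominal_ng_ml", "measured_ng_ml"), "QC"
  )
  names(df)[names(df) == "nominal_ng_ml"] <- "nominal"
  names(df)[names(df) == "measured_ng_ml"] <- "measured"
  if (!"is_lloq" %in% names(df)) df$is_lloq <- FALSE
  df$is_lloq <- as.logical(df$is_lloq)
  if (any(df$nominal <= 0) || any(!is.finite(df$measured))) {
    stop("QC file ", path, ": nominal must be positive, measured finite",
      call. = FALSE)
  }
  df
}

#' @rdname read_study_csv
#' @export
read_areas_csv <- function(path) {
  df <- read_checked_csv(
    path, c("analyte", "technique", "donor_id", "level", "analyte_area", "is_area"),
    "areas"
  )
  validate_area_panel(df)
}

#' @rdname read_study_csv
#' @export
read_paired_csv <- function(path) {
  df <- read_checked_csv(
    path, c("subject_id", "analyte", "c_pla_ng_ml", "c_dbs_ng_ml", "hct_pct"),
    "paired-sample"
  )
  names(df)[names(df) == "c_pla_ng_ml"] <- "c_pla"
  names(df)[names(df) == "c_dbs_ng_ml"] <- "c_dbs"
  df
}

#' @rdname read_study_csv
#' @export
read_isr_csv <- function(path) {
  df <- read_checked_csv(
    path, c("sample_id", "analyte", "matrix", "original_ng_ml", "repeat_ng_ml"),
    "ISR"
  )
  names(df)[names(df) == "original_ng_ml"] <- "original"
  names(df)[names(df) == "repeat_ng_ml"] <- "repeated"
  bad <- setdiff(unique(df$matrix), c("plasma", "dbs"))
  if (length(bad)) {
    stop("ISR file ", path, ": unknown matrix value(s): ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a complete synthetic demo study
#'
#' Emits, under one seed, the full set of CSV fixtures the pipeline
#' consumes: a calibration file (three analytes, duplicate calibrators over
#' several runs), a QC file with within-run, between-run, stability,
#' dilution and Hct-effect conditions, a peak-area file for recovery and
#' matrix-factor evaluation, a paired clinical-sample file, and an ISR file.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_runs Calibration runs per analyte (default 3).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_demo_study <- function(dir, seed = 1, n_runs = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  analytes <- c("olaparib", "rucaparib", "niraparib")
  paths <- list(
    calibration = file.path(dir, "calibration.csv"),
    qc = file.path(dir, "qc.csv"),
    areas = file.path(dir, "areas.csv"),
    paired = file.path(dir, "paired.csv"),
    isr = file.path(dir, "isr.csv")
  )

  cal <- do.call(rbind, lapply(seq_along(analytes), function(ai) {
    do.call(rbind, lapply(seq_len(n_runs), function(run) {
      pts <- gen_calibration_run(analytes[ai], noise_param = 3,
        seed = seed + 1000 * ai + run)
      data.frame(
        analyte = analytes[ai], run_id = run, level_label = pts$level_label,
        nominal_ng_ml = pts$nominal, response = pts$response
      )
    }))
  }))
  utils::write.csv(cal, paths$calibration, row.names = FALSE)

  qc_rows <- list()
  for (ai in seq_along(analytes)) {
    rng <- analyte_range(analytes[ai])
    levels <- c(lloq = rng$lloq, qc_low = rng$qc_low, qc_mid = rng$qc_mid,
                qc_high = rng$qc_high)
    k <- 0
    add <- function(condition, nominal, measured, is_lloq, hct = NA, dil = NA) {
      qc_rows[[length(qc_rows) + 1]] <<- data.frame(
        analyte = analytes[ai], condition = condition, nominal_ng_ml = nominal,
        measured_ng_ml = measured, is_lloq = is_lloq, hct_pct = hct,
        dilution_factor = dil
      )
    }
    for (li in seq_along(levels)) {
      nom <- levels[[li]]
      is_lloq <- names(levels)[li] == "lloq"
      k <- k + 1
      add("within-run", nom,
        gen_qc_panel(nom, bias = 0, cv = 4, n = 5, seed = seed + 100 * ai + k),
        is_lloq)
      for (run in 1:3) {
        k <- k + 1
        add("between-run", nom,
          gen_qc_panel(nom, bias = 0, cv = 4, n = 5, seed = seed + 100 * ai + 10 * run + k),
          is_lloq)
      }
      for (hct in c(29, 45)) {
        k <- k + 1
        add(paste0("hct:", hct), nom,
          gen_qc_panel(nom, bias = 5, cv = 4, n = 3, seed = seed + 100 * ai + hct + k),
          is_lloq, hct = hct)
      }
    }
    for (cond in c("stability:rt-5h", "stability:frozen", "stability:freeze-thaw")) {
      for (nom in levels[c("qc_low", "qc_high")]) {
        k <- k + 1
        add(cond, nom,
          gen_qc_panel(nom, bias = -2, cv = 3, n = 3, seed = seed + 100 * ai + k),
          FALSE)
      }
    }
    k <- k + 1
    add("dilution", 1.5 * rng$uloq,
      gen_qc_panel(1.5 * rng$uloq, bias = 3, cv = 3, n = 5, seed = seed + 100 * ai + k),
      FALSE, dil = 5)
  }
  utils::write.csv(do.call(rbind, qc_rows), paths$qc, row.names = FALSE)

  area_rows <- list()
  for (ai in seq_along(analytes)) {
    rng <- analyte_range(analytes[ai])
    for (li in c("qc_low", "qc_high")) {
      nom <- rng[[li]]
      base <- 2e-3 * nom * 1e5
      mk <- function(technique, donor, mult_a, mult_is, seed_off) {
        set.seed(seed + 7 * ai + seed_off)
        data.frame(
          analyte = analytes[ai], technique = technique, donor_id = donor,
          level = li,
          analyte_area = base * mult_a * (1 + stats::rnorm(3, 0, 0.03)),
          is_area = 1e5 * mult_is * (1 + stats::rnorm(3, 0, 0.03))
        )
      }
      for (d in 1:6) {
        area_rows[[length(area_rows) + 1]] <- mk("post", sprintf("D%d", d), 1.0, 1.0, d + li_num(li))
        area_rows[[length(area_rows) + 1]] <- mk("normal", sprintf("D%d", d), 0.95, 0.95, 20 + d + li_num(li))
      }
      area_rows[[length(area_rows) + 1]] <- mk("neat", "solvent", 1.0, 1.0, 40 + li_num(li))
    }
  }
  utils::write.csv(do.call(rbind, area_rows), paths$areas, row.names = FALSE)

  paired <- do.call(rbind, lapply(seq_along(analytes), function(ai) {
    p <- gen_paired_clinical(analytes[ai], seed = seed + 17 * ai)
    data.frame(
      subject_id = paste0(substr(analytes[ai], 1, 3), "-", p$subject_id),
      analyte = p$analyte, c_pla_ng_ml = p$c_pla, c_dbs_ng_ml = p$c_dbs,
      hct_pct = p$hct_pct, days_since_hct = p$days_since_hct,
      hours_since_dose = p$hours_since_dose
    )
  }))
  utils::write.csv(paired, paths$paired, row.names = FALSE)

  isr <- do.call(rbind, lapply(seq_along(analytes), function(ai) {
    do.call(rbind, lapply(c("plasma", "dbs"), function(mx) {
      pairs <- gen_isr_pairs(5, cv = 5, seed = seed + 29 * ai + nchar(mx))
      data.frame(
        sample_id = sprintf("%s-%s-%d", analytes[ai], mx, seq_len(5)),
        analyte = analytes[ai], matrix = mx,
        original_ng_ml = pairs$original, repeat_ng_ml = pairs$repeated
      )
    }))
  }))
  utils::write.csv(isr, paths$isr, row.names = FALSE)

  invisible(paths)
}

li_num <- function(li) if (identical(li, "qc_low")) 0L else 50L
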