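test_that("QC summaries compute mean, CV and accuracy as defined", {
  r <- summarize_qc(rep(100, 5), 100)
  expect_equal(r$mean_conc, 100)
  expect_equal(r$cv, 0)
  expect_equal(r$acc, 100)

  r2 <- summarize_qc(c(90, 100, 110), 100)
  expect_equal(r2$mean_conc, 100)
  expect_equal(r2$cv, 10) # sd = 10 by hand
  expect_equal(r2$acc, 100)

  # doubling the measurements doubles accuracy, leaves CV unchanged
  r3 <- summarize_qc(2 * c(90, 100, 110), 100)
  expect_equal(r3$acc, 200)
  expect_equal(r3$cv, r2$cv)
  # invariant under replicate relabeling
  r4 <- summarize_qc(c(110, 90, 100), 100)
  expect_equal(r4$cv, r2$cv)
  expect_equal(r4$acc, r2$acc)

  expect_error(summarize_qc(100, 100), "insufficient")
})

test_that("acceptance rules apply the correct band per level", {
  lloq_row <- summarize_qc(gen_qc_panel(100, bias = -13, cv = 0.01, n = 5, seed = 1),
    100, is_lloq = TRUE)
  lloq_row$acc <- 87
  lloq_row$cv <- 6
  expect_true(check_acceptance(lloq_row)$pass)

  low_row <- summarize_qc(c(83.9, 84.1), 100)
  expect_equal(low_row$acc, 84)
  expect_false(check_acceptance(low_row)$pass)

  noisy <- summarize_qc(c(90, 100, 110), 100)
  noisy$cv <- 16
  expect_false(check_acceptance(noisy)$pass)
})

test_that("acceptance is monotone in accuracy error and CV", {
  base <- summarize_qc(c(98, 100, 102), 100)
  for (acc in seq(80, 120, by = 2.5)) {
    for (cv in c(0, 10, 15, 16, 25)) {
      row <- base
      row$acc <- acc
      row$cv <- cv
      worse <- row
      worse$acc <- 100 + 1.1 * (acc - 100)
      worse$cv <- cv * 1.1
      p1 <- check_acceptance(row)$pass
      p2 <- check_acceptance(worse)$pass
      expect_false(!p1 && p2) # worsening never flips fail -> pass
    }
  }
})

make_panel <- function(normal_ratio, post_ratio, level = "qc_low", is_area = 1e5) {
  rbind(
    data.frame(technique = "normal", donor_id = "pool", level = level,
      analyte_area = normal_ratio * is_area, is_area = is_area),
    data.frame(technique = "post", donor_id = "pool", level = level,
      analyte_area = post_ratio * is_area, is_area = is_area)
  )
}

test_that("recovery is the normal/post signal ratio with replicate CV", {
  ident <- make_panel(c(1, 1, 1), c(1, 1, 1))
  r <- recovery(ident, "qc_low")
  expect_equal(r$rec, 100)
  expect_equal(r$cv, 0)

  hand <- make_panel(c(0.9, 1.0, 1.1), c(1.0, 1.0, 1.0))
  r2 <- recovery(hand, "qc_low")
  expect_equal(r2$rec, 100)
  expect_equal(r2$cv, 10)

  # DBS-like regime: normal extraction at 56% of the post-extraction signal
  dbs <- make_panel(0.56 * c(1, 1, 1), c(1, 1, 1))
  expect_equal(recovery(dbs, "qc_low")$rec, 56)

  # invariant under uniform rescaling of every area
  scaled <- hand
  scaled$analyte_area <- scaled$analyte_area * 7.3
  scaled$is_area <- scaled$is_area * 7.3
  expect_equal(recovery(scaled, "qc_low")$rec, r2$rec)

  zero <- make_panel(c(1, 1), c(0, 0))
  expect_error(recovery(zero, "qc_low"), "zero post-extraction")
})

donor_panel <- function(mf_analyte, mf_is, neat_a = 5e4, neat_is = 1e5) {
  donors <- sprintf("D%d", seq_along(mf_analyte))
  rbind(
    data.frame(technique = "neat", donor_id = "solvent", level = "qc_low",
      analyte_area = rep(neat_a, 3), is_area = rep(neat_is, 3)),
    data.frame(technique = "post", donor_id = donors, level = "qc_low",
      analyte_area = mf_analyte * neat_a, is_area = mf_is * neat_is)
  )
}

test_that("ISN matrix factor is the ratio of analyte to IS matrix factors", {
  flat <- donor_panel(rep(1, 6), rep(1, 6))
  r <- isn_matrix_factor(flat, "qc_low")
  expect_equal(r$isn_mf, 1)
  expect_equal(r$cv, 0)
  expect_false(r$cv_exceeds)

  shifted <- donor_panel(rep(1.02, 6), rep(1.00, 6))
  expect_equal(isn_matrix_factor(shifted, "qc_low")$isn_mf, 1.02)

  # seven donors, hand-computable ratio of ratios
  mfa <- c(1.05, 0.98, 1.10, 0.95, 1.00, 1.03, 0.99)
  mfi <- c(1.02, 1.00, 1.06, 0.97, 0.98, 1.01, 1.00)
  r7 <- isn_matrix_factor(donor_panel(mfa, mfi), "qc_low")
  expect_equal(r7$isn_mf, mean(mfa / mfi), tolerance = 1e-12)
  expect_equal(r7$n_donors, 7L)

  # a common per-donor multiplicative matrix factor cancels exactly
  f <- c(0.7, 0.9, 1.1, 1.4, 0.8, 1.2)
  cancel <- donor_panel(f, f)
  rc <- isn_matrix_factor(cancel, "qc_low")
  expect_equal(rc$per_donor$isn_mf, rep(1, 6), tolerance = 1e-12)
})

test_that("hematocrit-effect assessment verdicts per cell and overall", {
  qc <- expand.grid(hct_pct = c(29, 45), nominal = c(60, 153, 1020, 2550))
  qc <- qc[rep(seq_len(nrow(qc)), each = 3), ]
  qc$measured <- qc$nominal * 1.08
  qc$is_lloq <- qc$nominal == 60
  res <- hct_effect_assess(qc)
  expect_true(res$pass)
  expect_equal(nrow(res$table), 8L)
  expect_equal(res$table$acc, rep(108, 8))

  qc_bad <- qc
  qc_bad$measured[qc_bad$hct_pct == 29 & qc_bad$nominal == 1020] <- 1020 * 1.151
  res_bad <- hct_effect_assess(qc_bad)
  expect_false(res_bad$pass)
  expect_equal(sum(!res_bad$table$pass), 1L)

  expect_error(hct_effect_assess(qc[qc$nominal != 60 | qc$hct_pct != 45, ]),
    "incomplete design")
})

test_that("interference and sensitivity thresholds are boundary-correct", {
  expect_true(interference_check(0, 1000, "selectivity-analyte")$pass)
  expect_true(interference_check(199, 1000, "selectivity-analyte")$pass)
  expect_false(interference_check(201, 1000, "selectivity-analyte")$pass)
  expect_false(interference_check(60, 1000, "selectivity-IS")$pass)
  expect_false(interference_check(51, 1000, "carryover-IS")$pass)
  expect_error(interference_check(10, 0, "selectivity-analyte"), "positive")

  s <- sensitivity_check(500, 100)
  expect_true(s$response_ratio$pass)
  expect_false(sensitivity_check(499, 100)$response_ratio$pass)
  s2 <- sensitivity_check(500, 100, sn = 4.9)
  expect_false(s2$signal_to_noise$pass)
})

test_that("stability and dilution sets reuse the A&P rule engine", {
  qc <- data.frame(
    condition = rep(c("stability:frozen", "dilution"), each = 3),
    nominal = rep(c(255, 2550), each = 3),
    measured = c(251, 251, 251, 2550, 2550, 2550),
    dilution_factor = rep(c(NA, 5), each = 3)
  )
  tab <- stability_or_dilution_assess(qc)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$pass))
  expect_equal(tab$acc[tab$condition == "stability:frozen"], 100 * 251 / 255)

  qc_fail <- qc
  qc_fail$measured[1:3] <- 255 * 0.84
  expect_false(all(stability_or_dilution_assess(qc_fail)$pass))
})

test_that("synthetic QC panels recover their generating bias and CV", {
  x <- gen_qc_panel(1000, bias = 2, cv = 3, n = 1000, seed = 99)
  row <- summarize_qc(x, 1000)
  se_acc <- 3 / sqrt(1000) # percent scale
  expect_lt(abs(row$acc - 102), 3 * se_acc)
  se_cv <- 3 / sqrt(2 * 999)
  expect_lt(abs(row$cv - 3), 3 * se_cv)

  # -20% bias sits below the standard band; -21% is below even the LLOQ band
  biased <- summarize_qc(gen_qc_panel(100, bias = -20, cv = 1, n = 5, seed = 5), 100)
  expect_false(check_acceptance(biased)$pass)
  very_biased <- summarize_qc(gen_qc_panel(100, bias = -25, cv = 1, n = 5, seed = 5), 100)
  expect_false(check_acceptance(very_biased, is_lloq = TRUE)$pass)
})
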