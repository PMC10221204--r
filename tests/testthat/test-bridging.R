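test_that("eligibility filtering excludes out-of-range and stale Hct", {
  s <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    c_pla = c(100, 200, 300, 400), c_dbs = c(140, 280, 420, 560),
    hct_pct = c(28, 36, 46, 36), days_since_hct = c(1, 3, 2, 20)
  )
  res <- filter_eligible(s)
  expect_equal(res$eligible$subject_id, "b")
  expect_setequal(res$exclusions$reason,
    c("hct-out-of-range", "hct-out-of-range", "hct-determination-too-old"))
  # boundary: the validated range is a closed interval
  s2 <- data.frame(c_pla = 1, c_dbs = 1, hct_pct = c(29, 45))
  expect_equal(nrow(filter_eligible(s2)$eligible), 2L)

  empty <- filter_eligible(s[0, ])
  expect_equal(nrow(empty$eligible), 0L)
  expect_equal(nrow(empty$exclusions), 0L)
})

test_that("conversion factor is the mean DBS/plasma ratio", {
  ident <- data.frame(c_pla = c(100, 250, 900), c_dbs = c(100, 250, 900))
  expect_equal(conversion_factor(ident)$cf, 1)

  two <- data.frame(c_pla = c(100, 100), c_dbs = c(144, 140))
  expect_equal(conversion_factor(two)$cf, 1.42)

  mixed <- data.frame(c_pla = 1:2, c_dbs = 1:2, analyte = c("a", "b"))
  expect_error(conversion_factor(mixed), "mixed analytes")

  # alternative estimators agree on noise-free proportional data
  prop <- data.frame(c_pla = c(100, 500, 2000), c_dbs = 0.718 * c(100, 500, 2000))
  for (m in c("mean", "geometric", "regression")) {
    expect_equal(conversion_factor(prop, method = m)$cf, 0.718, tolerance = 1e-12)
  }

  small <- conversion_factor(data.frame(
    c_pla = rep(100, 10), c_dbs = rep(140, 10),
    subject_id = rep(c("s1", "s2"), 5)
  ))
  expect_false(small$meets_sample_size)
})

test_that("plasma estimation inverts the conversion factor", {
  expect_equal(estimate_plasma(718, 0.718), 1000)
  expect_equal(estimate_plasma(1440, 1.440), 1000)
  one <- data.frame(c_pla = 812, c_dbs = 1170)
  cm <- conversion_factor(one)
  expect_equal(estimate_plasma(one$c_dbs, cm), one$c_pla, tolerance = 1e-12)
  expect_error(estimate_plasma(100, -1), "positive")
})

test_that("Passing-Bablok recovers exact affine relations", {
  pb1 <- passing_bablok(1:5, 1:5)
  expect_equal(pb1$slope, 1)
  expect_equal(pb1$intercept, 0)
  pb2 <- passing_bablok(1:5, 2 * (1:5) + 1)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 1)
  expect_error(passing_bablok(rep(3, 4), 1:4), "identical")
  expect_error(passing_bablok(1:2, 1:2), "at least 3")
})

test_that("Passing-Bablok equals the exhaustive pairwise-median oracle", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(5:30, 1)
    x <- stats::runif(n, 50, 3000)
    if (rep %% 4 == 0) x[2] <- x[1] # duplicate x exercises infinite slopes
    y <- 0.9 * x + 20 + stats::rnorm(n, 0, 40)
    pb <- passing_bablok(x, y)
    or <- pb_oracle(x, y)
    expect_equal(pb$slope, or$slope, tolerance = 1e-12)
    expect_equal(pb$intercept, or$intercept, tolerance = 1e-12)
    expect_true(pb$slope_ci[1] <= pb$slope && pb$slope <= pb$slope_ci[2])
  }
})

test_that("Passing-Bablok is scale-equivariant and swap-invertible", {
  set.seed(303)
  x <- stats::runif(15, 100, 2000)
  y <- 1.3 * x + stats::rnorm(15, 0, 30)
  pb <- passing_bablok(x, y)
  pb_scaled <- passing_bablok(x, 5 * y)
  expect_equal(pb_scaled$slope, 5 * pb$slope, tolerance = 1e-9)
  pb_swap <- passing_bablok(y, x)
  expect_equal(pb_swap$slope, 1 / pb$slope, tolerance = 1e-6)
})

test_that("cusum linearity test separates affine from curved relations", {
  x <- as.numeric(1:12)
  ct_exact <- cusum_linearity_test(x, 3 * x + 2, slope = 3, intercept = 2)
  expect_equal(ct_exact$statistic, 0)
  expect_identical(ct_exact$band, "p > 0.05")

  xq <- as.numeric(1:20)
  pbq <- passing_bablok(xq, xq^2)
  expect_true(pbq$cusum$significant)
  expect_true(pbq$cusum$band %in% c("p <= 0.05", "p <= 0.01"))

  # mirroring residuals about the line leaves the statistic unchanged
  # (balanced fixture: equal counts above and below)
  y <- x + c(0.5, -0.5)
  ct_a <- cusum_linearity_test(x, y, slope = 1, intercept = 0)
  ct_b <- cusum_linearity_test(x, 2 * x - y, slope = 1, intercept = 0)
  expect_equal(ct_a$statistic, ct_b$statistic)

  expect_error(cusum_linearity_test(1:4, 1:4, 1, 0), "n < 5")
})

test_that("Bland-Altman bias, limits and trend test are exact on hand cases", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  expect_true(is.na(ba0$spearman_r))

  x <- c(10, 20, 30)
  ba <- bland_altman(x, x + c(-1, 0, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$bias_ci[2], qt(0.975, 2) / sqrt(3), tolerance = 1e-12)

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(404)
  n <- 1e5
  x <- stats::rnorm(n, 500, 50)
  y <- x + stats::rnorm(n, 3, 20)
  ba <- bland_altman(x, y)
  d <- y - x
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
})

test_that("Lin's CCC matches moment arithmetic and is bounded by Pearson", {
  expect_equal(lins_ccc(1:10, 1:10), 1)
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)

  set.seed(505)
  for (rep in 1:20) {
    x <- stats::rnorm(30, 10, 3)
    y <- 0.8 * x + stats::rnorm(30, 2, 1)
    ccc <- lins_ccc(x, y)
    expect_lte(abs(ccc), abs(stats::cor(x, y)) + 1e-12)
  }
  # equality when means and variances agree: y a permutation-free shift of x
  x <- stats::rnorm(50)
  y <- x * 1.0
  expect_equal(lins_ccc(x, y), stats::cor(x, y))

  expect_error(lins_ccc(c(1, 1), c(1, 1)), "undefined")
})

test_that("percent-difference rule uses the pairwise-mean denominator", {
  ident <- percent_diff_rule(c(100, 200), c(100, 200))
  expect_equal(ident$pct_diff, c(0, 0))
  expect_true(ident$pass)

  r <- percent_diff_rule(120, 100)
  expect_equal(r$pct_diff, 2000 / 110, tolerance = 1e-12) # 18.18%
  expect_true(r$within)

  # swapping the series flips only the sign of each %diff
  a <- c(100, 230, 510)
  b <- c(90, 280, 505)
  expect_equal(percent_diff_rule(a, b)$pct_diff, -percent_diff_rule(b, a)$pct_diff)

  expect_error(percent_diff_rule(1:3, 1:4), "length mismatch")
  expect_error(percent_diff_rule(c(1, -1), c(1, 1)), "positive")
})

test_that("ISR assessment is the %diff rule with repeat-minus-original orientation", {
  same <- isr_assess(c(100, 500), c(100, 500))
  expect_equal(same$pct_diff, c(0, 0))
  expect_true(same$pass)

  one <- isr_assess(100, 114)
  expect_equal(one$pct_diff, 1400 / 107, tolerance = 1e-12) # 13.08%
  expect_true(one$within)

  pairs <- gen_isr_pairs(20, cv = 4, seed = 8)
  res <- isr_assess(pairs$original, pairs$repeated)
  expect_true(all(abs(res$pct_diff) < 14))
  expect_true(res$pass)
})

test_that("agreement report ties the suite together on synthetic pairs", {
  p <- gen_paired_clinical("niraparib", n_subjects = 25, samples_per_subject = 2,
    seed = 606)
  rep <- agreement_report(p)
  expect_s3_class(rep$conversion, "conversion_model")
  expect_true(rep$conversion$meets_sample_size)
  expect_true(rep$pb$slope_ci[1] <= 1 && 1 <= rep$pb$slope_ci[2])
  expect_gt(rep$lins_ccc, 0.8)
  expect_true(rep$ema_fda_pass)
  expect_equal(nrow(rep$data), 50L)
  expect_equal(rep$data$ec_pla, p$c_dbs / rep$conversion$cf)
})
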