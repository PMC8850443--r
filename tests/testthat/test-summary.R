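test_that("distribution summary matches hand computations", {
  s <- distribution_summary(c(1, 2, 3, 4, 100))
  expect_equal(s$mean, 22)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)  # type-7: h = 4*0.25+1 = 2
  expect_equal(s$q3, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 100)
  expect_equal(s$n, 5)

  # symmetric set: zero skewness; excess kurtosis of {-1,0,1} = 1.5 - 3
  sym <- distribution_summary(c(-1, 0, 1))
  expect_equal(sym$skewness, 0)
  expect_equal(sym$kurtosis, 1.5 - 3)
  expect_equal(distribution_summary(c(-1, 0, 1),
                                    kurtosis_convention = "raw")$kurtosis, 1.5)

  # constant set: sd 0, shape statistics undefined
  cst <- distribution_summary(rep(4, 6))
  expect_equal(cst$sd, 0)
  expect_true(is.na(cst$skewness))
  expect_true(is.na(cst$kurtosis))

  expect_error(distribution_summary(numeric(0)), "empty")

  # quantiles invariant under k-fold concatenation
  v <- rnorm(40)
  s1 <- distribution_summary(v)
  s3 <- distribution_summary(rep(v, 3))
  expect_equal(s1[c("q1", "median", "q3")], s3[c("q1", "median", "q3")])
})

test_that("outlier fences match the worked example and degenerate cases", {
  v <- c(0, 1, 2, 3, 4, 100)
  got <- outlier_mask(v, outlier_rule("median"))
  expect_equal(got$fences, c(-1.25, 6.25))
  expect_identical(which(got$mask), 6L)
  expect_equal(got$n_removed, 1)

  # all-equal values: fences collapse to the value, nothing flagged
  eq <- outlier_mask(rep(7, 8))
  expect_equal(eq$n_removed, 0)

  expect_error(outlier_mask(c(1, 2, 3)), "at least 4")
})

test_that("outlier_mask agrees with the brute-force oracle on random sets", {
  set.seed(402)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    v <- round(rnorm(n, sd = sample(c(1, 10), 1)), 2)
    for (anchor in c("median", "quartiles")) {
      got <- outlier_mask(v, outlier_rule(anchor))$mask
      expect_identical(got, outlier_oracle(v, anchor),
                       label = paste("case", i, anchor))
    }
  }
})

test_that("flagged fraction on a normal sample matches the closed form", {
  set.seed(99)
  v <- rnorm(1e5)
  # median rule: fences at median +/- 1.5 IQR; IQR = 2*qnorm(.75) sd
  p_med <- 2 * stats::pnorm(-1.5 * 2 * stats::qnorm(0.75))
  f_med <- outlier_mask(v, outlier_rule("median"))$n_removed / length(v)
  expect_lt(abs(f_med - p_med), 0.005)
  # Tukey rule: fences at q1/q3 -/+ 1.5 IQR = +/- 2.698 sd
  p_tuk <- 2 * stats::pnorm(-(stats::qnorm(0.75) + 1.5 * 2 * stats::qnorm(0.75)))
  f_tuk <- outlier_mask(v, outlier_rule("quartiles"))$n_removed / length(v)
  expect_lt(abs(f_tuk - p_tuk), 0.005)
})

test_that("outlier rule is invariant under affine transforms", {
  set.seed(11)
  v <- rnorm(200, -5, 20)
  for (anchor in c("median", "quartiles")) {
    m0 <- outlier_mask(v, outlier_rule(anchor))$mask
    m1 <- outlier_mask(3.2 * v - 17, outlier_rule(anchor))$mask
    expect_identical(m0, m1)
  }
})

test_that("sensitivity report recomputes shifts by brute force", {
  clean <- c(seq(-5, 5, by = 0.5))
  rep0 <- sensitivity_report(clean)
  expect_equal(rep0$n_removed, 0)
  expect_equal(rep0$delta_mean, 0)
  expect_equal(rep0$delta_median, 0)

  v <- c(clean, 500)
  got <- sensitivity_report(v)
  kept <- v[!outlier_oracle(v, "median")]
  expect_equal(got$n_removed, length(v) - length(kept))
  expect_equal(got$delta_mean, mean(kept) - mean(v))
  expect_equal(got$delta_median, median(kept) - median(v))
  expect_equal(got$pct_removed, 100 * got$n_removed / length(v))
})

test_that("grouped table conserves counts and recovers generated crop ordering", {
  g <- generate_corpus(generator_config(n_records = 4000, seed = 31))
  h <- harmonize_records(g$records)

  tab <- grouped_impact_table(h, "crop", metrics = "YI_2005")
  expect_equal(sum(tab$n), sum(!is.na(h$YI_2005)))

  # single group equals the plain distribution summary
  one <- grouped_impact_table(transform(h, all = "all"), "all",
                              metrics = "YI_2005")
  ref <- distribution_summary(h$YI_2005[!is.na(h$YI_2005)])
  expect_equal(one$median, ref$median)
  expect_equal(one$n, ref$n)

  # per-degree metric drops only flag-undefined records
  pd <- grouped_impact_table(h, "crop", metrics = "per_degree")
  expect_equal(sum(pd$n),
               sum(h$per_degree_defined & !is.na(h$per_degree)))

  # group medians reflect the generated crop effects where the corpus can
  # identify them: maize (largest negative effect) lowest, rice (zero
  # effect) highest, ranks positively associated overall; the
  # soybean/wheat gap (1 pp) is inside soybean's sampling error at a 3%
  # crop share, so no strict full ordering is asserted
  med <- setNames(tab$median, tab$crop)
  eff <- g$truth$crop_effects[names(med)]
  expect_equal(names(which.min(med)), "maize")
  expect_equal(names(which.max(med)), "rice")
  expect_gt(cor(med, eff, method = "spearman"), 0)

  expect_error(grouped_impact_table(h, "not_a_key"), "unknown group key")
  expect_error(grouped_impact_table(h, "crop", metrics = "weird"),
               "unknown metric")
})

test_that("period bins split the century as configured", {
  expect_equal(period_bin(c(2020, 2050, 2069, 2070, 2085)),
               c("NF", "MC", "MC", "EC", "EC"))
})
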