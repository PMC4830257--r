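test_that("APA parser extracts the standard result formats", {
  x <- parse_apa_result("t(85) = 2.86, p = .005")
  expect_equal(nrow(x), 1L)
  expect_equal(x$test_family, "t")
  expect_equal(x$df2, 85)
  expect_equal(x$statistic, 2.86)
  expect_equal(x$p_operator, "eq")
  expect_equal(x$reported_p, 0.005)
  expect_equal(x$p_decimals, 3L)

  expect_equal(nrow(parse_apa_result("no statistics here")), 0L)

  x <- parse_apa_result("F(2, 120) = 3.41, p < .05")
  expect_equal(x$test_family, "F")
  expect_equal(c(x$df1, x$df2), c(2, 120))
  expect_equal(x$statistic, 3.41)
  expect_equal(x$p_operator, "lt")
  expect_equal(x$reported_p, 0.05)
})

test_that("parser handles dialects: chi2 spellings, N, unicode minus, 0.05", {
  x <- parse_apa_result("χ2(4) = 9.49, p = .05")
  expect_equal(x$test_family, "chi2")
  expect_equal(x$df1, 4)
  x <- parse_apa_result("chi2(1, N = 320) = 3.9, p=0.05")
  expect_equal(x$sample_n, 320)
  expect_equal(x$reported_p, 0.05)
  expect_equal(x$p_decimals, 2L)
  x <- parse_apa_result("Z = −2.10, p = .036")
  expect_equal(x$statistic, -2.10)
  x <- parse_apa_result("r(28) = .45, ns")
  expect_equal(x$p_operator, "ns")
  expect_true(is.na(x$reported_p))
  # several results in one sentence come back in order of appearance
  x <- parse_apa_result(
    "Effects held, t(12) = 2.2, p = .04, and F(1, 30) = 5.1, p = .03.")
  expect_equal(x$test_family, c("t", "F"))
})

test_that("recalculated p-values match direct distribution tails", {
  expect_equal(recalculate_p(tr("t", df2 = 85, statistic = 2.86)),
               0.005329363, tolerance = 1e-6)
  expect_equal(round(recalculate_p(tr("t", df2 = 85, statistic = 2.86)), 3),
               0.005)  # rounds to its reported value
  expect_equal(recalculate_p(tr("Z", statistic = 0)), 1)
  expect_equal(recalculate_p(tr("F", df1 = 1, df2 = 46, statistic = 4.0517)),
               0.05, tolerance = 1e-4)
})

test_that("p from r(df) equals p from the equivalent t to 1e-10", {
  for (r in c(0.1, 0.3, 0.62)) {
    for (df in c(10, 45, 200)) {
      t_equiv <- r * sqrt(df) / sqrt(1 - r^2)
      expect_equal(recalculate_p(tr("r", df2 = df, statistic = r)),
                   recalculate_p(tr("t", df2 = df, statistic = t_equiv)),
                   tolerance = 1e-10)
    }
  }
})

test_that("recalculated p decreases in |statistic| for each family", {
  grids <- list(
    tr("t", df2 = 30, statistic = seq(0.1, 5, by = 0.35)),
    tr("F", df1 = 3, df2 = 40, statistic = seq(0.2, 12, by = 0.9)),
    tr("chi2", df1 = 2, statistic = seq(0.2, 15, by = 1.1)),
    tr("Z", statistic = seq(0.1, 4, by = 0.3)),
    tr("r", df2 = 25, statistic = seq(0.05, 0.9, by = 0.08))
  )
  for (g in grids) expect_true(all(diff(recalculate_p(g)) < 0))
})

test_that("recalculation errors on missing df and impossible r", {
  expect_error(recalculate_p(tr("t", statistic = 2)), "incomputable")
  expect_error(recalculate_p(tr("F", df1 = 2, statistic = 3)), "incomputable")
  expect_error(recalculate_p(tr("r", df2 = 30, statistic = 1.2)), "impossible")
  expect_warning(
    out <- recalculate_p(tr("t", statistic = 2), strict = FALSE),
    "incomputable")
  expect_true(is.na(out))
})

test_that("consistency windows follow the reporting precision", {
  # reported .05 but recalculated .0567: outside even the widened window,
  # and significance flips
  x <- tr("t", df2 = 60, statistic = 1.945, p_operator = "eq",
          reported_p = 0.05, p_decimals = 2)
  rp <- recalculate_p(x)
  expect_gt(rp, 0.055)
  v <- consistency_check(x, "wide_05")
  expect_false(v$consistent)
  expect_true(v$gross_inconsistency)
  expect_equal(c(v$window_lo, v$window_hi), c(0.045, 0.055))

  # reported .005 with recalculated .00533 is within half a decimal
  x <- tr("t", df2 = 85, statistic = 2.86, p_operator = "eq",
          reported_p = 0.005, p_decimals = 3)
  v <- consistency_check(x)
  expect_true(v$consistent)
  expect_false(v$gross_inconsistency)

  # "p < .05" with recalculated just above .05 is a gross inconsistency
  x <- tr("t", df2 = 46, statistic = 2.0, p_operator = "lt",
          reported_p = 0.05, p_decimals = 2)
  expect_equal(round(recalculate_p(x), 3), 0.051)
  v <- consistency_check(x)
  expect_false(v$consistent)
  expect_true(v$gross_inconsistency)
})

test_that("impossible results are removed and nothing else", {
  fixture <- dplyr::bind_rows(
    tr("F", df1 = 0, df2 = 55, statistic = 3.1),   # F(0, 55)
    tr("r", df2 = 30, statistic = 1.2),            # r > 1
    tr("t", df2 = 10, statistic = 2.0),
    tr("chi2", df1 = 0, statistic = 5),
    tr("Z", statistic = 1.5),
    tr("r", df2 = 30, statistic = -0.4)
  )
  out <- filter_impossible(fixture)
  expect_equal(nrow(out$removed), 3L)
  expect_equal(out$removed$test_family, c("F", "r", "chi2"))
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(fixture))
  expect_equal(out$kept$statistic, c(2.0, 1.5, -0.4))
})

test_that("analysis subsets apply their membership rules", {
  fixture <- dplyr::bind_rows(
    tr("t", df2 = 40, statistic = 2.1, p_operator = "eq", reported_p = 0.04,
       p_decimals = 2),
    tr("t", df2 = 40, statistic = 2.1, p_operator = "lt", reported_p = 0.05,
       p_decimals = 2),
    tr("t", df2 = 40, statistic = 2.02, p_operator = "eq", reported_p = 0.05,
       p_decimals = 2),
    tr("F", df1 = 2, df2 = 120, statistic = 33.41, p_operator = "eq",
       reported_p = 0.001, p_decimals = 3),
    tr("F", df1 = 1, df2 = 46, statistic = 5.0, p_operator = "eq",
       reported_p = 0.03, p_decimals = 2),
    tr("t", df2 = 40, statistic = 0.5, p_operator = "ns")
  )
  expect_equal(nrow(select_subset(fixture, "all_reported")), 5L)
  # exact p drops inequality and ns records
  expect_equal(nrow(select_subset(fixture, "exact_p")), 4L)
  expect_equal(select_subset(fixture, "reported_eq_05")$reported_p, 0.05)
  expect_equal(nrow(select_subset(fixture, "recalc_exact_stat")), 6L)
  expect_equal(nrow(select_subset(fixture, "recalc_exact_both")), 4L)
  # model pool: t/r/F(1,.) with recalculated p <= .05; F(2,120) excluded
  # no matter how small its p
  pool <- select_subset(fixture, "model_fit_pool")
  expect_false(any(pool$test_family == "F" & pool$df1 != 1))
  expect_true(all(suppressWarnings(recalculate_p(pool, strict = FALSE)) <= 0.05))
  # rows 1 and 2 (same t statistic, p reported differently) and the F(1, .)
  # qualify; t(40) = 2.02 recalculates to just above .05 and drops out
  expect_equal(nrow(pool), 3L)
})

test_that("render/parse round trip is the identity on reported fields", {
  set.seed(4)
  corpus <- generate_corpus(corpus_config(n_articles = 40, seed = 7))
  reparsed <- corpus_roundtrip(corpus)
  expect_equal(nrow(reparsed), nrow(corpus))
  cols <- c("test_family", "df1", "df2", "sample_n", "stat_operator",
            "statistic", "p_operator", "reported_p", "p_decimals")
  expect_equal(as.data.frame(reparsed[cols]), as.data.frame(corpus[cols]))
})

test_that("test-result tables survive a CSV round trip", {
  set.seed(5)
  corpus <- generate_corpus(corpus_config(n_articles = 10, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_test_results(corpus, path)
  back <- read_test_results(path)
  cols <- pexcess:::test_result_columns
  expect_equal(as.data.frame(back[cols]), as.data.frame(corpus[cols]))
})
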