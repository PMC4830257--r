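test_that("Cohen's d converts to the tabulated Fisher-z values", {
  expect_equal(d_to_fisher_z(0), 0)
  expect_equal(round(d_to_fisher_z(0.5), 3), 0.247)
  expect_equal(round(d_to_fisher_z(0.8), 3), 0.390)
  expect_equal(d_to_fisher_z(-0.5), -d_to_fisher_z(0.5))  # odd function
})

test_that("effective normal parameters follow the t-to-r conversion", {
  rec <- effective_normal_params(tr("t", df2 = 46, statistic = 0))
  expect_equal(rec$z, 0)
  expect_equal(rec$sd_z, 1 / sqrt(45))

  rec <- effective_normal_params(tr("r", df2 = 45, statistic = 0.3))
  expect_equal(rec$z, atanh(0.3), tolerance = 1e-10)
  expect_equal(rec$sd_z, 1 / sqrt(44))

  # F(1, 46) = 4 maps exactly like t(46) = 2
  f_rec <- effective_normal_params(tr("F", df1 = 1, df2 = 46, statistic = 4))
  t_rec <- effective_normal_params(tr("t", df2 = 46, statistic = 2))
  expect_equal(f_rec$z, t_rec$z, tolerance = 1e-12)
  expect_equal(f_rec$sd_z, t_rec$sd_z)
  expect_equal(f_rec$p, t_rec$p, tolerance = 1e-12)

  expect_error(effective_normal_params(tr("chi2", df1 = 2, statistic = 5)),
               "unsupported family")
  expect_error(effective_normal_params(tr("F", df1 = 3, df2 = 40, statistic = 2)),
               "unsupported family")
})

test_that("expected bin proportions are uniform under the null and sum to 1", {
  sdz <- rep(1 / sqrt(45), 5)
  for (tail in c("two.sided", "one.sided")) {
    ep <- expected_bin_proportions(fisher_z_model(0, 0), sdz,
                                   c(0, 0.05), 40, tail = tail)
    expect_equal(ep, rep(1 / 40, 40), tolerance = 1e-9)
  }
  for (model in list(fisher_z_model(0.3, 0.1), fisher_z_model(0.05, 0.3))) {
    for (range in list(c(0, 1), c(0, 0.05), c(0, 0.00125))) {
      ep <- expected_bin_proportions(model, c(0.1, 0.15, 0.2), range, 40)
      expect_equal(sum(ep), 1, tolerance = 1e-9)
      expect_true(all(ep >= 0))
    }
  }
})

test_that("closed-form bin proportions match the Monte-Carlo oracle", {
  set.seed(20)
  settings <- list(c(0.3, 0.1), c(0, 0.08), c(0.15, 0), c(0.5, 0.2),
                   c(0.05, 0.15))
  for (s in settings) {
    sdz <- 1 / sqrt(45)
    n <- 4e5
    # generative model: theta ~ N(delta, tau), z ~ N(theta, sd), keep the
    # positive side, compute the two-tailed p and bin it
    z <- rnorm(n, rnorm(n, s[1], s[2]), sdz)
    p <- 2 * pnorm(-z / sdz)
    keep <- z > 0 & p <= 0.05
    h <- pvalue_histogram(p[keep], binwidth = 0.05 / 40)
    obs_prop <- h$count / sum(h$count)
    ep <- expected_bin_proportions(fisher_z_model(s[1], s[2]), sdz,
                                   c(0, 0.05), 40)
    se <- sqrt(ep * (1 - ep) / sum(keep))
    expect_true(all(abs(obs_prop - ep) < 3 * se + 1e-4),
                label = paste("setting", s[1], s[2]))
  }
})

test_that("model parameters are recovered from model-generated data", {
  set.seed(21)
  rec <- model_records(4e5, delta = 0.25, tau = 0, sd_z = 1 / sqrt(45))
  rec <- rec[rec$z > 0 & rec$p <= 0.05, ]
  expect_gt(nrow(rec), 1e5)
  fit <- fit_effect_model(rec[seq_len(1e5), ], fit_range = c(0, 0.05))
  expect_lt(abs(fit$delta - 0.25), 0.01)
  expect_lte(fit$tau, 0.02)
  expect_equal(sum(fit$expected_prop), 1, tolerance = 1e-9)
})

test_that("the delta-tau ridge of the truncated fit is nearly flat", {
  set.seed(22)
  sdz <- 1 / sqrt(45)
  rec <- model_records(3e6, delta = 0, tau = 0.077, sd_z = sdz)
  rec <- rec[rec$z > 0 & rec$p <= 0.00125, ]
  fit <- fit_effect_model(rec, fit_range = c(0, 0.00125))
  # chi-square barely changes along the documented trade-off between a
  # larger mean and a smaller spread
  edges <- seq(0, 0.00125, length.out = 41)
  binw <- 0.00125 / 40
  obs <- tabulate(pmin(pmax(ceiling(rec$p / binw), 1), 40), 40)
  chi2_at <- function(delta, tau) {
    ep <- expected_bin_proportions(fisher_z_model(delta, tau), rec$sd_z,
                                   c(0, 0.00125), 40)
    sum((obs - nrow(rec) * ep)^2 / (nrow(rec) * ep))
  }
  ridge_alt <- if (fit$delta < 0.05) chi2_at(0.1, 0.025) else chi2_at(0, 0.06)
  expect_lt(ridge_alt - fit$chi2, 3 * stats::qchisq(0.99, df = 38))
})

test_that("degenerate pools are flagged", {
  rec <- z_records(z = rep(2, 50), sd_z = rep(0.5, 50))
  expect_warning(fit <- fit_effect_model(rec, fit_range = c(0, 0.05)),
                 "degenerate")
  expect_true(fit$degenerate)
  expect_error(fit_effect_model(rec[0, ]), "empty pool")
})

test_that("excess measures expose a consistent odds ratio", {
  set.seed(23)
  rec <- model_records(6e5, delta = 0.2, tau = 0, sd_z = 1 / sqrt(45))
  rec <- rec[rec$z > 0 & rec$p <= 0.05, ]
  em <- excess_measures(rec)
  expect_equal(em$D,
               ((1 - em$p_obs_below_cut) / em$p_obs_below_cut) /
                 ((1 - em$p_exp_below_cut) / em$p_exp_below_cut),
               tolerance = 1e-12)
  expect_equal(em$effect_drop, em$delta_small - em$delta_all)
  # data straight from the model show no meaningful excess
  expect_lt(abs(em$D - 1), 0.15)
  expect_lt(abs(em$effect_drop), 0.03)
})

test_that("injecting just-significant p-values strictly increases D", {
  set.seed(24)
  sdz <- 1 / sqrt(45)
  rec <- model_records(6e5, delta = 0.2, tau = 0, sd_z = sdz)
  rec <- rec[rec$z > 0 & rec$p <= 0.05, ]
  base <- excess_measures(rec)
  D_prev <- base$D
  for (frac in c(0.1, 0.3)) {
    extra_p <- runif(round(frac * nrow(rec)), 0.00125, 0.05)
    extra <- z_records(z = qnorm(1 - extra_p / 2) * sdz,
                       sd_z = rep(sdz, length(extra_p)))
    em <- excess_measures(dplyr::bind_rows(rec, extra))
    expect_gt(em$D, D_prev)
    D_prev <- em$D
  }
})

test_that("the label-based true excess factor is exact count arithmetic", {
  o <- tibble::tibble(p_final = c(0.0005, 0.01, 0.02, 0.04, 0.2),
                      significant_via_peek = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(true_D_from_labels(o), 3 / 2)
  o$significant_via_peek <- FALSE
  expect_equal(true_D_from_labels(o), 1)
  # counts reported for the heterogeneous peeking condition
  n_int <- 582659; n_peek <- 106241
  o2 <- tibble::tibble(
    p_final = rep(0.01, n_int),
    significant_via_peek = rep(c(TRUE, FALSE), c(n_peek, n_int - n_peek)))
  expect_equal(round(true_D_from_labels(o2), 3), 1.223)
  o$significant_via_peek <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_error(true_D_from_labels(o), "denominator")
})

test_that("expected significant share has the right limits", {
  sdz <- rep(1 / sqrt(45), 20)
  expect_equal(expected_significant_share(fisher_z_model(0, 0), sdz), 0.05,
               tolerance = 1e-9)
  expect_gt(expected_significant_share(fisher_z_model(3, 0), sdz), 0.999)
  set.seed(25)
  # Monte-Carlo check at delta = 0, tau = .183
  n <- 4e5
  z <- rnorm(n, rnorm(n, 0, 0.183), 1 / sqrt(45))
  p <- 2 * pnorm(-abs(z) * sqrt(45))
  share <- expected_significant_share(fisher_z_model(0, 0.183),
                                      rep(1 / sqrt(45), 5))
  expect_lt(abs(mean(p <= 0.05) - share), 3 * sqrt(share * (1 - share) / n))
})
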