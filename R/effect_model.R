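#' Convert Cohen's d to a Fisher-z correlation
#'
#' For an equal-n two-group design, Cohen's d corresponds to a
#' point-biserial correlation r = d / sqrt(d^2 + 4); the Fisher transform
#' atanh(r) puts it on a scale whose sampling variance is approximately
#' 1 / (N - 3), enabling normal-theory modelling. Odd function of d.
#'
#' @param d Standardized mean difference (Cohen's d).
#' @return Fisher-z transformed correlation.
#' @examples
#' d_to_fisher_z(c(0, 0.2, 0.5, 0.8))
#' @export
d_to_fisher_z <- function(d) atanh(d / sqrt(d^2 + 4))

#' Normal effect-size model on the Fisher-z scale
#'
#' True effects (Fisher-transformed correlations) are assumed normally
#' distributed with mean `delta` >= 0 and standard deviation `tau` >= 0;
#' an observed effect with sampling standard deviation `sd_z` is then
#' Normal(delta, sqrt(tau^2 + sd_z^2)), restricted to the positive side
#' because only positive observed effects are modelled.
#'
#' @param delta Mean true effect (Fisher z), nonnegative.
#' @param tau Between-study standard deviation (Fisher z), nonnegative.
#' @return An object of class `fisher_z_model`.
#' @export
fisher_z_model <- function(delta, tau) {
  stopifnot(delta >= 0, tau >= 0)
  structure(list(delta = delta, tau = tau), class = "fisher_z_model")
}

#' @export
print.fisher_z_model <- function(x, ...) {
  cat(sprintf("Fisher-z effect model: delta = %.4g, tau = %.4g\n",
              x$delta, x$tau))
  invisible(x)
}

#' Map a test result to an observed Fisher z and its standard deviation
#'
#' Converts statistics of the model-fit pool (t, r, and F with df1 = 1) to
#' correlations -- r = t / sqrt(t^2 + df) for t-tests, t = sqrt(F) (sign
#' taken positive) for F(1, df2), the statistic itself for r-tests -- and
#' Fisher-transforms them. The effective sample size is N = df + 2 and the
#' sampling standard deviation of z is 1 / sqrt(N - 3).
#'
#' @param results Test-result tibble restricted to families t, r, or
#'   F(1, df2); other families raise an "unsupported family" error.
#' @return A tibble with columns `z` (signed observed Fisher z), `sd_z`,
#'   and `p`. The `p` column is the record's exact recalculated two-tailed
#'   p-value (used for pool membership and binning); the normal
#'   approximation enters only on the model side.
#' @export
effective_normal_params <- function(results) {
  fam <- results$test_family
  if (any(!(fam %in% c("t", "r", "F"))) ||
      any(fam == "F" & (is.na(results$df1) | results$df1 != 1)))
    stop("unsupported family: pool must contain only t, r, and F(df1 = 1) results")
  df <- results$df2
  stat <- results$statistic
  r <- numeric(nrow(results))
  i <- fam == "t"
  r[i] <- stat[i] / sqrt(stat[i]^2 + df[i])
  i <- fam == "F"
  tval <- sqrt(stat[i])
  r[i] <- tval / sqrt(stat[i] + df[i])
  i <- fam == "r"
  r[i] <- stat[i]
  z_records(z = atanh(r), sd_z = 1 / sqrt(df + 2 - 3),
            p = recalculate_p(results))
}

#' @rdname effective_normal_params
#' @param outcomes Simulated study outcomes from [simulate_studies()] or
#'   [simulate_condition()] (columns `t_final`, `df_final`, `p_final`).
#' @export
outcomes_to_zrecords <- function(outcomes) {
  r <- outcomes$t_final / sqrt(outcomes$t_final^2 + outcomes$df_final)
  z_records(z = atanh(r), sd_z = 1 / sqrt(outcomes$df_final - 1),
            p = outcomes$p_final)
}

#' @rdname effective_normal_params
#' @param z,sd_z Observed Fisher-z values and their sampling standard
#'   deviations.
#' @param p Exact two-tailed p-values to use for binning; defaults to the
#'   normal-approximation value `2 * pnorm(-abs(z) / sd_z)`.
#' @export
z_records <- function(z, sd_z, p = NULL) {
  stopifnot(length(z) == length(sd_z), all(sd_z > 0))
  if (is.null(p)) p <- 2 * pnorm(-abs(z) / sd_z)
  tibble::tibble(z = z, sd_z = sd_z, p = p)
}

# collapse sd_z values into unique groups with counts
sd_groups <- function(sd_z) {
  key <- signif(sd_z, 12)
  tab <- table(key)
  list(sd = as.numeric(names(tab)), w = as.numeric(tab))
}

# z thresholds of p cut points: p <= x  <=>  z >= zcut(x); two-tailed p
# maps via qnorm(1 - p/2) (positive side), one-tailed via qnorm(1 - p)
zcut_of_p <- function(p_edges, sd, tail = "two.sided") {
  if (tail == "one.sided") qnorm(1 - p_edges) * sd
  else qnorm(1 - p_edges / 2) * sd
}

# Expected bin proportions over a chi2[tau x delta] evaluation grid.
# Returns list(prop = nb x ndelta matrix per tau index closure, chi2 matrix).
chi2_surface <- function(obs, edges, groups, delta_grid, tau_grid,
                         tail = "two.sided") {
  nb <- length(edges) - 1L
  n_rec <- sum(obs)
  chi2 <- matrix(NA_real_, nrow = length(tau_grid), ncol = length(delta_grid))
  for (ti in seq_along(tau_grid)) {
    tau <- tau_grid[ti]
    num <- matrix(0, nrow = nb + 1L, ncol = length(delta_grid))
    for (j in seq_along(groups$sd)) {
      sdj <- groups$sd[j]
      sigma <- sqrt(tau^2 + sdj^2)
      zc <- zcut_of_p(edges, sdj, tail)
      # upper-tail mass beyond each cut, per delta
      surv <- pnorm((outer(zc, delta_grid, "-")) / sigma, lower.tail = FALSE)
      num <- num + groups$w[j] * surv
    }
    prop <- num[-1L, , drop = FALSE] - num[-(nb + 1L), , drop = FALSE]
    tot <- rep(colSums(prop), each = nb)
    prop <- prop / tot
    e <- n_rec * prop
    chi2[ti, ] <- colSums((obs - e)^2 / pmax(e, 1e-12))
  }
  chi2
}

#' Expected p-value bin proportions under the effect model
#'
#' Closed-form computation (no stochastic integration): for a record with
#' sampling sd `sd_z`, the observed z is Normal(delta, sqrt(tau^2 +
#' sd_z^2)); a two-tailed p bin (p_lo, p_hi] on the positive side maps to
#' z in [zcut(p_hi), zcut(p_lo)) with zcut(p) = qnorm(1 - p/2) * sd_z.
#' Per-record bin probabilities are averaged across records and
#' renormalized to sum to one over the fit range.
#'
#' @param model A [fisher_z_model()] (or list with `delta`, `tau`).
#' @param sd_z Sampling standard deviations of the records.
#' @param fit_range Two-element p range, e.g. `c(0, 0.05)`.
#' @param n_bins Number of equal-width bins (default 40).
#' @param tail `"two.sided"` (default; p bins map to positive z via
#'   `qnorm(1 - p/2)`) or `"one.sided"` (`qnorm(1 - p)`, for p-values
#'   stored as one-tailed, e.g. from the simulator's default design).
#' @return Numeric vector of `n_bins` proportions summing to 1.
#' @examples
#' # under the null the distribution of p conditional on any range is uniform
#' expected_bin_proportions(fisher_z_model(0, 0), rep(1 / sqrt(45), 10))
#' @export
expected_bin_proportions <- function(model, sd_z, fit_range = c(0, 0.05),
                                     n_bins = 40,
                                     tail = c("two.sided", "one.sided")) {
  tail <- match.arg(tail)
  if (length(sd_z) == 0) stop("empty records")
  edges <- seq(fit_range[1], fit_range[2], length.out = n_bins + 1L)
  groups <- sd_groups(sd_z)
  num <- numeric(n_bins + 1L)
  for (j in seq_along(groups$sd)) {
    sigma <- sqrt(model$tau^2 + groups$sd[j]^2)
    zc <- zcut_of_p(edges, groups$sd[j], tail)
    num <- num + groups$w[j] * pnorm((zc - model$delta) / sigma, lower.tail = FALSE)
  }
  prop <- diff(num)
  prop / sum(prop)
}

#' Fit the Fisher-z effect model to truncated significant p-values
#'
#' Estimates `delta` and `tau` by minimizing the Pearson chi-square
#' between observed and expected counts over `n_bins` equal-width bins of
#' the fit range. Only positive observed effects (z > 0) inside the range
#' are used. The optimizer is a deterministic coarse grid (delta in
#' [0, 1.5] step .01, tau in [0, .6] step .005) followed by two tenfold
#' local grid refinements. Because the objective has a near-flat ridge
#' trading delta against tau on truncated fit ranges, all grid points
#' within one chi-square unit of the minimum are treated as ties and
#' resolved toward the smallest tau, taking the best-fitting delta at that
#' tau; the reported misfit is the chi-square at the returned estimate.
#' Bins whose expected count falls below 1e-8 are flagged, not merged.
#'
#' @param records A z-record tibble ([z_records()],
#'   [effective_normal_params()], [outcomes_to_zrecords()]).
#' @param fit_range p range of the fit: typically `c(0, 1)`, `c(0, .05)`,
#'   or `c(0, .00125)`.
#' @param n_bins Number of bins (default 40).
#' @param delta_grid,tau_grid Coarse search grids.
#' @param refine Number of tenfold refinement passes (default 2).
#' @param tail p-to-z mapping; `"two.sided"` (default) restricts the fit
#'   to positive observed effects, `"one.sided"` uses all records (a
#'   one-tailed p already encodes the sign).
#' @return An object of class `effect_fit`: list with `delta`, `tau`,
#'   `chi2` (misfit at the optimum), `observed`, `expected_prop`, `edges`,
#'   `n_records`, `fit_range`, `n_bins`, `flagged_bins`, `degenerate`.
#' @export
fit_effect_model <- function(records, fit_range = c(0, 0.05), n_bins = 40,
                             delta_grid = seq(0, 1.5, by = 0.01),
                             tau_grid = seq(0, 0.6, by = 0.005),
                             refine = 2,
                             tail = c("two.sided", "one.sided")) {
  tail <- match.arg(tail)
  if (nrow(records) == 0) stop("empty pool")
  pos <- if (tail == "two.sided") records$z > 0 else rep(TRUE, nrow(records))
  inr <- records$p > fit_range[1] & records$p <= fit_range[2]
  rec <- records[pos & inr, , drop = FALSE]
  if (nrow(rec) == 0) stop("empty pool: no positive-effect records in range")
  edges <- seq(fit_range[1], fit_range[2], length.out = n_bins + 1L)
  binw <- (fit_range[2] - fit_range[1]) / n_bins
  idx <- pmin(pmax(ceiling((rec$p - fit_range[1]) / binw), 1L), n_bins)
  obs <- tabulate(idx, nbins = n_bins)
  degenerate <- sum(obs > 0) == 1L
  if (degenerate)
    warning("degenerate fit: all in-range records fall in a single bin")
  groups <- sd_groups(rec$sd_z)

  # The chi-square surface has a documented near-flat ridge trading delta
  # against tau; a machine-precision argmin on such a surface is decided by
  # sampling noise. Points within one chi-square unit of the minimum are
  # therefore treated as ties, resolved toward the smallest tau (then the
  # best-fitting delta at that tau), which makes the estimator
  # deterministic in the way the ridge demands.
  gmin <- Inf
  best <- c(delta = NA_real_, tau = NA_real_, chi2 = Inf)
  search <- function(dg, tg) {
    chi2 <- chi2_surface(obs, edges, groups, dg, tg, tail)
    gmin <<- min(gmin, min(chi2))
    row_best <- apply(chi2, 1, which.min)
    row_min <- chi2[cbind(seq_along(tg), row_best)]
    ok <- which(row_min <= gmin + 1)
    ti <- ok[which.min(tg[ok])]
    cand <- c(delta = dg[row_best[ti]], tau = tg[ti], chi2 = row_min[ti])
    if (best[["chi2"]] > gmin + 1 ||
        cand[["tau"]] < best[["tau"]] - 1e-12 ||
        (abs(cand[["tau"]] - best[["tau"]]) < 1e-12 &&
         cand[["chi2"]] < best[["chi2"]])) {
      best <<- cand
    }
  }
  search(delta_grid, tau_grid)
  d_step <- if (length(delta_grid) > 1) diff(delta_grid)[1] else 0.01
  t_step <- if (length(tau_grid) > 1) diff(tau_grid)[1] else 0.005
  for (pass in seq_len(refine)) {
    dg <- unique(pmax(best[["delta"]] + d_step * seq(-1, 1, by = 0.1), 0))
    tg <- unique(pmax(best[["tau"]] + t_step * seq(-1, 1, by = 0.1), 0))
    search(sort(dg), sort(tg))
    d_step <- d_step / 10
    t_step <- t_step / 10
  }
  model <- fisher_z_model(best[["delta"]], best[["tau"]])
  eprop <- expected_bin_proportions(model, rec$sd_z, fit_range, n_bins, tail)
  res <- list(
    delta = best[["delta"]], tau = best[["tau"]], chi2 = best[["chi2"]],
    observed = obs, expected_prop = eprop, edges = edges,
    n_records = nrow(rec), fit_range = fit_range, n_bins = n_bins,
    tail = tail,
    flagged_bins = which(nrow(rec) * eprop < 1e-8),
    degenerate = degenerate
  )
  class(res) <- "effect_fit"
  res
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf(paste0("Fisher-z effect fit on p in (%g, %g], %d bins, ",
                     "%d records\n  delta = %.4g, tau = %.4g, ",
                     "chi-square misfit = %.4g\n"),
              x$fit_range[1], x$fit_range[2], x$n_bins, x$n_records,
              x$delta, x$tau, x$chi2))
  invisible(x)
}

# model mass of {p <= x} (positive side for the two-tailed mapping),
# averaged over records
model_tail_mass <- function(model, sd_z, x, tail = "two.sided") {
  groups <- sd_groups(sd_z)
  sigma <- sqrt(model$tau^2 + groups$sd^2)
  zc <- zcut_of_p(rep(x, length(groups$sd)), groups$sd, tail)
  sum(groups$w * pnorm((zc - model$delta) / sigma, lower.tail = FALSE)) /
    sum(groups$w)
}

#' Excess measures for just-significant p-values
#'
#' Two measures of excess mass in the interval (`cut`, `sig_bound`],
#' computed from the pool of significant records (p <= `sig_bound`):
#' \describe{
#'   \item{effect-size drop}{`delta` estimated from p <= `cut` only, minus
#'     `delta` estimated from the whole significant range. QRPs that pile
#'     up just-significant p-values depress the full-range estimate, so a
#'     large positive drop is suspicious.}
#'   \item{D odds ratio}{the observed odds that a significant p-value lies
#'     in (`cut`, `sig_bound`] divided by the odds expected under the
#'     model fitted to p <= `cut` alone. D > 1 signals excess
#'     just-significant results; D = 1 when observed and expected
#'     proportions agree.}
#' }
#' The observed proportions use all pool records; the model fits use only
#' positive observed effects.
#'
#' @param records z-record tibble (see [fit_effect_model()]).
#' @param cut Small-p cut point (default .00125).
#' @param sig_bound Significance bound defining the pool (default .05).
#' @param n_bins Bins per fit (default 40).
#' @param tail p-to-z mapping passed to the fits (see
#'   [fit_effect_model()]).
#' @return An object of class `excess_measures`: list with `delta_all`,
#'   `delta_small`, `effect_drop`, `D`, `p_obs_below_cut`,
#'   `p_exp_below_cut`, `cut`, `sig_bound`, `n_pool`, and the two fits
#'   (`fit_small`, `fit_all`).
#' @export
excess_measures <- function(records, cut = 0.00125, sig_bound = 0.05,
                            n_bins = 40,
                            tail = c("two.sided", "one.sided")) {
  tail <- match.arg(tail)
  stopifnot(cut < sig_bound)
  pool <- records[records$p <= sig_bound, , drop = FALSE]
  if (nrow(pool) == 0) stop("empty pool")
  o <- sum(pool$p <= cut)
  if (o == 0) stop("cut too small for pool: no observed p-values below cut")
  p_obs <- o / nrow(pool)
  fit_small <- fit_effect_model(pool, fit_range = c(0, cut), n_bins = n_bins,
                                tail = tail)
  fit_all <- fit_effect_model(pool, fit_range = c(0, sig_bound),
                              n_bins = n_bins, tail = tail)
  model <- fisher_z_model(fit_small$delta, fit_small$tau)
  p_exp <- model_tail_mass(model, pool$sd_z, cut, tail) /
    model_tail_mass(model, pool$sd_z, sig_bound, tail)
  D <- ((1 - p_obs) / p_obs) / ((1 - p_exp) / p_exp)
  res <- list(delta_all = fit_all$delta, delta_small = fit_small$delta,
              effect_drop = fit_small$delta - fit_all$delta, D = D,
              p_obs_below_cut = p_obs, p_exp_below_cut = p_exp,
              cut = cut, sig_bound = sig_bound, n_pool = nrow(pool),
              fit_small = fit_small, fit_all = fit_all)
  class(res) <- "excess_measures"
  res
}

#' @export
print.excess_measures <- function(x, ...) {
  cat(sprintf(paste0("Excess measures on %d significant records ",
                     "(p <= %g, cut %g)\n  delta(p<=cut) = %.4g, ",
                     "delta(all) = %.4g, effect drop = %.4g\n",
                     "  D = %.4g  (observed %.4g vs expected %.4g below cut)\n"),
              x$n_pool, x$sig_bound, x$cut, x$delta_small, x$delta_all,
              x$effect_drop, x$D, x$p_obs_below_cut, x$p_exp_below_cut))
  invisible(x)
}

#' True excess factor from peeking labels
#'
#' For simulated studies carrying the `significant_via_peek` label, the
#' factor by which data peeking inflated the count of p-values in
#' (`cut`, `sig_bound`]: total interval count divided by the count not
#' obtained through peeking.
#'
#' @param outcomes Study-outcome tibble with columns `p_final` and
#'   `significant_via_peek`.
#' @inheritParams excess_measures
#' @return A single number >= 1 (1 when no interval p-value was obtained
#'   via peeking).
#' @export
true_D_from_labels <- function(outcomes, cut = 0.00125, sig_bound = 0.05) {
  inside <- outcomes$p_final > cut & outcomes$p_final <= sig_bound
  n_int <- sum(inside)
  n_peek <- sum(inside & outcomes$significant_via_peek)
  if (n_int - n_peek <= 0)
    stop("no interval p-values obtained without peeking: denominator <= 0")
  n_int / (n_int - n_peek)
}

#' Model-implied share of significant results
#'
#' Average over records of the probability that the two-tailed p-value is
#' at or below `alpha` under the effect model (both tails included, no
#' positivity restriction).
#'
#' @param model A [fisher_z_model()].
#' @param sd_z Sampling standard deviations of the records.
#' @param alpha Significance threshold (default .05).
#' @return Probability in (0, 1).
#' @export
expected_significant_share <- function(model, sd_z, alpha = 0.05) {
  if (length(sd_z) == 0) stop("empty records")
  zc <- qnorm(1 - alpha / 2) * sd_z
  sigma <- sqrt(model$tau^2 + sd_z^2)
  mean(pnorm((-zc - model$delta) / sigma) +
         pnorm((zc - model$delta) / sigma, lower.tail = FALSE))
}
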