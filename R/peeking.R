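#' Optional-stopping (data peeking) study design
#'
#' Describes a simulated two-group between-subjects study analysed with a
#' pooled-variance two-sample t-test, optionally with data peeking: if the
#' first test is not significant at `alpha`, a fraction of the original
#' per-group sample size is added and the accumulated data are retested,
#' up to `max_rounds` times. The study's true standardized effect is drawn
#' once as d ~ Normal(`delta`, `tau`) (Cohen's d scale).
#'
#' @param n_per_group Initial observations per group (default 24).
#' @param add_fraction Fraction of the original per-group sample size added
#'   per peeking round (default 1/3, i.e. 8 per group at the default n).
#' @param max_rounds Maximum number of additional sampling rounds
#'   (default 3, so the final sample can reach 2 x n_per_group).
#' @param alpha Significance threshold used at each look (default .05).
#' @param delta Mean of the true-effect distribution on the d scale.
#' @param tau Standard deviation of the true effect across studies
#'   (between-study heterogeneity) on the d scale.
#' @param keep_threshold Studies with final p below this value are the ones
#'   retained by [simulate_condition()] (default .1).
#' @param alternative Sidedness of the stored (and stopped-on) p-value:
#'   `"greater"` (default) stores the one-tailed p in the direction of the
#'   true effect, `"two.sided"` the conventional two-tailed p. The
#'   one-tailed convention is the one under which the simulator reproduces
#'   the reference study's tabulated counts; two-tailed matches how p-values
#'   recalculated from published APA results are treated.
#' @param seed Optional integer seed; a condition's output stream is fully
#'   determined by it.
#' @return An object of class `peeking_design`.
#' @examples
#' peeking_design(delta = 0.5, tau = 0.15, seed = 1)
#' @export
peeking_design <- function(n_per_group = 24, add_fraction = 1 / 3,
                           max_rounds = 3, alpha = 0.05, delta = 0, tau = 0,
                           keep_threshold = 0.1,
                           alternative = c("greater", "two.sided"),
                           seed = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(n_per_group >= 2, add_fraction > 0, max_rounds >= 0,
            alpha > 0, alpha < 1, tau >= 0, keep_threshold > 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 add_fraction = add_fraction,
                 max_rounds = as.integer(max_rounds), alpha = alpha,
                 delta = delta, tau = tau, keep_threshold = keep_threshold,
                 alternative = alternative, seed = seed),
            class = "peeking_design")
}

#' @export
print.peeking_design <- function(x, ...) {
  cat(sprintf(paste0("Peeking design: n_k = %d per group, +%d per round, ",
                     "max %d rounds, alpha = %g\n  d ~ Normal(%g, %g), ",
                     "keep p < %g\n"),
              x$n_per_group, round(x$add_fraction * x$n_per_group),
              x$max_rounds, x$alpha, x$delta, x$tau, x$keep_threshold))
  invisible(x)
}

# pooled two-sample t from per-group (n, mean, centered SS)
t_two_sample <- function(n1, mean1, ss1, n2, mean2, ss2,
                         alternative = "two.sided") {
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- if (alternative == "greater") pt(t, df, lower.tail = FALSE)
       else 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# exact pooling of two batches' sufficient statistics: combined centered SS
# picks up a between-batch term n*m/(n+m) * (mean difference)^2
pool_batch <- function(n, mean, ss, m, mean_b, ss_b) {
  list(n = n + m,
       mean = (n * mean + m * mean_b) / (n + m),
       ss = ss + ss_b + n * m / (n + m) * (mean - mean_b)^2)
}

#' Simulate a single study with optional data peeking
#'
#' Reference implementation operating on raw observations: standard-normal
#' data in two groups of `n_per_group`, the second offset by the study's
#' drawn effect d, tested with a pooled-variance two-sample t-test at each
#' look. If the first look is nonsignificant, `round(add_fraction *
#' n_per_group)` observations per group are appended and the accumulated
#' data retested, until significance or `max_rounds` additions. The
#' vectorized [simulate_condition()] reproduces this process exactly via
#' pooled sufficient statistics; this per-study version retains the raw
#' data and per-look trace and serves as the ground-truth oracle.
#'
#' @param design A [peeking_design()].
#' @param peeking If `FALSE`, only the first look is performed.
#' @return A one-row tibble with `p_final`, `t_final`, `df_final`,
#'   `n_final_per_group`, `rounds_used`, `peeked`, `significant_via_peek`,
#'   `d_drawn`; attribute `"looks"` holds the per-look trace (`n`, `t`,
#'   `p`) and attribute `"raw"` the raw observations per group.
#' @export
simulate_study <- function(design, peeking = TRUE) {
  stopifnot(inherits(design, "peeking_design"))
  d <- rnorm(1, design$delta, design$tau)
  nk <- design$n_per_group
  m_add <- round(design$add_fraction * nk)
  g1 <- rnorm(nk)
  g2 <- rnorm(nk, mean = d)
  max_rounds <- if (peeking) design$max_rounds else 0L
  looks <- list()
  rounds <- 0L
  repeat {
    n <- length(g1)
    tt <- t_two_sample(n, mean(g1), sum((g1 - mean(g1))^2),
                       n, mean(g2), sum((g2 - mean(g2))^2),
                       alternative = design$alternative)
    looks[[length(looks) + 1L]] <- tibble::tibble(n = n, t = tt$t, p = tt$p)
    if (tt$p <= design$alpha || rounds >= max_rounds) break
    g1 <- c(g1, rnorm(m_add))
    g2 <- c(g2, rnorm(m_add, mean = d))
    rounds <- rounds + 1L
  }
  out <- tibble::tibble(
    p_final = tt$p, t_final = tt$t, df_final = tt$df,
    n_final_per_group = length(g1), rounds_used = rounds,
    peeked = rounds > 0L,
    significant_via_peek = tt$p <= design$alpha && rounds > 0L,
    d_drawn = d
  )
  attr(out, "looks") <- dplyr::bind_rows(looks)
  attr(out, "raw") <- list(g1 = g1, g2 = g2)
  out
}

#' Simulate many studies at once
#'
#' Vectorized equivalent of repeated [simulate_study()] calls. Each batch
#' of m new observations per group is represented by its sufficient
#' statistics (mean ~ Normal(mu, 1/m), centered sum of squares ~
#' chi-squared(m - 1)), pooled exactly across looks, so later looks depend
#' on earlier data exactly as with raw-data accumulation.
#'
#' @inheritParams simulate_study
#' @param n_studies Number of studies to simulate.
#' @return A tibble with one row per study and the columns of
#'   [simulate_study()].
#' @export
simulate_studies <- function(n_studies, design, peeking = TRUE) {
  stopifnot(inherits(design, "peeking_design"), n_studies >= 1)
  d <- rnorm(n_studies, design$delta, design$tau)
  max_rounds <- if (peeking) design$max_rounds else 0L
  sim_t_core(rep(design$n_per_group, n_studies), d,
             rep(max_rounds, n_studies), design$add_fraction, design$alpha,
             design$alternative)
}

# vectorized optional-stopping t-test engine; nk, d and the per-study
# peeking allowance may all vary by study
sim_t_core <- function(nk, d, max_rounds, add_fraction, alpha,
                       alternative = "two.sided") {
  n_studies <- length(nk)
  m_add <- pmax(round(add_fraction * nk), 1L)
  n1 <- nk
  mean1 <- rnorm(n_studies, 0, 1 / sqrt(nk))
  mean2 <- rnorm(n_studies, d, 1 / sqrt(nk))
  ss1 <- rchisq(n_studies, nk - 1)
  ss2 <- rchisq(n_studies, nk - 1)
  tt <- t_two_sample(n1, mean1, ss1, n1, mean2, ss2, alternative)
  p <- tt$p
  tstat <- tt$t
  rounds <- integer(n_studies)
  if (any(max_rounds > 0L)) {
    active <- p > alpha & max_rounds > 0L
    for (r in seq_len(max(max_rounds))) {
      idx <- which(active)
      if (length(idx) == 0L) break
      k <- length(idx)
      m <- m_add[idx]
      b1 <- pool_batch(n1[idx], mean1[idx], ss1[idx],
                       m, rnorm(k, 0, 1 / sqrt(m)), rchisq(k, m - 1))
      b2 <- pool_batch(n1[idx], mean2[idx], ss2[idx],
                       m, rnorm(k, d[idx], 1 / sqrt(m)), rchisq(k, m - 1))
      mean1[idx] <- b1$mean; ss1[idx] <- b1$ss
      mean2[idx] <- b2$mean; ss2[idx] <- b2$ss
      n1[idx] <- b1$n
      tt <- t_two_sample(b1$n, b1$mean, b1$ss, b2$n, b2$mean, b2$ss, alternative)
      p[idx] <- tt$p
      tstat[idx] <- tt$t
      rounds[idx] <- r
      active[idx] <- tt$p > alpha & max_rounds[idx] > r
    }
  }
  tibble::tibble(
    p_final = p, t_final = tstat, df_final = 2 * n1 - 2,
    n_final_per_group = n1, rounds_used = rounds, peeked = rounds > 0L,
    significant_via_peek = p <= alpha & rounds > 0L,
    d_drawn = d
  )
}

#' Simulate a condition until enough studies are retained
#'
#' Runs studies (with or without peeking) until `n_keep` outcomes with
#' final p below the design's `keep_threshold` have been collected,
#' mirroring a stopping rule of the form "collect studies until N of them
#' have p < .1".
#'
#' @inheritParams simulate_study
#' @param n_keep Number of retained studies to collect.
#' @param return_all If `TRUE`, also return every simulated outcome
#'   (needed e.g. to examine the full p-value distribution on 0-1).
#' @return A list with `outcomes` (tibble of the first `n_keep` retained
#'   studies), `n_attempted` (total studies simulated), and -- when
#'   `return_all = TRUE` -- `all_outcomes`.
#' @export
simulate_condition <- function(design, n_keep, peeking = TRUE,
                               return_all = FALSE) {
  stopifnot(inherits(design, "peeking_design"), n_keep >= 1)
  if (!is.null(design$seed)) set.seed(design$seed)
  kept <- list()
  all_out <- list()
  n_kept <- 0
  n_attempted <- 0
  rate <- NA_real_
  while (n_kept < n_keep) {
    chunk <- if (is.na(rate)) max(2e4, ceiling(n_keep / 4))
             else ceiling(1.15 * (n_keep - n_kept) / max(rate, 1e-4))
    chunk <- min(chunk, 5e6)
    out <- simulate_studies(chunk, design, peeking = peeking)
    n_attempted <- n_attempted + chunk
    if (return_all) all_out[[length(all_out) + 1L]] <- out
    k <- out[out$p_final < design$keep_threshold, , drop = FALSE]
    kept[[length(kept) + 1L]] <- k
    n_kept <- n_kept + nrow(k)
    rate <- n_kept / n_attempted
  }
  kept <- dplyr::bind_rows(kept)
  res <- list(outcomes = kept[seq_len(n_keep), , drop = FALSE],
              n_attempted = n_attempted)
  if (return_all) res$all_outcomes <- dplyr::bind_rows(all_out)
  res
}

#' Histogram of p-values over half-open bins
#'
#' @param p Numeric vector of p-values.
#' @param binwidth Bin width; must divide the range length to within
#'   rounding.
#' @param range Two-element numeric range (default `c(0, 0.05)`). Bins are
#'   half-open `[lo, hi)`, so a value exactly equal to `range[2]` is out of
#'   range.
#' @return A tibble with `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   number of in-range values.
#' @export
pvalue_histogram <- function(p, binwidth, range = c(0, 0.05)) {
  width <- range[2] - range[1]
  nb <- width / binwidth
  if (abs(nb - round(nb)) > 1e-6)
    stop("binwidth does not divide the range length")
  nb <- as.integer(round(nb))
  p <- p[!is.na(p) & p >= range[1] & p < range[2]]
  idx <- pmin(pmax(floor((p - range[1]) / binwidth) + 1L, 1L), nb)
  edges <- range[1] + binwidth * (0:nb)
  tibble::tibble(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
                 count = tabulate(idx, nbins = nb))
}
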