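#' Configuration for a synthetic literature of APA test results
#'
#' Describes a generated corpus that emulates the statistical structure of
#' a large extracted psychology corpus: a mixture of true effects across
#' articles, several test families, exact versus inexact p-value reporting
#' (with the move from two to three reported decimals in 2010), and two
#' injectable questionable research practices -- data peeking at the
#' generative layer and incorrect rounding of p-values at the reporting
#' layer.
#'
#' @param n_articles Number of articles.
#' @param journals Tibble with columns `journal`, `year_from`, `year_to`;
#'   articles are spread uniformly over journals and years.
#' @param results_per_article Mean number of results per article (the
#'   count is 1 + Poisson(mean - 1)).
#' @param effect_mixture Tibble with columns `weight`, `delta_d`, `tau_d`:
#'   each result's true effect is drawn from a mixture of normals on the
#'   Cohen's d scale. Weights must sum to 1.
#' @param test_family_weights Named numeric vector over
#'   `c("t", "F", "r", "chi2", "Z")`; must sum to 1.
#' @param peeking_rate Probability that a t-machinery result (t, F with
#'   df1 = 1, r) was produced with data peeking (up to 3 rounds adding 1/3
#'   of the original per-group sample).
#' @param incorrect_rounding_rate Probability that a result whose
#'   recalculable p lies in (.05, .055] is reported as "= .05" or "< .05".
#' @param inexact_report_rate Probability that a p-value is reported
#'   inexactly (as an inequality or "ns") rather than as an exact value.
#' @param three_decimal_from_year First year in which exact p-values are
#'   reported to three decimals instead of two (default 2010).
#' @param n_per_group_range Range of per-group sample sizes, drawn
#'   log-uniformly.
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_articles = 200,
                          journals = tibble::tibble(
                            journal = c("JA", "JB", "JC"),
                            year_from = c(1985, 1985, 2003),
                            year_to = c(2013, 2013, 2013)),
                          results_per_article = 15,
                          effect_mixture = tibble::tibble(
                            weight = c(0.4, 0.4, 0.2),
                            delta_d = c(0, 0.4, 0.8),
                            tau_d = c(0, 0.1, 0.1)),
                          test_family_weights = c(t = 0.45, F = 0.30, r = 0.10,
                                                  chi2 = 0.10, Z = 0.05),
                          peeking_rate = 0.10,
                          incorrect_rounding_rate = 0.10,
                          inexact_report_rate = 0.73,
                          three_decimal_from_year = 2010,
                          n_per_group_range = c(10, 200),
                          seed = 1L) {
  stopifnot(abs(sum(effect_mixture$weight) - 1) < 1e-8,
            abs(sum(test_family_weights) - 1) < 1e-8,
            all(names(test_family_weights) == c("t", "F", "r", "chi2", "Z")),
            peeking_rate >= 0, peeking_rate <= 1,
            incorrect_rounding_rate >= 0, incorrect_rounding_rate <= 1,
            inexact_report_rate >= 0, inexact_report_rate <= 1,
            n_articles >= 1, results_per_article >= 1)
  structure(as.list(environment()), class = "corpus_config")
}

#' Generate a synthetic corpus of reported test results
#'
#' Simulates every result's underlying study (two-sample t machinery for
#' t, F(1, .) and r records; noncentral chi-squared/F and normal draws for
#' the remaining families), applies the configured reporting style and
#' QRPs, and returns a test-result table ([parse_apa_result()] schema)
#' with ground-truth side columns `truth_d`, `truth_p`, `truth_peeked`,
#' `truth_rounding_qrp`, `truth_exact_p`. Analysis functions never read
#' the `truth_*` columns; they exist so that detection methods can be
#' scored against a known generating process.
#'
#' Reporting rules: the test statistic is reported to two decimals; exact
#' p-values are rounded to two decimals (three from
#' `three_decimal_from_year` on) and an exact p rounding to zero becomes
#' "< .001" / "< .01"; inexact p-values use the conventional thresholds
#' .001, .01, .05 and nonsignificant results are reported as "> .05" or
#' "ns". The incorrect-rounding QRP reports p "= .05" or "< .05" when the
#' p recalculable from the (rounded) statistic lies in (.05, .055].
#'
#' @param config A [corpus_config()].
#' @return Tibble of test results with truth columns.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n_art <- config$n_articles
  art_journal_i <- sample.int(nrow(config$journals), n_art, replace = TRUE)
  art_year <- with(config$journals[art_journal_i, ],
                   year_from + floor(runif(n_art) * (year_to - year_from + 1)))
  n_res <- 1L + stats::rpois(n_art, max(config$results_per_article - 1, 0))
  art <- rep(seq_len(n_art), n_res)
  n <- length(art)

  fam <- sample(names(config$test_family_weights), n, replace = TRUE,
                prob = config$test_family_weights)
  comp <- sample.int(nrow(config$effect_mixture), n, replace = TRUE,
                     prob = config$effect_mixture$weight)
  d <- rnorm(n, config$effect_mixture$delta_d[comp],
             config$effect_mixture$tau_d[comp])
  lr <- log(config$n_per_group_range)
  nk <- round(exp(runif(n, lr[1], lr[2])))
  peeked <- runif(n) < config$peeking_rate

  # families riding on the two-sample t machinery (peeking applies here)
  t_like <- fam %in% c("t", "r") | fam == "F"
  stat <- numeric(n)
  df1 <- rep(NA_real_, n)
  df2 <- rep(NA_real_, n)
  sample_n <- rep(NA_real_, n)
  rounds <- integer(n)
  if (any(t_like)) {
    i <- which(t_like)
    sim <- sim_t_core(nk[i], d[i], ifelse(peeked[i], 3L, 0L), 1 / 3, 0.05)
    rounds[i] <- sim$rounds_used
    df2[i] <- sim$df_final
    stat[i] <- sim$t_final
    is_f <- fam[i] == "F"
    stat[i][is_f] <- sim$t_final[is_f]^2
    df1[i][is_f] <- 1
    is_r <- fam[i] == "r"
    stat[i][is_r] <- sim$t_final[is_r] /
      sqrt(sim$t_final[is_r]^2 + sim$df_final[is_r])
  }
  peeked <- peeked & t_like & rounds > 0L
  i <- which(fam == "chi2")
  if (length(i) > 0) {
    df1[i] <- sample(1:6, length(i), replace = TRUE)
    stat[i] <- rchisq(length(i), df1[i], ncp = 2 * nk[i] * d[i]^2 / 4)
    with_n <- runif(length(i)) < 0.5
    sample_n[i][with_n] <- 2 * nk[i][with_n]
  }
  i <- which(fam == "Z")
  if (length(i) > 0) stat[i] <- rnorm(length(i), d[i] * sqrt(nk[i] / 2), 1)

  true_p <- recalc_vec(fam, df1, df2, stat)
  stat_rep <- round(stat, 2)
  # correlations reported as 1.00 or 0.00 after rounding would be degenerate
  i <- fam == "r"
  stat_rep[i] <- pmax(pmin(stat_rep[i], 0.99), -0.99)
  recal_p <- recalc_vec(fam, df1, df2, stat_rep)

  year <- art_year[art]
  k_dec <- ifelse(year >= config$three_decimal_from_year, 3L, 2L)
  p_op <- character(n)
  p_rep <- numeric(n)
  p_k <- integer(n)
  exact <- runif(n) >= config$inexact_report_rate

  # reporting layer QRP: incorrect rounding into significance
  qrp <- recal_p > 0.05 & recal_p <= 0.055 &
    runif(n) < config$incorrect_rounding_rate
  q_eq <- qrp & runif(n) < 0.5
  p_op[q_eq] <- "eq"; p_rep[q_eq] <- 0.05; p_k[q_eq] <- 2L
  p_op[qrp & !q_eq] <- "lt"; p_rep[qrp & !q_eq] <- 0.05; p_k[qrp & !q_eq] <- 2L

  # exact reports round the p implied by the reported (rounded) statistic,
  # so an honest record is always internally consistent
  i <- !qrp & exact
  p_rep[i] <- round(recal_p[i], k_dec[i])
  p_op[i] <- "eq"
  p_k[i] <- k_dec[i]
  zero <- i & p_rep == 0
  p_op[zero] <- "lt"
  p_rep[zero] <- 10^(-k_dec[zero])

  i <- which(!qrp & !exact)
  if (length(i) > 0) {
    tp <- recal_p[i]
    op <- rep("gt", length(i))
    pv <- rep(0.05, length(i))
    kk <- rep(2L, length(i))
    op[tp < 0.05] <- "lt"
    pv[tp < 0.01] <- 0.01
    pv[tp < 0.001] <- 0.001
    kk[tp < 0.001] <- 3L
    ns <- tp >= 0.05 & runif(length(i)) < 0.3
    op[ns] <- "ns"
    p_op[i] <- op
    p_rep[i] <- ifelse(op == "ns", NA_real_, pv)
    p_k[i] <- ifelse(op == "ns", NA_integer_, kk)
  }

  tibble::tibble(
    source_id = sprintf("art%05d", art),
    journal = config$journals$journal[art_journal_i[art]],
    year = as.integer(year),
    test_family = fam, df1 = df1, df2 = df2, sample_n = sample_n,
    stat_operator = "eq", statistic = stat_rep,
    p_operator = p_op, reported_p = p_rep, p_decimals = p_k,
    truth_d = d, truth_p = true_p, truth_peeked = peeked,
    truth_rounding_qrp = qrp, truth_exact_p = exact & !qrp
  )
}

# vectorized p recalculation from bare columns (no tibble construction)
recalc_vec <- function(fam, df1, df2, stat) {
  p <- rep(NA_real_, length(fam))
  i <- fam == "t"
  p[i] <- 2 * pt(-abs(stat[i]), df2[i])
  i <- fam == "r"
  p[i] <- 2 * pt(-abs(stat[i] * sqrt(df2[i]) / sqrt(1 - stat[i]^2)), df2[i])
  i <- fam == "F"
  p[i] <- pf(stat[i], df1[i], df2[i], lower.tail = FALSE)
  i <- fam == "chi2"
  p[i] <- pchisq(stat[i], df1[i], lower.tail = FALSE)
  i <- fam == "Z"
  p[i] <- 2 * pnorm(-abs(stat[i]))
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Round-trip a corpus through APA text
#'
#' Renders every record to an APA result string and re-parses the strings;
#' the reported fields of the parse must reproduce the corpus exactly
#' (serialization identity).
#'
#' @param corpus Test-result tibble, e.g. from [generate_corpus()].
#' @return The re-parsed tibble, with provenance columns carried over.
#' @export
corpus_roundtrip <- function(corpus) {
  txt <- render_apa(corpus)
  reparsed <- lapply(seq_along(txt), function(i)
    parse_apa_result(txt[i], source_id = corpus$source_id[i],
                     journal = corpus$journal[i], year = corpus$year[i]))
  reparsed <- dplyr::bind_rows(reparsed)
  if (nrow(reparsed) != nrow(corpus))
    warning("round trip changed the number of records")
  reparsed
}
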