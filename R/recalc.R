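#' Recalculate p-values from reported test statistics
#'
#' Computes the p-value implied by each record's test statistic and degrees
#' of freedom, independently of the reported p. Conventions: two-tailed for
#' `t`, `r` (via the identity t = r * sqrt(df) / sqrt(1 - r^2)) and `Z`;
#' upper tail for `F` and chi-squared. Values are clamped into (0, 1].
#'
#' @param results Test-result tibble (see [parse_apa_result()]).
#' @param strict If `TRUE` (default), a record whose family lacks its
#'   required degrees of freedom raises an "incomputable" error and an `r`
#'   with |r| >= 1 raises an "impossible" error; if `FALSE`, such records
#'   yield `NA` with a warning.
#' @return Numeric vector of recalculated p-values, one per row.
#' @examples
#' x <- parse_apa_result("t(85) = 2.86, p = .005")
#' recalculate_p(x)
#' @export
recalculate_p <- function(results, strict = TRUE) {
  fam <- results$test_family
  stat <- results$statistic
  df1 <- results$df1
  df2 <- results$df2
  need_df2 <- fam %in% c("t", "r")
  need_both <- fam == "F"
  need_df1 <- fam == "chi2"
  bad_df <- (need_df2 & (is.na(df2) | df2 <= 0)) |
    (need_both & (is.na(df1) | is.na(df2) | df1 <= 0 | df2 <= 0)) |
    (need_df1 & (is.na(df1) | df1 <= 0))
  bad_r <- fam == "r" & abs(stat) >= 1
  if (any(bad_df, na.rm = TRUE)) {
    msg <- paste0("incomputable: missing or non-positive degrees of freedom in ",
                  sum(bad_df), " record(s)")
    if (strict) stop(msg) else warning(msg)
  }
  if (any(bad_r, na.rm = TRUE)) {
    msg <- paste0("impossible: |r| >= 1 in ", sum(bad_r), " record(s)")
    if (strict) stop(msg) else warning(msg)
  }
  p <- rep(NA_real_, length(fam))
  ok <- !bad_df & !bad_r & !is.na(stat)
  i <- ok & fam == "t"
  p[i] <- 2 * pt(-abs(stat[i]), df2[i])
  i <- ok & fam == "r"
  tval <- stat[i] * sqrt(df2[i]) / sqrt(1 - stat[i]^2)
  p[i] <- 2 * pt(-abs(tval), df2[i])
  i <- ok & fam == "F"
  p[i] <- pf(stat[i], df1[i], df2[i], lower.tail = FALSE)
  i <- ok & fam == "chi2"
  p[i] <- pchisq(stat[i], df1[i], lower.tail = FALSE)
  i <- ok & fam == "Z"
  p[i] <- 2 * pnorm(-abs(stat[i]))
  ifelse(is.na(p), p, pmin(1, pmax(p, .Machine$double.xmin)))
}

#' Check reported p-values against recalculated ones
#'
#' For exactly reported p-values (`p_operator == "eq"`), the reported value
#' is consistent when the recalculated p lies within half a unit in the last
#' reported decimal, i.e. in `[p - 5*10^-(k-1)/10, p + 5*10^-(k-1)/10)` for
#' k reported decimals (`half_decimal` policy). The `wide_05` policy widens
#' the window for p reported exactly as .05 to the closed interval
#' [.045, .055], the allowance for correct rounding at the significance
#' threshold. Inequality reports are consistent when the recalculated p
#' satisfies them. A gross inconsistency is an inconsistent record whose
#' significance status at alpha = .05 flips between the reported and the
#' recalculated value ("p > x" reports are taken as claims of
#' nonsignificance).
#'
#' @inheritParams recalculate_p
#' @param window_policy `"half_decimal"` or `"wide_05"`.
#' @return A tibble with columns `recalculated_p`, `consistent`,
#'   `gross_inconsistency`, `window_lo`, `window_hi` (windows are `NA` for
#'   inequality reports). Rows reported as `ns` or without a numeric p get
#'   `NA` verdicts.
#' @examples
#' x <- parse_apa_result("t(46) = 2.0, p = .05")
#' consistency_check(x, "wide_05")
#' @export
consistency_check <- function(results, window_policy = c("half_decimal", "wide_05")) {
  window_policy <- match.arg(window_policy)
  rp <- recalculate_p(results)
  reported <- results$reported_p
  pop <- results$p_operator
  k <- results$p_decimals
  k[is.na(k)] <- 2L
  usable <- pop %in% c("eq", "lt", "gt") & !is.na(reported)

  half <- 0.5 * 10^(-k)
  lo <- reported - half
  hi <- reported + half
  closed_hi <- rep(FALSE, length(reported))
  if (window_policy == "wide_05") {
    w <- pop == "eq" & !is.na(reported) & abs(reported - 0.05) < 1e-12
    lo[w] <- 0.045
    hi[w] <- 0.055
    closed_hi[w] <- TRUE
  }
  consistent <- rep(NA, length(reported))
  i <- usable & pop == "eq"
  consistent[i] <- rp[i] >= lo[i] & ifelse(closed_hi[i], rp[i] <= hi[i], rp[i] < hi[i])
  i <- usable & pop == "lt"
  consistent[i] <- rp[i] < reported[i]
  i <- usable & pop == "gt"
  consistent[i] <- rp[i] > reported[i]

  reported_sig <- ifelse(pop == "gt", FALSE, reported <= 0.05)
  gross <- usable & (reported_sig != (rp <= 0.05)) & !consistent
  gross[!usable] <- NA
  is_eq <- usable & pop == "eq"
  tibble::tibble(
    recalculated_p = rp,
    consistent = consistent,
    gross_inconsistency = gross,
    window_lo = ifelse(is_eq, lo, NA_real_),
    window_hi = ifelse(is_eq, hi, NA_real_)
  )
}

#' Remove impossible test results
#'
#' Flags records that cannot correspond to a real test: `F` with any
#' degrees of freedom <= 0 (e.g. F(0, 55)), `t`/`r` with df <= 0,
#' chi-squared with df <= 0, and correlations with |r| > 1. Records with
#' missing df are not flagged (they are incomputable, not impossible).
#'
#' @inheritParams recalculate_p
#' @return A list with elements `kept` and `removed`, both tibbles, input
#'   order preserved; `kept` and `removed` partition the input.
#' @export
filter_impossible <- function(results) {
  fam <- results$test_family
  bad <- rep(FALSE, nrow(results))
  has <- function(x) !is.na(x)
  bad[fam == "F" & ((has(results$df1) & results$df1 <= 0) |
                    (has(results$df2) & results$df2 <= 0))] <- TRUE
  bad[fam %in% c("t", "r") & has(results$df2) & results$df2 <= 0] <- TRUE
  bad[fam == "chi2" & has(results$df1) & results$df1 <= 0] <- TRUE
  bad[fam == "r" & has(results$statistic) & abs(results$statistic) > 1] <- TRUE
  list(kept = results[!bad, , drop = FALSE], removed = results[bad, , drop = FALSE])
}

#' Select an analysis subset of a test-result table
#'
#' The six subsets used throughout the distributional analyses:
#' \describe{
#'   \item{all_reported}{every record with a numeric reported p-value}
#'   \item{exact_p}{exactly reported p-values (`p_operator == "eq"`)}
#'   \item{reported_eq_05}{exact statistics with p reported exactly as .05}
#'   \item{recalc_exact_stat}{records with exactly reported test statistics
#'     (the recalculated-p pool)}
#'   \item{recalc_exact_both}{exact statistics and exact p-values}
#'   \item{model_fit_pool}{records usable by the effect-size model: `t`,
#'     `r`, and `F` with df1 = 1, exactly reported statistic, recalculated
#'     p <= .05}
#' }
#'
#' @inheritParams recalculate_p
#' @param subset One of the subset names above.
#' @return The selected rows, order preserved.
#' @export
select_subset <- function(results,
                          subset = c("all_reported", "exact_p", "reported_eq_05",
                                     "recalc_exact_stat", "recalc_exact_both",
                                     "model_fit_pool")) {
  subset <- match.arg(subset)
  pop <- results$p_operator
  keep <- switch(subset,
    all_reported = pop %in% c("eq", "lt", "gt") & !is.na(results$reported_p),
    exact_p = pop == "eq" & !is.na(results$reported_p),
    reported_eq_05 = results$stat_operator == "eq" & pop == "eq" &
      !is.na(results$reported_p) & abs(results$reported_p - 0.05) < 1e-12,
    recalc_exact_stat = results$stat_operator == "eq",
    recalc_exact_both = results$stat_operator == "eq" & pop == "eq" &
      !is.na(results$reported_p),
    model_fit_pool = {
      fam_ok <- results$test_family %in% c("t", "r") |
        (results$test_family == "F" & !is.na(results$df1) & results$df1 == 1)
      cand <- results$stat_operator == "eq" & fam_ok
      rp <- suppressWarnings(recalculate_p(results, strict = FALSE))
      cand & !is.na(rp) & rp <= 0.05
    }
  )
  keep[is.na(keep)] <- FALSE
  results[keep, , drop = FALSE]
}
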