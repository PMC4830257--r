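#' Caliper test for a bump of p-values just below a threshold
#'
#' Compares the frequency of p-values in two adjacent narrow intervals
#' below `upper` (default .05). Writing x for the count in the interval
#' nearest the threshold and N for the total across both intervals, the
#' proportion Pr = x/N should not exceed .5 for any mixture of true
#' effects, because the density of p must decrease monotonically; Pr > .5
#' therefore signals a bump. The reported one-tailed p-value is the exact
#' binomial tail P(X >= x | N, 1/2) of H0: Pr <= .5 against H1: Pr > .5.
#'
#' Bin placement depends on `mode`. For `"recalculated"` p-values (which
#' carry full precision) the bins are the adjacent half-open intervals
#' `[upper - 2w, upper - w)` and `[upper - w, upper)` for binwidth w. For
#' `"reported"` p-values, which cluster on the two-decimal grid, the lower
#' bin is shifted down to end at the gridpoint one hundredth below the
#' threshold: `(upper - .01 - w, upper - .01]` versus `(upper - w, upper)`,
#' so that a value reported exactly as .04 counts in the lower bin and
#' exactly .05 is excluded (at the default upper = .05).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param binwidth Width of each interval (default .00125).
#' @param upper Upper threshold (default .05); must satisfy
#'   `upper - 2 * binwidth >= 0`.
#' @param mode `"recalculated"` (default) or `"reported"`.
#' @return An object of class `caliper_result`: a list with `x`, `N`,
#'   `Pr`, `p_binomial`, `binwidth`, `upper`, `mode`, and `bins` (2x2
#'   matrix of interval endpoints, lower bin first). When `N == 0` the
#'   result is flagged with `no_test = TRUE` and `Pr`/`p_binomial` are `NA`.
#' @examples
#' # 40 p-values in the lower bin, 60 in the upper one
#' p <- c(runif(40, .0475, .04875), runif(60, .04875, .05))
#' caliper_test(p)
#' @export
caliper_test <- function(p_values, binwidth = 0.00125, upper = 0.05,
                         mode = c("recalculated", "reported")) {
  mode <- match.arg(mode)
  stopifnot(binwidth > 0, upper - 2 * binwidth >= -1e-12)
  p_values <- p_values[!is.na(p_values)]
  if (any(p_values < 0 | p_values > 1)) stop("p_values must lie in [0, 1]")
  if (mode == "recalculated") {
    bins <- rbind(lower = c(upper - 2 * binwidth, upper - binwidth),
                  upper = c(upper - binwidth, upper))
    in_lower <- p_values >= bins[1, 1] & p_values < bins[1, 2]
    in_upper <- p_values >= bins[2, 1] & p_values < bins[2, 2]
  } else {
    bins <- rbind(lower = c(upper - 0.01 - binwidth, upper - 0.01),
                  upper = c(upper - binwidth, upper))
    in_lower <- p_values > bins[1, 1] & p_values <= bins[1, 2]
    in_upper <- p_values > bins[2, 1] & p_values < bins[2, 2]
  }
  x <- sum(in_upper)
  N <- x + sum(in_lower)
  res <- list(
    x = x, N = N,
    Pr = if (N > 0) x / N else NA_real_,
    p_binomial = if (N > 0) pbinom(x - 1, N, 0.5, lower.tail = FALSE) else NA_real_,
    binwidth = binwidth, upper = upper, mode = mode, bins = bins,
    no_test = N == 0
  )
  class(res) <- "caliper_result"
  res
}

#' @export
print.caliper_result <- function(x, ...) {
  cat(sprintf("Caliper test (%s p-values, binwidth %.5g, threshold %.5g)\n",
              x$mode, x$binwidth, x$upper))
  if (x$no_test) {
    cat("  no p-values in either interval: no test\n")
  } else {
    cat(sprintf("  x = %d, N = %d, Pr = %.4g, one-tailed binomial p = %.4g\n",
                x$x, x$N, x$Pr, x$p_binomial))
  }
  invisible(x)
}

#' Caliper test per calendar year
#'
#' @inheritParams caliper_test
#' @param years Integer vector of the same length as `p_values`.
#' @return A tibble with one row per year with at least one p-value in the
#'   compared intervals (years with `N == 0` are omitted), columns `year`,
#'   `x`, `N`, `Pr`, `p_binomial`.
#' @export
caliper_by_year <- function(p_values, years, binwidth = 0.00125, upper = 0.05,
                            mode = c("recalculated", "reported")) {
  mode <- match.arg(mode)
  stopifnot(length(p_values) == length(years))
  keep <- !is.na(years)
  rows <- lapply(sort(unique(years[keep])), function(y) {
    ct <- caliper_test(p_values[keep & years == y], binwidth, upper, mode)
    if (ct$no_test) return(NULL)
    tibble::tibble(year = y, x = ct$x, N = ct$N, Pr = ct$Pr,
                   p_binomial = ct$p_binomial)
  })
  dplyr::bind_rows(rows)
}

#' Linear time trend of the Caliper proportion
#'
#' Fits ordinary least squares of (Pr - .5) on (year - center_year) across
#' yearly Caliper proportions. The intercept estimates the size of the bump
#' (excess over the no-bump value .5) at `center_year`; a positive slope
#' indicates an increasing bump over time. Two-tailed p-values are
#' reported.
#'
#' @param yearly A tibble with columns `year` and `Pr`, e.g. from
#'   [caliper_by_year()]; rows with `NA` Pr are dropped.
#' @param center_year Year at which the intercept is evaluated (typically
#'   the first year of data collection).
#' @return An object of class `trend_fit`: a list with a `coefficients`
#'   tibble (`term`, `estimate`, `se`, `t`, `p`), `center_year`,
#'   `timespan`, `n_years`, `df_residual`, and the underlying `lm` fit.
#' @export
bump_trend <- function(yearly, center_year = min(yearly$year)) {
  yearly <- yearly[!is.na(yearly$Pr), , drop = FALSE]
  if (nrow(yearly) < 3) stop("insufficient years: need >= 3 yearly proportions")
  dat <- data.frame(excess = yearly$Pr - 0.5, time = yearly$year - center_year)
  fit <- lm(excess ~ time, data = dat)
  # summary.lm warns on an exactly collinear/perfect fit; harmless here
  sm <- suppressWarnings(summary(fit)$coefficients)
  res <- list(
    coefficients = tibble::tibble(
      term = c("intercept", "year"),
      estimate = unname(sm[, 1]), se = unname(sm[, 2]),
      t = unname(sm[, 3]), p = unname(sm[, 4])
    ),
    center_year = center_year,
    timespan = range(yearly$year),
    n_years = nrow(yearly),
    df_residual = nrow(yearly) - 2L,
    fit = fit
  )
  class(res) <- "trend_fit"
  res
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Caliper bump trend, %d years (%d-%d), centered at %d\n",
              x$n_years, x$timespan[1], x$timespan[2], x$center_year))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}
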