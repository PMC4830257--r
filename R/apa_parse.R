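#' Parse APA-style test results from free text
#'
#' Scans prose for statistical results reported in APA style -- the test
#' statistic with its degrees of freedom in parentheses, followed by a
#' p-value, e.g. `t(85) = 2.86, p = .005`. Recognised families are
#' `t(df)`, `F(df1, df2)`, `r(df)`, chi-squared as `chi2(df)` /
#' `chi2(df, N = n)` (Greek and ASCII spellings), and `Z` (no df). The
#' p-part may be an exact value (`p = .005`), an inequality (`p < .05`,
#' `p > .10`) or `ns`. Both `.05` and `0.05` decimal dialects and ASCII or
#' Unicode minus signs are accepted. Text without a match yields zero rows;
#' a match whose numeric fields fail to parse is skipped with a warning.
#'
#' @param text Character vector of free-form text (each element is scanned
#'   independently; results are concatenated in order of appearance).
#' @param source_id,journal,year Optional provenance metadata recycled
#'   across the parsed records.
#' @return A tibble with one row per parsed result and columns
#'   `source_id`, `journal`, `year`, `test_family` (`"t"`, `"F"`, `"r"`,
#'   `"chi2"`, `"Z"`), `df1`, `df2`, `sample_n`, `stat_operator`
#'   (`"eq"`, `"lt"`, `"gt"`), `statistic`, `p_operator` (`"eq"`, `"lt"`,
#'   `"gt"`, `"ns"`), `reported_p`, `p_decimals` (number of decimals in the
#'   reported p string).
#' @examples
#' parse_apa_result("We found an effect, t(85) = 2.86, p = .005, as expected.")
#' parse_apa_result("no statistics here")
#' @export
parse_apa_result <- function(text, source_id = NA_character_,
                             journal = NA_character_, year = NA_integer_) {
  stopifnot(is.character(text))
  source_id <- rep_len(as.character(source_id), length(text))
  journal <- rep_len(as.character(journal), length(text))
  year <- rep_len(as.integer(year), length(text))
  out <- vector("list", length(text))
  for (i in seq_along(text)) {
    out[[i]] <- parse_apa_line(text[[i]], source_id[[i]], journal[[i]], year[[i]])
  }
  dplyr::bind_rows(out)
}

# number tokens: df may be fractional (corrected df), stats may be negative
.re_num <- "\\d+(?:\\.\\d+)?"
.re_signed <- "[-−–]?\\s*(?:\\d+\\.?\\d*|\\.\\d+)"
.re_pval <- "(?:\\d?\\.\\d+|[01])"
# ", p = .005" / ", p < .05" / ", ns"
.re_ppart <- paste0(",\\s*(?:(?:p\\s*([=<>])\\s*(", .re_pval, "))|(ns|n\\.s\\.))")
.re_chi <- "(?:(?:χ|[Cc]hi|[Xx])\\s*(?:\\^?2|²)|χ)"

apa_patterns <- function() {
  op <- "\\s*([=<>])\\s*"
  c(
    t = paste0("(?<![A-Za-z0-9])t\\s*\\(\\s*(", .re_num, ")\\s*\\)", op,
               "(", .re_signed, ")", .re_ppart),
    F = paste0("(?<![A-Za-z0-9])F\\s*\\(\\s*(", .re_num, ")\\s*,\\s*(",
               .re_num, ")\\s*\\)", op, "(", .re_signed, ")", .re_ppart),
    r = paste0("(?<![A-Za-z0-9])r\\s*\\(\\s*(", .re_num, ")\\s*\\)", op,
               "(", .re_signed, ")", .re_ppart),
    chi2 = paste0("(?<![A-Za-z0-9])", .re_chi, "\\s*\\(\\s*(", .re_num,
                  ")\\s*(?:,\\s*N\\s*=\\s*(", .re_num, ")\\s*)?\\)", op,
                  "(", .re_signed, ")", .re_ppart),
    Z = paste0("(?<![A-Za-z0-9])[Zz]", op, "(", .re_signed, ")", .re_ppart)
  )
}

parse_apa_line <- function(line, source_id, journal, year) {
  pats <- apa_patterns()
  rows <- list()
  for (fam in names(pats)) {
    m <- gregexpr(pats[[fam]], line, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.vector(m)
    cap <- attr(m, "capture.start")
    cap_len <- attr(m, "capture.length")
    for (j in seq_along(starts)) {
      groups <- vapply(seq_len(ncol(cap)), function(k) {
        if (cap[j, k] > 0) substr(line, cap[j, k], cap[j, k] + cap_len[j, k] - 1L)
        else NA_character_
      }, character(1))
      rec <- build_apa_record(fam, groups, source_id, journal, year)
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- c(rec, list(.pos = starts[j]))
    }
  }
  if (length(rows) == 0L) return(empty_test_results())
  res <- dplyr::bind_rows(rows)
  res <- res[order(res$.pos), , drop = FALSE]
  res$.pos <- NULL
  res
}

# capture-group layout per family:
# t/r:  df, stat_op, stat, p_op, p, ns
# F:    df1, df2, stat_op, stat, p_op, p, ns
# chi2: df, N,  stat_op, stat, p_op, p, ns
# Z:    stat_op, stat, p_op, p, ns
build_apa_record <- function(fam, g, source_id, journal, year) {
  num <- function(x) {
    if (is.na(x)) return(NA_real_)
    suppressWarnings(as.numeric(gsub("[−–]", "-", gsub("\\s", "", x))))
  }
  op_code <- function(x) c("=" = "eq", "<" = "lt", ">" = "gt")[[x]]
  idx <- switch(fam,
    t = , r = list(df1 = NA, df2 = 1, n = NA, sop = 2, stat = 3, pop = 4, p = 5, ns = 6),
    F = list(df1 = 1, df2 = 2, n = NA, sop = 3, stat = 4, pop = 5, p = 6, ns = 7),
    chi2 = list(df1 = 1, df2 = NA, n = 2, sop = 3, stat = 4, pop = 5, p = 6, ns = 7),
    Z = list(df1 = NA, df2 = NA, n = NA, sop = 1, stat = 2, pop = 3, p = 4, ns = 5)
  )
  grab <- function(k) if (is.na(k)) NA_character_ else g[[k]]
  stat <- num(grab(idx$stat))
  df1 <- num(grab(idx$df1)); df2 <- num(grab(idx$df2)); n <- num(grab(idx$n))
  is_ns <- !is.na(grab(idx$ns))
  p_str <- grab(idx$p)
  rp <- if (is_ns) NA_real_ else num(p_str)
  if (is.na(stat) || (!is_ns && is.na(rp))) {
    warning("skipping APA match with malformed numeric field: family ", fam)
    return(NULL)
  }
  p_dec <- if (is_ns || !grepl("\\.", p_str)) NA_integer_
           else nchar(sub("^[^.]*\\.", "", p_str))
  tibble::tibble(
    source_id = source_id, journal = journal, year = year,
    test_family = fam, df1 = df1, df2 = df2, sample_n = n,
    stat_operator = op_code(grab(idx$sop)), statistic = stat,
    p_operator = if (is_ns) "ns" else op_code(grab(idx$pop)),
    reported_p = rp, p_decimals = p_dec
  )
}

empty_test_results <- function() {
  tibble::tibble(
    source_id = character(), journal = character(), year = integer(),
    test_family = character(), df1 = double(), df2 = double(),
    sample_n = double(), stat_operator = character(), statistic = double(),
    p_operator = character(), reported_p = double(), p_decimals = integer()
  )
}

#' Render test results back to APA text
#'
#' Inverse of [parse_apa_result()]: formats each record as an APA result
#' string such that reparsing reproduces all reported fields exactly.
#' Chi-squared results are rendered with the ASCII spelling `chi2`.
#'
#' @param results A test-result tibble (see [parse_apa_result()]).
#' @return Character vector, one APA string per row.
#' @examples
#' x <- parse_apa_result("t(85) = 2.86, p = .005")
#' render_apa(x)
#' @export
render_apa <- function(results) {
  fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  op_sym <- c(eq = "=", lt = "<", gt = ">")
  vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    lhs <- switch(r$test_family,
      t = paste0("t(", fmt_num(r$df2), ")"),
      F = paste0("F(", fmt_num(r$df1), ", ", fmt_num(r$df2), ")"),
      r = paste0("r(", fmt_num(r$df2), ")"),
      chi2 = if (!is.na(r$sample_n))
        paste0("chi2(", fmt_num(r$df1), ", N = ", fmt_num(r$sample_n), ")")
      else paste0("chi2(", fmt_num(r$df1), ")"),
      Z = "Z"
    )
    ppart <- if (r$p_operator == "ns") "ns" else {
      pstr <- if (!is.na(r$p_decimals))
        sub("^0\\.", ".", sprintf("%.*f", r$p_decimals, r$reported_p))
      else fmt_num(r$reported_p)
      paste0("p ", op_sym[[r$p_operator]], " ", pstr)
    }
    paste0(lhs, " ", op_sym[[r$stat_operator]], " ", fmt_num(r$statistic),
           ", ", ppart)
  }, character(1))
}

#' Read or write a test-result table
#'
#' CSV schema: columns `source_id, journal, year, test_family, df1, df2,
#' sample_n, stat_operator, statistic, p_operator, reported_p, p_decimals`;
#' missing values empty; UTF-8. Extra columns (e.g. the `truth_*`
#' ground-truth columns written by [generate_corpus()]) are preserved.
#'
#' @param path File path.
#' @param results Test-result tibble.
#' @return `read_test_results()` returns a tibble; `write_test_results()`
#'   returns `results` invisibly.
#' @export
read_test_results <- function(path) {
  res <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           source_id = readr::col_character(),
                           journal = readr::col_character(),
                           year = readr::col_integer(),
                           test_family = readr::col_character(),
                           df1 = readr::col_double(),
                           df2 = readr::col_double(),
                           sample_n = readr::col_double(),
                           stat_operator = readr::col_character(),
                           statistic = readr::col_double(),
                           p_operator = readr::col_character(),
                           reported_p = readr::col_double(),
                           p_decimals = readr::col_integer(),
                           .default = readr::col_guess()
                         ))
  missing <- setdiff(test_result_columns, names(res))
  if (length(missing) > 0)
    stop("test-result table is missing columns: ", paste(missing, collapse = ", "))
  res
}

#' @rdname read_test_results
#' @export
write_test_results <- function(results, path) {
  readr::write_csv(results, path, na = "")
  invisible(results)
}
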