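#' Run the full p-value forensics pipeline
#'
#' Orchestrates an end-to-end run: load (or synthesize) a test-result
#' table, drop impossible records, then for each requested subset compute
#' Caliper tables per binwidth (overall and per journal), yearly bump
#' trends, and -- on the model-fit pool -- the effect-model fit and excess
#' measures. Outputs are plain tibbles/lists; when `out_dir` is given they
#' are written as CSV/JSON together with a copy of the manifest, and reruns
#' with the same manifest are byte-identical.
#'
#' @param manifest A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{input}{path to a test-result CSV, or `NULL` to synthesize}
#'     \item{corpus}{list of [corpus_config()] arguments, used when
#'       `input` is `NULL`}
#'     \item{subsets}{subset names for the Caliper analyses (default
#'       `c("exact_p", "recalc_exact_stat")`)}
#'     \item{binwidths}{Caliper binwidths (default .00125, .0025, .005,
#'       .01)}
#'     \item{cut, sig_bound}{excess-measure cut points (defaults .00125,
#'       .05)}
#'     \item{seed}{integer seed for the synthetic branch}
#'   }
#' @param out_dir Optional output directory.
#' @return A list with `corpus`, `caliper` (tibble), `trend` (tibble),
#'   `measures` (list), and `histogram` (tibble), invisibly written to
#'   `out_dir` when requested.
#' @export
run_pipeline <- function(manifest, out_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  defaults <- list(input = NULL, corpus = list(),
                   subsets = c("exact_p", "recalc_exact_stat"),
                   binwidths = c(0.00125, 0.0025, 0.005, 0.01),
                   cut = 0.00125, sig_bound = 0.05, seed = 1L)
  manifest <- utils::modifyList(defaults, manifest)

  corpus <- if (!is.null(manifest$input)) {
    read_test_results(manifest$input)
  } else {
    cfg <- do.call(corpus_config, c(manifest$corpus,
                                    if (is.null(manifest$corpus$seed))
                                      list(seed = manifest$seed)))
    generate_corpus(cfg)
  }
  corpus <- filter_impossible(corpus)$kept

  reported_subsets <- c("all_reported", "exact_p", "reported_eq_05")
  caliper_rows <- list()
  trend_rows <- list()
  for (ss in manifest$subsets) {
    sub <- select_subset(corpus, ss)
    mode <- if (ss %in% reported_subsets) "reported" else "recalculated"
    pvals <- if (mode == "reported") sub$reported_p
             else suppressWarnings(recalculate_p(sub, strict = FALSE))
    for (bw in manifest$binwidths) {
      for (jj in c("All", sort(unique(sub$journal)))) {
        sel <- if (jj == "All") rep(TRUE, nrow(sub)) else sub$journal == jj
        ct <- caliper_test(pvals[sel], binwidth = bw, mode = mode)
        caliper_rows[[length(caliper_rows) + 1L]] <- tibble::tibble(
          subset = ss, journal = jj, binwidth = bw, mode = mode,
          x = ct$x, N = ct$N, Pr = ct$Pr, p_binomial = ct$p_binomial,
          significant = !ct$no_test && ct$p_binomial <= 0.05,
          no_test = ct$no_test
        )
      }
    }
    yearly <- caliper_by_year(pvals, sub$year, binwidth = manifest$binwidths[1],
                              mode = mode)
    if (nrow(yearly) >= 3) {
      tr <- bump_trend(yearly, center_year = min(yearly$year))
      trend_rows[[length(trend_rows) + 1L]] <- dplyr::mutate(
        tr$coefficients, subset = ss, center_year = tr$center_year,
        significant = .data$p <= 0.05, .before = 1)
    }
  }

  pool <- select_subset(corpus, "model_fit_pool")
  measures <- if (nrow(pool) >= 2) {
    rec <- effective_normal_params(pool)
    em <- tryCatch(excess_measures(rec, cut = manifest$cut,
                                   sig_bound = manifest$sig_bound),
                   error = function(e) NULL)
    if (is.null(em)) list(no_test = TRUE) else list(
      delta_all = em$delta_all, delta_small = em$delta_small,
      effect_drop = em$effect_drop, D = em$D,
      p_obs_below_cut = em$p_obs_below_cut,
      p_exp_below_cut = em$p_exp_below_cut,
      chi2_small = em$fit_small$chi2, chi2_all = em$fit_all$chi2,
      tau_all = em$fit_all$tau, tau_small = em$fit_small$tau,
      n_pool = em$n_pool, cut = manifest$cut, sig_bound = manifest$sig_bound
    )
  } else list(no_test = TRUE)

  rp <- suppressWarnings(recalculate_p(corpus, strict = FALSE))
  hist <- pvalue_histogram(rp[!is.na(rp)], binwidth = manifest$binwidths[1])

  res <- list(corpus = corpus, caliper = dplyr::bind_rows(caliper_rows),
              trend = dplyr::bind_rows(trend_rows), measures = measures,
              histogram = hist, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res$caliper, file.path(out_dir, "caliper.csv"), na = "")
    readr::write_csv(res$trend, file.path(out_dir, "trend.csv"), na = "")
    readr::write_csv(res$histogram, file.path(out_dir, "histogram.csv"), na = "")
    write_test_results(corpus, file.path(out_dir, "corpus.csv"))
    jsonlite::write_json(res$measures, file.path(out_dir, "measures.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}
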