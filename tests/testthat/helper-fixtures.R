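# shared fixture builders; everything is generated in code

# one test-result row with sensible defaults
tr <- function(test_family = "t", df1 = NA_real_, df2 = NA_real_,
               sample_n = NA_real_, statistic = 0, stat_operator = "eq",
               p_operator = "eq", reported_p = NA_real_,
               p_decimals = NA_integer_, journal = "J", year = 2000L,
               source_id = "s1") {
  tibble::tibble(
    source_id = source_id, journal = journal, year = as.integer(year),
    test_family = test_family, df1 = df1, df2 = df2, sample_n = sample_n,
    stat_operator = stat_operator, statistic = statistic,
    p_operator = p_operator, reported_p = reported_p,
    p_decimals = as.integer(p_decimals)
  )
}

# records drawn from the Fisher-z effect model itself (the generative
# oracle): theta ~ N(delta, tau), z | theta ~ N(theta, sd_z)
model_records <- function(n, delta, tau, sd_z) {
  z <- rnorm(n, rnorm(n, delta, tau), sd_z)
  z_records(z = z, sd_z = rep(sd_z, n))
}
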