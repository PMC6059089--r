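# shared fixture builders; everything is generated in code at test time

# minimal well-formed cohort CSV; `rows` is a list of named overrides applied
# to the template row, one list element per output row
write_cohort_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  template <- list(
    id = NA_character_, state = "il", site = "kickapoo", season = "spring",
    sex = "female", age_class = "adult", mass_g = "420", activity = "bright",
    pcv_pct = "25", ta_c = "20", health_flags = "",
    ph_i = "7.35", po2_i = "48", pco2_i = "41", hco3_i = "23", tco2_i = "24",
    be_i = "1.5", lactate_i = "2.1"
  )
  tab <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- template
    r$id <- sprintf("X%02d", i)
    r[names(rows[[i]])] <- rows[[i]]
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  path
}

# random but physiologic corrected panels for round-trip checks
random_corrected_panels <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    ph_c = runif(n, 6.9, 7.9),
    po2_c = runif(n, 5, 120),
    pco2_c = runif(n, 5, 80),
    be = runif(n, -15, 15),
    lactate = runif(n, 0.1, 15),
    ta_c = runif(n, 5, 40)
  ))
}

# independent OLS oracle: solve the normal equations directly
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# independent AICc oracle from first principles
aicc_oracle <- function(rss, n, k) {
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  -2 * loglik + 2 * k + (2 * k * (k + 1)) / (n - k - 1)
}
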