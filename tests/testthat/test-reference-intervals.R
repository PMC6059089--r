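test_that("Horn screen leaves regular samples intact", {
  scr <- horn_outliers(1:10)
  expect_length(scr$outliers, 0)
  expect_equal(scr$retained, 1:10)
  expect_false(any(scr$is_outlier))
  # constant vector: fences collapse onto the constant, nothing flagged
  const <- horn_outliers(rep(5, 8))
  expect_length(const$outliers, 0)
  # fewer than 3 values: warn and retain
  expect_warning(tiny <- horn_outliers(c(1, 2)), "fewer than 3")
  expect_equal(tiny$retained, c(1, 2))
})

test_that("Horn screen flags gross outliers and spares clean samples", {
  # an 8-SD point is always flagged (simulation over seeded replicates)
  set.seed(421)
  hit <- replicate(50, {
    x <- c(rnorm(100), 8)
    tail(horn_outliers(x)$is_outlier, 1)
  })
  expect_equal(mean(hit), 1)
  # negative-valued data (base excess) go through the positivity shift
  set.seed(422)
  be <- c(rnorm(50, 0, 5), 60)
  scr <- horn_outliers(be)
  expect_true(scr$is_outlier[51])
  # sparing on clean Gaussian samples of n >= 40: a small overall flag rate
  # and no more than 10% flagged in the vast majority of samples
  set.seed(423)
  rates <- replicate(200, mean(horn_outliers(rnorm(60))$is_outlier))
  expect_lt(mean(rates), 0.05)
  expect_lte(quantile(rates, 0.95, names = FALSE), 0.10)
})

test_that("distribution label follows Shapiro-Wilk with KS reported alongside", {
  set.seed(31)
  norm <- assess_distribution(rnorm(200))
  expect_equal(norm$distribution, "gaussian")
  expect_true(all(!is.na(c(norm$sw_stat, norm$sw_p, norm$ks_stat, norm$ks_p))))
  expon <- assess_distribution(rexp(500))
  expect_equal(expon$distribution, "non_gaussian")
  expect_warning(small <- assess_distribution(rnorm(5)), "fewer than 8")
  expect_true(is.na(small$distribution))
})

test_that("nonparametric interval uses the p(n+1) rank index with clamping", {
  expect_equal(unname(nonparametric_ri(1:40)), c(1.025, 39.975))
  expect_equal(unname(nonparametric_ri(rep(3, 25))), c(3, 3))
  # at n = 39 the lower rank index hits 1: bound equals the observed minimum
  set.seed(5)
  x <- rnorm(39)
  expect_equal(unname(nonparametric_ri(x))[1], min(x))
  expect_warning(out <- nonparametric_ri(1:10), "min_n")
  expect_true(all(is.na(out)))
  # estimator consistency at n = 10000 against known quantile functions;
  # the uniform has unit tail density, so the sampling error of its extreme
  # quantiles is well inside the 0.02 tolerance
  set.seed(6)
  big <- runif(10000)
  ri <- nonparametric_ri(big)
  expect_lt(abs(ri[[1]] - 0.025), 0.02)
  expect_lt(abs(ri[[2]] - 0.975), 0.02)
})

test_that("bootstrap bound CI is seeded, reproducible and degenerate-safe", {
  set.seed(77)
  x <- rnorm(60)
  ci1 <- bootstrap_bound_ci(x, "lower", reps = 500, seed = 9)
  ci2 <- bootstrap_bound_ci(x, "lower", reps = 500, seed = 9)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_bound_ci(x, "lower", reps = 500, seed = 10)
  expect_false(identical(ci1, ci3))
  expect_true(ci1[["low"]] <= ci1[["high"]])
  # degenerate data give a degenerate CI
  expect_equal(unname(bootstrap_bound_ci(rep(2, 30), "upper", reps = 200,
                                         seed = 1)), c(2, 2))
  # the bound CI for the upper bound sits in the upper tail region
  ciu <- bootstrap_bound_ci(x, "upper", reps = 500, seed = 9)
  expect_gt(ciu[["low"]], median(x))
})

test_that("WCI/WRI ratio matches hand division on published-style inputs", {
  expect_equal(wci_wri(c(22.6, 41.8), c(41.8, 47.1)), 5.3 / 19.2,
               tolerance = 1e-12)
  expect_equal(wci_wri(c(24, 43), c(43, 48)), 5 / 19, tolerance = 1e-12)
  expect_identical(wci_wri(c(10, 20), c(15, 15)), 0)
  expect_warning(r <- wci_wri(c(5, 5), c(4, 6)), "zero-width")
  expect_true(is.nan(r))
  expect_error(wci_wri(c(20, 10), c(1, 2)), "out of order")
})

# drop auxiliary attributes so table comparisons see only the rows
ri_rows <- function(x) {
  d <- as.data.frame(x)
  attr(d, "exclusions") <- NULL
  attr(d, "settings") <- NULL
  d
}

make_ri_cohort <- function(seed = 88, n_fall = 17) {
  withr::with_seed(seed, {
    n <- c(spring = 38, summer = 41, fall = n_fall)
    season <- rep(names(n), times = n)
    m <- length(season)
    tibble::tibble(
      id = sprintf("r%03d", seq_len(m)),
      season = season,
      ph_c = rnorm(m, c(spring = 7.49, summer = 7.36, fall = 7.59)[season], 0.15),
      po2_c = rnorm(m, 57, 18),
      pco2_c = rnorm(m, c(spring = 33, summer = 44, fall = 25)[season], 10),
      hco3_c = rnorm(m, 29, 4.5),
      tco2_c = rnorm(m, 31, 4.5),
      lactate = pmax(rnorm(m, 5.5, 2.5), 0.1),
      be = rnorm(m, 1, 5))
  })
}

test_that("partitions below the minimum n report statistics but no interval", {
  coh <- make_ri_cohort()
  tab <- build_reference_table(coh, reps = 200, seed = 3)
  expect_s3_class(tab, "ri_table")
  fall <- tab[tab$partition == "fall", ]
  expect_true(all(!fall$computed))
  expect_true(all(is.na(fall$lower)))
  expect_true(all(!is.na(fall$mean)))
  comp <- tab[tab$computed, ]
  expect_true(all(comp$lower <= comp$median & comp$median <= comp$upper))
  expect_true(all(comp$ci_lower_low <= comp$ci_lower_high))
  expect_true(all(comp$imprecise ==
                    (pmax(comp$wci_wri_lower, comp$wci_wri_upper) > 0.2)))
})

test_that("a gross outlier is excluded per analyte and shifts only its own row", {
  coh <- make_ri_cohort()
  tab0 <- build_reference_table(coh, reps = 200, seed = 3)
  coh2 <- coh
  coh2$hco3_c[which(coh2$season == "summer")[1]] <- 95
  tab1 <- build_reference_table(coh2, reps = 200, seed = 3)
  cell0 <- tab0[tab0$analyte == "hco3" & tab0$partition == "summer", ]
  cell1 <- tab1[tab1$analyte == "hco3" & tab1$partition == "summer", ]
  # the displaced value is dropped by the Horn screen before statistics;
  # the single pass may carry further values over the fence with it, and n
  # falls by exactly the number flagged
  expect_gte(cell1$n_outliers, cell0$n_outliers + 1L)
  expect_equal(cell1$n, cell0$n + cell0$n_outliers - cell1$n_outliers)
  excl <- attr(tab1, "exclusions")
  expect_true(any(excl$analyte == "hco3" & excl$value == 95))
  # all other rows are untouched
  others0 <- ri_rows(tab0)[!(tab0$analyte == "hco3" & tab0$partition == "summer"), ]
  others1 <- ri_rows(tab1)[!(tab1$analyte == "hco3" & tab1$partition == "summer"), ]
  expect_equal(others1, others0, ignore_attr = "row.names")
})

test_that("the reference table is deterministic given data, config and seed", {
  coh <- make_ri_cohort()
  t1 <- build_reference_table(coh, reps = 300, seed = 12)
  t2 <- build_reference_table(coh, reps = 300, seed = 12)
  expect_identical(ri_rows(t1), ri_rows(t2))
})

test_that("clean Gaussian partitions are labelled gaussian", {
  coh <- make_ri_cohort(seed = 99)
  tab <- build_reference_table(coh, analytes = c("ph", "hco3", "tco2"),
                               reps = 200, seed = 4)
  big <- tab[tab$n >= 20, ]
  expect_true(mean(big$distribution == "gaussian") >= 0.8)
})
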