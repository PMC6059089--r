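test_that("OLS fits match hand least squares", {
  df <- tibble::tibble(y = c(1, 2, 3), x = c(1, 2, 3))
  fit <- suppressWarnings(fit_glm(df, "y", "x"))  # saturated-fit summary note
  expect_equal(unname(coef(fit$model)), c(0, 1), tolerance = 1e-12)
  expect_lt(fit$rss, 1e-24)
  df2 <- tibble::tibble(y = c(1, 2, 4), x = c(1, 2, 3))
  fit2 <- fit_glm(df2, "y", "x")
  expect_equal(unname(coef(fit2$model)), c(-2 / 3, 1.5), tolerance = 1e-12)
  expect_equal(fit2$rss, 1 / 6, tolerance = 1e-12)
})

test_that("parameter count includes the residual variance", {
  set.seed(101)
  df <- tibble::tibble(
    y = rnorm(96),
    activity = sample(c("bright", "quiet"), 96, TRUE),
    pcv_pct = rnorm(96, 25, 8),
    season = sample(c("spring", "summer", "fall"), 96, TRUE))
  expect_equal(fit_glm(df, "y")$k, 2L)
  expect_equal(fit_glm(df, "y", "activity")$k, 3L)
  expect_equal(fit_glm(df, "y", "season")$k, 4L)
  expect_equal(fit_glm(df, "y", c("pcv_pct", "season"))$k, 5L)
  expect_equal(fit_glm(df, "y", c("activity", "pcv_pct", "season"))$k, 6L)
})

test_that("categorical predictors use spring and bright reference levels", {
  set.seed(102)
  df <- tibble::tibble(
    y = rnorm(60),
    activity = sample(c("bright", "quiet"), 60, TRUE),
    season = sample(c("spring", "summer", "fall"), 60, TRUE))
  fit <- fit_glm(df, "y", c("activity", "season"))
  expect_setequal(names(coef(fit$model)),
                  c("(Intercept)", "activityquiet", "seasonsummer",
                    "seasonfall"))
  # rank deficiency is reported with the aliased column
  df$dup <- df$activity
  expect_error(fit_glm(df, "y", c("activity", "dup")), "aliased")
})

test_that("AICc matches its closed form and degenerates predictably", {
  # correction term alone, k = 2 and n = 96
  fit <- list(loglik = 0, k = 2, n = 96)
  expect_equal(aicc(fit), 4 + 12 / 93, tolerance = 1e-12)
  # AICc approaches AIC from above as n grows at fixed k
  a <- vapply(c(20, 50, 200, 2000), function(n)
    aicc(list(loglik = -10, k = 3, n = n)), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_equal(a[4], 20 + 6, tolerance = 0.02)
  expect_error(aicc(list(loglik = 0, k = 5, n = 6)), "undefined")
})

test_that("OLS and AICc agree with independent oracles on random designs", {
  set.seed(103)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    p <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(n * p), n))
    y <- rnorm(n)
    df <- tibble::as_tibble(as.data.frame(X[, -1, drop = FALSE]))
    df$y <- y
    fit <- fit_glm(df, "y", setdiff(names(df), "y"))
    beta <- ols_normal_equations(X, y)
    expect_lt(max(abs(unname(coef(fit$model)) - beta)), 1e-8)
    expect_lt(abs(aicc(fit) - aicc_oracle(fit$rss, fit$n, fit$k)), 1e-9)
    # the stated Gaussian log-likelihood equals R's
    expect_equal(fit$loglik, as.numeric(logLik(fit$model)), tolerance = 1e-9)
  }
})

test_that("Akaike weights renormalise evidence and rank deterministically", {
  w <- akaike_weights(c(0, 2))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[1] / w[2], exp(1), tolerance = 1e-12)
  expect_equal(akaike_weights(5), 1)
  set.seed(104)
  df <- tibble::tibble(
    y = rnorm(80), x = rnorm(80),
    season = sample(c("spring", "summer", "fall"), 80, TRUE))
  fits <- list(fit_glm(df, "y"), fit_glm(df, "y", "x"),
               fit_glm(df, "y", c("x", "season")))
  tab <- rank_models(fits)
  expect_s3_class(tab, "model_rank_table")
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(sum(tab$delta == 0), 1)
  expect_equal(tab$aicc, sort(tab$aicc))
  # fits on different datasets are rejected
  fits2 <- list(fit_glm(df, "y"), fit_glm(df[1:40, ], "y", "x"))
  expect_error(rank_models(fits2), "different n")
})

test_that("candidate tables share one complete-case dataset", {
  set.seed(105)
  n <- 100
  df <- tibble::tibble(
    y = rnorm(n),
    activity = sample(c("bright", "quiet"), n, TRUE),
    pcv_pct = rnorm(n, 25, 8),
    season = sample(c("spring", "summer", "fall"), n, TRUE))
  # 3 missing activity only, 1 missing pcv only, 1 missing both
  df$activity[1:3] <- NA
  df$pcv_pct[4] <- NA
  df$activity[5] <- NA
  df$pcv_pct[5] <- NA
  tab <- candidate_table(df, "y")
  expect_true(all(tab$n == n - 5))
  expect_setequal(tab$model, names(default_candidates()))
  # permuting row order changes nothing
  rows_only <- function(x) { d <- as.data.frame(x); attr(d, "fits") <- NULL; d }
  tab_perm <- candidate_table(df[sample(n), ], "y")
  expect_equal(rows_only(tab_perm), rows_only(tab))
  expect_error(candidate_table(df[1:10, ], "y"), "complete cases")
})

test_that("an all-noise response keeps the null model competitive", {
  set.seed(106)
  near_top <- replicate(40, {
    df <- tibble::tibble(
      y = rnorm(90),
      activity = sample(c("bright", "quiet"), 90, TRUE),
      pcv_pct = rnorm(90, 25, 8),
      season = sample(c("spring", "summer", "fall"), 90, TRUE))
    tab <- candidate_table(df, "y")
    tab$delta[tab$model == "Null"] <= 2
  })
  expect_gt(mean(near_top), 0.5)
})

test_that("collinearity screen flags |r| above threshold", {
  set.seed(107)
  df <- tibble::tibble(x = rnorm(1000))
  df$y <- df$x
  df$z <- rnorm(1000)
  scr <- collinearity_screen(df, c("x", "y", "z"))
  expect_equal(nrow(scr), 3)
  xy <- scr[scr$var1 == "x" & scr$var2 == "y", ]
  expect_equal(xy$r, 1, tolerance = 1e-12)
  expect_true(xy$flagged)
  xz <- scr[scr$var1 == "x" & scr$var2 == "z", ]
  expect_lt(abs(xz$r), 0.1)
  expect_false(xz$flagged)
  df$c <- 1
  expect_warning(collinearity_screen(df, c("x", "c")), "constant")
})

test_that("adjustment removes constructed confounding bias", {
  set.seed(108)
  n <- 2000
  confounder <- rnorm(n)
  exposure <- confounder + rnorm(n)
  y <- 0.5 * exposure + 2 * confounder + rnorm(n)
  df <- tibble::tibble(y = y, exposure = exposure, confounder = confounder)
  crude <- adjusted_effect(df, "y", "exposure", character(0))
  adj <- adjusted_effect(df, "y", "exposure", "confounder")
  # crude estimate is biased away from the generating value, adjusted is not
  expect_gt(crude$estimate, 1)
  expect_equal(adj$estimate, 0.5, tolerance = 0.1)
  expect_true(adj$conf_low < 0.5 && 0.5 < adj$conf_high)
  expect_equal(adj$adjusted_for, "confounder")
  expect_error(adjusted_effect(df, "y", "exposure", "exposure"),
               "adjustment set")
})

test_that("null exposures give small estimates and calibrated p-values", {
  set.seed(109)
  ps <- replicate(100, {
    df <- tibble::tibble(y = rnorm(50), x = rnorm(50))
    adjusted_effect(df, "y", "x", character(0))$p
  })
  expect_gt(mean(ps > 0.05), 0.85)
  expect_gt(min(ps), 0)
})

test_that("season contrasts reduce to raw mean differences on balanced data", {
  set.seed(110)
  df <- tibble::tibble(
    season = rep(c("spring", "summer", "fall"), each = 20),
    y = rnorm(60, rep(c(0, 2, 1), each = 20)))
  fit <- fit_glm(df, "y", "season")
  con <- season_contrasts(fit)
  expect_equal(nrow(con), 3)
  means <- tapply(df$y, df$season, mean)
  ss <- con[con$contrast == "spring - summer", ]
  expect_equal(ss$estimate, unname(means["spring"] - means["summer"]),
               tolerance = 1e-9)
  # a fit without season cannot produce seasonal contrasts
  expect_error(season_contrasts(fit_glm(df, "y")), "season")
})

test_that("tidy and glance summarise fitted analyte models", {
  set.seed(111)
  df <- tibble::tibble(y = rnorm(40), x = rnorm(40))
  fit <- fit_glm(df, "y", "x", name = "X")
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "x"))
  expect_true(all(td$conf.low < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$aicc, aicc(fit))
  expect_equal(gl$model, "X")
})
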