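#' Default candidate model set
#'
#' The five candidate general linear models compared for every blood-gas
#' analyte: an intercept-only null, activity level alone, season alone,
#' PCV + season, and the full additive model activity + PCV + season.
#' Season stands in for air temperature in all candidates because the two
#' are strongly correlated and season is antecedent to temperature in the
#' causal diagram.
#'
#' @return Named list of character vectors of predictor column names.
#' @export
default_candidates <- function() {
  list(
    "Null" = character(0),
    "Activity" = "activity",
    "Season" = "season",
    "PCV + Season" = c("pcv_pct", "season"),
    "Activity + PCV + Season" = c("activity", "pcv_pct", "season")
  )
}

#' Default confounder adjustment sets per exposure
#'
#' Derived from the causal diagram: season is antecedent to everything
#' (unadjusted); air temperature is confounded by season; PCV is confounded
#' by season and temperature; activity has no measured confounders.
#' These are configuration, not hard-coded truth -- pass your own sets to
#' [adjusted_effect()] when the assumed diagram differs.
#'
#' @return Named list: exposure column -> character vector of adjustment
#'   columns.
#' @export
default_adjustment_sets <- function() {
  list(ta_c = "season",
       pcv_pct = c("season", "ta_c"),
       activity = character(0),
       season = character(0))
}

# factor coding with fixed reference levels (spring, bright) so printed
# effect directions are comparable across fits
prepare_model_frame <- function(data, response, terms) {
  cols <- c(response, terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  if ("season" %in% names(df)) {
    df$season <- factor(df$season, levels = seasons())
    df$season <- droplevels(df$season)
  }
  if ("activity" %in% names(df)) {
    df$activity <- factor(df$activity, levels = c("bright", "quiet"))
    df$activity <- droplevels(df$activity)
  }
  df
}

#' Fit a Gaussian general linear model for an analyte
#'
#' Ordinary least squares of `response` on `terms` (empty `terms` gives the
#' intercept-only null model). Categorical predictors are dummy-coded with
#' fixed reference levels (season: spring; activity: bright). Rows with a
#' missing response or predictor are dropped (complete-case).
#'
#' The returned object carries the Gaussian log-likelihood
#' \eqn{-n/2\,(\ln 2\pi + \ln(RSS/n) + 1)} and the parameter count
#' `k` = number of regression coefficients + 1 for the residual variance
#' (so the null model has k = 2).
#'
#' @param data Data frame with the response and predictor columns.
#' @param response Response column name (typically a corrected analyte
#'   column such as `"ph_c"`).
#' @param terms Character vector of predictor column names (possibly empty).
#' @param name Optional model label (defaults to `terms` joined by " + "
#'   or "Null").
#' @return An object of class `"bg_fit"`: list with `model` (the `lm` fit),
#'   `name`, `response`, `terms`, `n`, `k`, `loglik`, `rss`, `adj_r2`,
#'   `p_overall` (overall F-test against intercept-only; `NA` for the null).
#' @export
fit_glm <- function(data, response, terms = character(0), name = NULL) {
  df <- prepare_model_frame(data, response, terms)
  n <- nrow(df)
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    stop("fit_glm(): rank-deficient design; aliased column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  p <- length(coef(fit))
  k <- p + 1L
  if (n < p) stop("fit_glm(): n (", n, ") below the number of coefficients (",
                  p, ").", call. = FALSE)
  rss <- sum(stats::residuals(fit)^2)
  # a saturated (zero-residual) fit has unbounded Gaussian likelihood
  loglik <- if (rss <= 0) Inf else -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  sm <- summary(fit)
  p_overall <- if (is.null(sm$fstatistic)) NA_real_ else {
    fs <- sm$fstatistic
    unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  structure(list(
    model = fit,
    name = if (is.null(name)) {
      if (length(terms) == 0) "Null" else paste(terms, collapse = " + ")
    } else name,
    response = response, terms = terms, n = n, k = k,
    loglik = loglik, rss = rss,
    adj_r2 = sm$adj.r.squared, p_overall = p_overall
  ), class = "bg_fit")
}

#' @export
print.bg_fit <- function(x, ...) {
  cat("<bg_fit> ", x$response, " ~ ", x$name,
      "  (n = ", x$n, ", k = ", x$k, ", AICc = ",
      format(aicc(x), digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ln L + 2k + 2k(k+1)/(n-k-1)}, with `k` counting the
#' residual variance. Undefined (error) when `n <= k + 1`.
#'
#' @param fit A [fit_glm()] object, or any object with `loglik`, `k`, `n`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  n <- fit$n; k <- fit$k
  if (n - k - 1 <= 0) {
    stop("aicc(): undefined for n = ", n, ", k = ", k,
         " (requires n - k - 1 > 0).", call. = FALSE)
  }
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} where
#' \eqn{\Delta_i} is each model's AICc minus the minimum AICc in the set.
#' Accepts either raw AICc values or deltas (the minimum is subtracted
#' either way).
#'
#' @param delta Numeric vector of AICc values or AICc differences.
#' @return Numeric vector of weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 0.46, 5.22, 8.53, 12.38))
akaike_weights <- function(delta) {
  d <- delta - min(delta)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank a candidate set by AICc
#'
#' Computes AICc differences and Akaike weights over fits of the same
#' complete-case dataset, sorted ascending by AICc with ties broken by the
#' smaller parameter count. Fits with differing n are an error: case-wise
#' deletion over the union of candidate predictors must precede fitting
#' (see [candidate_table()]).
#'
#' @param fits List of [fit_glm()] objects sharing one dataset.
#' @return Tibble of class `"model_rank_table"`: `model`, `response`, `n`,
#'   `k`, `aicc`, `delta`, `weight`, `adj_r2`, `p_overall`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "bg_fit")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("rank_models(): fits use different n (", paste(ns, collapse = ", "),
         "); apply case-wise deletion over the shared predictor set before ",
         "fitting.", call. = FALSE)
  }
  tab <- tibble::tibble(
    model = vapply(fits, function(f) f$name, character(1)),
    response = vapply(fits, function(f) f$response, character(1)),
    n = as.integer(ns),
    k = vapply(fits, function(f) f$k, integer(1)),
    aicc = vapply(fits, aicc, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    p_overall = vapply(fits, function(f) f$p_overall, numeric(1))
  )
  tab$delta <- tab$aicc - min(tab$aicc)
  tab$weight <- akaike_weights(tab$aicc)
  tab <- tab[order(tab$aicc, tab$k), c("model", "response", "n", "k", "aicc",
                                       "delta", "weight", "adj_r2",
                                       "p_overall")]
  structure(tab, class = c("model_rank_table", class(tab)), fits = fits)
}

#' AICc ranking of the candidate set for one analyte
#'
#' Restricts the cohort to rows complete in the response and every predictor
#' used by any candidate (one shared dataset, per case-wise deletion), fits
#' all candidates and ranks them.
#'
#' @param data Corrected cohort tibble.
#' @param response Response column name (e.g. `"ph_c"`).
#' @param candidates Named list of predictor sets; defaults to
#'   [default_candidates()].
#' @param min_n Minimum shared sample size (default 20).
#' @return A `"model_rank_table"` tibble (see [rank_models()]).
#' @export
candidate_table <- function(data, response, candidates = default_candidates(),
                            min_n = 20) {
  all_terms <- unique(unlist(candidates))
  shared <- prepare_model_frame(data, response, all_terms)
  if (nrow(shared) < min_n) {
    stop("candidate_table(): only ", nrow(shared),
         " complete cases (< ", min_n, ").", call. = FALSE)
  }
  fits <- purrr::imap(candidates, function(terms, nm) {
    fit_glm(shared, response, terms, name = nm)
  })
  rank_models(unname(fits))
}

#' Pairwise collinearity screen for continuous predictors
#'
#' Pearson correlation for every pair; pairs with `|r|` above the threshold
#' are flagged as strongly correlated and should not co-occur in one model.
#'
#' @param data Data frame.
#' @param vars Character vector of (at least two) continuous predictor
#'   columns.
#' @param threshold Flagging threshold on `|r|` (default 0.5).
#' @return Tibble: `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_screen <- function(data, vars, threshold = 0.5) {
  stopifnot(length(vars) >= 2, all(vars %in% names(data)))
  pairs <- utils::combn(vars, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    x <- data[[v1]]; y <- data[[v2]]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("collinearity_screen(): constant column in pair ", v1, "/", v2,
              "; correlation undefined.", call. = FALSE)
      NA_real_
    } else {
      cor(x[ok], y[ok])
    }
    tibble::tibble(var1 = v1, var2 = v2, r = r,
                   flagged = !is.na(r) && abs(r) > threshold)
  })
}

#' Confounder-adjusted effect of one exposure on one analyte
#'
#' Multivariable linear regression of the response on the exposure plus its
#' adjustment set (confounders only; intervening variables must be left
#' out). For a continuous exposure the estimate is its slope; for a
#' categorical exposure, one row per non-reference level difference.
#'
#' @param data Corrected cohort tibble.
#' @param response Response column name.
#' @param exposure Exposure column name.
#' @param adjustment_set Character vector of adjustment columns; defaults to
#'   the entry for `exposure` in [default_adjustment_sets()] (empty if
#'   absent). Including the exposure itself is an error.
#' @param level Confidence level for the interval (default 0.95).
#' @return Tibble of class `"effect_table"`: `response`, `exposure`,
#'   `level` (factor level or `NA` for continuous), `estimate`, `se`,
#'   `statistic`, `p`, `conf_low`, `conf_high`, `adjusted_for`, `n_used`.
#' @export
adjusted_effect <- function(data, response, exposure, adjustment_set = NULL,
                            level = 0.95) {
  if (is.null(adjustment_set)) {
    sets <- default_adjustment_sets()
    adjustment_set <- if (exposure %in% names(sets)) sets[[exposure]] else character(0)
  }
  if (exposure %in% adjustment_set) {
    stop("adjusted_effect(): exposure '", exposure,
         "' cannot be in its own adjustment set.", call. = FALSE)
  }
  fit <- fit_glm(data, response, c(exposure, adjustment_set))
  sm <- summary(fit$model)$coefficients
  ci <- confint(fit$model, level = level)
  rn <- rownames(sm)
  is_exposure_coef <- if (is.numeric(data[[exposure]])) {
    rn == exposure
  } else {
    startsWith(rn, exposure)
  }
  rows <- which(is_exposure_coef)
  if (length(rows) == 0) stop("adjusted_effect(): no coefficient found for '",
                              exposure, "'.", call. = FALSE)
  tibble::new_tibble(tibble::tibble(
    response = response,
    exposure = exposure,
    level = ifelse(rn[rows] == exposure, NA_character_,
                   sub(paste0("^", exposure), "", rn[rows])),
    estimate = unname(sm[rows, "Estimate"]),
    se = unname(sm[rows, "Std. Error"]),
    statistic = unname(sm[rows, "t value"]),
    p = unname(sm[rows, "Pr(>|t|)"]),
    conf_low = unname(ci[rows, 1]),
    conf_high = unname(ci[rows, 2]),
    adjusted_for = paste(adjustment_set, collapse = "+"),
    n_used = fit$n
  ), class = "effect_table")
}

#' Pairwise seasonal contrasts from a fitted model
#'
#' Differences of model-adjusted season means (continuous covariates held at
#' their sample means, other factors averaged over), with t-based standard
#' errors and p-values, via estimated marginal means. On balanced data with
#' no covariates these reduce to raw season mean differences. No
#' multiplicity adjustment by default.
#'
#' @param fit A [fit_glm()] object whose model includes `season`.
#' @param adjust Multiplicity adjustment passed to the contrast machinery
#'   (default `"none"`).
#' @param level Confidence level (default 0.95).
#' @return Tibble of class `"effect_table"`: `response`, `contrast`,
#'   `estimate`, `se`, `df`, `statistic`, `p`, `conf_low`, `conf_high`.
#' @export
season_contrasts <- function(fit, adjust = "none", level = 0.95) {
  stopifnot(inherits(fit, "bg_fit"))
  if (!"season" %in% fit$terms) {
    stop("season_contrasts(): fit does not include season.", call. = FALSE)
  }
  emm <- emmeans::emmeans(fit$model, "season",
                          data = stats::model.frame(fit$model))
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  s <- as.data.frame(summary(prs, infer = c(TRUE, TRUE), level = level))
  tibble::new_tibble(tibble::tibble(
    response = fit$response,
    contrast = as.character(s$contrast),
    estimate = s$estimate,
    se = s$SE,
    df = s$df,
    statistic = s$t.ratio,
    p = s$p.value,
    conf_low = s$lower.CL,
    conf_high = s$upper.CL
  ), class = "effect_table")
}
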