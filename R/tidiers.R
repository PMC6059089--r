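#' Tidy a fitted analyte model
#'
#' One row per regression coefficient, broom-style.
#'
#' @param x A [fit_glm()] object.
#' @param conf.level Confidence level for the interval (default 0.95).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.bg_fit <- function(x, conf.level = 0.95, ...) {
  sm <- summary(x$model)$coefficients
  ci <- confint(x$model, level = conf.level)
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )
}

#' One-row model summary for a fitted analyte model
#'
#' @param x A [fit_glm()] object.
#' @param ... Unused.
#' @return One-row tibble: `response`, `model`, `n`, `k`, `logLik`, `rss`,
#'   `aicc`, `adj.r.squared`, `p.value`.
#' @export
glance.bg_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, model = x$name, n = x$n, k = x$k,
    logLik = x$loglik, rss = x$rss, aicc = aicc(x),
    adj.r.squared = x$adj_r2, p.value = x$p_overall
  )
}

#' Top-model summary of a candidate ranking
#'
#' @param x A `"model_rank_table"` from [candidate_table()] or
#'   [rank_models()].
#' @param ... Unused.
#' @return One-row tibble: the best-ranked model with its weight and the
#'   evidence ratio over the runner-up.
#' @export
glance.model_rank_table <- function(x, ...) {
  top <- x[1, ]
  tibble::tibble(
    response = top$response, top_model = top$model, n = top$n,
    weight = top$weight,
    evidence_ratio = if (nrow(x) > 1) top$weight / x$weight[2] else Inf,
    n_models = nrow(x)
  )
}
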