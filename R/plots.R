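#' Plot a seasonal reference-interval table
#'
#' One facet per analyte: the reference interval as a vertical range per
#' season, the median as a point, and the bootstrap confidence intervals of
#' the bounds as error bars. Partitions without a computed interval show
#' the observed range as a dashed line.
#'
#' @param object A `"ri_table"` tibble from [build_reference_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ri_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$partition <- factor(df$partition, levels = unique(df$partition))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$partition)) +
    ggplot2::geom_linerange(
      data = df[!df$computed & !is.na(df$min), ],
      ggplot2::aes(ymin = .data$min, ymax = .data$max),
      linetype = "dashed", colour = "grey50") +
    ggplot2::geom_linerange(
      data = df[df$computed, ],
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      linewidth = 1.2, colour = "steelblue") +
    ggplot2::geom_errorbar(
      data = df[df$computed, ],
      ggplot2::aes(ymin = .data$ci_lower_low, ymax = .data$ci_lower_high),
      width = 0.2, colour = "grey30") +
    ggplot2::geom_errorbar(
      data = df[df$computed, ],
      ggplot2::aes(ymin = .data$ci_upper_low, ymax = .data$ci_upper_high),
      width = 0.2, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 1.5) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Reference intervals by season",
                  subtitle = "Range: 95% reference interval; bars: 90% CI of each bound; point: median")
}

#' Plot Akaike weights of a candidate ranking
#'
#' @param object A `"model_rank_table"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_rank_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL,
                  title = paste0("Candidate models for ", df$response[1]))
}

#' Forest plot of effect estimates
#'
#' @param object An `"effect_table"` tibble from [adjusted_effect()] or
#'   [season_contrasts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  lab <- if ("contrast" %in% names(df)) df$contrast else
    ifelse(is.na(df$level), df$exposure, paste0(df$exposure, ": ", df$level))
  df$label <- paste(df$response, lab, sep = " | ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL,
                  title = "Adjusted effect estimates")
}
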