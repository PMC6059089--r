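#' Horn's outlier screen
#'
#' Horn's method for reference-population outlier exclusion: the sample is
#' brought close to symmetry with a Box-Cox transform (power chosen by
#' maximum likelihood over a lambda grid), then Tukey interquartile fences
#' \eqn{[Q_1 - 1.5\,IQR,\; Q_3 + 1.5\,IQR]} are applied on the transformed
#' scale. Values outside the fences are outliers. Data containing values
#' at or below zero (base excess can be negative) are shifted by
#' \eqn{1 - \min(x)} before the transform; the screen is a single pass (no
#' iteration).
#'
#' @param values Numeric vector, at least 3 finite values for screening;
#'   with fewer, everything is retained with a warning.
#' @param k Fence multiplier (default 1.5).
#' @param lambda_grid Box-Cox powers searched (default `seq(-3, 3, 0.05)`).
#' @return A list of class `"horn_screen"`: `retained`, `outliers`,
#'   `is_outlier` (logical, aligned with `values`), `lambda`, `fences`
#'   (transformed scale).
#' @export
#' @examples
#' horn_outliers(c(rnorm(50), 25))
horn_outliers <- function(values, k = 1.5, lambda_grid = seq(-3, 3, 0.05)) {
  stopifnot(is.numeric(values))
  x <- values[is.finite(values)]
  if (length(x) != length(values)) {
    stop("horn_outliers(): values must be finite.", call. = FALSE)
  }
  if (length(x) < 3) {
    warning("horn_outliers(): fewer than 3 values; no screening performed.",
            call. = FALSE)
    return(structure(list(retained = values, outliers = numeric(0),
                          is_outlier = rep(FALSE, length(values)),
                          lambda = NA_real_, fences = c(NA_real_, NA_real_)),
                     class = "horn_screen"))
  }
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  if (sd(xs) == 0) {
    # degenerate: fences collapse onto the constant, nothing is outside
    return(structure(list(retained = values, outliers = numeric(0),
                          is_outlier = rep(FALSE, length(values)),
                          lambda = 1, fences = c(xs[1], xs[1]) - shift),
                     class = "horn_screen"))
  }
  lambda <- boxcox_lambda_ml(xs, lambda_grid)
  z <- boxcox_transform(xs, lambda)
  q <- quantile(z, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  is_out <- z < fences[1] | z > fences[2]
  structure(list(retained = values[!is_out], outliers = values[is_out],
                 is_outlier = is_out, lambda = lambda, fences = fences),
            class = "horn_screen")
}

# maximum-likelihood Box-Cox power on a grid (positive data)
boxcox_lambda_ml <- function(x, lambda_grid) {
  bc <- MASS::boxcox(x ~ 1, lambda = lambda_grid, plotit = FALSE,
                     interp = FALSE)
  bc$x[which.max(bc$y)]
}

boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' @export
print.horn_screen <- function(x, ...) {
  cat("Horn outlier screen: n =", length(x$is_outlier),
      "| outliers =", sum(x$is_outlier),
      "| lambda =", format(x$lambda), "\n")
  if (sum(x$is_outlier) > 0) cat("  flagged:", format(x$outliers), "\n")
  invisible(x)
}

#' Distributional label for a reference sample
#'
#' Labels the sample `gaussian` or `non_gaussian` by the Shapiro-Wilk test
#' at level `alpha`; the Kolmogorov-Smirnov statistic against a normal with
#' the sample's moments is reported alongside but does not drive the label
#' (Shapiro-Wilk is the stronger test at reference-interval sample sizes).
#'
#' @param values Numeric vector; at least 8 non-missing values, otherwise
#'   the label is `NA` with a warning.
#' @param alpha Significance level for the label (default 0.05).
#' @return One-row tibble: `n`, `distribution`, `sw_stat`, `sw_p`,
#'   `ks_stat`, `ks_p`.
#' @export
assess_distribution <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 8) {
    warning("assess_distribution(): fewer than 8 values; no label assigned.",
            call. = FALSE)
    return(tibble::tibble(n = length(x), distribution = NA_character_,
                          sw_stat = NA_real_, sw_p = NA_real_,
                          ks_stat = NA_real_, ks_p = NA_real_))
  }
  sw <- shapiro.test(x)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  tibble::tibble(
    n = length(x),
    distribution = ifelse(sw$p.value >= alpha, "gaussian", "non_gaussian"),
    sw_stat = unname(sw$statistic), sw_p = sw$p.value,
    ks_stat = unname(ks$statistic), ks_p = ks$p.value
  )
}

# rank-index quantile, h = p*(n+1) with linear interpolation, clamped to the
# observed range (R's type-6 estimator)
q_type6 <- function(x, p) {
  quantile(x, probs = p, type = 6, names = FALSE)
}

#' Nonparametric reference interval
#'
#' Central-`coverage` reference interval by the nonparametric percentile
#' method: bounds are the \eqn{(1-c)/2} and \eqn{1-(1-c)/2} sample
#' quantiles using the rank index \eqn{p(n+1)} with linear interpolation,
#' clamped to the observed minimum/maximum (so at n around 40 a bound can
#' coincide with the sample extreme).
#'
#' @param values Numeric vector (missing values dropped).
#' @param coverage Central coverage (default 0.95).
#' @param min_n Minimum sample size; below it the interval is not computed
#'   and `c(NA, NA)` is returned with a warning (default 20).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' nonparametric_ri(1:40)
nonparametric_ri <- function(values, coverage = 0.95, min_n = 20) {
  x <- values[!is.na(values)]
  if (length(x) < min_n) {
    warning("nonparametric_ri(): n = ", length(x), " < min_n = ", min_n,
            "; interval not computed.", call. = FALSE)
    return(c(lower = NA_real_, upper = NA_real_))
  }
  tail_p <- (1 - coverage) / 2
  c(lower = q_type6(x, tail_p), upper = q_type6(x, 1 - tail_p))
}

#' Bootstrap confidence interval for a reference-interval bound
#'
#' Percentile bootstrap: the chosen bound of the nonparametric reference
#' interval is recomputed on `reps` with-replacement resamples of size n,
#' and the central-`level` percentile interval of those replicate bounds is
#' returned. Seeded and reproducible.
#'
#' @param values Numeric vector (missing values dropped).
#' @param which `"lower"` or `"upper"` bound.
#' @param coverage Reference-interval coverage (default 0.95).
#' @param reps Number of bootstrap replicates (default 5000; at least 100).
#' @param level Confidence level of the bound CI (default 0.90).
#' @param seed Optional integer seed (local RNG scope).
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_bound_ci <- function(values, which = c("lower", "upper"),
                               coverage = 0.95, reps = 5000, level = 0.90,
                               seed = NULL) {
  which <- match.arg(which)
  stopifnot(reps >= 100)
  x <- values[!is.na(values)]
  n <- length(x)
  stopifnot(n >= 2)
  p <- if (which == "lower") (1 - coverage) / 2 else 1 - (1 - coverage) / 2
  boots <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
    apply(matrix(x[idx], nrow = n), 2, q_type6_fast, p = p, n = n)
  })
  ci <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  c(low = ci[1], high = ci[2])
}

# type-6 quantile specialised for repeated calls at fixed p and n
q_type6_fast <- function(x, p, n) {
  xs <- sort.int(x, method = "quick")
  h <- p * (n + 1)
  if (h <= 1) return(xs[1])
  if (h >= n) return(xs[n])
  fl <- floor(h)
  xs[fl] + (h - fl) * (xs[fl + 1] - xs[fl])
}

# evaluate an expression under a temporary RNG state (no-op when seed NULL)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ratio of confidence-interval width to reference-interval width
#'
#' The precision diagnostic WCI/WRI: the width of a bound's confidence
#' interval divided by the total width of the reference interval. Ratios
#' above 0.2 indicate that a larger reference sample is recommended.
#'
#' @param ri Numeric `c(lower, upper)` reference interval, `upper > lower`.
#' @param ci Numeric `c(low, high)` confidence interval of one bound.
#' @return The ratio (a non-negative number); `NaN` with a warning for a
#'   zero-width reference interval.
#' @export
#' @examples
#' wci_wri(c(22.6, 41.8), c(41.8, 47.1))
wci_wri <- function(ri, ci) {
  wri <- ri[2] - ri[1]
  wci <- ci[2] - ci[1]
  if (wri < 0 || wci < 0) stop("wci_wri(): interval bounds out of order.",
                               call. = FALSE)
  if (wri == 0) {
    warning("wci_wri(): zero-width reference interval; ratio undefined.",
            call. = FALSE)
    return(NaN)
  }
  unname(wci / wri)
}

#' Seasonal reference-interval table
#'
#' For each analyte and season partition of a corrected, eligibility-screened
#' cohort: drops missing values, excludes within-partition outliers by
#' [horn_outliers()], computes descriptive statistics, the distribution
#' label, the nonparametric reference interval, bootstrap confidence
#' intervals on both bounds, WCI/WRI ratios and the imprecision flag.
#' Partitions smaller than `min_n` (after outlier removal) report
#' descriptive statistics only, with `computed = FALSE`.
#'
#' @param data Corrected cohort tibble (see [correct_panel()]) with `id` and
#'   the partition column; restrict it to reference-eligible animals first
#'   (see [screen_cohort()]).
#' @param analytes Analytes to tabulate (default all seven).
#' @param partition Name of the partition column (default `"season"`).
#' @param coverage Reference-interval coverage (default 0.95).
#' @param level Bound-CI confidence level (default 0.90).
#' @param reps Bootstrap replicates (default 5000).
#' @param min_n Minimum partition size for interval computation (default 20).
#' @param alpha Normality-test level (default 0.05).
#' @param wci_threshold Imprecision flag threshold on max WCI/WRI
#'   (default 0.2).
#' @param seed Optional integer seed driving all bootstrap draws.
#' @return A tibble of class `"ri_table"`, one row per analyte x partition,
#'   with attribute `exclusions` (tibble of per-partition outlier removals:
#'   `analyte`, partition, `id`, `value`).
#' @export
build_reference_table <- function(data, analytes = blood_gas_analytes(),
                                  partition = "season", coverage = 0.95,
                                  level = 0.90, reps = 5000, min_n = 20,
                                  alpha = 0.05, wci_threshold = 0.2,
                                  seed = NULL) {
  stopifnot(is.data.frame(data), partition %in% names(data),
            "id" %in% names(data))
  parts <- if (identical(partition, "season")) {
    intersect(seasons(), unique(data[[partition]]))
  } else {
    sort(unique(data[[partition]]))
  }
  grid <- tidyr::expand_grid(analyte = analytes, part = parts)
  exclusions <- list()
  rows <- purrr::pmap_dfr(grid, function(analyte, part) {
    col <- corrected_col(analyte)
    sub <- data[!is.na(data[[partition]]) & data[[partition]] == part, ]
    vals <- sub[[col]]
    ids <- sub$id
    keep <- !is.na(vals)
    vals <- vals[keep]; ids <- ids[keep]
    if (length(vals) >= 3) {
      scr <- horn_outliers(vals)
      if (any(scr$is_outlier)) {
        exclusions[[length(exclusions) + 1]] <<- tibble::tibble(
          analyte = analyte, partition = part,
          id = ids[scr$is_outlier], value = vals[scr$is_outlier])
      }
      vals <- vals[!scr$is_outlier]
      n_out <- sum(scr$is_outlier)
    } else {
      n_out <- 0L
    }
    n <- length(vals)
    base <- tibble::tibble(
      analyte = analyte, partition = part, n = n, n_outliers = n_out,
      mean = if (n > 0) mean(vals) else NA_real_,
      sd = if (n > 1) sd(vals) else NA_real_,
      median = if (n > 0) median(vals) else NA_real_,
      min = if (n > 0) min(vals) else NA_real_,
      max = if (n > 0) max(vals) else NA_real_
    )
    dist <- if (n >= 8) assess_distribution(vals, alpha) else
      tibble::tibble(distribution = NA_character_, sw_stat = NA_real_,
                     sw_p = NA_real_, ks_stat = NA_real_, ks_p = NA_real_)
    if (n >= min_n) {
      ri <- nonparametric_ri(vals, coverage, min_n)
      cell_seed <- cell_seed_for(seed, analyte, part)
      ci_lo <- bootstrap_bound_ci(vals, "lower", coverage, reps, level,
                                  seed = cell_seed)
      ci_up <- bootstrap_bound_ci(vals, "upper", coverage, reps, level,
                                  seed = if (is.null(cell_seed)) NULL else cell_seed + 1L)
      w_lo <- wci_wri(ri, ci_lo)
      w_up <- wci_wri(ri, ci_up)
      intr <- tibble::tibble(
        lower = ri[[1]], upper = ri[[2]],
        ci_lower_low = ci_lo[[1]], ci_lower_high = ci_lo[[2]],
        ci_upper_low = ci_up[[1]], ci_upper_high = ci_up[[2]],
        wci_wri_lower = w_lo, wci_wri_upper = w_up,
        imprecise = max(w_lo, w_up) > wci_threshold, computed = TRUE)
    } else {
      intr <- tibble::tibble(
        lower = NA_real_, upper = NA_real_,
        ci_lower_low = NA_real_, ci_lower_high = NA_real_,
        ci_upper_low = NA_real_, ci_upper_high = NA_real_,
        wci_wri_lower = NA_real_, wci_wri_upper = NA_real_,
        imprecise = NA, computed = FALSE)
    }
    dplyr::bind_cols(base,
                     dist[c("distribution", "sw_stat", "sw_p", "ks_stat", "ks_p")],
                     intr)
  })
  out <- structure(rows, class = c("ri_table", class(rows)))
  attr(out, "exclusions") <- if (length(exclusions) > 0) {
    dplyr::bind_rows(exclusions)
  } else {
    tibble::tibble(analyte = character(), partition = character(),
                   id = character(), value = numeric())
  }
  attr(out, "settings") <- list(coverage = coverage, level = level,
                                reps = reps, min_n = min_n, alpha = alpha,
                                wci_threshold = wci_threshold, seed = seed)
  out
}

# deterministic sub-seed per analyte x partition cell, < 2^31
cell_seed_for <- function(seed, analyte, part) {
  if (is.null(seed)) return(NULL)
  ai <- match(analyte, blood_gas_analytes())
  pi_ <- match(part, c(seasons(), part))[1]
  as.integer((as.numeric(seed) + 7919 * ai + 104729 * pi_) %% 2147483629)
}
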