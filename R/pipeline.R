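#' Default pipeline configuration
#'
#' Settings for the end-to-end run: either a `simulate` block (a
#' [sim_config()]) or an `input` path to a cohort CSV; screening options
#' (active-disease codes, multi-analyte outlier threshold); reference-
#' interval options (coverage, bound-CI level, bootstrap replicates,
#' minimum partition n, imprecision threshold); and modelling options
#' (candidate sets, exposures with adjustment sets).
#'
#' @param ... Named overrides (nested lists are replaced wholesale).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,
    simulate = sim_config(),
    screening = list(active_codes = default_active_codes(),
                     outlier_threshold = 2),
    ri = list(coverage = 0.95, level = 0.90, reps = 5000, min_n = 20,
              alpha = 0.05, wci_threshold = 0.2),
    models = list(candidates = default_candidates(),
                  adjustment_sets = default_adjustment_sets(),
                  min_n = 20),
    analytes = blood_gas_analytes()
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    stop("pipeline_config(): unknown option(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

read_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    raw <- yaml::read_yaml(config)
    cfg <- pipeline_config()
    for (nm in intersect(names(raw), names(cfg))) {
      if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
        cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
      } else {
        cfg[[nm]] <- raw[[nm]]
      }
    }
    return(cfg)
  }
  if (is.list(config)) {
    return(do.call(pipeline_config, config))
  }
  stop("run_pipeline(): config must be a pipeline_config, a list, or a YAML ",
       "path.", call. = FALSE)
}

#' Run the full blood-gas analysis pipeline
#'
#' Executes the study replica in fixed order: ingest (read a cohort CSV, or
#' simulate one with artifacts), temperature-correct the panels, screen
#' eligibility (active-disease exclusions for the reference population;
#' animals with outliers in two or more analytes excluded everywhere),
#' build the seasonal reference-interval table, rank the candidate models
#' per analyte, and estimate adjusted effects with seasonal contrasts.
#' Deterministic given (input, config, seed). Every exclusion is tallied in
#' the run manifest.
#'
#' @param config A [pipeline_config()], a plain list of overrides, or a
#'   path to a YAML file with the same structure.
#' @param out_dir Optional output directory; when given, writes
#'   `corrected.csv`, `eligibility.csv`, `reference_intervals.csv`,
#'   `model_selection.csv`, `effects.csv` and `manifest.json`.
#' @param seed Integer seed driving simulation and bootstrap.
#' @return (Invisibly) a list of class `"ectogas_run"`: `cohort`,
#'   `corrected`, `eligibility`, `ri_table`, `model_tables` (named list of
#'   rank tables), `effects`, `contrasts`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  cfg <- read_pipeline_config(config)
  counts <- list()

  if (!is.null(cfg$input)) {
    cohort <- read_cohort(cfg$input)
    counts$rows_dropped_malformed <- nrow(attr(cohort, "problems"))
  } else {
    if (is.null(seed)) seed <- cfg$simulate$seed
    if (is.null(seed)) {
      stop("run_pipeline(): a seed is required for a simulated run.",
           call. = FALSE)
    }
    sim <- if (inherits(cfg$simulate, "sim_config")) cfg$simulate else
      do.call(sim_config, cfg$simulate)
    cohort <- generate_cohort(sim, seed = seed)
    cohort <- inject_artifacts(cohort, sim, seed = seed + 1L)
    counts$rows_dropped_malformed <- 0L
  }
  counts$read <- nrow(cohort)

  corrected <- correct_panel(cohort)
  elig <- screen_cohort(corrected,
                        active_codes = cfg$screening$active_codes,
                        threshold = cfg$screening$outlier_threshold)
  counts$excluded_health <- sum(vapply(elig$reasons, function(r)
    any(startsWith(r, "active_lesion:")), logical(1)))
  counts$excluded_outlier <- sum(vapply(elig$reasons, function(r)
    any(startsWith(r, "multi_analyte_outlier:")), logical(1)))
  counts$eligible_ri <- sum(elig$eligible_ri)
  counts$eligible_model <- sum(elig$eligible_model)

  ri_data <- corrected[corrected$id %in% elig$id[elig$eligible_ri], ]
  ri_tab <- build_reference_table(
    ri_data, analytes = cfg$analytes,
    coverage = cfg$ri$coverage, level = cfg$ri$level, reps = cfg$ri$reps,
    min_n = cfg$ri$min_n, alpha = cfg$ri$alpha,
    wci_threshold = cfg$ri$wci_threshold,
    seed = if (is.null(seed)) NULL else seed + 2L)

  model_data <- corrected[corrected$id %in% elig$id[elig$eligible_model], ]
  model_tables <- lapply(setNames(cfg$analytes, cfg$analytes), function(a) {
    candidate_table(model_data, corrected_col(a),
                    candidates = cfg$models$candidates,
                    min_n = cfg$models$min_n)
  })
  counts$model_n <- vapply(model_tables, function(t) t$n[1], integer(1))
  counts$deleted_missing <- nrow(model_data) - unname(counts$model_n)

  effects <- dplyr::bind_rows(lapply(cfg$analytes, function(a) {
    resp <- corrected_col(a)
    dplyr::bind_rows(lapply(names(cfg$models$adjustment_sets), function(exp_) {
      adjusted_effect(model_data, resp, exp_,
                      adjustment_set = cfg$models$adjustment_sets[[exp_]])
    }))
  }))
  contrasts <- dplyr::bind_rows(lapply(cfg$analytes, function(a) {
    resp <- corrected_col(a)
    full <- fit_glm(model_data, resp, c("activity", "pcv_pct", "season"),
                    name = "Activity + PCV + Season")
    season_contrasts(full)
  }))

  manifest <- list(
    package = "ectogas",
    version = as.character(utils::packageVersion("ectogas")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = serialize_config(cfg),
    counts = counts,
    ri_exclusions = nrow(attr(ri_tab, "exclusions"))
  )

  result <- structure(list(cohort = cohort, corrected = corrected,
                           eligibility = elig, ri_table = ri_tab,
                           model_tables = model_tables, effects = effects,
                           contrasts = contrasts, manifest = manifest),
                      class = "ectogas_run")
  if (!is.null(out_dir)) write_run(result, out_dir)
  invisible(result)
}

serialize_config <- function(cfg) {
  drop_class <- function(x) {
    if (is.list(x)) { attributes(x) <- list(names = names(x)); lapply(x, drop_class) }
    else x
  }
  drop_class(unclass(cfg))
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$corrected, file.path(out_dir, "corrected.csv"))
  write_table(result$eligibility, file.path(out_dir, "eligibility.csv"))
  write_table(render_ri_table(result$ri_table),
              file.path(out_dir, "reference_intervals.csv"))
  write_table(dplyr::bind_rows(lapply(result$model_tables, render_model_table)),
              file.path(out_dir, "model_selection.csv"))
  write_table(result$effects, file.path(out_dir, "effects.csv"), digits = 4)
  write_table(result$contrasts, file.path(out_dir, "contrasts.csv"),
              digits = 4)
  manifest <- result$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.ectogas_run <- function(x, ...) {
  cat("<ectogas_run>\n")
  cat("  animals read:      ", x$manifest$counts$read, "\n")
  cat("  eligible (RI):     ", x$manifest$counts$eligible_ri, "\n")
  cat("  eligible (models): ", x$manifest$counts$eligible_model, "\n")
  cat("  RI rows computed:  ", sum(x$ri_table$computed), "of",
      nrow(x$ri_table), "\n")
  invisible(x)
}

#' Publication-shaped reference-interval report
#'
#' Renders an [build_reference_table()] result in the conventional report
#' layout: per-analyte rounding (pH to 2 dp, pressures to 0-1 dp, and so
#' on), a `reference_range` string, bound-CI strings, and a footnote marker
#' `"a"` on rows whose WCI/WRI exceeds the imprecision threshold. Rows
#' below the minimum n keep their descriptive statistics with `NA` interval
#' fields.
#'
#' @param ri A `"ri_table"` tibble.
#' @return A tibble with columns `analyte`, `season`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, `distribution`, `reference_range`, `ci_lower`,
#'   `ci_upper`, `flag`.
#' @export
render_ri_table <- function(ri) {
  stopifnot(inherits(ri, "ri_table"))
  info <- analyte_info()
  digits <- setNames(info$digits, info$analyte)
  d <- digits[ri$analyte]
  vround <- function(x, d) vapply(seq_along(x), function(i) round(x[i], d[i]),
                                  numeric(1))
  fmt <- function(x, d) {
    vapply(seq_along(x), function(i) {
      if (is.na(x[i])) NA_character_ else
        formatC(x[i], format = "f", digits = d[i])
    }, character(1))
  }
  tibble::tibble(
    analyte = ri$analyte,
    season = ri$partition,
    n = ri$n,
    mean = vround(ri$mean, d),
    sd = vround(ri$sd, d),
    median = vround(ri$median, d),
    min = vround(ri$min, d),
    max = vround(ri$max, d),
    distribution = dplyr::case_match(ri$distribution,
                                     "gaussian" ~ "G",
                                     "non_gaussian" ~ "NG",
                                     .default = NA_character_),
    reference_range = ifelse(ri$computed,
                             paste0(fmt(ri$lower, d), "-", fmt(ri$upper, d)),
                             NA_character_),
    ci_lower = ifelse(ri$computed,
                      paste0(fmt(ri$ci_lower_low, d), "-",
                             fmt(ri$ci_lower_high, d)),
                      NA_character_),
    ci_upper = ifelse(ri$computed,
                      paste0(fmt(ri$ci_upper_low, d), "-",
                             fmt(ri$ci_upper_high, d)),
                      NA_character_),
    flag = ifelse(!is.na(ri$imprecise) & ri$imprecise, "a", "")
  )
}

#' Publication-shaped model-selection report
#'
#' Renders a [candidate_table()] result with the conventional columns:
#' Model, N, K, AICc, delta AICc, and Akaike weight to 2 decimal places.
#'
#' @param ranks A `"model_rank_table"` tibble.
#' @return A tibble: `response`, `model`, `n`, `k`, `aicc`, `delta`,
#'   `weight`, `adj_r2`, `p_overall`.
#' @export
render_model_table <- function(ranks) {
  stopifnot(inherits(ranks, "model_rank_table"))
  tibble::tibble(
    response = ranks$response,
    model = ranks$model,
    n = ranks$n,
    k = ranks$k,
    aicc = round(ranks$aicc, 2),
    delta = round(ranks$delta, 2),
    weight = round(ranks$weight, 2),
    adj_r2 = round(ranks$adj_r2, 3),
    p_overall = signif(ranks$p_overall, 3)
  )
}
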