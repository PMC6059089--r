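#' Simulation configuration for a synthetic blood-gas cohort
#'
#' Returns the default generating configuration, with any element
#' overridable through `...`. Defaults emulate a ~100-animal field study
#' over three seasons:
#'
#' * `n_per_season` 40/42/20 (spring/summer/fall), so the small fall
#'   partition exercises minimum-n gating downstream.
#' * Season air-temperature means 19.0/24.47/16.65 degrees C (within-season
#'   SD 2.5), reproducing pairwise seasonal differences of +5.47
#'   (summer-spring), +7.82 (summer-fall) and -2.34 (fall-spring) degrees C
#'   and an overall mean near 21 degrees C.
#' * PCV (%) linear in season and temperature: spring intercept 21.7, summer
#'   +7, fall +2.3, slope 0.1 %/degree C about 20 degrees C, residual SD 7 —
#'   implying a marginal SD near 8 and a PCV-temperature correlation near
#'   0.3.
#' * Quiet-activity probability 0.673.
#' * Analyte models on the temperature-corrected scale (intercept at spring,
#'   bright, PCV 25%): pH 7.59 with quiet -0.19, summer -0.13, fall +0.09,
#'   PCV slope -0.008/%; pO2 66 mmHg with quiet -9.3, PCV -0.8; pCO2 24.7
#'   mmHg with quiet +15, summer +10, fall -7.5, PCV +0.6; lactate 5.38
#'   mmol/l with summer +2.36, fall -0.36, PCV +0.12 (floored at 0.1).
#'   Residual SDs (0.11, 17, 9, 2.2) are backed out from field marginal SDs
#'   at top-model adjusted R-squared of roughly 0.12-0.62.
#' * Bicarbonate and total CO2 are not independently simulated: they derive
#'   from pH/pCO2 via Henderson-Hasselbalch, and base excess is
#'   HCO3 - 24.8 plus Gaussian noise (SD `be_sd`), preserving the
#'   metabolic-axis correlation.
#' * Missingness (analyzer errors and field omissions): activity 4%, PCV 2%,
#'   BE 2%, lactate 1%. Pathologic outliers: 3% of animals displaced by
#'   `magnitude` (8) residual SDs in at least `n_analytes` (2) analytes.
#' * Exam findings: benign codes (e.g. healed carapacial lesions) at 12%,
#'   active-disease codes at 3%.
#'
#' @param ... Named overrides for any config element.
#' @param seed Optional integer seed stored in the config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(..., seed = NULL) {
  cfg <- list(
    n_per_season = c(spring = 40L, summer = 42L, fall = 20L),
    ta_mean = c(spring = 19.0, summer = 24.47, fall = 16.65),
    ta_sd = 2.5,
    p_quiet = 0.673,
    pcv_ref = 25,
    pcv_model = list(intercept = 21.7,
                     season_offsets = c(spring = 0, summer = 7, fall = 2.3),
                     ta_slope = 0.1, ta_center = 20, sd = 7),
    analyte_models = list(
      ph = list(intercept = 7.59,
                season_offsets = c(spring = 0, summer = -0.13, fall = 0.09),
                quiet_offset = -0.19, pcv_slope = -0.008, sd = 0.11),
      po2 = list(intercept = 66,
                 season_offsets = c(spring = 0, summer = 0, fall = 0),
                 quiet_offset = -9.3, pcv_slope = -0.8, sd = 17),
      pco2 = list(intercept = 24.7,
                  season_offsets = c(spring = 0, summer = 10, fall = -7.5),
                  quiet_offset = 15, pcv_slope = 0.6, sd = 9),
      lactate = list(intercept = 5.38,
                     season_offsets = c(spring = 0, summer = 2.36, fall = -0.36),
                     quiet_offset = 0, pcv_slope = 0.12, sd = 2.2)
    ),
    be_sd = 1.0,
    missing_rates = c(activity = 0.04, pcv_pct = 0.02, be_i = 0.02,
                      lactate_i = 0.01),
    outlier = list(rate = 0.03, magnitude = 8, n_analytes = 2L),
    p_benign_lesion = 0.12,
    p_active_lesion = 0.03,
    seed = seed
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    stop("sim_config(): unknown option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", paste(x$n_per_season, collapse = "/"),
      "(spring/summer/fall), seed =",
      if (is.null(x$seed)) "unset" else x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Simulates per-animal records under the configured linear effect
#' structure. True analyte values are generated on the temperature-corrected
#' (animal-temperature) scale; bicarbonate and total CO2 derive from pH and
#' pCO2 via Henderson-Hasselbalch, base excess from bicarbonate; the
#' analyzer-scale (37 degrees C) panel is obtained by exact algebraic
#' inversion of the correction formulae ([invert_panel()]), so correcting
#' the generated instrument panel recovers the true values to machine
#' precision. Fully deterministic given the seed.
#'
#' True corrected values are attached as `*_true` columns for oracle use and
#' are not part of the cohort CSV schema.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; overrides `config$seed`. One of the two must be
#'   supplied.
#' @return Cohort tibble: [cohort_schema()] columns plus `ph_c_true`,
#'   `po2_c_true`, `pco2_c_true`, `hco3_c_true`, `tco2_c_true`, `be_true`,
#'   `lactate_true`.
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) {
    stop("generate_cohort(): an explicit seed is required (config$seed or ",
         "seed argument).", call. = FALSE)
  }
  with_local_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  stopifnot(all(config$n_per_season >= 0))
  season <- rep(names(config$n_per_season), times = config$n_per_season)
  n <- length(season)
  ta <- rnorm(n, config$ta_mean[season], config$ta_sd)
  activity <- ifelse(runif(n) < config$p_quiet, "quiet", "bright")
  pm <- config$pcv_model
  pcv <- pm$intercept + pm$season_offsets[season] +
    pm$ta_slope * (ta - pm$ta_center) + rnorm(n, 0, pm$sd)
  pcv <- pmin(pmax(pcv, 1), 60)

  truth <- function(m) {
    m$intercept + m$season_offsets[season] +
      m$quiet_offset * (activity == "quiet") +
      m$pcv_slope * (pcv - config$pcv_ref) + rnorm(n, 0, m$sd)
  }
  am <- config$analyte_models
  ph_c <- truth(am$ph)
  po2_c <- pmax(truth(am$po2), 1)
  pco2_c <- pmax(truth(am$pco2), 1)
  lactate <- pmax(truth(am$lactate), 0.1)
  alpha <- alpha_co2(ta)
  pka <- pka_co2(ph_c, ta)
  hco3_c <- hco3_from_hh(alpha, pco2_c, ph_c, pka)
  tco2_c <- tco2_from_hh(hco3_c, alpha, pco2_c)
  be <- hco3_c - 24.8 + rnorm(n, 0, config$be_sd)

  # demographics: nuisance fields, not part of the generating effect model
  state <- sample(c("il", "tn"), n, replace = TRUE, prob = c(0.6, 0.4))
  site <- ifelse(state == "il",
                 sample(c("middle_fork", "kickapoo", "forest_glen"), n, TRUE),
                 "oak_ridge")
  sex <- sample(c("male", "female", "unknown"), n, TRUE, prob = c(0.5, 0.42, 0.08))
  age_class <- sample(c("adult", "juvenile"), n, TRUE, prob = c(0.92, 0.08))
  mass_g <- pmax(rnorm(n, 429, 143), 41)
  u <- runif(n)
  health_flags <- ifelse(
    u < config$p_active_lesion,
    sample(default_active_codes(), n, TRUE),
    ifelse(u < config$p_active_lesion + config$p_benign_lesion,
           sample(c("carapace_lesion_healed", "asymmetrical_nares",
                    "plastron_lesion_healed"), n, TRUE),
           "")
  )

  truth_tbl <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    state = state, site = site, season = season, sex = sex,
    age_class = age_class, mass_g = mass_g, activity = activity,
    pcv_pct = pcv, ta_c = ta, health_flags = health_flags,
    ph_c = ph_c, po2_c = po2_c, pco2_c = pco2_c,
    hco3_c = hco3_c, tco2_c = tco2_c, be = be, lactate = lactate
  )
  inst <- invert_panel(truth_tbl)
  out <- inst[c(cohort_schema())]
  out$ph_c_true <- ph_c
  out$po2_c_true <- po2_c
  out$pco2_c_true <- pco2_c
  out$hco3_c_true <- hco3_c
  out$tco2_c_true <- tco2_c
  out$be_true <- be
  out$lactate_true <- lactate
  out
}

#' Inject analyzer missingness and pathologic outliers
#'
#' Emulates the data artifacts seen in field panels: each configured field
#' is independently blanked with its missing rate (analyzer errors, missed
#' measurements), and a fraction of animals receive a pathologic
#' disturbance — at least `n_analytes` analyzer analytes displaced by
#' plus/minus `magnitude` residual SDs — which the multi-analyte outlier
#' screen should later exclude.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param config The [sim_config()] used for generation.
#' @param seed Integer seed (required for reproducibility).
#' @return The cohort with artifacts applied and attributes
#'   `injection_log` (tibble: `id`, `analyte`, `delta`) and `missing_log`
#'   (tibble: `id`, `field`).
#' @export
inject_artifacts <- function(cohort, config, seed) {
  stopifnot(is.data.frame(cohort))
  with_local_seed(as.integer(seed), {
    out <- tibble::as_tibble(cohort)
    n <- nrow(out)
    missing_log <- list()
    for (field in names(config$missing_rates)) {
      hit <- runif(n) < config$missing_rates[[field]]
      if (any(hit)) {
        out[[field]][hit] <- NA
        missing_log[[field]] <- tibble::tibble(id = out$id[hit], field = field)
      }
    }
    sds <- c(ph_i = config$analyte_models$ph$sd,
             po2_i = config$analyte_models$po2$sd,
             pco2_i = config$analyte_models$pco2$sd,
             lactate_i = config$analyte_models$lactate$sd)
    # displacement directions form a coherent pathologic acidosis picture:
    # low pH and pO2, high pCO2 and lactate (a downward lactate shift would
    # only hit the physiologic floor and mimic a healthy value)
    signs <- c(ph_i = -1, po2_i = -1, pco2_i = 1, lactate_i = 1)
    outlier_rows <- which(runif(n) < config$outlier$rate)
    inj <- list()
    for (i in outlier_rows) {
      cols <- sample(names(sds), config$outlier$n_analytes)
      delta <- signs[cols] * config$outlier$magnitude * sds[cols]
      floors <- c(ph_i = 6.0, po2_i = 0.5, pco2_i = 0.5, lactate_i = 0.1)
      for (j in seq_along(cols)) {
        if (!is.na(out[[cols[j]]][i])) {
          out[[cols[j]]][i] <- max(out[[cols[j]]][i] + delta[j],
                                   floors[[cols[j]]])
        }
      }
      inj[[length(inj) + 1]] <- tibble::tibble(id = out$id[i], analyte = cols,
                                               delta = unname(delta))
    }
    attr(out, "injection_log") <- if (length(inj) > 0) dplyr::bind_rows(inj) else
      tibble::tibble(id = character(), analyte = character(), delta = numeric())
    attr(out, "missing_log") <- if (length(missing_log) > 0)
      dplyr::bind_rows(missing_log) else
      tibble::tibble(id = character(), field = character())
    out
  })
}
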