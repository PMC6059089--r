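#' Cohort CSV schema
#'
#' Column names of the per-animal cohort CSV: identifiers and demographics
#' (`id`, `state`, `site`, `season`, `sex`, `age_class`), physiology
#' (`mass_g`, `activity`, `pcv_pct`, `health_flags`), environment (`ta_c`,
#' mean daily air temperature in degrees C) and the analyzer blood-gas panel
#' measured at 37 degrees C (`ph_i`, `po2_i`, `pco2_i`, `hco3_i`, `tco2_i`,
#' `be_i`, `lactate_i`). Missing values are empty cells; enumerations are
#' stored lowercase; `health_flags` is a semicolon-separated list of exam
#' abnormality codes (empty for an unremarkable exam).
#'
#' @return Character vector of column names in canonical order.
#' @export
cohort_schema <- function() {
  c("id", "state", "site", "season", "sex", "age_class", "mass_g",
    "activity", "pcv_pct", "ta_c", "health_flags",
    "ph_i", "po2_i", "pco2_i", "hco3_i", "tco2_i", "be_i", "lactate_i")
}

cohort_enums <- function() {
  list(season = seasons(),
       sex = c("male", "female", "unknown"),
       age_class = c("adult", "juvenile"),
       activity = c("bright", "quiet"))
}

#' Read a cohort CSV
#'
#' Reads per-animal records in the [cohort_schema()] layout. Empty cells
#' become `NA`; enumeration fields are lowercased and checked against their
#' allowed values; numeric fields are checked for parseability and basic
#' range sanity (PCV in \[0, 100\], temperature within `ta_window`). Rows
#' that violate a constraint are dropped from the returned tibble and
#' collected, with their row numbers and messages, in the `"problems"`
#' attribute (also raised as a warning). A missing schema column is an
#' error naming the column.
#'
#' @param path Path to a CSV file with a header row.
#' @param ta_window Allowed physiologic window for `ta_c`, degrees C.
#' @return A tibble with one row per valid record, columns as in
#'   [cohort_schema()], and attribute `problems` (tibble: `row`, `message`).
#' @export
read_cohort <- function(path, ta_window = c(-10, 45)) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(cohort_schema(), names(raw))
  if (length(missing_cols) > 0) {
    stop("read_cohort(): input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[cohort_schema()]
  n <- nrow(raw)
  problems <- character(n)

  note <- function(rows, msg) {
    problems[rows] <<- ifelse(problems[rows] == "", msg,
                              paste(problems[rows], msg, sep = "; "))
  }

  blank_to_na <- function(x) ifelse(trimws(x) == "", NA_character_, trimws(x))
  out <- tibble::as_tibble(lapply(raw, blank_to_na))

  for (col in names(cohort_enums())) {
    out[[col]] <- tolower(out[[col]])
    allowed <- cohort_enums()[[col]]
    bad <- !is.na(out[[col]]) & !(out[[col]] %in% allowed)
    if (any(bad)) {
      note(which(bad), paste0("invalid ", col, " (allowed: ",
                              paste(allowed, collapse = ", "), ")"))
    }
  }
  for (col in c("mass_g", "pcv_pct", "ta_c",
                analyte_info()$instrument_col)) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- !is.na(out[[col]]) & is.na(parsed)
    if (any(bad)) note(which(bad), paste0("unparseable numeric in ", col))
    out[[col]] <- parsed
  }
  note(which(!is.na(out$pcv_pct) & (out$pcv_pct < 0 | out$pcv_pct > 100)),
       "pcv_pct outside [0, 100]")
  note(which(!is.na(out$ta_c) & (out$ta_c < ta_window[1] | out$ta_c > ta_window[2])),
       paste0("ta_c outside [", ta_window[1], ", ", ta_window[2], "]"))
  note(which(!is.na(out$ph_i) & (out$ph_i <= 0 | out$ph_i >= 14)),
       "ph_i outside (0, 14)")
  for (col in c("po2_i", "pco2_i")) {
    note(which(!is.na(out[[col]]) & out[[col]] < 0),
         paste0(col, " negative"))
  }
  note(which(is.na(out$id)), "missing id")
  note(which(is.na(out$season)), "missing season")

  bad_rows <- which(problems != "")
  prob_tbl <- tibble::tibble(row = bad_rows, message = problems[bad_rows])
  if (length(bad_rows) > 0) {
    warning("read_cohort(): dropped ", length(bad_rows),
            " malformed row(s); see attr(, 'problems').", call. = FALSE)
    out <- out[-bad_rows, ]
  }
  out$health_flags[is.na(out$health_flags)] <- ""
  attr(out, "problems") <- prob_tbl
  out
}

#' Write a report table to CSV
#'
#' Writes any tabular result with a stable column order and documented
#' rounding. Numeric columns are rounded to `digits` decimal places before
#' writing (a single value, or a named vector giving per-column digits);
#' re-reading reproduces the values at the written precision. Missing values
#' are written as empty cells.
#'
#' @param rows Data frame to write.
#' @param path Output file path.
#' @param digits `NULL` for full precision, a single integer, or a named
#'   integer vector (names = column names; unnamed columns keep full
#'   precision).
#' @return `rows` (with rounding applied), invisibly.
#' @export
write_table <- function(rows, path, digits = NULL) {
  stopifnot(is.data.frame(rows))
  out <- tibble::as_tibble(rows)
  if (!is.null(digits)) {
    num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
    if (is.null(names(digits))) {
      for (col in num_cols) out[[col]] <- round(out[[col]], digits)
    } else {
      for (col in intersect(num_cols, names(digits))) {
        out[[col]] <- round(out[[col]], digits[[col]])
      }
    }
  }
  # list-columns (e.g. eligibility reasons) serialized as ';'-joined strings
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], paste, character(1), collapse = ";")
    }
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(out)
}

#' Write a cohort tibble back to CSV
#'
#' Inverse of [read_cohort()] for valid records: columns in schema order,
#' missing values as empty cells, full numeric precision so that
#' read-after-write is the identity.
#'
#' @param cohort Cohort tibble.
#' @param path Output file path.
#' @return The written tibble, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write_table(cohort[intersect(cohort_schema(), names(cohort))], path)
}

#' Default physical-exam codes treated as active disease
#'
#' Animals whose exam carries any of these codes are excluded from the
#' reference-population dataset: open-mouth breathing, the combination of
#' ocular swelling / nasal discharge / diarrhea, necrotic shell fractures,
#' and discharge or oral-plaque findings indicating an active process.
#' Healed shell lesions, asymmetrical nares and similar static findings are
#' deliberately not on the list: they are common in free-living animals and
#' do not indicate active disease.
#'
#' @return Character vector of codes.
#' @export
default_active_codes <- function() {
  c("open_mouth_breathing", "ocular_swelling", "nasal_discharge",
    "diarrhea", "oral_plaques", "necrotic_shell_fracture")
}

split_flags <- function(flags) {
  lapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) trimws(f[trimws(f) != ""]))
}

#' Screen a cohort for active-disease exclusions
#'
#' An animal is ineligible for reference-interval construction when any of
#' its exam abnormality codes is in `active_codes`. Health findings do not
#' by themselves exclude an animal from predictor modelling. Screening is
#' per-animal, hence idempotent and order-independent.
#'
#' @param cohort Cohort data frame with `id` and `health_flags` columns
#'   (semicolon-separated codes, `""` for none).
#' @param active_codes Codes constituting active disease; defaults to
#'   [default_active_codes()].
#' @return A tibble (one row per animal): `id`, `eligible_ri`,
#'   `eligible_model`, `reasons` (list-column of matching codes, empty when
#'   eligible).
#' @export
screen_health <- function(cohort, active_codes = default_active_codes()) {
  stopifnot(is.data.frame(cohort), all(c("id", "health_flags") %in% names(cohort)))
  flags <- split_flags(cohort$health_flags)
  hits <- lapply(flags, function(f) intersect(f, active_codes))
  tibble::tibble(
    id = cohort$id,
    eligible_ri = lengths(hits) == 0,
    eligible_model = TRUE,
    reasons = lapply(hits, function(h) {
      if (length(h) == 0) character(0) else paste0("active_lesion:", h)
    })
  )
}

#' Exclude animals with outliers in multiple analytes
#'
#' Animals flagged as an outlier (by the per-analyte Horn screen, see
#' [flag_analyte_outliers()]) in `threshold` or more analytes are treated as
#' having a genuine pathologic disturbance rather than an isolated aberrant
#' value, and are excluded from both modelling and reference-interval
#' construction. Animals flagged in a single analyte are retained; the lone
#' value is still handled per-analyte downstream.
#'
#' @param flags Long tibble with columns `id`, `analyte`, `outlier`
#'   (logical), as returned by [flag_analyte_outliers()].
#' @param threshold Minimum number of flagged analytes for exclusion
#'   (default 2).
#' @return A tibble (one row per animal): `id`, `eligible_ri`,
#'   `eligible_model`, `n_flagged`, `reasons` (list-column).
#' @export
screen_multi_analyte_outliers <- function(flags, threshold = 2) {
  stopifnot(is.data.frame(flags),
            all(c("id", "analyte", "outlier") %in% names(flags)))
  per_id <- flags |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_flagged = sum(.data$outlier, na.rm = TRUE),
      flagged_analytes = list(.data$analyte[which(.data$outlier)]),
      .groups = "drop"
    )
  excluded <- per_id$n_flagged >= threshold
  tibble::tibble(
    id = per_id$id,
    eligible_ri = !excluded,
    eligible_model = !excluded,
    n_flagged = per_id$n_flagged,
    reasons = mapply(function(excl, a) {
      if (excl) paste0("multi_analyte_outlier:", a) else character(0)
    }, excl = excluded, a = per_id$flagged_analytes, SIMPLIFY = FALSE,
    USE.NAMES = FALSE)
  )
}

#' Per-analyte outlier flags over a corrected cohort
#'
#' Runs [horn_outliers()] analyte-wise over the whole corrected cohort
#' (missing values dropped per analyte) and returns one row per animal and
#' analyte, for use by [screen_multi_analyte_outliers()].
#'
#' @param corrected Corrected cohort tibble (see [correct_panel()]) with an
#'   `id` column.
#' @param analytes Analytes to screen; default all seven.
#' @return Long tibble: `id`, `analyte`, `value`, `outlier` (logical; `NA`
#'   where the value is missing).
#' @export
flag_analyte_outliers <- function(corrected, analytes = blood_gas_analytes()) {
  stopifnot(is.data.frame(corrected), "id" %in% names(corrected))
  purrr::map_dfr(analytes, function(a) {
    col <- corrected_col(a)
    if (!col %in% names(corrected)) {
      stop("flag_analyte_outliers(): corrected column '", col,
           "' not found; run correct_panel() first.", call. = FALSE)
    }
    x <- corrected[[col]]
    keep <- !is.na(x)
    flag <- rep(NA, length(x))
    if (sum(keep) >= 3) {
      scr <- horn_outliers(x[keep])
      flag[keep] <- scr$is_outlier
    } else if (sum(keep) > 0) {
      flag[keep] <- FALSE
    }
    tibble::tibble(id = corrected$id, analyte = a, value = x, outlier = flag)
  })
}

#' Combined eligibility over health and multi-analyte outlier screens
#'
#' Merges [screen_health()] and [screen_multi_analyte_outliers()] into one
#' eligibility report per animal. An animal is eligible for a stage only if
#' every screen passes it for that stage; reasons accumulate.
#'
#' @param corrected Corrected cohort tibble with `id` and `health_flags`.
#' @inheritParams screen_health
#' @inheritParams screen_multi_analyte_outliers
#' @return Eligibility tibble: `id`, `eligible_ri`, `eligible_model`,
#'   `reasons` (list-column).
#' @export
screen_cohort <- function(corrected, active_codes = default_active_codes(),
                          threshold = 2) {
  health <- screen_health(corrected, active_codes)
  outl <- screen_multi_analyte_outliers(flag_analyte_outliers(corrected),
                                        threshold = threshold)
  merged <- dplyr::left_join(
    health,
    outl |> dplyr::select("id", out_ri = "eligible_ri",
                          out_model = "eligible_model", out_reasons = "reasons"),
    by = "id"
  )
  tibble::tibble(
    id = merged$id,
    eligible_ri = merged$eligible_ri & merged$out_ri,
    eligible_model = merged$eligible_model & merged$out_model,
    reasons = mapply(function(a, b) c(a, b), merged$reasons, merged$out_reasons,
                     SIMPLIFY = FALSE)
  )
}
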