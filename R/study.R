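PATIENT_COLUMNS <- c("id", "age", "sex", "alps_ipsi", "alps_contra",
                     "tumor_adc", "event", "tumor_type", "details",
                     "tumor_location", "tumor_side", "ptbe", "roi_in_ptbe",
                     "included")
CONTROL_COLUMNS <- c("id", "sex", "age", "alps_right", "alps_left",
                     "matched_patients")

#' Load a per-subject cohort table
#'
#' Reads and validates a patients or controls CSV in the packaged fixture
#' schema (see the extdata README): typed columns, unique ids, controlled
#' category vocabularies, adult ages, and — for patients — both hemisphere
#' ALPS values present exactly on included rows.
#'
#' @param file CSV path
#' @param role `"patients"` or `"controls"`
#' @return a tibble of subject records (class `alps_subjects`)
#' @export
load_subject_table <- function(file, role = c("patients", "controls")) {
  role <- match.arg(role)
  tab <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  want <- if (role == "patients") PATIENT_COLUMNS else CONTROL_COLUMNS
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("schema mismatch: missing column(s) %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  tab <- tab[want]
  if (anyDuplicated(tab$id)) abort("duplicate subject ids.")
  if (any(tab$age < 18)) abort("subjects must be adults (age >= 18).")
  if (!all(tab$sex %in% c("male", "female"))) {
    abort("invalid category token in `sex`.")
  }
  if (role == "patients") {
    vocab <- list(
      event = c("first_diagnosis", "local_recurrence", "distance_recurrence"),
      tumor_type = c("primary", "metastasis"),
      tumor_side = c("left", "right", "intraventricular"),
      ptbe = c("yes", "no")
    )
    for (col in names(vocab)) {
      if (!all(tab[[col]] %in% vocab[[col]])) {
        abort(sprintf("invalid category token in `%s`.", col))
      }
    }
    has_both <- is.finite(tab$alps_ipsi) & is.finite(tab$alps_contra)
    if (any(tab$included & !has_both)) {
      abort("included patients must carry both hemisphere ALPS values.")
    }
    if (any(!tab$included & (is.finite(tab$alps_ipsi) |
                               is.finite(tab$alps_contra)))) {
      abort("excluded patients must have empty ALPS cells.")
    }
  }
  class(tab) <- c("alps_subjects", class(tab))
  attr(tab, "role") <- role
  tab
}

#' Packaged cohort tables
#'
#' The study's per-subject records: 30 consecutive brain-tumor patients
#' (24 included) and 12 sex/age-matched healthy controls.
#'
#' @return a validated `alps_subjects` tibble
#' @export
alps_patients <- function() {
  load_subject_table(
    system.file("extdata", "table1_patients.csv", package = "alpsdti",
                mustWork = TRUE),
    role = "patients"
  )
}

#' @rdname alps_patients
#' @export
alps_controls <- function() {
  load_subject_table(
    system.file("extdata", "table2_controls.csv", package = "alpsdti",
                mustWork = TRUE),
    role = "controls"
  )
}

included_patients <- function(patients) {
  dplyr::filter(patients, .data$included)
}

#' Ipsi- vs contralateral hemisphere comparison
#'
#' Descriptives of the ALPS index per hemisphere over included patients
#' plus the paired Wilcoxon signed-rank test on (ipsi, contra). When every
#' pair is tied the test is not computable and is reported as such.
#'
#' @param patients an `alps_subjects` patients table
#' @return list with `descriptives` (tibble, one row per hemisphere),
#'   `test` (`alps_test` or NULL) and `note`
#' @export
run_hemisphere_comparison <- function(patients) {
  inc <- included_patients(patients)
  if (nrow(inc) < 2) abort("need at least 2 included patients.")
  desc <- dplyr::bind_rows(
    dplyr::mutate(describe(inc$alps_ipsi), hemisphere = "tumor_ipsilateral"),
    dplyr::mutate(describe(inc$alps_contra), hemisphere = "tumor_contralateral")
  )
  desc <- dplyr::relocate(desc, "hemisphere")
  test <- tryCatch(wilcoxon_signed_rank(inc$alps_ipsi, inc$alps_contra),
                   error = function(e) NULL)
  list(
    descriptives = desc, test = test,
    note = if (is.null(test)) "no difference computable (all pairs tied)"
           else NA_character_
  )
}

#' Subgroup comparisons of the ipsilateral ALPS index
#'
#' Splits included patients by age (strictly < `age_cut` vs strictly >
#' `age_cut`; subjects exactly at the cut belong to neither group), sex,
#' tumor type, and whether the ipsilateral ROIs lay inside peritumoral
#' edema, then reports per-group descriptives of the ipsilateral index and
#' a Mann-Whitney U test per split. The ipsilateral index is used for all
#' splits, consistent with the per-group means of the cohort report.
#'
#' @param patients an `alps_subjects` patients table
#' @param age_cut years (default 55)
#' @return list with `descriptives` (tibble: parameter, level, n, mean,
#'   sd, median, q1, q3) and `tests` (tibble: parameter, p_two_sided, ...)
#' @export
run_group_comparisons <- function(patients, age_cut = 55) {
  inc <- included_patients(patients)
  splits <- list(
    age = list(
      levels = c(sprintf("< %g", age_cut), sprintf("> %g", age_cut)),
      groups = list(inc$alps_ipsi[inc$age < age_cut],
                    inc$alps_ipsi[inc$age > age_cut])
    ),
    sex = list(
      levels = c("male", "female"),
      groups = list(inc$alps_ipsi[inc$sex == "male"],
                    inc$alps_ipsi[inc$sex == "female"])
    ),
    tumor_type = list(
      levels = c("primary", "metastasis"),
      groups = list(inc$alps_ipsi[inc$tumor_type == "primary"],
                    inc$alps_ipsi[inc$tumor_type == "metastasis"])
    ),
    roi_in_ptbe = list(
      levels = c("inside_ptbe", "outside_ptbe"),
      groups = list(inc$alps_ipsi[inc$roi_in_ptbe],
                    inc$alps_ipsi[!inc$roi_in_ptbe])
    )
  )
  desc <- purrr::imap(splits, function(sp, nm) {
    purrr::map2(sp$levels, sp$groups, function(lv, g) {
      if (length(g) == 0) abort(sprintf("empty group '%s' in split '%s'.", lv, nm))
      dplyr::mutate(describe(g, require_sd = FALSE),
                    parameter = nm, level = lv)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows() |> dplyr::relocate("parameter", "level")
  tests <- purrr::imap(splits, function(sp, nm) {
    dplyr::mutate(tidy(mann_whitney_u(sp$groups[[1]], sp$groups[[2]])),
                  parameter = nm)
  }) |> dplyr::bind_rows() |> dplyr::relocate("parameter")
  list(descriptives = desc, tests = tests)
}

#' ALPS index regressions
#'
#' The three linear regressions of the study: ipsilateral index on age,
#' contralateral index on age, and ipsilateral index on tumor ADC, over
#' included patients.
#'
#' @param patients an `alps_subjects` patients table
#' @return tibble: response, predictor, n, slope, intercept, r_squared,
#'   p_slope
#' @export
run_regressions <- function(patients) {
  inc <- included_patients(patients)
  specs <- list(
    list(response = "alps_ipsi", predictor = "age"),
    list(response = "alps_contra", predictor = "age"),
    list(response = "alps_ipsi", predictor = "tumor_adc")
  )
  purrr::map(specs, function(sp) {
    fit <- linear_regression(inc[[sp$predictor]], inc[[sp$response]])
    tibble(response = sp$response, predictor = sp$predictor, n = fit$n,
           slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared, p_slope = fit$p_slope)
  }) |> dplyr::bind_rows()
}

#' Healthy-control summary
#'
#' Descriptives of the right/left hemisphere index and age over the
#' control table, plus the paired right-vs-left signed-rank test.
#'
#' @param controls an `alps_subjects` controls table
#' @return list with `descriptives` and `test`
#' @export
run_control_summary <- function(controls) {
  desc <- dplyr::bind_rows(
    dplyr::mutate(describe(controls$alps_right), measure = "alps_right"),
    dplyr::mutate(describe(controls$alps_left), measure = "alps_left"),
    dplyr::mutate(describe(controls$age), measure = "age")
  ) |> dplyr::relocate("measure")
  test <- tryCatch(wilcoxon_signed_rank(controls$alps_right, controls$alps_left),
                   error = function(e) NULL)
  list(descriptives = desc, test = test)
}

#' Patient vs matched-control comparison
#'
#' Matches each included patient to a control ([match_controls()]), picks
#' the control hemisphere per `hemisphere_rule`, and runs the paired
#' signed-rank test against the chosen patient hemisphere. The cohort
#' report's own hemisphere convention is unstated, so its printed
#' matched-HC means/p-values are not reproduced claims; the rule stays
#' explicit here.
#'
#' @param patients,controls `alps_subjects` tables
#' @param side patient hemisphere, `"ipsi"` or `"contra"`
#' @param hemisphere_rule,tolerance_years see [match_controls()]
#' @return list with `pairs` (tibble), `patient_mean`, `control_mean`,
#'   `test`
#' @export
run_matched_comparison <- function(patients, controls,
                                   side = c("ipsi", "contra"),
                                   hemisphere_rule = "tumor_side",
                                   tolerance_years = 2) {
  side <- match.arg(side)
  inc <- included_patients(patients)
  asg <- match_controls(inc, controls, tolerance_years, hemisphere_rule)
  ctrl <- controls[match(asg$control_id, controls$id), ]
  pat <- inc[match(asg$patient_id, inc$id), ]
  control_value <- switch(hemisphere_rule,
    fixed_left = ctrl$alps_left,
    fixed_right = ctrl$alps_right,
    tumor_side = ifelse(pat$tumor_side == "right",
                        ctrl$alps_right, ctrl$alps_left)
  )
  patient_value <- if (side == "ipsi") pat$alps_ipsi else pat$alps_contra
  pairs <- tibble(
    patient_id = pat$id, control_id = ctrl$id,
    patient_alps = patient_value, control_alps = control_value
  )
  list(
    pairs = pairs,
    patient_mean = mean(patient_value), control_mean = mean(control_value),
    test = wilcoxon_signed_rank(patient_value, control_value)
  )
}

#' Run the full study
#'
#' Cohort counts, hemisphere comparison, subgroup comparisons, regressions
#' and the control summary over the packaged (or any schema-compatible)
#' tables. Fully deterministic: repeated runs on the same inputs produce
#' identical reports.
#'
#' @param patients,controls `alps_subjects` tables (default: the packaged
#'   fixtures)
#' @param age_cut subgroup age dichotomy (default 55)
#' @return an `alps_study_report` (list of sections)
#' @export
run_study <- function(patients = alps_patients(), controls = alps_controls(),
                      age_cut = 55) {
  inc <- included_patients(patients)
  counts <- tibble(
    n_total = nrow(patients), n_included = nrow(inc),
    n_male = sum(inc$sex == "male"), n_female = sum(inc$sex == "female"),
    n_primary = sum(inc$tumor_type == "primary"),
    n_metastasis = sum(inc$tumor_type == "metastasis"),
    n_controls = if (is.null(controls)) 0L else nrow(controls)
  )
  structure(
    list(
      counts = counts,
      demographics = dplyr::bind_rows(
        dplyr::mutate(describe(inc$age), measure = "patient_age"),
        dplyr::mutate(describe(inc$tumor_adc), measure = "tumor_adc")
      ) |> dplyr::relocate("measure"),
      hemisphere = run_hemisphere_comparison(patients),
      groups = run_group_comparisons(patients, age_cut = age_cut),
      regressions = run_regressions(patients),
      controls = if (is.null(controls)) NULL else run_control_summary(controls)
    ),
    class = "alps_study_report"
  )
}

#' @export
print.alps_study_report <- function(x, ...) {
  cat("DTI-ALPS study report\n")
  cat(sprintf("  %d/%d patients included (%d male, %d female; %d primary, %d metastasis), %d controls\n",
              x$counts$n_included, x$counts$n_total, x$counts$n_male,
              x$counts$n_female, x$counts$n_primary, x$counts$n_metastasis,
              x$counts$n_controls))
  h <- x$hemisphere$descriptives
  cat(sprintf("  ALPS ipsi %.2f +/- %.2f (median %.2f) vs contra %.2f +/- %.2f (median %.2f)",
              h$mean[1], h$sd[1], h$median[1], h$mean[2], h$sd[2], h$median[2]))
  if (!is.null(x$hemisphere$test)) {
    cat(sprintf(", signed-rank p = %.3g", x$hemisphere$test$p_two_sided))
  }
  cat("\n")
  invisible(x)
}

#' @rdname run_study
#' @param x an `alps_study_report`
#' @param ... unused
#' @method glance alps_study_report
#' @export
glance.alps_study_report <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble(
      ipsi_mean = x$hemisphere$descriptives$mean[1],
      contra_mean = x$hemisphere$descriptives$mean[2],
      hemisphere_p = if (is.null(x$hemisphere$test)) NA_real_
                     else x$hemisphere$test$p_two_sided
    )
  )
}

#' Emit a study report to disk
#'
#' Writes `report.json` (full precision, fixed key order), `report.md`
#' (values rounded to 2 decimals, half away from zero) and the descriptive
#' tables as CSV under `dir`. Byte-identical across re-runs on identical
#' inputs.
#'
#' @param report an `alps_study_report`
#' @param dir destination directory (created if needed)
#' @return `dir`, invisibly
#' @export
emit_report <- function(report, dir) {
  stopifnot(inherits(report, "alps_study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    counts = as.list(report$counts),
    demographics = report$demographics,
    hemisphere = list(
      descriptives = report$hemisphere$descriptives,
      test = if (is.null(report$hemisphere$test)) NULL
             else tidy(report$hemisphere$test),
      note = report$hemisphere$note
    ),
    groups = report$groups,
    regressions = report$regressions,
    controls = if (is.null(report$controls)) NULL else list(
      descriptives = report$controls$descriptives,
      test = if (is.null(report$controls$test)) NULL
             else tidy(report$controls$test)
    )
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", dataframe = "rows", pretty = TRUE)
  readr::write_csv(report$hemisphere$descriptives,
                   file.path(dir, "hemisphere_descriptives.csv"))
  readr::write_csv(report$groups$descriptives,
                   file.path(dir, "group_descriptives.csv"))
  readr::write_csv(report$groups$tests, file.path(dir, "group_tests.csv"))
  readr::write_csv(report$regressions, file.path(dir, "regressions.csv"))
  writeLines(format_report_md(report), file.path(dir, "report.md"))
  invisible(dir)
}

format_report_md <- function(report) {
  r2 <- function(x) sprintf("%.2f", round_half_away(x, 2))
  h <- report$hemisphere$descriptives
  lines <- c(
    "# DTI-ALPS study report", "",
    sprintf("Included patients: %d of %d (%d male, %d female; %d primary, %d metastasis). Controls: %d.",
            report$counts$n_included, report$counts$n_total,
            report$counts$n_male, report$counts$n_female,
            report$counts$n_primary, report$counts$n_metastasis,
            report$counts$n_controls),
    "",
    "| Parameter | n | Mean ± sd | Median (Q1, Q3) | p |",
    "|---|---|---|---|---|",
    sprintf("| Hemisphere | | | | %s |",
            if (is.null(report$hemisphere$test)) report$hemisphere$note
            else sprintf("%.3g", report$hemisphere$test$p_two_sided)),
    sprintf("| – %s | %d | %s ± %s | %s (%s, %s) | |",
            h$hemisphere, h$n, r2(h$mean), r2(h$sd), r2(h$median),
            r2(h$q1), r2(h$q3))
  )
  g <- report$groups$descriptives
  t <- report$groups$tests
  for (pm in unique(g$parameter)) {
    gp <- g[g$parameter == pm, ]
    lines <- c(
      lines,
      sprintf("| %s | | | | %.3g |", pm,
              t$p_two_sided[t$parameter == pm]),
      sprintf("| – %s | %d | %s ± %s | %s (%s, %s) | |",
              gp$level, gp$n, r2(gp$mean), r2(gp$sd), r2(gp$median),
              r2(gp$q1), r2(gp$q3))
    )
  }
  reg <- report$regressions
  lines <- c(
    lines, "",
    "## Regressions", "",
    sprintf("- %s ~ %s: slope %.3g, R² %.3g, p %.3g",
            reg$response, reg$predictor, reg$slope, reg$r_squared,
            reg$p_slope)
  )
  lines
}
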