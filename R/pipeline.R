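# Cohort IO and the end-to-end study pipeline:
# read-or-simulate -> score -> evaluate -> report.

#' Read a cohort CSV
#'
#' One row per patient, header exactly the [cohort_fields()] names; flag
#' columns as 0/1 (or TRUE/FALSE), `guarding_grade` as
#' none/light/medium/strong, `histopathology` as the four-level label or
#' empty. Unknown columns are ignored with a warning; invalid values are
#' aggregated across all rows into one error naming every offending row and
#' field.
#'
#' @param path CSV path.
#' @param require_histopathology require a complete histopathology column
#'   (needed for evaluation).
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path, require_histopathology = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), cohort_fields())
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  if ("histopathology" %in% names(df)) {
    df$histopathology[!is.na(df$histopathology) &
                        df$histopathology == ""] <- NA_character_
  }
  df <- validate_cohort(df, require_histopathology = require_histopathology)
  df[, intersect(cohort_fields(), names(df))]
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: flags are serialised as 0/1 so the file
#' round-trips exactly.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  for (f in intersect(.flag_fields, names(out))) {
    out[[f]] <- as.integer(out[[f]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Study run configuration
#'
#' @param scoring a [scoring_config()].
#' @param dialect display-rounding dialect for rendered tables.
#' @param boot_reps bootstrap resamples for AUC-difference intervals
#'   (0 disables them).
#' @param seed seed for the bootstrap.
#' @return list of class `run_config`.
#' @export
run_config <- function(scoring = scoring_config(), dialect = "half_up",
                       boot_reps = 0, seed = 20220101) {
  structure(list(scoring = scoring, dialect = dialect,
                 boot_reps = boot_reps, seed = seed), class = "run_config")
}

#' Read a run configuration from a JSON key-value file
#'
#' Flat JSON object whose keys are the [scoring_config()] arguments
#' (thresholds, cutoffs, strictness switches) and/or the [run_config()]
#' arguments `dialect`, `boot_reps`, `seed`. Unknown keys warn and are
#' ignored; anything not given keeps its default.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_keys <- names(formals(scoring_config))
  run_keys <- c("dialect", "boot_reps", "seed")
  unknown <- setdiff(names(raw), c(score_keys, run_keys))
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  scoring <- do.call(scoring_config, raw[intersect(names(raw), score_keys)])
  do.call(run_config, c(list(scoring = scoring),
                        raw[intersect(names(raw), run_keys)]))
}

#' Run the full diagnostic-accuracy study on a cohort
#'
#' Scores every patient with all three systems, evaluates each against the
#' histopathology gold standard (confusion matrix, the eight summary
#' metrics, empirical AUC), and collects pairwise AUC differences, pairwise
#' Pearson correlations of the raw scores, the histology breakdown and the
#' negative-appendectomy rate into one report. All metrics are stored at
#' full precision; display rounding is applied only when the report is
#' printed or rendered to a table, so rounding ambiguity cannot creep into
#' the report itself. Deterministic given cohort + config (the bootstrap is
#' seeded).
#'
#' @param cohort cohort data.frame with complete histopathology labels.
#' @param config a [run_config()].
#' @return object of class `study_report`.
#' @export
run_study <- function(cohort, config = run_config()) {
  cohort <- validate_cohort(cohort, require_histopathology = TRUE)
  labels <- histo_positive(cohort$histopathology)
  if (all(labels) || all(!labels)) {
    stop("cohort must contain both histopathology-positive and -negative ",
         "patients", call. = FALSE)
  }
  scored <- score_cohort(cohort, config = config$scoring)
  systems <- c("alvarado", "air", "ripasa")

  per_system <- lapply(systems, function(sys) {
    calls <- scored[[paste0(sys, "_positive")]]
    scores <- scored[[paste0(sys, "_score")]]
    cm <- confusion_matrix(calls, labels)
    met <- diagnostic_metrics(cm)
    cut <- system_cutoff(sys, config$scoring)
    list(system = sys, cutoff = cut$cutoff, strict = cut$strict,
         n_positive_calls = sum(calls), confusion = cm, metrics = met,
         auc = roc_auc(scores, labels)$auc,
         score_mean = mean(scores), score_sd = stats::sd(scores))
  })
  names(per_system) <- systems

  pairs <- utils::combn(systems, 2, simplify = FALSE)
  auc_diffs <- lapply(pairs, function(pr) {
    d <- auc_difference(scored[[paste0(pr[1], "_score")]],
                        scored[[paste0(pr[2], "_score")]], labels,
                        boot_reps = config$boot_reps, seed = config$seed)
    c(list(a = pr[1], b = pr[2]), d)
  })
  correlations <- lapply(pairs, function(pr) {
    list(a = pr[1], b = pr[2],
         r = pearson_r(scored[[paste0(pr[1], "_score")]],
                       scored[[paste0(pr[2], "_score")]]))
  })

  histology <- table(factor(cohort$histopathology, levels = .histo_levels))
  structure(list(
    schema_version = "1.0",
    n = nrow(cohort),
    n_pos = sum(labels), n_neg = sum(!labels),
    negative_appendectomy_rate = 100 * mean(!labels),
    histology = as.list(as.integer(histology)) |>
      stats::setNames(names(histology)),
    systems = per_system,
    auc_differences = auc_diffs,
    correlations = correlations,
    dialect = config$dialect
  ), class = "study_report")
}

#' Render a report's per-system metrics as a display table
#'
#' @param report a `study_report`.
#' @return data.frame, one row per system, display-rounded (half-up, one
#'   decimal for percentages, two for ratios, three for AUC).
#' @export
report_table <- function(report) {
  rows <- lapply(report$systems, function(s) {
    r <- round_metrics(s$metrics, report$dialect)
    data.frame(system = s$system, cutoff = s$cutoff,
               sensitivity = r[["sensitivity"]], specificity = r[["specificity"]],
               ppv = r[["ppv"]], npv = r[["npv"]],
               plr = r[["plr"]], nlr = r[["nlr"]],
               auc = apply_rounding(s$auc, 3, report$dialect),
               accuracy = r[["accuracy"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("cohort n=%d: %d positive, %d negative (negative appendectomy %.1f%%)\n",
              x$n, x$n_pos, x$n_neg,
              round_half_up(x$negative_appendectomy_rate, 1)))
  print(report_table(x))
  for (co in x$correlations) {
    cat(sprintf("Pearson r(%s, %s) = %.2f\n", co$a, co$b,
                round_half_up(co$r, 2)))
  }
  invisible(x)
}

#' Write a study report as JSON
#'
#' Full-precision JSON (no display rounding): the stored percentages carry
#' all digits and [report_table()] is the only place rounding happens.
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$systems <- lapply(out$systems, function(s) {
    s$confusion <- unclass(s$confusion)
    s$metrics <- c(unclass(s$metrics)[c("sensitivity", "specificity", "ppv",
                                        "npv", "accuracy", "plr", "nlr")],
                   list(undefined = attr(s$metrics, "undefined")))
    s
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Audit a report's own cells against its own confusion matrix
#'
#' Self-consistency check: rebuilds a [reported_row()] from the report's
#' display-rounded cells and runs [audit_row()] on it. Because the report
#' rounds only at render time, every cell must come back `match`.
#'
#' @param report a `study_report`.
#' @param system which system's row to audit.
#' @return an `audit_report`.
#' @export
self_audit <- function(report, system = "alvarado") {
  s <- report$systems[[system]]
  r <- round_metrics(s$metrics, report$dialect)
  row <- reported_row(system, s$cutoff,
                      sensitivity = r[["sensitivity"]],
                      specificity = r[["specificity"]],
                      n_pos = report$n_pos, n_neg = report$n_neg,
                      ppv = r[["ppv"]], npv = r[["npv"]],
                      plr = r[["plr"]], nlr = r[["nlr"]],
                      accuracy = r[["accuracy"]])
  audit_row(row, dialect = report$dialect)
}
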