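# Patient-record schema shared by the scoring, simulation and IO layers.
# One patient = one row of a plain data.frame with these columns.

.flag_fields <- c(
  "migratory_rif_pain", "anorexia", "nausea", "vomiting",
  "nausea_or_vomiting", "rif_pain", "rif_tenderness", "rebound_tenderness",
  "rovsing_sign", "urinalysis_negative", "foreign_national"
)

.numeric_fields <- c(
  "age_years", "temperature_c", "wbc_e9_per_L", "pmn_percent",
  "crp_mg_per_L", "symptom_duration_h"
)

.guarding_levels <- c("none", "light", "medium", "strong")
.histo_levels <- c("acute_inflamed", "gangrenous", "perforated", "negative")
.sex_levels <- c("male", "female")

#' Column names of a patient cohort
#'
#' The canonical column order for a cohort `data.frame`: demographics,
#' symptoms, signs, labs and the optional histopathology label. This is also
#' the header contract of the cohort CSV read by [read_cohort()].
#'
#' @return character vector of column names.
#' @export
cohort_fields <- function() {
  c("age_years", "sex", .flag_fields[1:4], "nausea_or_vomiting",
    .flag_fields[6:9], "guarding_grade", "temperature_c", "wbc_e9_per_L",
    "pmn_percent", "crp_mg_per_L", "urinalysis_negative",
    "symptom_duration_h", "foreign_national", "histopathology")
}

#' Construct a single patient record
#'
#' Builds a one-row cohort `data.frame` describing one patient's presentation:
#' demographics, the symptoms and signs used by the Alvarado, AIR and RIPASA
#' scores, laboratory values, and (optionally) the histopathology label that
#' serves as the diagnostic gold standard.
#'
#' All clinical flags default to `FALSE` and labs to unremarkable values, so a
#' record can be specified by naming only what is present or abnormal.
#' `nausea_or_vomiting` (the RIPASA item) is derived as `nausea | vomiting`
#' unless given explicitly.
#'
#' @param age_years age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param migratory_rif_pain,anorexia,nausea,vomiting,rif_pain,rif_tenderness,rebound_tenderness,rovsing_sign
#'   logical symptom/sign flags.
#' @param nausea_or_vomiting logical; derived from `nausea`/`vomiting` when `NULL`.
#' @param guarding_grade one of `"none"`, `"light"`, `"medium"`, `"strong"`.
#' @param temperature_c body temperature in degrees Celsius.
#' @param wbc_e9_per_L white-cell count, 1e9 cells per litre.
#' @param pmn_percent polymorphonuclear (neutrophil) fraction, percent.
#' @param crp_mg_per_L C-reactive protein, mg/L.
#' @param urinalysis_negative logical; `TRUE` if urinalysis is unremarkable.
#' @param symptom_duration_h duration of symptoms in hours (> 0).
#' @param foreign_national logical RIPASA demographic item.
#' @param histopathology one of `"acute_inflamed"`, `"gangrenous"`,
#'   `"perforated"`, `"negative"`, or `NA` when unknown (scoring does not need it).
#' @return one-row `data.frame` with the [cohort_fields()] columns.
#' @examples
#' p <- patient(age_years = 25, sex = "male", rif_tenderness = TRUE,
#'              wbc_e9_per_L = 14)
#' alvarado_score(p)
#' @export
patient <- function(age_years = 25, sex = "male",
                    migratory_rif_pain = FALSE, anorexia = FALSE,
                    nausea = FALSE, vomiting = FALSE,
                    nausea_or_vomiting = NULL,
                    rif_pain = FALSE, rif_tenderness = FALSE,
                    rebound_tenderness = FALSE, guarding_grade = "none",
                    rovsing_sign = FALSE, temperature_c = 36.8,
                    wbc_e9_per_L = 7, pmn_percent = 60, crp_mg_per_L = 0,
                    urinalysis_negative = TRUE, symptom_duration_h = 24,
                    foreign_national = FALSE, histopathology = NA_character_) {
  if (is.null(nausea_or_vomiting)) nausea_or_vomiting <- nausea | vomiting
  df <- data.frame(
    age_years = age_years, sex = sex,
    migratory_rif_pain = migratory_rif_pain, anorexia = anorexia,
    nausea = nausea, vomiting = vomiting,
    nausea_or_vomiting = nausea_or_vomiting,
    rif_pain = rif_pain, rif_tenderness = rif_tenderness,
    rebound_tenderness = rebound_tenderness, guarding_grade = guarding_grade,
    rovsing_sign = rovsing_sign, temperature_c = temperature_c,
    wbc_e9_per_L = wbc_e9_per_L, pmn_percent = pmn_percent,
    crp_mg_per_L = crp_mg_per_L, urinalysis_negative = urinalysis_negative,
    symptom_duration_h = symptom_duration_h,
    foreign_national = foreign_national, histopathology = histopathology,
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
  df[, cohort_fields()]
}

#' Validate a cohort data frame
#'
#' Checks a cohort against the record invariants (value ranges, enumerations,
#' flag types). Problems across all rows are aggregated into a single error so
#' a malformed file is reported once, with every offending row and field
#' named, rather than failing on the first bad cell. There is deliberately no
#' imputation: the scores are decision rules and silently defaulting a missing
#' item would corrupt any downstream accuracy estimate.
#'
#' @param cohort data.frame of patient records (see [cohort_fields()]).
#' @param require_histopathology if `TRUE`, the histopathology label must be
#'   present and non-missing in every row (needed for evaluation, not scoring).
#' @return the validated cohort, invisibly, with `nausea_or_vomiting` derived
#'   if it was absent.
#' @export
validate_cohort <- function(cohort, require_histopathology = FALSE) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame", call. = FALSE)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)

  if (!"nausea_or_vomiting" %in% names(cohort) &&
      all(c("nausea", "vomiting") %in% names(cohort))) {
    cohort$nausea_or_vomiting <- cohort$nausea | cohort$vomiting
  }

  required <- setdiff(cohort_fields(), "histopathology")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"histopathology" %in% names(cohort)) {
    cohort$histopathology <- NA_character_
  }

  problems <- character(0)
  note <- function(rows, field, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(
        "row %s: field '%s' %s", paste(rows, collapse = ","), field, msg))
    }
  }

  bad_na <- function(x) which(is.na(x))
  for (f in setdiff(required, "sex")) {
    note(bad_na(cohort[[f]]), f, "is missing (no imputation is performed)")
  }
  note(bad_na(cohort$sex), "sex", "is missing (no imputation is performed)")

  for (f in .flag_fields) {
    x <- cohort[[f]]
    if (!is.logical(x)) {
      if (is.numeric(x) && all(x %in% c(0, 1, NA))) {
        cohort[[f]] <- as.logical(x)
      } else {
        note(seq_len(nrow(cohort))[!is.na(x) & !x %in% c(0, 1, TRUE, FALSE)],
             f, "must be logical (or 0/1)")
      }
    }
  }

  ok <- function(x, cond) which(!is.na(x) & !cond)
  note(ok(cohort$age_years, cohort$age_years > 0), "age_years", "must be > 0")
  note(ok(cohort$sex, cohort$sex %in% .sex_levels), "sex",
       "must be 'male' or 'female'")
  note(ok(cohort$guarding_grade, cohort$guarding_grade %in% .guarding_levels),
       "guarding_grade",
       paste0("must be one of ", paste(.guarding_levels, collapse = "/")))
  note(ok(cohort$temperature_c,
          cohort$temperature_c >= 30 & cohort$temperature_c <= 45),
       "temperature_c", "must be in [30,45] degC")
  note(ok(cohort$wbc_e9_per_L, cohort$wbc_e9_per_L >= 0), "wbc_e9_per_L",
       "must be >= 0")
  note(ok(cohort$pmn_percent,
          cohort$pmn_percent >= 0 & cohort$pmn_percent <= 100),
       "pmn_percent", "must be in [0,100]")
  note(ok(cohort$crp_mg_per_L, cohort$crp_mg_per_L >= 0), "crp_mg_per_L",
       "must be >= 0")
  note(ok(cohort$symptom_duration_h, cohort$symptom_duration_h > 0),
       "symptom_duration_h", "must be > 0")
  note(ok(cohort$histopathology, cohort$histopathology %in% .histo_levels),
       "histopathology",
       paste0("must be one of ", paste(.histo_levels, collapse = "/")))
  if (require_histopathology) {
    note(bad_na(cohort$histopathology), "histopathology",
         "is required for evaluation")
  }

  if (length(problems) > 0) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' Disease-positive indicator from histopathology
#'
#' The gold standard: a specimen is disease-positive when histopathology shows
#' acutely inflamed, gangrenous or perforated appendicitis; `"negative"` is a
#' negative appendectomy.
#'
#' @param histopathology character vector of histopathology labels.
#' @return logical vector (`NA` where the label is missing).
#' @export
histo_positive <- function(histopathology) {
  bad <- !is.na(histopathology) & !histopathology %in% .histo_levels
  if (any(bad)) {
    stop("unknown histopathology label(s): ",
         paste(unique(histopathology[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(histopathology), NA,
         histopathology %in% c("acute_inflamed", "gangrenous", "perforated"))
}
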