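# Alvarado, AIR and RIPASA scoring rules.
#
# Each rule is an additive table of item weights over symptoms, signs and
# labs; the per-patient functions return the score, its risk band and the
# binary call at the system's study cutoff. The vectorised internals do the
# arithmetic; the exported single-patient functions wrap them.

#' Scoring configuration
#'
#' Thresholds the published weight tables leave implicit, plus the per-system
#' cutoffs. The Alvarado table names "elevated temperature", "leukocytosis"
#' and "shift to the left" without numeric definitions; the classical
#' thresholds (37.3 degC, 10e9/L WBC, 75% PMN) are the defaults and all are
#' configurable so alternatives can be evaluated. Cutoff strictness encodes
#' whether a call is positive strictly above the cutoff (Alvarado > 7,
#' AIR > 5) or at-or-above it (RIPASA >= 7.5, since 7.5 itself opens the
#' high-probability band).
#'
#' @param alvarado_temp_c Alvarado "elevated temperature" threshold, degC
#'   (score if temperature >= threshold).
#' @param alvarado_wbc Alvarado leukocytosis threshold, 1e9/L (>=).
#' @param alvarado_pmn Alvarado left-shift threshold, percent PMN (>=).
#' @param ripasa_wbc RIPASA leukocytosis threshold, 1e9/L (>=).
#' @param air_temp_c AIR fever threshold, degC (score if temperature > threshold).
#' @param alvarado_cutoff,air_cutoff,ripasa_cutoff per-system cutoff values.
#' @param alvarado_strict,air_strict,ripasa_strict `TRUE` for a strictly-greater
#'   call, `FALSE` for greater-or-equal.
#' @return a list of class `scoring_config`.
#' @export
scoring_config <- function(alvarado_temp_c = 37.3, alvarado_wbc = 10,
                           alvarado_pmn = 75, ripasa_wbc = 10,
                           air_temp_c = 38.5,
                           alvarado_cutoff = 7, alvarado_strict = TRUE,
                           air_cutoff = 5, air_strict = TRUE,
                           ripasa_cutoff = 7.5, ripasa_strict = FALSE) {
  structure(list(
    alvarado_temp_c = alvarado_temp_c, alvarado_wbc = alvarado_wbc,
    alvarado_pmn = alvarado_pmn, ripasa_wbc = ripasa_wbc,
    air_temp_c = air_temp_c,
    alvarado_cutoff = alvarado_cutoff, alvarado_strict = alvarado_strict,
    air_cutoff = air_cutoff, air_strict = air_strict,
    ripasa_cutoff = ripasa_cutoff, ripasa_strict = ripasa_strict
  ), class = "scoring_config")
}

.required_fields <- list(
  alvarado = c("migratory_rif_pain", "anorexia", "nausea", "rif_tenderness",
               "rebound_tenderness", "temperature_c", "wbc_e9_per_L",
               "pmn_percent"),
  air = c("vomiting", "rif_pain", "rebound_tenderness", "guarding_grade",
          "temperature_c", "pmn_percent", "wbc_e9_per_L", "crp_mg_per_L"),
  ripasa = c("sex", "age_years", "rif_pain", "migratory_rif_pain", "anorexia",
             "nausea_or_vomiting", "symptom_duration_h", "rif_tenderness",
             "guarding_grade", "rebound_tenderness", "rovsing_sign",
             "temperature_c", "wbc_e9_per_L", "urinalysis_negative",
             "foreign_national")
)

check_required <- function(cohort, system) {
  fields <- .required_fields[[system]]
  if (!"nausea_or_vomiting" %in% names(cohort) &&
      all(c("nausea", "vomiting") %in% names(cohort))) {
    cohort$nausea_or_vomiting <- cohort$nausea | cohort$vomiting
  }
  for (f in fields) {
    if (!f %in% names(cohort)) {
      stop(system, " score: missing required field '", f, "'", call. = FALSE)
    }
    idx <- which(is.na(cohort[[f]]))
    if (length(idx) > 0) {
      stop(system, " score: field '", f, "' is missing in record(s) ",
           paste(idx, collapse = ","),
           " (missing data are an error, never imputed)", call. = FALSE)
    }
  }
  if ("guarding_grade" %in% fields) {
    bad <- which(!cohort$guarding_grade %in% .guarding_levels)
    if (length(bad) > 0) {
      stop(system, " score: field 'guarding_grade' has invalid value(s) in ",
           "record(s) ", paste(bad, collapse = ","), call. = FALSE)
    }
  }
  cohort
}

# ---- vectorised scorers ----------------------------------------------------

alvarado_score_vec <- function(cohort, config = scoring_config()) {
  p <- check_required(cohort, "alvarado")
  p$migratory_rif_pain * 1 +
    p$anorexia * 1 +
    p$nausea * 1 +
    p$rif_tenderness * 2 +
    p$rebound_tenderness * 1 +
    (p$temperature_c >= config$alvarado_temp_c) * 1 +
    (p$wbc_e9_per_L >= config$alvarado_wbc) * 2 +
    (p$pmn_percent >= config$alvarado_pmn) * 1
}

air_score_vec <- function(cohort, config = scoring_config()) {
  p <- check_required(cohort, "air")
  # graded peritonism: muscular defence medium/strong dominates; light
  # rebound tenderness or light guarding scores 1; mutually exclusive.
  grade <- match(p$guarding_grade, .guarding_levels) - 1L
  peritonism <- pmax(grade, as.integer(p$rebound_tenderness))
  band2 <- function(x, lo, hi) (x >= lo & x < hi) * 1 + (x >= hi) * 2
  p$vomiting * 1 +
    p$rif_pain * 1 +
    pmin(peritonism, 3L) +
    (p$temperature_c > config$air_temp_c) * 1 +
    band2(p$pmn_percent, 70, 85) +
    band2(p$wbc_e9_per_L, 10, 15) +
    band2(p$crp_mg_per_L, 1, 5)
}

ripasa_score_vec <- function(cohort, config = scoring_config()) {
  p <- check_required(cohort, "ripasa")
  ifelse(p$sex == "male", 1.0, 0.5) +
    ifelse(p$age_years < 40, 1.0, 0.5) +
    p$rif_pain * 0.5 +
    p$migratory_rif_pain * 0.5 +
    p$anorexia * 1.0 +
    p$nausea_or_vomiting * 1.0 +
    ifelse(p$symptom_duration_h < 48, 1.0, 0.5) +
    p$rif_tenderness * 1.0 +
    (p$guarding_grade != "none") * 2.0 +
    p$rebound_tenderness * 1.0 +
    p$rovsing_sign * 2.0 +
    (p$temperature_c > 37 & p$temperature_c < 39) * 1.0 +
    (p$wbc_e9_per_L >= config$ripasa_wbc) * 1.0 +
    p$urinalysis_negative * 1.0 +
    p$foreign_national * 1.0
}

positive_call <- function(score, cutoff, strict) {
  if (strict) score > cutoff else score >= cutoff
}

system_cutoff <- function(system, config) {
  list(cutoff = config[[paste0(system, "_cutoff")]],
       strict = config[[paste0(system, "_strict")]])
}

# ---- risk bands ------------------------------------------------------------

#' Risk band of an Alvarado score
#'
#' Below 5 appendicitis is unlikely; 5-7 is suspected; above 7 it is likely.
#'
#' @param score integer Alvarado score(s) in 0..10.
#' @return character vector of bands.
#' @export
alvarado_band <- function(score) {
  stopifnot(all(score >= 0 & score <= 10))
  ifelse(score < 5, "unlikely", ifelse(score <= 7, "suspected", "likely"))
}

#' Risk band of an AIR score
#'
#' 0-4 low probability, 5-8 suspected, 9-12 high probability. The published
#' footnote enumerates 5-7 and 9-12, leaving score 8 unmapped; the original
#' AIR rule places 8 in the intermediate band, which is adopted here so band
#' assignment is total.
#'
#' @param score integer AIR score(s) in 0..12.
#' @return character vector of bands.
#' @export
air_band <- function(score) {
  stopifnot(all(score >= 0 & score <= 12))
  ifelse(score < 5, "low", ifelse(score <= 8, "suspected", "high"))
}

#' Risk band of a RIPASA score
#'
#' Below 5: unlikely (observation). 5-7: low probability (observation and
#' ultrasound). 7.5-11.5: high probability (prepare for appendectomy). 12 and
#' above: appendicitis diagnosis (appendectomy). Scores live on a 0.5-point
#' lattice, so these bands partition every reachable value; the 11.5-12 gap
#' in the published footnote is closed upward (12 opens the top band).
#'
#' @param score RIPASA score(s), multiples of 0.5 in 1.5..16.
#' @return character vector of bands.
#' @export
ripasa_band <- function(score) {
  stopifnot(all(score >= 0 & score <= 16.5))
  ifelse(score < 5, "unlikely",
         ifelse(score < 7.5, "low_probability",
                ifelse(score < 12, "high_probability", "diagnosis")))
}

band_for <- function(system, score) {
  switch(system,
    alvarado = alvarado_band(score),
    air = air_band(score),
    ripasa = ripasa_band(score),
    stop("unknown system: ", system)
  )
}

# ---- per-patient API -------------------------------------------------------

score_result <- function(system, score, band, positive) {
  structure(list(system = system, score = score, band = band,
                 positive = positive), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("%s score: %s  band: %s  call: %s\n",
              toupper(x$system), format(x$score), x$band,
              if (x$positive) "positive" else "negative"))
  invisible(x)
}

one_score <- function(system, vec_fun, p, config) {
  if (!is.data.frame(p)) p <- as.data.frame(p, stringsAsFactors = FALSE)
  if (nrow(p) != 1) stop("expected a single patient record", call. = FALSE)
  s <- vec_fun(p, config)
  cut <- system_cutoff(system, config)
  score_result(system, s, band_for(system, s),
               positive_call(s, cut$cutoff, cut$strict))
}

#' Alvarado score for one patient
#'
#' Ten-point additive rule: migratory pain 1, anorexia 1, nausea 1, right
#' lower-quadrant tenderness 2, rebound tenderness 1, elevated temperature 1,
#' leukocytosis 2, left shift 1. The study cutoff calls appendicitis at a
#' score strictly above 7.
#'
#' @param p a single patient record ([patient()] or a one-row cohort data.frame).
#' @param config a [scoring_config()].
#' @return a `score_result` with the score (integer 0-10), band and binary call.
#' @examples
#' alvarado_score(patient(rif_tenderness = TRUE, wbc_e9_per_L = 14))
#' @export
alvarado_score <- function(p, config = scoring_config()) {
  one_score("alvarado", alvarado_score_vec, p, config)
}

#' AIR (Appendicitis Inflammatory Response) score for one patient
#'
#' Twelve-point rule: vomiting 1, right iliac fossa pain 1, graded peritonism
#' (light rebound/guarding 1, medium defence 2, strong 3), temperature above
#' 38.5 degC 1, PMN fraction 70-84% 1 / 85%+ 2, WBC 10-14.9 1 / 15+ 2, CRP
#' 1-4.9 mg/L 1 / 5+ 2. The study cutoff calls appendicitis strictly above 5.
#'
#' @inheritParams alvarado_score
#' @return a `score_result` with the score (integer 0-12), band and binary call.
#' @export
air_score <- function(p, config = scoring_config()) {
  one_score("air", air_score_vec, p, config)
}

#' RIPASA score for one patient
#'
#' The RIPASA rule sums demographics (sex, age, nationality), symptoms,
#' signs, duration, leukocytosis and urinalysis on a half-point lattice; the
#' three mandatory mutually-exclusive categories (sex, age, duration) make
#' 1.5 the smallest and 16.0 the largest reachable score (the published table
#' prints a nominal total of 17.5). Fever scores only in the open band
#' 37-39 degC. The study cutoff calls appendicitis at 7.5 or more, 7.5 being
#' the lower edge of the high-probability band.
#'
#' @inheritParams alvarado_score
#' @return a `score_result` with the score (multiple of 0.5 in 1.5-16), band
#'   and binary call.
#' @export
ripasa_score <- function(p, config = scoring_config()) {
  one_score("ripasa", ripasa_score_vec, p, config)
}

#' Score a whole cohort
#'
#' Applies the requested scoring systems to every record, in input order, and
#' returns one row per patient with the score, risk band and binary call per
#' system. Records must be complete; a record failing validation aborts the
#' run with its row index.
#'
#' @param cohort cohort data.frame (see [cohort_fields()]).
#' @param systems subset of `c("alvarado","air","ripasa")`.
#' @param config a [scoring_config()].
#' @return data.frame with columns `<system>_score`, `<system>_band`,
#'   `<system>_positive` for each requested system.
#' @export
score_cohort <- function(cohort, systems = c("alvarado", "air", "ripasa"),
                         config = scoring_config()) {
  systems <- match.arg(systems, several.ok = TRUE)
  cohort <- validate_cohort(cohort)
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  funs <- list(alvarado = alvarado_score_vec, air = air_score_vec,
               ripasa = ripasa_score_vec)
  for (sys in systems) {
    s <- funs[[sys]](cohort, config)
    cut <- system_cutoff(sys, config)
    out[[paste0(sys, "_score")]] <- s
    out[[paste0(sys, "_band")]] <- band_for(sys, s)
    out[[paste0(sys, "_positive")]] <- positive_call(s, cut$cutoff, cut$strict)
  }
  out
}
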