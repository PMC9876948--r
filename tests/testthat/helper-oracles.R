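# Independent oracles: deliberately naive re-derivations of each rule,
# written item-by-item from the published weight tables, against which the
# package's vectorised implementations are property-tested.

random_patients <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  flags <- function() sample(c(TRUE, FALSE), n, replace = TRUE)
  data.frame(
    age_years = runif(n, 9, 70),
    sex = sample(c("male", "female"), n, replace = TRUE),
    migratory_rif_pain = flags(), anorexia = flags(), nausea = flags(),
    vomiting = flags(), rif_pain = flags(), rif_tenderness = flags(),
    rebound_tenderness = flags(),
    guarding_grade = sample(c("none", "light", "medium", "strong"), n,
                            replace = TRUE),
    rovsing_sign = flags(),
    temperature_c = runif(n, 35, 41),
    wbc_e9_per_L = runif(n, 2, 30),
    pmn_percent = runif(n, 30, 100),
    crp_mg_per_L = runif(n, 0, 150),
    urinalysis_negative = flags(),
    symptom_duration_h = runif(n, 2, 200),
    foreign_national = flags(),
    histopathology = sample(c("acute_inflamed", "gangrenous", "perforated",
                              "negative"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

oracle_alvarado <- function(p) {
  s <- 0
  if (p$migratory_rif_pain) s <- s + 1
  if (p$anorexia) s <- s + 1
  if (p$nausea) s <- s + 1
  if (p$rif_tenderness) s <- s + 2
  if (p$rebound_tenderness) s <- s + 1
  if (p$temperature_c >= 37.3) s <- s + 1
  if (p$wbc_e9_per_L >= 10) s <- s + 2
  if (p$pmn_percent >= 75) s <- s + 1
  s
}

oracle_air <- function(p) {
  s <- 0
  if (p$vomiting) s <- s + 1
  if (p$rif_pain) s <- s + 1
  if (p$guarding_grade == "strong") {
    s <- s + 3
  } else if (p$guarding_grade == "medium") {
    s <- s + 2
  } else if (p$guarding_grade == "light" || p$rebound_tenderness) {
    s <- s + 1
  }
  if (p$temperature_c > 38.5) s <- s + 1
  if (p$pmn_percent >= 85) s <- s + 2 else if (p$pmn_percent >= 70) s <- s + 1
  if (p$wbc_e9_per_L >= 15) s <- s + 2 else if (p$wbc_e9_per_L >= 10) s <- s + 1
  if (p$crp_mg_per_L >= 5) s <- s + 2 else if (p$crp_mg_per_L >= 1) s <- s + 1
  s
}

oracle_ripasa <- function(p) {
  s <- 0
  s <- s + if (p$sex == "male") 1.0 else 0.5
  s <- s + if (p$age_years < 40) 1.0 else 0.5
  if (p$rif_pain) s <- s + 0.5
  if (p$migratory_rif_pain) s <- s + 0.5
  if (p$anorexia) s <- s + 1.0
  if (p$nausea || p$vomiting) s <- s + 1.0
  s <- s + if (p$symptom_duration_h < 48) 1.0 else 0.5
  if (p$rif_tenderness) s <- s + 1.0
  if (p$guarding_grade != "none") s <- s + 2.0
  if (p$rebound_tenderness) s <- s + 1.0
  if (p$rovsing_sign) s <- s + 2.0
  if (p$temperature_c > 37 && p$temperature_c < 39) s <- s + 1.0
  if (p$wbc_e9_per_L >= 10) s <- s + 1.0
  if (p$urinalysis_negative) s <- s + 1.0
  if (p$foreign_national) s <- s + 1.0
  s
}

# AUC as an exhaustive count over all positive x negative pairs
# (Mann-Whitney convention: ties count one half).
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Second, independently-written reconstruction: tn-outer/tp-inner loop and
# half-up matching expressed as a half-open interval instead of re-rounding.
oracle_reconstruct <- function(sens, spec, n_pos, n_neg) {
  dp_s <- nchar(sub("^[^.]*\\.?", "", format(sens)))
  dp_p <- nchar(sub("^[^.]*\\.?", "", format(spec)))
  in_band <- function(v, r, dp) {
    half <- 0.5 * 10^(-dp)
    v >= r - half - 1e-12 && v < r + half - 1e-12
  }
  out <- list()
  for (tn in 0:n_neg) {
    for (tp in 0:n_pos) {
      if (in_band(100 * tp / n_pos, sens, dp_s) &&
          in_band(100 * tn / n_neg, spec, dp_p)) {
        out[[length(out) + 1]] <- c(tp = tp, fp = n_neg - tn,
                                    fn = n_pos - tp, tn = tn)
      }
    }
  }
  out
}
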