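# The three scoring rules: worked examples from the weight tables, cutoff
# semantics, band maps, and property tests against naive item-sum oracles.

max_alvarado_patient <- function() {
  patient(migratory_rif_pain = TRUE, anorexia = TRUE, nausea = TRUE,
          rif_tenderness = TRUE, rebound_tenderness = TRUE,
          temperature_c = 38.2, wbc_e9_per_L = 14, pmn_percent = 82)
}

test_that("Alvarado worked examples: full table, empty table, partial sums", {
  full <- alvarado_score(max_alvarado_patient())
  expect_identical(full$score, 10)
  expect_identical(full$band, "likely")
  expect_true(full$positive)

  none <- alvarado_score(patient())  # afebrile, normal labs, no findings
  expect_identical(none$score, 0)
  expect_identical(none$band, "unlikely")
  expect_false(none$positive)

  partial <- alvarado_score(patient(rif_tenderness = TRUE, wbc_e9_per_L = 12))
  expect_identical(partial$score, 4)
  expect_identical(partial$band, "unlikely")
})

test_that("AIR worked examples: maximal, empty and hand-summed patients", {
  maximal <- air_score(patient(vomiting = TRUE, rif_pain = TRUE,
                               guarding_grade = "strong", temperature_c = 39,
                               pmn_percent = 90, wbc_e9_per_L = 16,
                               crp_mg_per_L = 60))
  expect_identical(maximal$score, 12)
  expect_identical(maximal$band, "high")
  expect_true(maximal$positive)

  none <- air_score(patient(temperature_c = 36.8, pmn_percent = 60,
                            wbc_e9_per_L = 7, crp_mg_per_L = 0))
  expect_identical(none$score, 0)
  expect_identical(none$band, "low")

  # vomiting 1 + light rebound 1 + WBC 12 (band 1) + CRP 3 (band 1)
  four <- air_score(patient(vomiting = TRUE, rebound_tenderness = TRUE,
                            wbc_e9_per_L = 12, crp_mg_per_L = 3,
                            pmn_percent = 60))
  expect_identical(four$score, 4)
  expect_identical(four$band, "low")
  expect_false(four$positive)
})

test_that("AIR peritonism grade is mutually exclusive and dominated by guarding", {
  light_rebound <- patient(rebound_tenderness = TRUE, pmn_percent = 60)
  strong_and_rebound <- patient(rebound_tenderness = TRUE,
                                guarding_grade = "strong", pmn_percent = 60)
  expect_identical(air_score(light_rebound)$score, 1)
  expect_identical(air_score(strong_and_rebound)$score, 3)
})

test_that("RIPASA worked examples: near-maximal, minimal, exact-cutoff", {
  young_male_all <- patient(
    age_years = 25, sex = "male", rif_pain = TRUE, migratory_rif_pain = TRUE,
    anorexia = TRUE, nausea = TRUE, vomiting = TRUE, symptom_duration_h = 24,
    rif_tenderness = TRUE, guarding_grade = "light", rebound_tenderness = TRUE,
    rovsing_sign = TRUE, temperature_c = 38, wbc_e9_per_L = 14,
    urinalysis_negative = TRUE, foreign_national = FALSE, pmn_percent = 60)
  r <- ripasa_score(young_male_all)
  expect_identical(r$score, 15)
  expect_true(r$positive)

  minimal <- ripasa_score(patient(age_years = 45, sex = "female",
                                  symptom_duration_h = 72,
                                  urinalysis_negative = FALSE,
                                  temperature_c = 36.5, wbc_e9_per_L = 7,
                                  pmn_percent = 60))
  expect_identical(minimal$score, 1.5)
  expect_identical(minimal$band, "unlikely")
  expect_false(minimal$positive)

  # 45-y female >48h (1.5) + anorexia + nausea/vomiting + tenderness +
  # rebound + leukocytosis + negative urinalysis = exactly 7.5
  boundary <- ripasa_score(patient(age_years = 45, sex = "female",
                                   symptom_duration_h = 72, anorexia = TRUE,
                                   nausea = TRUE, rif_tenderness = TRUE,
                                   rebound_tenderness = TRUE,
                                   wbc_e9_per_L = 12, temperature_c = 36.5,
                                   pmn_percent = 60))
  expect_identical(boundary$score, 7.5)
  expect_identical(boundary$band, "high_probability")
  expect_true(boundary$positive)
})

test_that("cutoff semantics: strictly above for Alvarado/AIR, at-or-above for RIPASA", {
  alv7 <- patient(migratory_rif_pain = TRUE, anorexia = TRUE, nausea = TRUE,
                  rif_tenderness = TRUE, wbc_e9_per_L = 12, pmn_percent = 60)
  expect_identical(alvarado_score(alv7)$score, 7)
  expect_false(alvarado_score(alv7)$positive)

  air5 <- patient(vomiting = TRUE, rif_pain = TRUE, rebound_tenderness = TRUE,
                  wbc_e9_per_L = 12, crp_mg_per_L = 3, pmn_percent = 60)
  expect_identical(air_score(air5)$score, 5)
  expect_false(air_score(air5)$positive)
  air6 <- patient(vomiting = TRUE, rif_pain = TRUE, rebound_tenderness = TRUE,
                  wbc_e9_per_L = 12, crp_mg_per_L = 8, pmn_percent = 60)
  expect_identical(air_score(air6)$score, 6)
  expect_true(air_score(air6)$positive)

  cfg <- scoring_config(alvarado_strict = FALSE)
  expect_true(alvarado_score(alv7, cfg)$positive)
})

test_that("missing required fields raise errors naming the field, never impute", {
  p <- patient()
  p$wbc_e9_per_L <- NA_real_
  expect_error(alvarado_score(p), "wbc_e9_per_L")
  expect_error(air_score(p), "wbc_e9_per_L")
  p2 <- patient()
  p2$guarding_grade <- "severe"
  expect_error(air_score(p2), "guarding_grade")
  expect_error(patient(temperature_c = 3.7), "temperature_c")
})

test_that("configurable thresholds move the implicit lab items", {
  p <- patient(wbc_e9_per_L = 9.5)
  expect_identical(alvarado_score(p)$score, 0)
  expect_identical(alvarado_score(p, scoring_config(alvarado_wbc = 9))$score, 2)
  expect_identical(ripasa_score(p, scoring_config(ripasa_wbc = 9))$score,
                   ripasa_score(p)$score + 1)
})

test_that("score_cohort composes the per-patient rules and preserves order", {
  cohort <- rbind(max_alvarado_patient(), patient(), patient(anorexia = TRUE))
  scored <- score_cohort(cohort)
  expect_identical(nrow(scored), 3L)
  expect_identical(scored$alvarado_score,
                   vapply(1:3, function(i) alvarado_score(cohort[i, ])$score,
                          numeric(1)))
  expect_identical(scored$ripasa_score,
                   vapply(1:3, function(i) ripasa_score(cohort[i, ])$score,
                          numeric(1)))
  expect_error(score_cohort(cohort[0, ]), "empty")
  single <- score_cohort(cohort[2, ])
  expect_identical(nrow(single), 1L)
})

test_that("scores match naive item-sum oracles on 1000 random patients", {
  cohort <- random_patients(1000, seed = 42)
  scored <- score_cohort(cohort)
  expect_equal(scored$alvarado_score,
               vapply(seq_len(1000), function(i) oracle_alvarado(cohort[i, ]),
                      numeric(1)))
  expect_equal(scored$air_score,
               vapply(seq_len(1000), function(i) oracle_air(cohort[i, ]),
                      numeric(1)))
  expect_equal(scored$ripasa_score,
               vapply(seq_len(1000), function(i) oracle_ripasa(cohort[i, ]),
                      numeric(1)))
})

test_that("score ranges, lattices and band totality hold on random patients", {
  cohort <- random_patients(500, seed = 7)
  scored <- score_cohort(cohort)
  expect_true(all(scored$alvarado_score %in% 0:10))
  expect_true(all(scored$air_score %in% 0:12))
  expect_true(all(scored$ripasa_score %in% seq(1.5, 16, by = 0.5)))
  expect_true(all(scored$alvarado_band %in% c("unlikely", "suspected", "likely")))
  expect_true(all(scored$air_band %in% c("low", "suspected", "high")))
  expect_true(all(scored$ripasa_band %in%
                    c("unlikely", "low_probability", "high_probability",
                      "diagnosis")))
  # totality over every reachable lattice point
  expect_false(anyNA(alvarado_band(0:10)))
  expect_false(anyNA(air_band(0:12)))
  expect_false(anyNA(ripasa_band(seq(1.5, 16, by = 0.5))))
})

test_that("turning any item on never lowers any score (monotone items)", {
  cohort <- random_patients(200, seed = 11)
  scored <- score_cohort(cohort)
  flags <- c("migratory_rif_pain", "anorexia", "nausea", "vomiting",
             "rif_pain", "rif_tenderness", "rebound_tenderness",
             "rovsing_sign", "urinalysis_negative", "foreign_national")
  for (f in flags) {
    bumped <- cohort
    bumped[[f]] <- TRUE
    bumped$nausea_or_vomiting <- bumped$nausea | bumped$vomiting
    s2 <- score_cohort(bumped)
    for (col in c("alvarado_score", "air_score", "ripasa_score")) {
      expect_true(all(s2[[col]] >= scored[[col]]),
                  label = paste("monotone in", f, "for", col))
    }
  }
  labs <- cohort
  labs$wbc_e9_per_L <- pmax(labs$wbc_e9_per_L, 16)
  labs$pmn_percent <- pmax(labs$pmn_percent, 90)
  labs$crp_mg_per_L <- pmax(labs$crp_mg_per_L, 10)
  s3 <- score_cohort(labs)
  for (col in c("alvarado_score", "air_score", "ripasa_score")) {
    expect_true(all(s3[[col]] >= scored[[col]]),
                label = paste("monotone in labs for", col))
  }
})

test_that("RIPASA fever item is the open band (37, 39): banded, not monotone", {
  at <- function(t) ripasa_score(patient(temperature_c = t))$score
  base <- at(36.5)
  expect_identical(at(37), base)        # edge excluded
  expect_identical(at(37.1), base + 1)
  expect_identical(at(38.9), base + 1)
  expect_identical(at(39), base)        # edge excluded
  # +2 degC pushes a febrile patient past 39 and removes exactly the point
  expect_identical(at(37.5) - at(39.5), 1)
})
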