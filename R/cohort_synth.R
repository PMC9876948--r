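# Seeded synthetic appendectomy cohorts.
#
# The generator draws the histopathology label first (disease-positive vs
# negative appendectomy) and every clinical feature conditionally on that
# label; features are conditionally independent given the label unless the
# optional shared latent severity is switched on. Labs are drawn as raw
# values (truncated normals / log-normals on clinically plausible ranges) and
# thresholded downstream by the scoring rules, so the scorer consumes the
# same fields a real cohort CSV would carry.

.lab_bounds <- list(
  temperature = c(35, 41), wbc = c(2, 30), pmn = c(40, 99),
  crp = c(0, 300), duration = c(2, 240)
)

class_params <- function(flags, guarding_w, temperature, wbc, pmn, crp,
                         duration, sex_male_p, age) {
  list(flags = flags, guarding_w = guarding_w, temperature = temperature,
       wbc = wbc, pmn = pmn, crp = crp, duration = duration,
       sex_male_p = sex_male_p, age = age)
}

#' Parameters of the synthetic-cohort generator
#'
#' Defaults encode the study conditions this package emulates: a cohort of
#' 132 appendectomy patients, 121 histopathology-positive (92 acutely
#' inflamed, 4 gangrenous, 25 perforated) and 11 negative, 79 male / 53
#' female, age drawn from a normal(24, 11.6) truncated to 9-70 years. The
#' class-conditional feature probabilities and lab distributions were tuned
#' once, with [calibrate_cohort_params()], so that each score's sensitivity
#' and specificity at its study cutoff lands near the published operating
#' characteristics; they are one consistent choice, not an estimate of the
#' study population (feature-level marginals were never published).
#'
#' @param n cohort size.
#' @param prevalence probability a patient is histopathology-positive.
#' @param histo_mix probabilities of acute_inflamed/gangrenous/perforated
#'   given positive (must sum to 1).
#' @param pos,neg class-conditional parameter blocks: `flags` (Bernoulli
#'   probabilities per clinical flag), `guarding_w` (log-weights over
#'   guarding grades, softmax-normalised), `temperature`/`wbc`/`pmn`
#'   (truncated-normal `mean`, `sd`), `crp`/`duration` (log-normal `meanlog`,
#'   `sdlog`), `sex_male_p` (probability of male sex) and `age`
#'   (truncated-normal `mean`, `sd` on `min`-`max` years). Sex and age are
#'   class-conditional because negative appendectomies are reported to skew
#'   towards women of reproductive age; the small negative fraction keeps the
#'   cohort-level sex ratio and age distribution near the published marginals.
#' @param severity optional shared latent severity: a standard-normal `z` per
#'   patient enters every flag's logit with coefficient `flag_loading` and
#'   every lab's mean with coefficient `lab_loading` (in SD units). Both
#'   default to 0, i.e. pure conditional independence given the label.
#' @param seed default generator seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(
    n = 132,
    prevalence = 121 / 132,
    histo_mix = c(acute_inflamed = 92, gangrenous = 4, perforated = 25) / 121,
    pos = class_params(
      flags = c(migratory_rif_pain = 0.99, anorexia = 0.92, nausea = 0.96,
                vomiting = 0.3925, rif_pain = 0.94, rif_tenderness = 0.99,
                rebound_tenderness = 0.9575, rovsing_sign = 0.345,
                urinalysis_negative = 0.6875, foreign_national = 0.02),
      guarding_w = c(none = 0, light = -0.3625, medium = -0.7375,
                     strong = -1.625),
      temperature = list(mean = 37.75, sd = 0.55),
      wbc = list(mean = 14.9, sd = 3.2),
      pmn = list(mean = 78.5625, sd = 7.5),
      crp = list(meanlog = 1.975, sdlog = 1.0),
      duration = list(meanlog = 4.3125, sdlog = 0.55),
      sex_male_p = 0.65,
      age = list(mean = 22, sd = 11, min = 9, max = 70)
    ),
    neg = class_params(
      flags = c(migratory_rif_pain = 0.645, anorexia = 0.66, nausea = 0.71,
                vomiting = 0.115, rif_pain = 0.1575, rif_tenderness = 0.845,
                rebound_tenderness = 0.51, rovsing_sign = 0.01,
                urinalysis_negative = 0.03, foreign_national = 0.02),
      guarding_w = c(none = 0, light = -3.175, medium = -3.85,
                     strong = -4.6625),
      temperature = list(mean = 36.93, sd = 0.45),
      wbc = list(mean = 12.8, sd = 3.0),
      pmn = list(mean = 76.5, sd = 7.0),
      crp = list(meanlog = 0.8, sdlog = 1.0),
      duration = list(meanlog = 4.425, sdlog = 0.5),
      sex_male_p = 0.05,
      age = list(mean = 48.75, sd = 9, min = 9, max = 70)
    ),
    severity = list(flag_loading = 0.9, lab_loading = 0.6),
    seed = 20220101) {
  p <- structure(list(
    n = n, prevalence = prevalence, histo_mix = histo_mix,
    pos = pos, neg = neg, severity = severity, seed = seed
  ), class = "cohort_params")
  validate_cohort_params(p)
  p
}

#' @rdname cohort_params
#' @export
default_params <- function() cohort_params()

validate_cohort_params <- function(p) {
  stopifnot(p$n >= 1, p$n == round(p$n))
  if (p$prevalence <= 0 || p$prevalence >= 1) {
    stop("prevalence must be in (0,1)", call. = FALSE)
  }
  if (abs(sum(p$histo_mix) - 1) > 1e-9 || any(p$histo_mix < 0)) {
    stop("histo_mix must be a probability simplex over the three positive ",
         "histology categories", call. = FALSE)
  }
  for (cls in c("pos", "neg")) {
    fl <- p[[cls]]$flags
    if (any(fl < 0 | fl > 1)) {
      stop(cls, " flag probabilities must be in [0,1]", call. = FALSE)
    }
    if (!setequal(names(p[[cls]]$guarding_w), .guarding_levels)) {
      stop(cls, " guarding_w must cover exactly the guarding grades",
           call. = FALSE)
    }
    if (p[[cls]]$sex_male_p < 0 || p[[cls]]$sex_male_p > 1) {
      stop(cls, " sex_male_p must be in [0,1]", call. = FALSE)
    }
  }
  invisible(p)
}

# Inverse-CDF truncated normal; vectorised over mean. Drawing through a
# single runif call keeps the RNG stream length independent of parameters,
# so cohorts are bit-identical for a given seed.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  fa <- stats::pnorm(lo, mean, sd)
  fb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(fa + stats::runif(n) * (fb - fa), mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(stats::qlnorm(stats::runif(n), meanlog, sdlog), lo), hi)
}

#' Generate a synthetic appendectomy cohort
#'
#' Draws `n` patient records under [cohort_params()]: histopathology label
#' first (Bernoulli prevalence, then the histology mix among positives), then
#' demographics and every clinical feature conditional on the label. The same
#' seed always yields the bit-identical cohort, regardless of platform,
#' because every variate is drawn through a fixed-length inverse-CDF stream.
#'
#' @param params a [cohort_params()].
#' @param n cohort size; defaults to `params$n`.
#' @param seed integer seed; defaults to `params$seed`.
#' @return a validated cohort data.frame (see [cohort_fields()]) with the
#'   histopathology column filled in.
#' @examples
#' cohort <- generate_cohort(cohort_params(), n = 50, seed = 1)
#' table(cohort$histopathology)
#' @export
generate_cohort <- function(params = cohort_params(), n = params$n,
                            seed = params$seed) {
  validate_cohort_params(params)
  stopifnot(n >= 1)
  with_seed(seed, {
    diseased <- stats::runif(n) < params$prevalence
    u_h <- stats::runif(n)
    cum <- cumsum(params$histo_mix)
    histo <- ifelse(!diseased, "negative",
                    ifelse(u_h < cum[1], "acute_inflamed",
                           ifelse(u_h < cum[2], "gangrenous", "perforated")))
    sex_p <- ifelse(diseased, params$pos$sex_male_p, params$neg$sex_male_p)
    sex <- ifelse(stats::runif(n) < sex_p, "male", "female")
    age <- rtrunc_norm(
      n,
      ifelse(diseased, params$pos$age$mean, params$neg$age$mean),
      ifelse(diseased, params$pos$age$sd, params$neg$age$sd),
      ifelse(diseased, params$pos$age$min, params$neg$age$min),
      ifelse(diseased, params$pos$age$max, params$neg$age$max)
    )
    z <- stats::rnorm(n)
    fload <- params$severity$flag_loading
    lload <- params$severity$lab_loading

    flag_p <- function(name) {
      p0 <- ifelse(diseased, params$pos$flags[[name]], params$neg$flags[[name]])
      if (fload == 0) p0
      else stats::plogis(stats::qlogis(pmin(pmax(p0, 1e-6), 1 - 1e-6)) +
                           fload * z)
    }
    flags <- lapply(names(params$pos$flags),
                    function(f) stats::runif(n) < flag_p(f))
    names(flags) <- names(params$pos$flags)

    gw_pos <- exp(params$pos$guarding_w[.guarding_levels])
    gw_neg <- exp(params$neg$guarding_w[.guarding_levels])
    gp_pos <- cumsum(gw_pos / sum(gw_pos))
    gp_neg <- cumsum(gw_neg / sum(gw_neg))
    u_g <- stats::runif(n)
    cut1 <- ifelse(diseased, gp_pos[1], gp_neg[1])
    cut2 <- ifelse(diseased, gp_pos[2], gp_neg[2])
    cut3 <- ifelse(diseased, gp_pos[3], gp_neg[3])
    guarding <- ifelse(u_g < cut1, "none",
                       ifelse(u_g < cut2, "light",
                              ifelse(u_g < cut3, "medium", "strong")))

    lab_norm <- function(field, bounds) {
      m <- ifelse(diseased, params$pos[[field]]$mean, params$neg[[field]]$mean)
      s <- ifelse(diseased, params$pos[[field]]$sd, params$neg[[field]]$sd)
      rtrunc_norm(n, m + lload * z * s, s, bounds[1], bounds[2])
    }
    lab_lnorm <- function(field, bounds) {
      ml <- ifelse(diseased, params$pos[[field]]$meanlog,
                   params$neg[[field]]$meanlog)
      sl <- ifelse(diseased, params$pos[[field]]$sdlog,
                   params$neg[[field]]$sdlog)
      rtrunc_lnorm(n, ml + lload * z * sl, sl, bounds[1], bounds[2])
    }
    temperature <- lab_norm("temperature", .lab_bounds$temperature)
    wbc <- lab_norm("wbc", .lab_bounds$wbc)
    pmn <- lab_norm("pmn", .lab_bounds$pmn)
    crp <- lab_lnorm("crp", .lab_bounds$crp)
    duration <- lab_lnorm("duration", .lab_bounds$duration)

    cohort <- data.frame(
      age_years = age, sex = sex,
      migratory_rif_pain = flags$migratory_rif_pain,
      anorexia = flags$anorexia, nausea = flags$nausea,
      vomiting = flags$vomiting,
      nausea_or_vomiting = flags$nausea | flags$vomiting,
      rif_pain = flags$rif_pain, rif_tenderness = flags$rif_tenderness,
      rebound_tenderness = flags$rebound_tenderness,
      guarding_grade = guarding, rovsing_sign = flags$rovsing_sign,
      temperature_c = temperature, wbc_e9_per_L = wbc, pmn_percent = pmn,
      crp_mg_per_L = crp, urinalysis_negative = flags$urinalysis_negative,
      symptom_duration_h = duration,
      foreign_national = flags$foreign_national,
      histopathology = histo, stringsAsFactors = FALSE
    )
    cohort <- cohort[, cohort_fields()]
    validate_cohort(cohort, require_histopathology = TRUE)
    cohort
  })
}

# Monte-Carlo sensitivity/specificity of each system under `params`.
mc_operating_point <- function(params, n_mc, seed,
                               config = scoring_config()) {
  cohort <- generate_cohort(params, n = n_mc, seed = seed)
  labels <- histo_positive(cohort$histopathology)
  scored <- score_cohort(cohort, config = config)
  out <- list()
  for (sys in c("alvarado", "air", "ripasa")) {
    cm <- confusion_matrix(scored[[paste0(sys, "_positive")]], labels)
    out[[sys]] <- c(sens = cm$tp / (cm$tp + cm$fn),
                    spec = cm$tn / (cm$fp + cm$tn))
  }
  out
}

#' Operating-characteristic targets from published rows
#'
#' @param rows list of [reported_row()]s, default [published_rows()].
#' @return named list, per system, of `c(sens=, spec=)` as fractions.
#' @export
operating_targets <- function(rows = published_rows()) {
  out <- lapply(rows, function(r) c(sens = r$sensitivity / 100,
                                    spec = r$specificity / 100))
  names(out) <- vapply(rows, `[[`, character(1), "system")
  out
}

calibration_knobs <- function() {
  flags <- names(cohort_params()$pos$flags)
  knobs <- list()
  for (cls in c("pos", "neg")) {
    for (f in setdiff(flags, "foreign_national")) {
      knobs[[length(knobs) + 1]] <- list(
        path = paste0(cls, ".flags.", f), step = 0.06, lo = 0.01, hi = 0.99)
    }
    for (g in c("light", "medium", "strong")) {
      knobs[[length(knobs) + 1]] <- list(
        path = paste0(cls, ".guarding_w.", g), step = 0.3, lo = -5, hi = 3)
    }
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".temperature.mean"), step = 0.08, lo = 36.2, hi = 38.5)
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".wbc.mean"), step = 0.4, lo = 6, hi = 18)
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".pmn.mean"), step = 1.5, lo = 55, hi = 90)
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".crp.meanlog"), step = 0.2, lo = 0, hi = 5)
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".duration.meanlog"), step = 0.15, lo = 2, hi = 4.8)
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".sex_male_p"), step = 0.08, lo = 0.05, hi = 0.95)
    knobs[[length(knobs) + 1]] <- list(
      path = paste0(cls, ".age.mean"), step = 2, lo = 15, hi = 55)
  }
  knobs
}

get_path <- function(l, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) l <- l[[k]]
  l
}

set_path <- function(l, path, value) {
  ks <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(ks) == 1) {
    l[[ks]] <- value
  } else {
    l[[ks[1]]] <- set_path(l[[ks[1]]], paste(ks[-1], collapse = "."), value)
  }
  l
}

#' Calibrate generator parameters to operating-characteristic targets
#'
#' Coordinate search over the class-conditional feature parameters,
#' minimising the summed squared deviation of Monte-Carlo sensitivity and
#' specificity (at each system's cutoff) from the targets. Each candidate is
#' evaluated on a cohort generated with the same evaluation seed (common
#' random numbers), so comparisons between candidates are low-noise and the
#' whole search is reproducible: the same seed returns identical parameters.
#'
#' @param targets per-system `c(sens=, spec=)` fractions, as from
#'   [operating_targets()].
#' @param params starting [cohort_params()].
#' @param n_mc Monte-Carlo cohort size per objective evaluation.
#' @param seed seed for the evaluation cohorts.
#' @param passes coordinate-descent sweeps; the step halves after each pass.
#' @param knobs list of knob definitions (`path`, `step`, `lo`, `hi`);
#'   defaults to every class-conditional flag probability, guarding
#'   log-weight and lab location parameter.
#' @param tol warn (non-convergence) if any achieved sens/spec deviates from
#'   its target by more than this fraction at the end.
#' @return calibrated `cohort_params` with attributes `achieved` (data.frame
#'   of per-system achieved vs target operating points) and `objective`.
#' @export
calibrate_cohort_params <- function(targets = operating_targets(),
                                    params = cohort_params(),
                                    n_mc = 20000, seed = 1, passes = 3,
                                    knobs = calibration_knobs(),
                                    tol = 0.05) {
  objective <- function(p) {
    op <- mc_operating_point(p, n_mc, seed)
    sum(vapply(names(targets), function(sys) {
      sum((op[[sys]] - targets[[sys]])^2)
    }, numeric(1)))
  }
  best <- objective(params)
  for (pass in seq_len(passes)) {
    for (k in knobs) {
      cur <- get_path(params, k$path)
      step <- k$step / 2^(pass - 1)
      for (cand in c(cur - step, cur + step)) {
        cand <- min(max(cand, k$lo), k$hi)
        if (cand == cur) next
        trial <- set_path(params, k$path, cand)
        val <- objective(trial)
        if (val < best) {
          best <- val
          params <- trial
        }
      }
    }
  }
  op <- mc_operating_point(params, n_mc, seed)
  achieved <- do.call(rbind, lapply(names(targets), function(sys) {
    data.frame(system = sys,
               sens = op[[sys]]["sens"], target_sens = targets[[sys]]["sens"],
               spec = op[[sys]]["spec"], target_spec = targets[[sys]]["spec"],
               row.names = NULL)
  }))
  dev <- max(abs(c(achieved$sens - achieved$target_sens,
                   achieved$spec - achieved$target_spec)))
  if (dev > tol) {
    warning(sprintf(
      "calibration did not converge: worst deviation %.3f > %.3f; ",
      dev, tol), "returning best-found parameters", call. = FALSE)
  }
  attr(params, "achieved") <- achieved
  attr(params, "objective") <- best
  params
}
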