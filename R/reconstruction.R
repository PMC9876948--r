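# Integer confusion-matrix reconstruction from published rounded metrics.
#
# A published accuracy row reports sensitivity/specificity rounded for
# display, but the underlying 2x2 cells are integers on known marginals
# (here: histopathology-positive and -negative counts). Exhaustively testing
# every candidate (tp, tn) pair recovers the matrix (often uniquely), after
# which every other reported cell can be recomputed and audited for internal
# consistency — a granularity check in the GRIM tradition, specialised to
# diagnostic 2x2 tables.

#' A published operating-characteristics row
#'
#' Bundles one published row — system name, cutoff, the printed sensitivity
#' and specificity, the cohort marginals, and any further printed cells — for
#' [reconstruct_matrix()] and [audit_row()]. The precision at which each cell
#' was printed is inferred from the value itself (`25` at 0 decimals, `33.3`
#' at 1, `78.03` at 2) and each cell is later matched at its own precision.
#'
#' @param system system name (free text, e.g. `"alvarado"`).
#' @param cutoff the cutoff the row was computed at.
#' @param sensitivity,specificity printed values, percent.
#' @param n_pos,n_neg disease-positive and -negative cohort marginals.
#' @param ppv,npv,accuracy optional printed percentages.
#' @param plr,nlr optional printed likelihood ratios.
#' @return object of class `reported_row`.
#' @examples
#' reported_row("alvarado", cutoff = 7, sensitivity = 88.4, specificity = 63.6,
#'              n_pos = 121, n_neg = 11)
#' @export
reported_row <- function(system, cutoff, sensitivity, specificity,
                         n_pos, n_neg, ppv = NA_real_, npv = NA_real_,
                         plr = NA_real_, nlr = NA_real_,
                         accuracy = NA_real_) {
  stopifnot(n_pos >= 1, n_neg >= 1, n_pos == round(n_pos), n_neg == round(n_neg))
  vals <- c(sensitivity = sensitivity, specificity = specificity,
            ppv = ppv, npv = npv, accuracy = accuracy)
  if (any(!is.na(vals) & (vals < 0 | vals > 100))) {
    stop("percentages must be in [0,100]", call. = FALSE)
  }
  if (any(!is.na(c(plr, nlr)) & c(plr, nlr) < 0)) {
    stop("likelihood ratios must be >= 0", call. = FALSE)
  }
  structure(list(
    system = system, cutoff = cutoff,
    sensitivity = sensitivity, specificity = specificity,
    ppv = ppv, npv = npv, plr = plr, nlr = nlr, accuracy = accuracy,
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg)
  ), class = "reported_row")
}

#' Recover the integer confusion matrices behind a published row
#'
#' Exhaustive search: every `tp` in `0..n_pos` and `tn` in `0..n_neg` is
#' tested, and a candidate matrix is kept iff its sensitivity and specificity
#' round (half-up by default) to the printed values at their printed
#' precision. The search space is `(n_pos+1) x (n_neg+1)` candidates —
#' milliseconds at clinical cohort sizes — and the result is flagged unique
#' when exactly one matrix survives.
#'
#' @param row a [reported_row()].
#' @param dialect rounding dialect used to match printed values,
#'   `"half_up"` (default) or `"half_even"`.
#' @return object of class `reconstruction`: list with `matrices` (a list of
#'   `confusion_matrix`), `unique` flag, and the `row`.
#' @examples
#' r <- reported_row("alvarado", 7, 88.4, 63.6, n_pos = 121, n_neg = 11)
#' reconstruct_matrix(r)
#' @export
reconstruct_matrix <- function(row, dialect = "half_up") {
  stopifnot(inherits(row, "reported_row"))
  d_sens <- printed_decimals(row$sensitivity)
  d_spec <- printed_decimals(row$specificity)
  tp_ok <- which(abs(apply_rounding(100 * (0:row$n_pos) / row$n_pos, d_sens,
                                    dialect) - row$sensitivity) < 1e-9) - 1L
  tn_ok <- which(abs(apply_rounding(100 * (0:row$n_neg) / row$n_neg, d_spec,
                                    dialect) - row$specificity) < 1e-9) - 1L
  if (length(tp_ok) == 0 || length(tn_ok) == 0) {
    stop("impossible row: no integer matrix on marginals (", row$n_pos, ", ",
         row$n_neg, ") yields sensitivity ", row$sensitivity,
         " and specificity ", row$specificity, call. = FALSE)
  }
  matrices <- list()
  for (tp in tp_ok) {
    for (tn in tn_ok) {
      matrices[[length(matrices) + 1]] <-
        new_confusion_matrix(tp, row$n_neg - tn, row$n_pos - tp, tn)
    }
  }
  structure(list(matrices = matrices, unique = length(matrices) == 1,
                 row = row), class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("%d candidate matrix(es) for %s at cutoff %s (%s)\n",
              length(x$matrices), x$row$system, format(x$row$cutoff),
              if (x$unique) "unique" else "not unique"))
  for (m in x$matrices) {
    cat(sprintf("  tp=%d fp=%d fn=%d tn=%d\n", m$tp, m$fp, m$fn, m$tn))
  }
  invisible(x)
}

audit_one_metric <- function(metric, reported, computed, dialect,
                             from_rounded = NA_real_) {
  dp <- printed_decimals(reported)
  ulp <- 10^(-dp)
  rounded <- apply_rounding(computed, dp, dialect)
  delta <- rounded - reported
  verdict <- if (abs(delta) < 1e-9) "match"
             else if (abs(delta) <= ulp + 1e-9) sprintf("near-miss(%g)", abs(delta))
             else "impossible"
  data.frame(
    metric = metric, reported = reported, computed = computed,
    computed_rounded = rounded, delta = delta, verdict = verdict,
    matches_truncated = abs(trunc_digits(computed, dp) - reported) < 1e-9,
    from_rounded = if (is.na(from_rounded)) NA_real_
                   else apply_rounding(from_rounded, dp, dialect),
    matches_from_rounded = if (is.na(from_rounded)) NA
                           else abs(apply_rounding(from_rounded, dp, dialect) -
                                    reported) < 1e-9,
    stringsAsFactors = FALSE
  )
}

#' Audit a published row for internal consistency
#'
#' Reconstructs the candidate confusion matrices behind the row's printed
#' sensitivity/specificity, recomputes every further printed cell (PPV, NPV,
#' PLR, NLR, accuracy) from each candidate, and issues a verdict per cell:
#' `match` (equal at the cell's printed precision), `near-miss(d)` (off by at
#' most one unit in the last printed digit), or `impossible`.
#'
#' Two ambiguities of published tables are reported rather than adjudicated:
#' some cells look truncated rather than rounded (`matches_truncated`), and
#' likelihood ratios are sometimes computed from the *display-rounded*
#' sensitivity/specificity rather than from the raw counts — e.g. 96.7/27.3
#' instead of (117/121)/(3/11) — so for PLR/NLR the audit also reports that
#' derivation (`from_rounded`, `matches_from_rounded`).
#'
#' @inheritParams reconstruct_matrix
#' @return object of class `audit_report`: list with the `reconstruction`,
#'   `unique` flag, and `audits` — one verdict data.frame per candidate
#'   matrix, one row per reported metric.
#' @examples
#' row <- reported_row("alvarado", 7, 88.4, 63.6, n_pos = 121, n_neg = 11,
#'                     ppv = 96.4, npv = 33.3, plr = 2.43, nlr = 0.18,
#'                     accuracy = 86.3)
#' audit_row(row)
#' @export
audit_row <- function(row, dialect = "half_up") {
  rec <- reconstruct_matrix(row, dialect)
  audits <- lapply(rec$matrices, function(m) {
    met <- diagnostic_metrics(m)
    sens_r <- apply_rounding(met$sensitivity, printed_decimals(row$sensitivity),
                             dialect)
    spec_r <- apply_rounding(met$specificity, printed_decimals(row$specificity),
                             dialect)
    plr_from_rounded <- if (spec_r < 100) sens_r / (100 - spec_r) else NA_real_
    nlr_from_rounded <- if (spec_r > 0) (100 - sens_r) / spec_r else NA_real_
    rows <- list()
    for (metric in c("ppv", "npv", "plr", "nlr", "accuracy")) {
      if (is.na(row[[metric]])) next
      fr <- switch(metric, plr = plr_from_rounded, nlr = nlr_from_rounded,
                   NA_real_)
      rows[[metric]] <- audit_one_metric(metric, row[[metric]], met[[metric]],
                                         dialect, from_rounded = fr)
    }
    do.call(rbind, rows)
  })
  structure(list(reconstruction = rec, unique = rec$unique, audits = audits,
                 row = row, dialect = dialect), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  print(x$reconstruction)
  for (i in seq_along(x$audits)) {
    m <- x$reconstruction$matrices[[i]]
    cat(sprintf("candidate %d (tp=%d fp=%d fn=%d tn=%d):\n",
                i, m$tp, m$fp, m$fn, m$tn))
    a <- x$audits[[i]]
    if (is.null(a)) { cat("  no further cells reported\n"); next }
    for (j in seq_len(nrow(a))) {
      cat(sprintf("  %-8s reported %-7s computed %-8.4f -> %s%s\n",
                  a$metric[j], format(a$reported[j]), a$computed[j],
                  a$verdict[j],
                  if (isTRUE(a$matches_from_rounded[j]) &&
                      a$verdict[j] != "match")
                    " (matches when derived from rounded sens/spec)" else ""))
    }
  }
  invisible(x)
}

#' Published accuracy rows shipped with the package
#'
#' The three published Table-4-style rows (Alvarado at cutoff >7, AIR at >5,
#' RIPASA at >=7.5) from a prospective 132-patient appendectomy cohort with
#' 121 histopathology-positive and 11 negative specimens, as shipped in
#' `inst/extdata/published_rows.csv`. These are the audit engine's standard
#' worked example.
#'
#' @return list of [reported_row()] objects, one per system.
#' @export
published_rows <- function() {
  path <- system.file("extdata", "published_rows.csv",
                      package = "appendiscore", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    reported_row(df$system[i], df$cutoff[i], df$sensitivity[i],
                 df$specificity[i], n_pos = df$n_pos[i], n_neg = df$n_neg[i],
                 ppv = df$ppv[i], npv = df$npv[i], plr = df$plr[i],
                 nlr = df$nlr[i], accuracy = df$accuracy[i])
  })
}
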