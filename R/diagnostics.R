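# Diagnostic-accuracy evaluation against the histopathology gold standard.

#' Cross-tabulate binary calls against disease labels
#'
#' @param calls logical (or 0/1) vector of test calls, `TRUE` = positive call.
#' @param labels logical (or 0/1) vector of disease status, or a character
#'   vector of histopathology labels (converted via [histo_positive()]).
#' @return object of class `confusion_matrix`: a list with integer cells
#'   `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_matrix <- function(calls, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- histo_positive(as.character(labels))
  }
  if (length(calls) != length(labels)) {
    stop("calls and labels must have equal length", call. = FALSE)
  }
  if (length(calls) == 0) stop("empty input", call. = FALSE)
  if (anyNA(calls) || anyNA(labels)) {
    stop("calls/labels contain missing values", call. = FALSE)
  }
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  new_confusion_matrix(
    tp = sum(calls & labels), fp = sum(calls & !labels),
    fn = sum(!calls & labels), tn = sum(!calls & !labels)
  )
}

#' Construct a confusion matrix from its four cells
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return object of class `confusion_matrix`.
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(call = c("positive", "negative"),
                              disease = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Summary accuracy metrics from a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive value
#' and accuracy (as percentages), and the positive and negative likelihood
#' ratios. Values are returned at full precision; display rounding (half-up,
#' one decimal for percentages, two for ratios) is applied only by
#' [round_metrics()], so rounding never contaminates downstream arithmetic.
#'
#' A metric whose denominator is empty (e.g. PPV with no positive calls, PLR
#' at specificity 1) is returned as `NA` and named in the `undefined`
#' attribute rather than silently becoming infinite.
#'
#' @param cm a `confusion_matrix`.
#' @return object of class `diagnostic_summary`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (percent), `plr`, `nlr`
#'   (ratios), plus cell counts; attribute `undefined` names any undefined
#'   metrics.
#' @examples
#' diagnostic_metrics(new_confusion_matrix(107, 4, 14, 7))
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (tp + fn < 1 || fp + tn < 1) {
    stop("both disease classes must be represented (tp+fn >= 1, fp+tn >= 1)",
         call. = FALSE)
  }
  n <- tp + fp + fn + tn
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); NA_real_ }
    else num / den
  }
  out <- list(
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    ppv = 100 * div(tp, tp + fp, "ppv"),
    npv = 100 * div(tn, tn + fn, "npv"),
    accuracy = 100 * (tp + tn) / n,
    plr = div(sens, 1 - spec, "plr"),
    nlr = div(1 - sens, spec, "nlr"),
    tp = tp, fp = fp, fn = fn, tn = tn, n = n
  )
  structure(out, class = "diagnostic_summary", undefined = undefined)
}

#' Display rounding for a diagnostic summary
#'
#' @param x a `diagnostic_summary` (or any named list of metrics).
#' @param dialect rounding dialect, `"half_up"` (default) or `"half_even"`.
#' @return named numeric vector with percentages at one decimal and
#'   likelihood ratios at two.
#' @export
round_metrics <- function(x, dialect = "half_up") {
  pct <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  out <- c(
    vapply(pct, function(f) apply_rounding(x[[f]], 1, dialect), numeric(1)),
    plr = apply_rounding(x[["plr"]], 2, dialect),
    nlr = apply_rounding(x[["nlr"]], 2, dialect)
  )
  out
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  r <- round_metrics(x)
  cat(sprintf(
    "n=%d (tp=%d fp=%d fn=%d tn=%d)\nsens %.1f%%  spec %.1f%%  ppv %.1f%%  npv %.1f%%  acc %.1f%%  PLR %.2f  NLR %.2f\n",
    x$n, x$tp, x$fp, x$fn, x$tn, r["sensitivity"], r["specificity"],
    r["ppv"], r["npv"], r["accuracy"], r["plr"], r["nlr"]))
  u <- attr(x, "undefined")
  if (length(u) > 0) cat("undefined:", paste(u, collapse = ", "), "\n")
  invisible(x)
}

#' Empirical ROC curve and area under it
#'
#' Sweeps every distinct score value as a threshold (call positive at
#' score >= threshold), traces the empirical ROC from (0,0) to (1,1) and
#' integrates it by the trapezoid rule. Tied scores produce diagonal
#' segments, so the area equals the Mann-Whitney statistic: the probability
#' that a random diseased patient outscores a random non-diseased one, ties
#' counting one half.
#'
#' @param scores numeric score vector (higher = more disease-like).
#' @param labels disease labels as in [confusion_matrix()]; both classes must
#'   be present.
#' @return object of class `roc_curve`: list with `auc` and `points`, a
#'   data.frame of `threshold`, `fpr`, `tpr` (threshold `Inf` is the
#'   all-negative origin).
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- histo_positive(as.character(labels))
  }
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores/labels contain missing values", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to plot a ROC curve", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t) sum(scores == t & labels),
                            numeric(1))) / n_pos)
  fpr <- c(0, cumsum(vapply(thr, function(t) sum(scores == t & !labels),
                            numeric(1))) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(
    auc = auc,
    points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("empirical ROC: %d points, AUC = %.3f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Paired difference between two AUCs
#'
#' Computes `auc(scores_b) - auc(scores_a)` on the same patients, optionally
#' with a seeded paired-bootstrap percentile interval. The bootstrap is
#' stratified by disease status so every resample contains both classes. The
#' published comparison this mirrors reported a p-value by an unstated
#' method; the bootstrap interval here is this package's own (clearly
#' labelled) significance machinery, not a reimplementation of that method.
#'
#' @param scores_a,scores_b numeric score vectors for the two systems on the
#'   same patients.
#' @param labels disease labels (both classes present).
#' @param boot_reps bootstrap resamples; 0 (default) skips the interval.
#' @param conf interval coverage, default 0.95.
#' @param seed integer seed for the bootstrap; same seed, same interval.
#' @return list with `auc_a`, `auc_b`, `delta`, and when `boot_reps > 0`
#'   `ci` (percentile interval) and `boot_reps`.
#' @export
auc_difference <- function(scores_a, scores_b, labels, boot_reps = 0,
                           conf = 0.95, seed = NULL) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must cover the same patients", call. = FALSE)
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- histo_positive(as.character(labels))
  }
  labels <- as.logical(labels)
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  out <- list(auc_a = auc_a, auc_b = auc_b, delta = auc_b - auc_a)
  if (boot_reps > 0) {
    idx_pos <- which(labels); idx_neg <- which(!labels)
    deltas <- with_seed(seed, vapply(seq_len(boot_reps), function(i) {
      idx <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
      roc_auc(scores_b[idx], labels[idx])$auc -
        roc_auc(scores_a[idx], labels[idx])$auc
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    out$ci <- unname(stats::quantile(deltas, c(alpha, 1 - alpha), type = 6))
    out$boot_reps <- boot_reps
  }
  out
}

#' Pearson product-moment correlation between two score vectors
#'
#' Thin validated wrapper around [stats::cor()]: requires at least three
#' paired observations and non-degenerate variance in both vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}
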