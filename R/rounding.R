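#' Round half away from zero at a fixed number of decimals
#'
#' Published clinical tables are almost always rounded half-up (5 rounds away
#' from zero), whereas base [round()] uses IEC 60559 half-even. The audit
#' machinery needs the half-up dialect to decide whether a printed cell is
#' consistent with an integer confusion matrix, so it is implemented here and
#' used everywhere a displayed value is produced.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (non-negative integer).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) gives 2
#' round_half_up(86.365, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # 1e-9 guards against representation error in rationals like 114/132*100;
  # genuine .4499... cases are never that close to the boundary here.
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @describeIn round_half_up Banker's rounding (half to even), the alternative
#'   dialect offered for sensitivity analysis of the audit. A thin wrapper
#'   around base [round()].
#' @export
round_half_even <- function(x, digits = 0) round(x, digits)

# Truncation toward zero at `digits` decimals; some published cells look
# truncated rather than rounded, and the audit reports this dialect too.
trunc_digits <- function(x, digits = 0) {
  p <- 10^digits
  trunc(x * p + sign(x) * 1e-9) / p
}

# Number of decimal places needed to represent x exactly (capped at 6).
# Used to infer the precision at which a published value was printed:
# 25 -> 0, 33.3 -> 1, 78.03 -> 2.
printed_decimals <- function(x) {
  for (d in 0:6) {
    if (abs(x - round(x * 10^d) / 10^d) < 1e-9) return(d)
  }
  6L
}

apply_rounding <- function(x, digits, dialect = c("half_up", "half_even")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    half_up = round_half_up(x, digits),
    half_even = round_half_even(x, digits)
  )
}

# Evaluate an expression with a temporary RNG state; restores (or clears)
# .Random.seed afterwards so callers' RNG streams are untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
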