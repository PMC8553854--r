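## Power analysis for paired t-tests (via the one-sample reduction on
## differences) and the arousal-style median split.

#' Power of a two-sided paired t-test at effect size d
#'
#' Models the paired test as a one-sample t-test on the within-pair
#' differences: `n - 1` degrees of freedom and noncentrality `d * sqrt(n)`,
#' where `d` is the standardized mean difference (Cohen's d for paired
#' samples).
#'
#' @param n number of pairs (>= 2).
#' @param alpha two-sided significance level.
#' @param d standardized effect size (>= 0).
#' @return numeric(1), the power.
#' @examples
#' achievedPower(107, 0.05, 0.27)
#' @export
achievedPower <- function(n, alpha = 0.05, d) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, d >= 0)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
}

#' Minimal detectable effect size for a paired t-test
#'
#' The smallest standardized effect size `d` at which a two-sided paired
#' t-test with `n` pairs reaches the target power, found by monotone
#' root-finding on [achievedPower()] to |power error| < 1e-8 (the reverse
#' power analysis).
#'
#' @param n number of pairs (>= 2).
#' @param alpha two-sided level (default 0.05).
#' @param power target power (default 0.80).
#' @return numeric(1), the minimal detectable d.
#' @examples
#' round(minimalDetectableEffect(107, 0.05, 0.80), 2)  # 0.27
#' @export
minimalDetectableEffect <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) return(0)
  f <- function(d) achievedPower(n, alpha, d) - power
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Median split of labeled values
#'
#' Splits items into a high group (strictly above the median) and a low group
#' (at or below the median; ties go low by convention). Used to separate
#' stimuli into high- and low-arousal sets after the fact.
#'
#' @param values numeric vector (length >= 2).
#' @param ids optional identifiers (default: names of `values`, or indices).
#' @return list with `high` and `low` (data.frames of id and value), the
#'   `median`, and `degenerate` (TRUE when all values are equal, leaving the
#'   high group empty).
#' @export
medianSplit <- function(values, ids = NULL) {
  stopifnot(length(values) >= 2)
  if (is.null(ids)) ids <- names(values) %||% seq_along(values)
  stopifnot(length(ids) == length(values))
  med <- stats::median(values)
  hi <- values > med
  list(
    high = data.frame(id = ids[hi], value = values[hi]),
    low = data.frame(id = ids[!hi], value = values[!hi]),
    median = med,
    degenerate = !any(hi)
  )
}
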