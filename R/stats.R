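#' Summarize prediction-minus-measurement differences
#'
#' Element-wise differences `predicted - measured` (positive means
#' over-prediction) summarized by mean, sample standard deviation, minimum,
#' maximum and count — the per-player, per-stroke accuracy summary used to
#' report kinematic prediction error.
#'
#' @param predicted,measured Numeric vectors of equal length (deg or s).
#' @return A one-row data frame with columns `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_differences <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 1) {
    stop("predicted and measured must be non-empty vectors of equal length",
         call. = FALSE)
  }
  d <- predicted - measured
  if (anyNA(d)) stop("differences contain missing values", call. = FALSE)
  s <- if (length(d) == 1) {
    warning("only one difference: standard deviation reported as 0")
    0
  } else {
    stats::sd(d)
  }
  data.frame(mean = mean(d), sd = s, min = min(d), max = max(d),
             n = length(d))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test (Satterthwaite degrees of freedom) between two groups
#' of differences, as used to compare per-stroke prediction errors.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df` and `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) {
    stop("test undefined: both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bonferroni-adjusted significance level
#'
#' Divides the family-wise alpha by the number of comparisons; the value is
#' returned at full precision together with the conventionally reported
#' three-decimal rounding (0.05 over six comparisons reports as 0.008).
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return List with `alpha_adjusted` (full precision) and `alpha_reported`
#'   (rounded to three decimals).
#' @examples
#' bonferroni_alpha(0.05, 6)
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  adj <- alpha / m
  list(alpha_adjusted = adj, alpha_reported = round(adj, 3))
}
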