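#' The Choquet integral
#'
#' Aggregates non-negative values against a fuzzy measure.  Values are
#' sorted in decreasing order (ties broken stably by original index); with
#' `T_i` the set of elements at descending ranks `i..N` and
#' `T_{N+1} = {}`, the integral is
#' `sum_i x_(i) [mu(T_i) - mu(T_{i+1})]`,
#' i.e. each value is weighted by the measure increment of the nested tail
#' sets of smaller-or-equal elements.  For an additive measure this
#' reduces to the weighted sum `sum_i s_i x_i`.
#'
#' @param values non-negative numeric vector.
#' @param measure a function taking an integer index subset and returning
#'   the measure value in `[0, 1]` (normalized, monotone), e.g. a closure
#'   over [lmdelta_measure()].
#' @param shift if `TRUE`, negative inputs are allowed: the minimum is
#'   subtracted first (with a warning) so the aggregation acts on shifts.
#'   Off by default because the integral is defined on non-negative reals.
#' @param standard if `TRUE`, use the textbook ascending-sort form (nested
#'   tails of *larger* elements) instead of the descending convention used
#'   throughout this package.  The two coincide for additive measures but
#'   differ for general fuzzy measures.
#' @return the aggregated value (single real).
#' @examples
#' s <- c(0.2, 0.5, 0.3)
#' additive <- function(A) sum(s[A])
#' choquet(c(3, 1, 2), additive)  # 1.7 = 0.2*3 + 0.5*1 + 0.3*2
#' @export
choquet <- function(values, measure, shift = FALSE, standard = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty-set: nothing to aggregate")
  if (any(!is.finite(values))) stop("negative-input: non-finite value")
  if (any(values < 0)) {
    if (!shift) stop("negative-input: Choquet integral is defined on non-negative reals (use shift = TRUE to opt in)")
    warning("choquet: shifting inputs by -min(values) = ", format(-min(values)))
    values <- values - min(values)
  }
  n <- length(values)
  ord <- if (standard) order(values, seq_len(n)) else order(-values, seq_len(n))
  muT <- numeric(n + 1L)            # muT[i] = measure of tails ord[i:n]; muT[n+1] = 0
  for (i in seq_len(n)) muT[i] <- measure(ord[i:n])
  sum(values[ord] * (muT[seq_len(n)] - muT[seq_len(n) + 1L]))
}

#' Ordered weighted averaging (OWA)
#'
#' `sum_i w_i x_(i)` over the values sorted in decreasing order.  A special
#' case of the Choquet integral with a symmetric (cardinality-only)
#' measure.
#'
#' @param values numeric vector.
#' @param weights non-negative weights summing to 1, same length as
#'   `values`.
#' @return the aggregated value.
#' @export
owa <- function(values, weights) {
  values <- as.numeric(values); weights <- as.numeric(weights)
  if (length(values) == 0L) stop("empty-set: nothing to aggregate")
  if (length(weights) != length(values))
    stop("invalid-weights: need one weight per value")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9)
    stop("invalid-weights: weights must be non-negative and sum to 1")
  sum(weights * sort(values, decreasing = TRUE))
}

#' Classical (non-fuzzy) aggregation operators
#'
#' The additive/linear operators traditionally used to collapse LOVI
#' vectors into global descriptors: sums, Minkowski norms, central-tendency
#' and dispersion statistics.
#'
#' @param values numeric vector.
#' @param stat one of `"sum"`, `"norm"` (Minkowski), `"mean"`,
#'   `"geometric_mean"`, `"harmonic_mean"`, `"variance"`, `"sd"`,
#'   `"skewness"` (adjusted, see [adjusted_skewness()]), `"kurtosis"`
#'   (excess), `"min"`, `"max"`, `"range"`.
#' @param p Minkowski exponent for `stat = "norm"` (`p >= 1`).
#' @return the aggregated value.
#' @export
classical_aggregate <- function(values, stat = "sum", p = 2) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty-set: nothing to aggregate")
  switch(match.arg(stat, c("sum", "norm", "mean", "geometric_mean",
                           "harmonic_mean", "variance", "sd", "skewness",
                           "kurtosis", "min", "max", "range")),
    sum  = sum(values),
    norm = {
      if (!is.numeric(p) || p < 1) stop("invalid-p: Minkowski p must be >= 1")
      sum(abs(values)^p)^(1 / p)
    },
    mean = mean(values),
    geometric_mean = {
      if (any(values <= 0)) stop("domain: geometric mean needs positive values")
      exp(mean(log(values)))
    },
    harmonic_mean = {
      if (any(values <= 0)) stop("domain: harmonic mean needs positive values")
      length(values) / sum(1 / values)
    },
    variance = if (length(values) > 1L) stats::var(values) else 0,
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    skewness = adjusted_skewness(values),
    kurtosis = {
      m <- mean(values); s2 <- mean((values - m)^2)
      if (s2 == 0) 0 else mean((values - m)^4) / s2^2 - 3
    },
    min = min(values),
    max = max(values),
    range = max(values) - min(values))
}
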