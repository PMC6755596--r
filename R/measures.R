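#' Singleton (fuzzy-density) measure
#'
#' A singleton measure assigns to every element of a finite criterion set a
#' fuzzy density `s(x_i)` in `[0, 1]`, with the densities summing to 1.  It
#' fully parameterizes the L-m-delta, Sugeno lambda and P fuzzy measures.
#'
#' @param densities numeric vector of densities, one per element, in
#'   original element order.
#' @param scheme how the densities were generated: `"AO1"`, `"AO2"`,
#'   `"UNIFORM"` or `"USER"`.
#' @param alpha the exponent used by the AO generator (if any).
#' @return an object of class `singleton_measure`: the density vector with
#'   `scheme` and `alpha` attributes.
#' @seealso [ao1_densities()], [ao2_densities()], [lmdelta_measure()]
#' @export
singleton_measure <- function(densities, scheme = "USER", alpha = NA_real_) {
  densities <- as.numeric(densities)
  if (length(densities) < 1L) stop("empty-set: need at least one density")
  if (any(!is.finite(densities))) stop("invalid-density: non-finite density")
  if (any(densities < -1e-12) || any(densities > 1 + 1e-12))
    stop("invalid-density: densities must lie in [0, 1]")
  if (abs(sum(densities) - 1) > 1e-9)
    stop("invalid-density: densities must sum to 1 (tolerance 1e-9)")
  structure(pmin(pmax(densities, 0), 1),
            class = "singleton_measure", scheme = scheme, alpha = alpha)
}

#' @export
print.singleton_measure <- function(x, ...) {
  cat(sprintf("<singleton_measure> scheme=%s alpha=%s n=%d\n",
              attr(x, "scheme"), format(attr(x, "alpha")), length(x)))
  print(as.numeric(x), ...)
  invisible(x)
}

# strip class/attrs; accepts plain numeric vectors too
as_densities <- function(s) {
  d <- as.numeric(s)
  if (length(d) < 1L) stop("empty-set: no densities")
  d
}

#' AO1 singleton densities
#'
#' Aggregated Objects Type 1: the density of element i is
#' `b_i^alpha / sum_j b_j^alpha`, where `b_i` is that element's
#' (non-negative) value.  Densities are returned in the original element
#' order; the sorted formulation is order-equivalent because the
#' denominator is permutation-invariant.  The convention `0^0 = 1` makes
#' `alpha = 0` yield the uniform measure.
#'
#' @param values non-negative numeric vector (e.g. a LOVI vector).
#' @param alpha exponent in `[0, 1]`.
#' @return a [singleton_measure].  A degenerate denominator (all values 0
#'   with `alpha > 0`) yields uniform densities `1/n`.
#' @examples
#' ao1_densities(c(2, 1, 1), alpha = 1)   # 0.5 0.25 0.25
#' ao1_densities(c(7, 3, 9, 1), alpha = 0) # uniform
#' @export
ao1_densities <- function(values, alpha) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty-set: AO1 needs at least one value")
  if (any(!is.finite(values))) stop("negative-lovi: non-finite value")
  if (any(values < 0)) stop("negative-lovi: AO1 requires non-negative values")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  num <- values^alpha               # R already defines 0^0 = 1
  den <- sum(num)
  d <- if (den <= 0 || !is.finite(den)) rep(1 / length(values), length(values))
       else num / den
  singleton_measure(d, scheme = "AO1", alpha = alpha)
}

#' AO2 singleton densities
#'
#' Aggregated Objects Type 2: the density of element i is
#' `(1 - b_i)^alpha / sum_j (1 - b_j)^alpha`.  Raw LOVIs routinely exceed
#' 1, so the input is first min-max rescaled to `[0, 1]`; this guarantees
#' non-negative densities while preserving the ordering.  All-equal input
#' (degenerate rescaling) yields uniform densities.
#'
#' @inheritParams ao1_densities
#' @param values numeric vector (any sign; rescaled internally).
#' @return a [singleton_measure].
#' @examples
#' ao2_densities(c(5, 5, 5), alpha = 0.7)  # uniform
#' ao2_densities(c(0, 1), alpha = 1)       # c(1, 0)
#' @export
ao2_densities <- function(values, alpha) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty-set: AO2 needs at least one value")
  if (any(!is.finite(values))) stop("invalid-value: non-finite value")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  rng <- max(values) - min(values)
  if (rng <= 0) {
    d <- rep(1 / length(values), length(values))
  } else {
    b <- (values - min(values)) / rng
    num <- (1 - b)^alpha
    den <- sum(num)
    d <- if (den <= 0 || !is.finite(den)) rep(1 / length(values), length(values))
         else num / den
  }
  singleton_measure(d, scheme = "AO2", alpha = alpha)
}

check_subset <- function(subset, n) {
  if (length(subset) == 0L) return(integer(0))
  subset <- as.integer(subset)
  if (anyNA(subset) || any(subset < 1L) || any(subset > n))
    stop("bad-index: subset indices must lie in 1..", n)
  unique(subset)
}

#' The L-m-delta fuzzy measure
#'
#' Closed-form fuzzy measure combining the maximized L-measure and the
#' delta-measure.  For a subset `A` of the criterion set `X` (|X| = n) with
#' singleton densities `s` summing to 1:
#' \itemize{
#'   \item `L = -1`: `max_{x in A} s(x)` (the P-measure);
#'   \item `-1 < L <= 0`:
#'     `(1+L) S (1 + L m) / (1 + L S) - L m`, where `S = sum_{A} s` and
#'     `m = max_{A} s`; at `L = 0` this is additive;
#'   \item `L > 0`:
#'     `L (|A|-1) S (1-S) / ((n-|A|) sum_{X-A} s + L (|A|-1) S) + S`.
#' }
#' The boundary conditions `g(empty) = 0` and `g(X) = 1` are part of the
#' definition and hold for every `L` (at `L = -1` the branch formula alone
#' would give `max(s) < 1` on the full set for sum-normalized densities, so
#' the definitional boundary takes precedence there).  The measure is
#' non-decreasing in both the subset and `L`, subadditive for
#' `-1 < L < 0` and superadditive for `L > 0`.
#'
#' @param subset integer indices of the subset `A` (possibly empty).
#' @param s singleton densities: a [singleton_measure] or numeric vector
#'   summing to 1.
#' @param L synergy parameter, `L >= -1`.
#' @return the measure value in `[0, 1]`.
#' @examples
#' s <- c(0.5, 0.3, 0.2)
#' lmdelta_measure(c(1, 2), s, L = 0)    # additive: 0.8
#' lmdelta_measure(c(1, 2), s, L = -1)   # max: 0.5
#' lmdelta_measure(c(1, 2), s, L = 0.5)  # superadditive: 0.9333...
#' @export
lmdelta_measure <- function(subset, s, L) {
  s <- as_densities(s)
  n <- length(s)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < -1)
    stop("invalid-L: L must be a real >= -1")
  A <- check_subset(subset, n)
  if (length(A) == 0L) return(0)
  if (length(A) == n) return(1)    # definitional upper boundary, every L
  S  <- sum(s[A])
  mx <- max(s[A])
  if (L == -1) return(mx)
  if (L <= 0) return((1 + L) * S * (1 + L * mx) / (1 + L * S) - L * mx)
  a <- length(A)
  Srest <- sum(s[-A])              # = sum over X - A
  num <- L * (a - 1) * S * (1 - S)
  den <- (n - a) * Srest + L * (a - 1) * S
  if (den <= 0) return(S)          # singleton / degenerate limit
  num / den + S
}

#' The P-measure
#'
#' `mu(A) = max_{x in A} s(x)`; the L-m-delta measure at `L = -1` coincides
#' with it on proper subsets (on the full set the L-m-delta boundary
#' condition forces 1, whereas the plain P-measure of sum-normalized
#' densities tops out at `max(s)`).
#'
#' @inheritParams lmdelta_measure
#' @return the measure value.
#' @export
p_measure <- function(subset, s) {
  s <- as_densities(s)
  A <- check_subset(subset, length(s))
  if (length(A) == 0L) return(0)
  max(s[A])
}

#' Solve for the Sugeno lambda parameter
#'
#' The Sugeno lambda-measure requires `prod_i (1 + lambda s_i) = 1 + lambda`
#' with `lambda > -1`.  When the densities sum to 1 (this package's
#' convention for singleton measures) the unique admissible root is
#' `lambda = 0` (additivity).  For user-supplied unnormalized densities the
#' non-trivial root is bracketed on `(-1, 0)` (when `sum(s) > 1`) or
#' `(0, Inf)` (when `sum(s) < 1`) and solved by bisection to 1e-12.
#'
#' @param s densities (numeric vector, each in `(0, 1)`; need not sum to 1).
#' @return the lambda root (a single real > -1).
#' @export
sugeno_lambda_root <- function(s) {
  s <- as_densities(s)
  tot <- sum(s)
  if (abs(tot - 1) <= 1e-9) return(0)
  if (length(s) < 2L || any(s <= 0) || any(s >= 1))
    stop("no-lambda-root: densities must lie in (0, 1) with n >= 2 when sum != 1")
  f <- function(lam) prod(1 + lam * s) - 1 - lam
  if (tot > 1) { lo <- -1 + 1e-12; hi <- -1e-12 } else {
    lo <- 1e-12; hi <- 1
    while (f(hi) <= 0 && hi < 1e6) hi <- hi * 2
  }
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no-lambda-root: could not bracket a root on (-1, Inf)")
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < 1e-12) break
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' The Sugeno lambda-measure
#'
#' `g(A) = (prod_{i in A} (1 + lambda s_i) - 1) / lambda` for
#' `lambda != 0`, and `sum_{i in A} s_i` for `lambda = 0`.
#'
#' @inheritParams lmdelta_measure
#' @param lambda the lambda parameter, typically from
#'   [sugeno_lambda_root()].
#' @return the measure value.
#' @export
sugeno_lambda_measure <- function(subset, s, lambda) {
  s <- as_densities(s)
  A <- check_subset(subset, length(s))
  if (length(A) == 0L) return(0)
  if (lambda == 0) return(sum(s[A]))
  (prod(1 + lambda * s[A]) - 1) / lambda
}
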