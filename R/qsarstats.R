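#' Ordinary least-squares regression model
#'
#' Fits `y ~ X` with an intercept and reports the training diagnostics
#' used for QSAR model assessment (R-squared and the Fisher F statistic).
#'
#' @param X numeric design matrix (cases x variables), without an
#'   intercept column.
#' @param y numeric response vector.
#' @return an object of class `mlr_model` with elements `coefficients`
#'   (named, intercept first), `fitted`, `residuals`, `r2`, `fisher_f`,
#'   `labels`.
#' @export
mlr_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) stop("singular-design: design matrix is rank deficient")
  fit <- stats::lm.fit(Xi, y)
  fitted <- Xi %*% fit$coefficients
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  p <- ncol(X); n <- length(y)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  f <- if (rss == 0 || p == 0) Inf
       else ((tss - rss) / p) / (rss / (n - p - 1))
  structure(list(coefficients = fit$coefficients, labels = colnames(X),
                 fitted = as.numeric(fitted), residuals = y - as.numeric(fitted),
                 r2 = r2, fisher_f = f),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d variable(s), R2 = %.4f, F = %.3f\n",
              length(x$labels), x$r2, x$fisher_f))
  print(x$coefficients, ...)
  invisible(x)
}

#' Predict from an `mlr_model`
#' @param object an [mlr_fit()] model.
#' @param newdata matrix with the model's variables as columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && all(object$labels %in% colnames(newdata)))
    newdata <- newdata[, object$labels, drop = FALSE]
  as.numeric(cbind(1, newdata) %*% object$coefficients)
}

# leave-one-out residuals via the exact OLS identity e_i / (1 - h_i);
# algebraically identical to refitting with each case held out
loo_press <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  if (qr(Xi)$rank < ncol(Xi)) stop("singular-design: design matrix is rank deficient")
  fit <- stats::lm.fit(Xi, y)
  h <- rowSums(qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]^2)
  e <- y - Xi %*% fit$coefficients
  sum((e / (1 - h))^2)
}

#' Leave-one-out cross-validated Q-squared
#'
#' `Q2_loo = 1 - PRESS / sum((y - mean(y))^2)`, where PRESS accumulates
#' the squared prediction error of each case when it is held out of the
#' fit.  Computed through the exact hat-matrix identity for OLS, which
#' reproduces the explicit refits to machine precision.
#'
#' @inheritParams mlr_fit
#' @return Q2_loo (at most 1; 1 iff PRESS is 0).
#' @export
q2_loo <- function(X, y) {
  y <- as.numeric(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("degenerate-response: constant y")
  1 - loo_press(X, y) / tss
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Bootstrap Q-squared
#'
#' Mean over `B` seeded bootstrap resamples of the out-of-bag predictive
#' q-squared: the model is refit on each resample and evaluated on the
#' cases it did not draw, against the resample's training mean.  Empty
#' out-of-bag sets are skipped.
#'
#' @inheritParams mlr_fit
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return mean out-of-bag q-squared.
#' @export
q2_boot <- function(X, y, B = 1000L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  with_seed(seed, {
    qs <- numeric(0)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) == 0L) next
      Xi <- cbind(1, X[idx, , drop = FALSE])
      if (qr(Xi)$rank < ncol(Xi)) next
      beta <- stats::lm.fit(Xi, y[idx])$coefficients
      pred <- cbind(1, X[oob, , drop = FALSE]) %*% beta
      den <- sum((y[oob] - mean(y[idx]))^2)
      if (den == 0) next
      qs <- c(qs, 1 - sum((y[oob] - pred)^2) / den)
    }
    mean(qs)
  })
}

#' External-validation Q-squared
#'
#' `Q2_ext = 1 - sum((yhat - y_test)^2) / sum((y_test - ybar_train)^2)`:
#' test-set prediction error referenced to the training-set mean.
#'
#' @param model an [mlr_fit()] model.
#' @param X_test,y_test external test set.
#' @param ybar_train mean of the training responses.
#' @return Q2_ext.
#' @export
q2_ext <- function(model, X_test, y_test, ybar_train) {
  pred <- predict(model, X_test)
  den <- sum((y_test - ybar_train)^2)
  if (den == 0) stop("degenerate-response: test responses equal the training mean")
  1 - sum((pred - y_test)^2) / den
}

#' Y-scrambling (response permutation) test
#'
#' Mean R-squared over `K` seeded permutations of the response; a model
#' fitting signal rather than chance should score far above this baseline.
#'
#' @inheritParams mlr_fit
#' @param K number of permutations.
#' @param seed integer seed.
#' @return mean scrambled R-squared.
#' @export
y_scramble <- function(X, y, K = 300L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  with_seed(seed, mean(vapply(seq_len(K), function(k)
    mlr_fit(X, sample(y))$r2, numeric(1))))
}

#' Genetic-algorithm variable selection for MLR
#'
#' Seeded GA over variable subsets of fixed size `n_vars`, with fitness
#' `Q2_loo`: tournament selection (size 3), uniform crossover, per-bit
#' mutation rate `1/p`, elitism of one.  Deterministic for a fixed seed.
#'
#' @inheritParams mlr_fit
#' @param n_vars subset size to select.
#' @param pop population size.
#' @param gens number of generations (`0` evaluates the random initial
#'   population only).
#' @param seed integer seed.
#' @return the best subset's [mlr_fit()] model, with the achieved fitness
#'   in `$q2_loo` and the selected column indices in `$selected`.
#' @export
ga_select <- function(X, y, n_vars, pop = 50L, gens = 100L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  stopifnot(n_vars >= 1L, n_vars <= p)
  fitness <- function(sub) tryCatch(q2_loo(X[, sub, drop = FALSE], y),
                                    error = function(e) -Inf)
  # chromosomes are p-bit membership masks, repaired to exactly n_vars bits
  repair <- function(mask) {
    on <- which(mask)
    if (length(on) > n_vars) mask[sample(on, length(on) - n_vars)] <- FALSE
    else if (length(on) < n_vars) {
      off <- which(!mask)
      mask[if (length(off) == 1L) off else sample(off, n_vars - length(on))] <- TRUE
    }
    mask
  }
  as_mask <- function(sub) { m <- logical(p); m[sub] <- TRUE; m }
  with_seed(seed, {
    popl <- replicate(pop, as_mask(sample.int(p, n_vars)), simplify = FALSE)
    fits <- vapply(popl, function(m) fitness(which(m)), numeric(1))
    for (g in seq_len(gens)) {
      nextl <- list(popl[[which.max(fits)]])          # elitism
      while (length(nextl) < pop) {
        pick <- function() {
          cand <- sample.int(pop, 3L)
          popl[[cand[which.max(fits[cand])]]]
        }
        pa <- pick(); pb <- pick()
        keep <- stats::runif(p) < 0.5                 # uniform crossover
        child <- ifelse(keep, pa, pb)
        flip <- stats::runif(p) < 1 / p               # per-bit mutation
        child <- xor(child, flip)
        nextl[[length(nextl) + 1L]] <- repair(child)
      }
      popl <- nextl
      fits <- vapply(popl, function(m) fitness(which(m)), numeric(1))
    }
    best <- which(popl[[which.max(fits)]])
    model <- mlr_fit(X[, best, drop = FALSE], y)
    model$selected <- best
    model$q2_loo <- max(fits)
    model
  })
}

#' Variability pre-filter for descriptor columns
#'
#' Ranks descriptor columns by the Shannon entropy of their `bins`-bin
#' histogram (a variability criterion: flat distributions score high,
#' spiked ones low) and keeps the `top_m` most variable.  Constant columns
#' always rank last and are dropped.  Ties are broken by column label.
#'
#' @param m numeric matrix with column names.
#' @param top_m number of columns to keep.
#' @param bins histogram bin count.
#' @return character vector of retained column names, best first.
#' @export
variability_filter <- function(m, top_m, bins = 10L) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  ent <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[is.finite(x)]
    if (length(x) == 0L || max(x) == min(x)) return(-Inf)
    cnt <- tabulate(pmin(bins, 1L + floor((x - min(x)) / (max(x) - min(x)) * bins)),
                    nbins = bins)
    pr <- cnt[cnt > 0] / sum(cnt)
    -sum(pr * log2(pr))
  }, numeric(1))
  ord <- order(-ent, colnames(m))
  keep <- ord[seq_len(min(top_m, ncol(m)))]
  keep <- keep[is.finite(ent[keep])]
  colnames(m)[keep]
}

#' Friedman first-step ranks and best-configuration selection
#'
#' `friedman_ranks` ranks the configurations within each row of a
#' statistics-by-configurations matrix (best = rank 1, midranks for ties;
#' by default larger statistic values are better) and averages the ranks
#' per configuration.  `select_best` applies the selection rule: keep the
#' configurations whose average rank is below
#' `mean(average ranks) - sd(average ranks)`.
#'
#' @param results numeric matrix, statistics (rows) x configurations
#'   (columns).
#' @param larger_is_better rank direction.
#' @return `friedman_ranks`: list with `ranks` (matrix of within-row
#'   ranks) and `avg` (named average rank per configuration).
#' @export
friedman_ranks <- function(results, larger_is_better = TRUE) {
  results <- as.matrix(results)
  if (is.null(colnames(results))) colnames(results) <- paste0("c", seq_len(ncol(results)))
  ranks <- t(apply(results, 1L, function(r)
    rank(if (larger_is_better) -r else r, ties.method = "average")))
  colnames(ranks) <- colnames(results)
  list(ranks = ranks, avg = colMeans(ranks))
}

#' @rdname friedman_ranks
#' @param ranks result of `friedman_ranks`.
#' @return `select_best`: character vector of selected configuration
#'   names (possibly empty).
#' @export
select_best <- function(ranks) {
  avg <- ranks$avg
  names(avg)[avg < mean(avg) - stats::sd(avg)]
}

# exact null distribution of W+ by convolution over 2*|rank| integer
# weights; equivalent to enumerating all 2^m sign assignments
wplus_tail_probs <- function(ranks2, Wobs2) {
  counts <- c(1, numeric(sum(ranks2)))     # counts[s + 1] = #assignments with W+ = s/2
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  total <- 2^length(ranks2)
  s <- seq_along(counts) - 1
  c(lower = sum(counts[s <= Wobs2]) / total,
    upper = sum(counts[s >= Wobs2]) / total)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test with the exact null distribution obtained by
#' enumerating all `2^m` sign assignments (as a convolution over the
#' ranks, which handles midranks for tied absolute differences).  Zero
#' differences are dropped; the two-sided p doubles the smaller one-sided
#' tail and is capped at 1.
#'
#' @param x,y paired numeric vectors.
#' @return list with `w_plus` (sum of positive-difference ranks), `m`
#'   (non-zero pairs) and `p_two_sided`.
#' @examples
#' pr <- qext_pairs()
#' wilcoxon_exact(pr$q2_ext_fuzzy, pr$q2_ext_nonfuzzy)$p_two_sided  # 0.0078125
#' @export
wilcoxon_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("degenerate-pairs: all differences are zero")
  if (m > 25L) stop("too-many-pairs: exact enumeration limited to m <= 25")
  r <- rank(abs(d), ties.method = "average")
  wplus <- sum(r[d > 0])
  tails <- wplus_tail_probs(as.integer(round(2 * r)), round(2 * wplus))
  list(w_plus = wplus, m = m,
       p_two_sided = min(1, 2 * min(tails)))
}

#' Adjusted (sample) skewness
#'
#' The adjusted Fisher-Pearson coefficient
#' `n / ((n-1)(n-2)) * sum(((x - xbar) / s)^3)` with `s` the
#' (n-1)-denominator sample standard deviation -- the convention used by
#' SPSS and spreadsheet software.
#'
#' @param values numeric vector (length >= 3 for a non-zero result).
#' @return skewness coefficient.
#' @export
adjusted_skewness <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) return(0)
  s <- stats::sd(x)
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Percent improvement
#'
#' `100 * (f - nf) / nf`: the relative gain of a fuzzy model's statistic
#' `f` over its non-fuzzy counterpart `nf`.
#'
#' @param f,nf numeric values (vectorized).
#' @return percent improvement.
#' @export
percent_improvement <- function(f, nf) 100 * (f - nf) / nf

#' Published paired external-validation values
#'
#' The packaged table of external-validation Q-squared values for the
#' best 7-variable models built with fuzzy (Choquet-integral) and
#' non-fuzzy descriptors on eight benchmark QSAR datasets (ACE, ACHE,
#' BZR, COX2, DHFR, GPB, THER, THR), transcribed from the published
#' comparison.  It is the input fixture for the fuzzy-vs-non-fuzzy
#' comparison statistics.
#'
#' @return data.frame with columns `dataset`, `q2_ext_fuzzy`,
#'   `q2_ext_nonfuzzy` (8 rows).
#' @export
qext_pairs <- function() {
  f <- system.file("extdata", "qext_pairs.csv", package = "choqmd")
  utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
}

#' Fuzzy-vs-non-fuzzy comparison report
#'
#' Recomputes, from a paired performance table alone, the comparison
#' statistics between fuzzy and non-fuzzy descriptor models: the exact
#' Wilcoxon signed-rank p-value, the adjusted skewness of each column,
#' per-dataset percent improvements, and five-number summaries of both
#' columns.
#'
#' @param table a paired table as returned by [qext_pairs()] (the
#'   default).
#' @return list with `wilcoxon` (from [wilcoxon_exact()]),
#'   `skewness_fuzzy`, `skewness_nonfuzzy`, `improvements_pct` (named by
#'   dataset, sorted decreasing) and `summary` (min/quartiles/max per
#'   column).
#' @export
paper_comparison_report <- function(table = qext_pairs()) {
  stopifnot(all(c("dataset", "q2_ext_fuzzy", "q2_ext_nonfuzzy") %in% names(table)))
  imp <- stats::setNames(
    percent_improvement(table$q2_ext_fuzzy, table$q2_ext_nonfuzzy),
    table$dataset)
  fn <- function(x) stats::setNames(as.numeric(stats::quantile(x, c(0, .25, .5, .75, 1))),
                                    c("min", "q1", "median", "q3", "max"))
  list(wilcoxon = wilcoxon_exact(table$q2_ext_fuzzy, table$q2_ext_nonfuzzy),
       skewness_fuzzy = adjusted_skewness(table$q2_ext_fuzzy),
       skewness_nonfuzzy = adjusted_skewness(table$q2_ext_nonfuzzy),
       improvements_pct = sort(imp, decreasing = TRUE),
       summary = list(fuzzy = fn(table$q2_ext_fuzzy),
                      nonfuzzy = fn(table$q2_ext_nonfuzzy)))
}
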