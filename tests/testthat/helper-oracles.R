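# Independent oracle implementations used only by the tests.
# These deliberately do not share code paths with the package internals.

# all subsets of 1..n as a list (including the empty set)
all_subsets <- function(n) {
  out <- list(integer(0))
  for (mask in seq_len(2^n - 1)) {
    out[[mask + 1L]] <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
  }
  out
}

# literal transcription of the printed 3-element Choquet expansion:
# C = x_(1)[mu(T1) - mu(T2)] + x_(2)[mu(T2) - mu(T3)] + x_(3) mu(T3)
# generalized term-by-term for n <= 4, with T_i the descending tails.
choquet_bruteforce <- function(values, mu) {
  n <- length(values)
  stopifnot(n <= 4)
  ord <- order(-values, seq_len(n))
  total <- 0
  for (i in seq_len(n)) {
    Ti  <- ord[i:n]
    Tip <- if (i < n) ord[(i + 1):n] else integer(0)
    mu_next <- if (length(Tip) > 0) mu(Tip) else 0
    total <- total + values[ord[i]] * (mu(Ti) - mu_next)
  }
  total
}

# classic (non-fuzzy) descriptor family oracles: plain summation forms
classic_md1 <- function(L, ap, lp) ap * sum(L^lp)

classic_md4 <- function(L, adj, ap, lp) {
  n <- length(L)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (adj[i, j] == 1) tot <- tot + (L[i] * L[j])^lp
  ap * tot
}

classic_md5 <- function(L, ap, lp) {
  n <- length(L)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) tot <- tot + (L[i] * L[j])^lp
  ap * tot
}

# product form over fragments (the classic Kier-Hall shape)
classic_md6 <- function(L, fragments, ap, lp) {
  ap * sum(vapply(fragments, function(fr) prod(L[fr])^lp, numeric(1)))
}

classic_md7 <- function(L, adj, frag, ap, lp) {
  tot <- 0
  for (i in frag) for (j in frag)
    if (adj[i, j] == 1) tot <- tot + (L[i] * L[j])^lp
  ap * tot
}

# fresh Sinkhorn/IPF implementation run to a tighter tolerance
ipf_oracle <- function(m, tol = 1e-10, iters = 5000) {
  for (it in seq_len(iters)) {
    m <- m / rowSums(m)
    m <- t(t(m) / colSums(m))
    if (max(abs(rowSums(m) - 1), abs(colSums(m) - 1)) < tol) break
  }
  m
}

# exact Wilcoxon by literal enumeration of all 2^m sign assignments
wilcoxon_bruteforce <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  ws <- numeric(2^m)
  for (mask in 0:(2^m - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L
    ws[mask + 1L] <- sum(r[signs])
  }
  lower <- mean(ws <= wobs + 1e-9)
  upper <- mean(ws >= wobs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# rigid motion: random rotation (QR of a Gaussian matrix) plus translation
rigid_motion <- function(coords, seed = 99) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, c(3.2, -1.5, 0.7), "+")
}

random_density <- function(n) {
  d <- runif(n)
  d / sum(d)
}
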