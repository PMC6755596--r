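#' Vertex degrees
#'
#' The classical local vertex invariant: the degree of each atom in the
#' bond graph.
#'
#' @param mol a [molecule].
#' @return numeric vector of length `n_atoms(mol)`.
#' @export
vertex_degrees <- function(mol) rowSums(adjacency(mol))

#' Inter-atomic relation matrix (k = 1, non-stochastic)
#'
#' Pairwise geometric relations between atoms:
#' \describe{
#'   \item{euclidean}{`||r_i - r_j||_2` in Angstrom;}
#'   \item{soergel}{coordinates are first translated per axis so the
#'     minimum is 0 (the coefficient needs the non-negative octant), then
#'     `sum_k |a_k - b_k| / sum_k max(a_k, b_k)` (0 when both atoms sit at
#'     the origin).}
#' }
#' The diagonal is 0 and the matrix is symmetric.
#'
#' @param mol a [molecule].
#' @param metric `"euclidean"` or `"soergel"`.
#' @return `n x n` numeric matrix.
#' @export
relation_matrix <- function(mol, metric = c("euclidean", "soergel")) {
  metric <- match.arg(metric)
  n <- n_atoms(mol)
  if (n == 0L) stop("empty-molecule")
  if (metric == "euclidean") {
    m <- as.matrix(stats::dist(mol$coords))
    dimnames(m) <- NULL
    return(m)
  }
  xyz <- sweep(mol$coords, 2L, apply(mol$coords, 2L, min))
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    den <- sum(pmax(xyz[i, ], xyz[j, ]))
    m[i, j] <- if (den == 0) 0 else sum(abs(xyz[i, ] - xyz[j, ])) / den
  }
  m
}

#' Hadamard (entrywise) matrix power
#'
#' Entrywise k-th power, `k` in `-12..-1, 1..12`.  For negative `k` the
#' reciprocal power is applied off-diagonal only: zero entries map to 0
#' and the diagonal is set to 0, so the power range is usable on hollow
#' relation matrices without division by zero.
#'
#' @param m numeric matrix.
#' @param k integer power.
#' @return numeric matrix.
#' @export
hadamard_power <- function(m, k) {
  k <- as.integer(k)
  if (is.na(k) || k == 0L || abs(k) > 12L)
    stop("invalid-k: k must be a non-zero integer in -12..12")
  if (k > 0L) return(m^k)
  out <- m
  nz <- m != 0
  out[nz] <- m[nz]^k
  out[!nz] <- 0
  diag(out) <- 0
  out
}

#' Stochastic normalization of a relation matrix
#'
#' \describe{
#'   \item{ns}{non-stochastic: returned unchanged;}
#'   \item{ss}{simple-stochastic: each row divided by its row sum (zero
#'     rows are left as zeros, with a message);}
#'   \item{ds}{double-stochastic: alternating row/column (Sinkhorn)
#'     scaling until every row and column sum is within 1e-8 of 1, at most
#'     1000 iterations;}
#'   \item{mp}{mutual probability: all entries divided by the grand sum.}
#' }
#'
#' @param m non-negative numeric matrix.
#' @param scheme `"ns"`, `"ss"`, `"ds"` or `"mp"`.
#' @return normalized matrix.
#' @export
normalize_matrix <- function(m, scheme = c("ns", "ss", "ds", "mp")) {
  scheme <- match.arg(scheme)
  if (scheme == "ns") return(m)
  if (scheme == "ss") {
    rs <- rowSums(m)
    zero <- rs == 0
    if (any(zero)) message("normalize_matrix: leaving ", sum(zero), " zero row(s) as zeros")
    rs[zero] <- 1
    return(m / rs)
  }
  if (scheme == "mp") {
    gs <- sum(m)
    if (gs == 0) stop("degenerate-matrix: grand sum is 0")
    return(m / gs)
  }
  # ds: Sinkhorn iteration
  out <- m
  for (it in seq_len(1000L)) {
    rs <- rowSums(out)
    if (any(rs == 0)) stop("degenerate-matrix: zero row in ds normalization")
    out <- out / rs
    cs <- colSums(out)
    if (any(cs == 0)) stop("degenerate-matrix: zero column in ds normalization")
    out <- sweep(out, 2L, cs, "/")
    res <- max(abs(rowSums(out) - 1), abs(colSums(out) - 1))
    if (res < 1e-8) return(out)
  }
  stop("sinkhorn-no-converge: residual ", format(res), " after 1000 iterations")
}

#' Atom-level split of a relation matrix
#'
#' Keeps row `a` and column `a` of the matrix and zeroes everything else,
#' yielding the atom-level matrix for atom `a`.  Summing the splits over
#' all atoms counts every off-diagonal entry twice (and the diagonal
#' once), which is documented so users needing a strict partition can
#' halve.
#'
#' @param m `n x n` numeric matrix.
#' @param a atom index.
#' @return `n x n` matrix, non-zero only on row/column `a`.
#' @export
atom_level_split <- function(m, a) {
  n <- nrow(m)
  a <- as.integer(a)
  if (is.na(a) || a < 1L || a > n) stop("bad-index: atom out of range")
  out <- matrix(0, n, n)
  out[a, ] <- m[a, ]
  out[, a] <- m[, a]
  out
}

#' Bilinear and linear algebraic forms on an atom-level matrix
#'
#' `bilinear_lovi` contracts the atom-level matrix with two property
#' vectors: `sum_ij m_ij x_i y_j`.  `linear_lovi` sums the entries of
#' `m %*% y`, i.e. the bilinear form with `x` the all-ones vector.
#'
#' @param am atom-level matrix (from [atom_level_split()]).
#' @param x,y per-atom property vectors.
#' @return single numeric LOVI value.
#' @export
bilinear_lovi <- function(am, x, y) as.numeric(t(as.numeric(x)) %*% am %*% as.numeric(y))

#' @rdname bilinear_lovi
#' @export
linear_lovi <- function(am, y) sum(am %*% as.numeric(y))

#' Configuration for geometric two-linear LOVIs
#'
#' Bundles the choices of the relation-matrix pipeline: metric, matrix
#' power, stochastic normalization, property vector(s) and algebraic form.
#'
#' @param metric `"euclidean"` or `"soergel"`.
#' @param normalization `"ns"`, `"ss"`, `"ds"` or `"mp"`.
#' @param k Hadamard power (non-zero integer in `-12..12`).
#' @param property per-atom property for the contraction (bundled table
#'   column or user value), used as `y` (and as `x` unless `property2`).
#' @param property2 optional second property for the bilinear form.
#' @param form `"linear"` (sum of `m %*% y`) or `"bilinear"`
#'   (`x' m y`).
#' @param power_after_norm apply the Hadamard power after (instead of
#'   before) the stochastic normalization.
#' @param include_h keep hydrogen atoms (default) or strip them before the
#'   pipeline.
#' @param user_csv optional property-override CSV (see
#'   [property_vector()]).
#' @return an object of class `qubils_config`.
#' @export
qubils_config <- function(metric = "euclidean", normalization = "ss", k = 1L,
                          property = "electronegativity", property2 = NULL,
                          form = c("linear", "bilinear"),
                          power_after_norm = FALSE, include_h = TRUE,
                          user_csv = NULL) {
  structure(list(metric = match.arg(metric, c("euclidean", "soergel")),
                 normalization = match.arg(normalization, c("ns", "ss", "ds", "mp")),
                 k = as.integer(k), property = property, property2 = property2,
                 form = match.arg(form), power_after_norm = power_after_norm,
                 include_h = include_h, user_csv = user_csv),
            class = "qubils_config")
}

strip_hydrogens <- function(mol) {
  keep <- which(mol$atoms != "H")
  if (length(keep) == n_atoms(mol)) return(mol)
  if (length(keep) == 0L) stop("empty-molecule: only hydrogens present")
  remap <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    ok <- !is.na(remap[b[, 1]]) & !is.na(remap[b[, 2]])
    b <- b[ok, , drop = FALSE]
    b[, 1] <- remap[b[, 1]]; b[, 2] <- remap[b[, 2]]
  }
  molecule(mol$atoms[keep], mol$coords[keep, , drop = FALSE], b, mol$name)
}

#' Geometric two-linear atom-level descriptors (LOVIs)
#'
#' Runs the full pipeline: relation matrix -> Hadamard power -> stochastic
#' normalization -> per-atom split -> (bi)linear contraction with the
#' property vector(s).  By default the power is applied to the
#' non-stochastic matrix before normalization; `power_after_norm` in the
#' configuration swaps the order.
#'
#' @param mol a [molecule].
#' @param config a [qubils_config].
#' @return numeric LOVI vector, one entry per (retained) atom.
#' @export
qubils_lovis <- function(mol, config) {
  stopifnot(inherits(config, "qubils_config"))
  if (!config$include_h) mol <- strip_hydrogens(mol)
  g <- relation_matrix(mol, config$metric)
  if (config$power_after_norm) {
    g <- normalize_matrix(g, config$normalization)
    g <- hadamard_power(g, config$k)
  } else {
    g <- hadamard_power(g, config$k)
    g <- normalize_matrix(g, config$normalization)
  }
  y <- property_vector(mol, config$property, config$user_csv)
  x <- if (is.null(config$property2)) y
       else property_vector(mol, config$property2, config$user_csv)
  n <- n_atoms(mol)
  vapply(seq_len(n), function(a) {
    am <- atom_level_split(g, a)
    if (config$form == "linear") linear_lovi(am, y) else bilinear_lovi(am, x, y)
  }, numeric(1))
}

#' Simple paths with m edges
#'
#' Enumerates all simple paths of `m` edges in the bond graph; each
#' undirected path is reported once, oriented so its lexicographically
#' smaller endpoint comes first.  `m = 0` yields the single vertices.
#'
#' @param mol a [molecule].
#' @param m path length in edges (`>= 0`).
#' @return list of integer vertex vectors (each of length `m + 1`).
#' @export
path_fragments <- function(mol, m) {
  m <- as.integer(m)
  if (m < 0L) stop("invalid-order: m must be >= 0")
  n <- n_atoms(mol)
  if (m == 0L) return(as.list(seq_len(n)))
  g <- mol_graph(mol)
  out <- list()
  for (v in seq_len(n)) {
    ps <- igraph::all_simple_paths(g, from = v, cutoff = m)
    for (p in ps) {
      p <- as.integer(p)
      if (length(p) == m + 1L && p[1] < p[length(p)]) out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Cyclomatic number (ring count)
#'
#' `C = B - n + (number of connected components)` for a bond graph with
#' `B` edges and `n` atoms.
#'
#' @param mol a [molecule].
#' @return integer ring count.
#' @export
cyclomatic_number <- function(mol) {
  nrow(mol$bonds) - n_atoms(mol) + igraph::components(mol_graph(mol))$no
}

#' Bond-angle and dihedral multi-metric tensors
#'
#' Three-tuple tensor: `entry(i, j, l)` is the angle (degrees) at the
#' middle index `j` for pairwise-distinct indices, 0 otherwise.
#' Four-tuple tensor: the signed dihedral angle (degrees) of the ordered
#' quadruple, 0 when indices repeat.  These feed the tri-/quadrilinear
#' extensions of the two-linear pipeline.
#'
#' @param mol a [molecule].
#' @param multimetric `"bond_angle"` (order 3) or `"dihedral"` (order 4).
#' @return dense numeric array of rank 3 or 4.
#' @export
tuple_tensor <- function(mol, multimetric = c("bond_angle", "dihedral")) {
  multimetric <- match.arg(multimetric)
  n <- n_atoms(mol)
  xyz <- mol$coords
  if (multimetric == "bond_angle") {
    arr <- array(0, c(n, n, n))
    for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) {
      if (anyDuplicated(c(i, j, l))) next
      arr[i, j, l] <- bond_angle(xyz[i, ], xyz[j, ], xyz[l, ])
    }
    return(arr)
  }
  arr <- array(0, c(n, n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) for (h in seq_len(n)) {
    if (anyDuplicated(c(i, j, l, h))) next
    arr[i, j, l, h] <- dihedral_angle(xyz[i, ], xyz[j, ], xyz[l, ], xyz[h, ])
  }
  arr
}

#' Geometric angles
#'
#' `bond_angle` returns the angle (degrees) at `b` in the triple
#' `a - b - c`; `dihedral_angle` the signed dihedral (degrees) of the
#' ordered quadruple `a - b - c - d`.
#'
#' @param a,b,c,d 3D coordinate vectors.
#' @return angle in degrees.
#' @export
bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' @rdname bond_angle
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
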