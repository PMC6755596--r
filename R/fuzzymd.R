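#' Aggregation specifications
#'
#' `agg_choquet()` describes a Choquet-integral aggregation: the fuzzy
#' measure family with its parameter and the singleton-density generator.
#' Densities are recomputed from the very multiset being fused (the
#' transformed LOVIs or pair contributions), so the belonging degree of a
#' contribution is determined by its magnitude within the set.
#' `agg_classical()` describes a non-fuzzy baseline operator.
#'
#' @param measure fuzzy measure family: `"lmdelta"`, `"sugeno"` or `"p"`.
#' @param L synergy parameter of the L-m-delta measure (`>= -1`); ignored
#'   by the other families.
#' @param singleton density generator: `"ao1"`, `"ao2"` or `"uniform"`.
#' @param alpha exponent of the AO generator, in `[0, 1]`.
#' @param standard use the textbook ascending Choquet convention (see
#'   [choquet()]).
#' @return an object of class `agg_spec`.
#' @examples
#' agg_choquet(L = 0.5, singleton = "ao1", alpha = 0.2)
#' agg_classical("norm", p = 2)
#' @export
agg_choquet <- function(measure = "lmdelta", L = 0,
                        singleton = c("ao1", "ao2", "uniform"), alpha = 0,
                        standard = FALSE) {
  structure(list(kind = "choquet",
                 measure = match.arg(measure, c("lmdelta", "sugeno", "p")),
                 L = L, singleton = match.arg(singleton), alpha = alpha,
                 standard = standard),
            class = "agg_spec")
}

#' @rdname agg_choquet
#' @param stat,p classical operator and Minkowski exponent, as in
#'   [classical_aggregate()].
#' @export
agg_classical <- function(stat = "sum", p = 2) {
  structure(list(kind = "classical", stat = stat, p = p), class = "agg_spec")
}

#' Aggregate a contribution multiset under a specification
#'
#' For a Choquet specification, the singleton densities are generated from
#' `values` itself (AO1/AO2/uniform), the configured fuzzy measure is
#' built on them, and [choquet()] is applied.  For a classical
#' specification, [classical_aggregate()] is dispatched.
#'
#' @param values numeric vector of contributions.
#' @param agg an [agg_choquet()] / [agg_classical()] specification.
#' @return the aggregated value.
#' @export
fuzzy_aggregate <- function(values, agg) {
  stopifnot(inherits(agg, "agg_spec"))
  if (agg$kind == "classical")
    return(classical_aggregate(values, agg$stat, agg$p))
  n <- length(values)
  if (n == 0L) stop("empty-set: nothing to aggregate")
  dens <- switch(agg$singleton,
                 ao1 = as.numeric(ao1_densities(values, agg$alpha)),
                 ao2 = as.numeric(ao2_densities(values, agg$alpha)),
                 uniform = rep(1 / n, n))
  mu <- switch(agg$measure,
               lmdelta = function(A) lmdelta_measure(A, dens, agg$L),
               p = function(A) p_measure(A, dens),
               sugeno = {
                 lam <- sugeno_lambda_root(dens)
                 function(A) sugeno_lambda_measure(A, dens, lam)
               })
  choquet(values, mu, standard = agg$standard)
}

transform_lovis <- function(L, alpha_prime, lambda_prime) {
  if (any(L < 0) || (any(L == 0) && lambda_prime < 0))
    stop("domain: LOVIs must be positive for this exponent")
  t <- alpha_prime * L^lambda_prime
  if (any(!is.finite(t))) stop("domain: non-finite transformed LOVI")
  t
}

#' Fuzzy descriptor family FMD1 (power-sum type)
#'
#' Classic form: `alpha' * sum_i L_i^lambda'`.  Fuzzy form: the Choquet
#' aggregation of the transformed vector
#' `(alpha' L_1^lambda', ..., alpha' L_n^lambda')`, with singleton
#' densities computed from that same transformed vector.  With the
#' first-Zagreb parameters (`alpha' = 1`, `lambda' = 2`) on vertex degrees
#' this is the fuzzy first Zagreb index.
#'
#' @param L numeric LOVI vector.
#' @param alpha_prime,lambda_prime real parameters of the family.
#' @param agg an [agg_choquet()] specification.
#' @return single descriptor value.
#' @export
fmd1 <- function(L, alpha_prime = 1, lambda_prime = 1, agg = agg_choquet()) {
  fuzzy_aggregate(transform_lovis(L, alpha_prime, lambda_prime), agg)
}

ordered_pair_terms <- function(L, pairs, alpha_prime, lambda_prime) {
  if (nrow(pairs) == 0L) stop("no-edges: no contributing pairs")
  prod_ij <- L[pairs[, 1]] * L[pairs[, 2]]
  if (any(prod_ij < 0) || (any(prod_ij == 0) && lambda_prime < 0))
    stop("domain: non-positive LOVI product with this exponent")
  t <- alpha_prime * prod_ij^lambda_prime
  if (any(!is.finite(t))) stop("domain: non-finite pair contribution")
  t
}

adjacent_ordered_pairs <- function(mol, within = NULL) {
  a <- adjacency(mol)
  idx <- which(a == 1, arr.ind = TRUE)     # ordered pairs: both directions
  if (!is.null(within))
    idx <- idx[idx[, 1] %in% within & idx[, 2] %in% within, , drop = FALSE]
  idx
}

#' Fuzzy descriptor family FMD4 (adjacency-pair type)
#'
#' Classic form: `alpha' * sum_ij a_ij (L_i L_j)^lambda'` over the
#' adjacency matrix (each undirected edge contributes twice, once per
#' orientation).  Fuzzy form: the Choquet aggregation of the multiset of
#' ordered adjacent-pair contributions.  Pairs with `a_ij = 0` are
#' excluded from the multiset (they contribute nothing to the classic sum
#' but would distort the Choquet reordering); `include_zero_terms = TRUE`
#' restores the literal all-pairs reading with structural zeros.
#' Parameter choices give the fuzzy second Zagreb (`1, 1`), fuzzy Randic
#' (`1, -1/2`) and fuzzy Balaban-like (`B/(C+1), -1/2`) indices.
#'
#' @inheritParams fmd1
#' @param mol a [molecule] providing the adjacency.
#' @param include_zero_terms include non-adjacent ordered pairs as zero
#'   contributions.
#' @return single descriptor value.
#' @export
fmd4 <- function(L, mol, alpha_prime = 1, lambda_prime = 1,
                 agg = agg_choquet(), include_zero_terms = FALSE) {
  pairs <- adjacent_ordered_pairs(mol)
  t <- ordered_pair_terms(L, pairs, alpha_prime, lambda_prime)
  if (include_zero_terms) {
    n <- n_atoms(mol)
    t <- c(t, numeric(n * (n - 1L) - length(t)))
  }
  fuzzy_aggregate(t, agg)
}

#' Fuzzy descriptor family FMD5 (all-pairs type)
#'
#' As [fmd4()] but over all ordered pairs `i != j`, without the adjacency
#' factor; the multiset has `n (n - 1)` contributions.
#'
#' @inheritParams fmd4
#' @return single descriptor value.
#' @export
fmd5 <- function(L, alpha_prime = 1, lambda_prime = 1, agg = agg_choquet()) {
  n <- length(L)
  if (n < 2L) stop("no-edges: need at least two vertices")
  pairs <- which(matrix(TRUE, n, n) & !diag(TRUE, n), arr.ind = TRUE)
  fuzzy_aggregate(ordered_pair_terms(L, pairs, alpha_prime, lambda_prime), agg)
}

#' Fuzzy descriptor family FMD6 (fragment-product type)
#'
#' Classic form: `alpha' * sum_k (prod_{i in k} L_i)^lambda'` over graph
#' fragments `k`.  Fuzzy form: each fragment's `lambda'`-powered LOVIs are
#' Choquet-aggregated with densities recomputed (and hence renormalized)
#' within the fragment, and the per-fragment values are plainly summed and
#' scaled by `alpha'`.  With `lambda' = -1/2` over `m`-edge paths this is
#' the fuzzy Kier-Hall connectivity index of order `m`.
#'
#' @inheritParams fmd1
#' @param fragments list of integer vertex vectors (e.g. from
#'   [path_fragments()]).
#' @return single descriptor value (0, with a warning, for an empty
#'   fragment list).
#' @export
fmd6 <- function(L, fragments, alpha_prime = 1, lambda_prime = 1,
                 agg = agg_choquet()) {
  if (length(fragments) == 0L) {
    warning("fmd6: empty fragment list, returning 0")
    return(0)
  }
  per <- vapply(fragments, function(fr) {
    fuzzy_aggregate(transform_lovis(L[fr], 1, lambda_prime), agg)
  }, numeric(1))
  alpha_prime * sum(per)
}

#' Fuzzy descriptor family FMD7 (fragment autocorrelation type)
#'
#' As [fmd4()] restricted to ordered adjacent pairs whose endpoints both
#' lie in the given atom set; the basis of fuzzy autocorrelation
#' descriptors.
#'
#' @inheritParams fmd4
#' @param fragment integer vector of atom indices.
#' @return single descriptor value.
#' @export
fmd7 <- function(L, mol, fragment, alpha_prime = 1, lambda_prime = 1,
                 agg = agg_choquet()) {
  pairs <- adjacent_ordered_pairs(mol, within = fragment)
  fuzzy_aggregate(ordered_pair_terms(L, pairs, alpha_prime, lambda_prime), agg)
}

#' Named fuzzy topological indices
#'
#' Thin bindings of the FMD families on the vertex-degree LOVIs:
#' \describe{
#'   \item{fuzzy_first_zagreb}{FMD1 with `alpha' = 1, lambda' = 2`;}
#'   \item{fuzzy_second_zagreb}{FMD4 with `alpha' = 1, lambda' = 1`;}
#'   \item{fuzzy_randic}{FMD4 with `alpha' = 1, lambda' = -1/2`;}
#'   \item{fuzzy_balaban}{FMD4 with `alpha' = B / (C + 1)` (B edges, C
#'     rings) and `lambda' = -1/2`;}
#'   \item{fuzzy_kier_hall}{FMD6 with `lambda' = -1/2` over `m`-edge
#'     paths;}
#'   \item{fuzzy_autocorrelation}{FMD7 on the given atom set.}
#' }
#'
#' @param mol a [molecule].
#' @param agg an [agg_choquet()] specification.
#' @param m Kier-Hall path order (edges).
#' @param fragment atom set for the autocorrelation index.
#' @return single descriptor value.
#' @export
fuzzy_first_zagreb <- function(mol, agg = agg_choquet())
  fmd1(vertex_degrees(mol), 1, 2, agg)

#' @rdname fuzzy_first_zagreb
#' @export
fuzzy_second_zagreb <- function(mol, agg = agg_choquet())
  fmd4(vertex_degrees(mol), mol, 1, 1, agg)

#' @rdname fuzzy_first_zagreb
#' @export
fuzzy_randic <- function(mol, agg = agg_choquet())
  fmd4(vertex_degrees(mol), mol, 1, -0.5, agg)

#' @rdname fuzzy_first_zagreb
#' @export
fuzzy_balaban <- function(mol, agg = agg_choquet()) {
  B <- nrow(mol$bonds)
  C <- cyclomatic_number(mol)
  fmd4(vertex_degrees(mol), mol, B / (C + 1), -0.5, agg)
}

#' @rdname fuzzy_first_zagreb
#' @export
fuzzy_kier_hall <- function(mol, m = 1L, agg = agg_choquet())
  fmd6(vertex_degrees(mol), path_fragments(mol, m), 1, -0.5, agg)

#' @rdname fuzzy_first_zagreb
#' @export
fuzzy_autocorrelation <- function(mol, fragment = seq_len(n_atoms(mol)),
                                  agg = agg_choquet())
  fmd7(vertex_degrees(mol), mol, fragment, 1, 1, agg)

#' Global fuzzy geometric descriptor
#'
#' Choquet aggregation of the geometric two-linear LOVIs from
#' [qubils_lovis()]; identical to [fmd1()] with
#' `alpha' = lambda' = 1` on that LOVI vector.
#'
#' @param mol a [molecule].
#' @param qconfig a [qubils_config].
#' @param agg an [agg_choquet()] specification.
#' @return single descriptor value.
#' @export
fuzzy_qubils_global <- function(mol, qconfig = qubils_config(),
                                agg = agg_choquet()) {
  fmd1(qubils_lovis(mol, qconfig), 1, 1, agg)
}

#' Descriptor configuration
#'
#' One column of a descriptor matrix: which FMD family, its parameters,
#' the LOVI source and the aggregation.
#'
#' @param label unique column label.
#' @param family `"fmd1"`, `"fmd4"`, `"fmd5"`, `"fmd6"`, `"fmd7"` or
#'   `"qubils_global"`.
#' @param alpha_prime,lambda_prime family parameters.
#' @param lovis `"degree"` for vertex degrees or a [qubils_config] for
#'   geometric LOVIs.
#' @param m fragment path order (FMD6).
#' @param fragment atom set (FMD7); `NULL` for all atoms.
#' @param agg an [agg_choquet()] / [agg_classical()] specification.
#' @return an object of class `descriptor_config`.
#' @export
descriptor_config <- function(label, family = "fmd1", alpha_prime = 1,
                              lambda_prime = 1, lovis = "degree", m = 1L,
                              fragment = NULL, agg = agg_choquet()) {
  family <- match.arg(family, c("fmd1", "fmd4", "fmd5", "fmd6", "fmd7",
                                "qubils_global"))
  structure(list(label = label, family = family, alpha_prime = alpha_prime,
                 lambda_prime = lambda_prime, lovis = lovis, m = as.integer(m),
                 fragment = fragment, agg = agg),
            class = "descriptor_config")
}

lovis_for <- function(mol, config) {
  if (inherits(config$lovis, "qubils_config")) qubils_lovis(mol, config$lovis)
  else if (identical(config$lovis, "degree")) vertex_degrees(mol)
  else stop("invalid-config: unknown LOVI source")
}

eval_descriptor <- function(mol, config) {
  L <- lovis_for(mol, config)
  switch(config$family,
    fmd1 = fmd1(L, config$alpha_prime, config$lambda_prime, config$agg),
    fmd4 = fmd4(L, mol, config$alpha_prime, config$lambda_prime, config$agg),
    fmd5 = fmd5(L, config$alpha_prime, config$lambda_prime, config$agg),
    fmd6 = fmd6(L, path_fragments(mol, config$m), config$alpha_prime,
                config$lambda_prime, config$agg),
    fmd7 = fmd7(L, mol,
                if (is.null(config$fragment)) seq_len(n_atoms(mol)) else config$fragment,
                config$alpha_prime, config$lambda_prime, config$agg),
    qubils_global = fuzzy_aggregate(L, config$agg))
}

#' Compute a descriptor matrix
#'
#' Applies every configuration to every molecule.  Per-cell failures are
#' recorded as `NA` with a reason code (attribute `"reasons"`) and never
#' abort the batch; the result is deterministic given the configurations
#' and the input order.
#'
#' @param mols list of [molecule] objects.
#' @param configs list of [descriptor_config] objects with unique labels.
#' @return numeric matrix (molecules x descriptors) of class
#'   `descriptor_matrix`, with row names from molecule names and an
#'   attached `"reasons"` character matrix for failed cells.
#' @export
compute_matrix <- function(mols, configs) {
  labels <- vapply(configs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("invalid-config: duplicate labels")
  mol_names <- vapply(seq_along(mols), function(i) {
    nm <- mols[[i]]$name
    if (nzchar(nm)) nm else sprintf("mol%03d", i)
  }, "")
  vals <- matrix(NA_real_, length(mols), length(configs),
                 dimnames = list(mol_names, labels))
  reasons <- matrix(NA_character_, length(mols), length(configs),
                    dimnames = list(mol_names, labels))
  for (i in seq_along(mols)) for (j in seq_along(configs)) {
    res <- tryCatch(eval_descriptor(mols[[i]], configs[[j]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      reasons[i, j] <- sub(":.*$", "", conditionMessage(res))
    } else vals[i, j] <- res
  }
  structure(vals, reasons = reasons, class = c("descriptor_matrix", "matrix"))
}

#' Write a descriptor matrix as CSV/TSV
#'
#' First column is the molecule name, remaining columns the descriptor
#' labels; missing cells are written as `NA:<reason>`.  Values are
#' formatted with 15 significant digits so equal inputs give byte-equal
#' files.
#'
#' @param dm a matrix from [compute_matrix()].
#' @param path output path.
#' @param sep `","` (CSV) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(dm, path, sep = ",") {
  reasons <- attr(dm, "reasons")
  cells <- matrix(sprintf("%.15g", dm), nrow(dm), ncol(dm))
  if (!is.null(reasons)) {
    bad <- !is.na(reasons)
    cells[bad] <- paste0("NA:", reasons[bad])
  }
  lines <- c(paste(c("molecule", colnames(dm)), collapse = sep),
             vapply(seq_len(nrow(dm)), function(i)
               paste(c(rownames(dm)[i], cells[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

agg_from_list <- function(x) {
  type <- x$type %||% "choquet"
  if (type == "choquet") {
    meas <- x$measure %||% list()
    singl <- x$singleton %||% list()
    agg_choquet(measure = switch(meas$family %||% "lmdelta",
                                 lmdelta = "lmdelta", lambda = "sugeno",
                                 sugeno = "sugeno", p = "p"),
                L = meas$L %||% 0,
                singleton = singl$type %||% "ao1",
                alpha = singl$alpha %||% 0)
  } else agg_classical(stat = x$stat %||% type, p = x$p %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_from_list <- function(x, i = 1L) {
  lov <- x$lovis %||% list(source = "degree")
  lovis <- if (identical(lov$source %||% "degree", "degree")) "degree"
  else qubils_config(metric = lov$metric %||% "euclidean",
                     normalization = lov$normalization %||% "ss",
                     k = lov$k %||% 1L,
                     property = (lov$properties %||% "electronegativity")[[1]],
                     property2 = if (length(lov$properties %||% list()) > 1L)
                       lov$properties[[2]] else NULL,
                     form = lov$form %||% "linear")
  descriptor_config(label = x$label %||% sprintf("d%03d", i),
                    family = tolower(x$family %||% "fmd1"),
                    alpha_prime = x$alpha_prime %||% 1,
                    lambda_prime = x$lambda_prime %||% 1,
                    lovis = lovis,
                    m = (x$fragments %||% list(order = 1L))$order %||% 1L,
                    agg = agg_from_list(x$aggregator %||% list()))
}

#' Read descriptor configurations from YAML
#'
#' The YAML file is a list of descriptor blocks
#' (`family`, `alpha_prime`, `lambda_prime`, `lovis`, `fragments`,
#' `aggregator`, `label`); see the packaged presets
#' (`system.file("extdata", "presets.yaml", package = "choqmd")`) for the
#' layout and [preset_configs()] for ready-made configurations.
#'
#' @param path path to a YAML configuration.
#' @return list of [descriptor_config] objects.
#' @export
read_config_yaml <- function(path) {
  blocks <- yaml::read_yaml(path)
  if (!is.null(blocks$descriptors)) blocks <- blocks$descriptors
  lapply(seq_along(blocks), function(i) config_from_list(blocks[[i]], i))
}

#' Packaged descriptor presets
#'
#' Default configuration grids: the L-m-delta synergy grid
#' `L in {-0.75, -0.5, -0.25, 0.25, 0.5, 0.75}` crossed with the
#' best-performing density settings (AO1 with `alpha` in
#' `{0.2, 0.3, 0.8, 0.9}`; AO2 with `alpha` in `{0.0, 0.5, 0.6}`), applied
#' to the geometric two-linear LOVIs (Euclidean metric, simple-stochastic
#' normalization, `k = 1`, electronegativity, linear form).
#'
#' @param name preset name (currently `"default"`).
#' @return list of [descriptor_config] objects.
#' @export
preset_configs <- function(name = "default") {
  stopifnot(identical(name, "default"))
  read_config_yaml(system.file("extdata", "presets.yaml", package = "choqmd"))
}
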