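#' Construct a molecule
#'
#' A lightweight 3D molecule model: element symbols, Cartesian coordinates
#' in Angstrom and an undirected bond list.  Coordinates are consumed as
#' given (no hydrogen addition, no sanitization, no geometry optimization
#' -- structures are expected to arrive already embedded in 3D).
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix `n x 3` of Cartesian coordinates (Angstrom).
#' @param bonds integer matrix with columns `i`, `j`, `order` (1-based atom
#'   indices), or `NULL` for no bonds.
#' @param name molecule name.
#' @return an object of class `molecule`.
#' @export
molecule <- function(atoms, coords, bonds = NULL, name = "") {
  atoms <- as.character(atoms)
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(atoms)
  if (n < 1L) stop("empty-molecule: need at least one atom")
  if (nrow(coords) != n) stop("invalid-molecule: coords must be n x 3")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3)
    colnames(bonds) <- c("i", "j", "order")
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
      stop("invalid-bond: bond references atom outside 1..n")
    if (any(bonds[, 1] == bonds[, 2]))
      stop("invalid-bond: self-bond")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("invalid-bond: duplicate undirected bond")
  }
  structure(list(atoms = atoms, coords = coords, bonds = bonds, name = name),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms
#' @param mol a [molecule].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$atoms)

#' Adjacency matrix of the bond graph
#' @param mol a [molecule].
#' @return symmetric 0/1 matrix `n x n` with zero diagonal.
#' @export
adjacency <- function(mol) {
  n <- n_atoms(mol)
  a <- matrix(0, n, n)
  if (nrow(mol$bonds) > 0L) {
    a[mol$bonds[, 1:2, drop = FALSE]] <- 1
    a[mol$bonds[, 2:1, drop = FALSE]] <- 1
  }
  a
}

mol_graph <- function(mol) {
  igraph::graph_from_adjacency_matrix(adjacency(mol), mode = "undirected")
}

#' Read molecules from an SDF file
#'
#' Reads V2000 molfile records (delimited by `$$$$`).  Parsing is
#' delegated to \pkg{ChemmineR}; a validation pass first checks each
#' record's counts line and rejects V3000 records.  Atoms and coordinates
#' are taken verbatim: no hydrogens are added and nothing is sanitized.
#'
#' @param path path to an SDF file.
#' @return a list of [molecule] objects (empty list for an empty file).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("sdf-parse: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  # split into records on $$$$
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) + 1L }
  n_rec <- 0L
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:min(ends[r], length(lines))]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (all(!nzchar(trimws(rec)))) next
    n_rec <- n_rec + 1L
    if (any(grepl("V3000", rec, fixed = TRUE)))
      stop("unsupported-dialect: record ", n_rec, " is V3000")
    if (length(rec) < 4L) stop("sdf-parse: record ", n_rec, " truncated")
    counts <- rec[4L]
    na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
    if (is.na(na) || is.na(nb) || na < 1L || length(rec) < 4L + na + nb)
      stop("sdf-parse: malformed counts line in record ", n_rec)
  }
  if (n_rec == 0L) return(list())
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    atoms <- sub("_[0-9]+$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (NROW(bb) > 0L) unname(cbind(bb[, 1], bb[, 2], bb[, 3])) else NULL
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || is.na(nm)) nm <- ""
    out[[k]] <- molecule(atoms, coords, bonds, name = trimws(nm))
  }
  out
}

#' Write molecules to an SDF file
#'
#' Writes V2000 molfile records with `$$$$` separators, fixed-width
#' coordinate fields at molfile precision (4 decimals).
#'
#' @param mols a [molecule] or list of molecules.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    n <- n_atoms(mol); nb <- nrow(mol$bonds)
    writeLines(c(mol$name, "  choqmd", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (i in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3],
                         mol$atoms[i]), con)
    for (b in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         mol$bonds[b, 1], mol$bonds[b, 2], mol$bonds[b, 3]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

.prop_cache <- new.env(parent = emptyenv())

bundled_properties <- function() {
  if (is.null(.prop_cache$tab)) {
    f <- system.file("extdata", "atomic_properties.csv", package = "choqmd")
    .prop_cache$tab <- utils::read.csv(f, comment.char = "#",
                                       stringsAsFactors = FALSE)
  }
  .prop_cache$tab
}

#' Per-atom property vector
#'
#' Looks up a per-element property (bundled: Pauling `electronegativity`,
#' IUPAC `atomic_mass`) for every atom of a molecule.  A user CSV with
#' columns `symbol,value` (or `symbol,<property_id>`) takes precedence over
#' the bundled table, element by element.
#'
#' @param mol a [molecule].
#' @param property_id property name: a bundled column or the value column
#'   of `user_csv`.
#' @param user_csv optional path to a CSV overriding/extending the table.
#' @return numeric vector of length `n_atoms(mol)`.
#' @export
property_vector <- function(mol, property_id = "electronegativity",
                            user_csv = NULL) {
  tab <- bundled_properties()
  vals <- if (property_id %in% names(tab))
    stats::setNames(tab[[property_id]], tab$symbol) else stats::setNames(numeric(0), character(0))
  if (!is.null(user_csv)) {
    u <- utils::read.csv(user_csv, comment.char = "#", stringsAsFactors = FALSE)
    col <- if (property_id %in% names(u)) property_id
           else if ("value" %in% names(u)) "value"
           else stop("missing-property: user CSV lacks a '", property_id, "' or 'value' column")
    vals[u$symbol] <- u[[col]]
  }
  miss <- setdiff(unique(mol$atoms), names(vals))
  if (length(miss) > 0L)
    stop("missing-property: no '", property_id, "' value for element(s) ",
         paste(miss, collapse = ", "))
  unname(vals[mol$atoms])
}

#' Deterministic fixture molecules
#'
#' Small geometries with known graph and metric structure, used throughout
#' the examples and tests:
#' \describe{
#'   \item{p3}{collinear 3-carbon chain, C-C bond length 1.54 A;}
#'   \item{star}{methane-like star: one central carbon with four
#'     tetrahedral neighbors at 1.09 A;}
#'   \item{hexagon}{planar hexagonal carbon ring with 1.40 A sides;}
#'   \item{alkane}{collinear carbon chain of `chain_length` atoms at
#'     1.54 A spacing.}
#' }
#'
#' @param chain_length number of atoms in the alkane chain fixture.
#' @return named list of [molecule] objects.
#' @export
fixture_molecules <- function(chain_length = 5L) {
  p3 <- molecule(rep("C", 3),
                 cbind(c(0, 1.54, 3.08), 0, 0),
                 rbind(c(1, 2, 1), c(2, 3, 1)), name = "p3")
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  star <- molecule(c("C", rep("H", 4)),
                   rbind(c(0, 0, 0), 1.09 * dirs),
                   cbind(1L, 2:5, 1L), name = "star")
  th <- (0:5) * pi / 3
  hexagon <- molecule(rep("C", 6),
                      cbind(1.40 * cos(th), 1.40 * sin(th), 0),
                      cbind(1:6, c(2:6, 1L), 1L), name = "hexagon")
  m <- max(as.integer(chain_length), 1L)
  alkane <- molecule(rep("C", m),
                     cbind(1.54 * (seq_len(m) - 1L), 0, 0),
                     if (m > 1L) cbind(seq_len(m - 1L), 2:m, 1L) else NULL,
                     name = "alkane")
  list(p3 = p3, star = star, hexagon = hexagon, alkane = alkane)
}

#' Random chain molecule
#'
#' `n` carbon atoms bonded in a chain, coordinates uniform in a 10 A box;
#' reproducible for equal seeds (the global RNG state is preserved).
#'
#' @param n number of atoms.
#' @param seed integer seed.
#' @return a [molecule].
#' @export
random_molecule <- function(n, seed) {
  n <- as.integer(n)
  if (n < 1L) stop("empty-molecule: n must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  molecule(rep("C", n),
           matrix(stats::runif(3 * n, 0, 10), ncol = 3),
           if (n > 1L) cbind(seq_len(n - 1L), 2:n, 1L) else NULL,
           name = sprintf("random-%d-%d", n, seed))
}
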