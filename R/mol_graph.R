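# Molecular graph featurization and masking.
#
# The feature layout follows the DeepChem-style general graph-convolution
# featurization: one-hot blocks plus named scalars, frozen in the constant
# tables below. Hydrogens are implicit (heavy-atom graph); the hydrogen count
# is a node feature. The layout is part of the package contract: checkpoints
# record it and refuse graphs with a different width.

.ATOM_TYPES <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B")
.HYBRIDS <- c("sp", "sp2", "sp3")
.MAX_DEGREE <- 5L   # one-hot 0..5
.MAX_NUMH <- 4L     # one-hot 0..4
.BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Node/bond feature layout
#'
#' Returns the frozen column layout of the featurizer: a list with
#' `node` and `bond` data frames (column name, block, index). The widths of
#' the two matrices produced by [featurize()] are `nrow(layout$node)` and
#' `nrow(layout$bond)`.
#'
#' @return list with elements `node`, `bond`, `n_node_features`,
#'   `n_bond_features`.
#' @export
feature_layout <- function() {
  node <- c(
    paste0("atom_", c(.ATOM_TYPES, "other")),
    "formal_charge",
    paste0("hybrid_", c(.HYBRIDS, "other")),
    "hbond_donor", "hbond_acceptor",
    "aromatic",
    paste0("degree_", 0:.MAX_DEGREE),
    paste0("num_h_", 0:.MAX_NUMH),
    "chiral_cw", "chiral_ccw",
    "partial_charge"
  )
  bond <- c(
    paste0("bond_", .BOND_TYPES),
    "in_ring", "conjugated",
    "stereo_none", "stereo_directional"
  )
  list(
    node = data.frame(column = node, index = seq_along(node)),
    bond = data.frame(column = bond, index = seq_along(bond)),
    n_node_features = length(node),
    n_bond_features = length(bond)
  )
}

.one_hot <- function(value, levels, other = TRUE) {
  v <- numeric(length(levels) + as.integer(other))
  k <- match(value, levels)
  if (is.na(k)) {
    if (other) v[length(v)] <- 1
  } else {
    v[k] <- 1
  }
  v
}

# electronegativity-difference surrogate for Gasteiger partial charges:
# formal charge + 0.1 * sum over neighbors (incl. implicit H) of EN(j)-EN(i)
.partial_charges <- function(mol) {
  en <- .ELECTRONEG[mol$atoms$element]
  q <- as.numeric(mol$atoms$charge)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    q[i] <- q[i] + 0.1 * (en[j] - en[i])
    q[j] <- q[j] + 0.1 * (en[i] - en[j])
  }
  q + 0.1 * mol$atoms$n_h * (.ELECTRONEG[["H"]] - en)
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Node features encode atom type, formal charge, hybridization,
#' hydrogen-bonding role, aromaticity, degree, hydrogen count, chirality tags
#' and a partial-charge surrogate; bond features encode bond type, ring
#' membership, conjugation and stereo marks. See [feature_layout()] for the
#' frozen column order.
#'
#' @param smiles SMILES string (or an already parsed `toxgat_mol`).
#' @param keep_largest_fragment passed to [parse_smiles()]; disconnected
#'   inputs fail by default.
#' @return object of class `MoleculeGraph`: list with `smiles`,
#'   `node_features` (m x F_n), `bond_list` (B x 2 integer, 1-based, i < j),
#'   `bond_features` (B x F_b), `adjacency` (m x m binary symmetric) and the
#'   parsed molecule in `$mol`.
#' @examples
#' g <- featurize("CCO")
#' dim(g$node_features)
#' @export
featurize <- function(smiles, keep_largest_fragment = FALSE) {
  mol <- if (inherits(smiles, "toxgat_mol")) smiles else
    parse_smiles(smiles, keep_largest_fragment = keep_largest_fragment)
  m <- nrow(mol$atoms)
  lay <- feature_layout()
  X <- matrix(0, m, lay$n_node_features,
              dimnames = list(NULL, lay$node$column))
  pq <- .partial_charges(mol)
  for (a in seq_len(m)) {
    at <- mol$atoms[a, ]
    donor <- at$element %in% c("N", "O") && at$n_h >= 1
    acceptor <- at$element %in% c("N", "O") && at$charge <= 0
    X[a, ] <- c(
      .one_hot(at$element, .ATOM_TYPES),
      at$charge,
      .one_hot(at$hybrid, .HYBRIDS),
      as.numeric(donor), as.numeric(acceptor),
      as.numeric(at$aromatic),
      .one_hot(min(at$degree, .MAX_DEGREE), 0:.MAX_DEGREE, other = FALSE),
      .one_hot(min(at$n_h, .MAX_NUMH), 0:.MAX_NUMH, other = FALSE),
      as.numeric(at$chiral == "cw"), as.numeric(at$chiral == "ccw"),
      pq[a]
    )
  }
  B <- nrow(mol$bonds)
  E <- matrix(0, B, lay$n_bond_features,
              dimnames = list(NULL, lay$bond$column))
  for (b in seq_len(B)) {
    bd <- mol$bonds[b, ]
    E[b, ] <- c(
      .one_hot(bd$order, .BOND_TYPES, other = FALSE),
      as.numeric(bd$in_ring), as.numeric(bd$conjugated),
      as.numeric(bd$stereo == "none"), as.numeric(bd$stereo == "directional")
    )
  }
  A <- matrix(0L, m, m)
  if (B > 0) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1L
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1L
  }
  g <- list(
    smiles = mol$smiles,
    node_features = X,
    bond_list = cbind(i = mol$bonds$i, j = mol$bonds$j),
    bond_features = E,
    adjacency = A,
    mol = mol
  )
  class(g) <- "MoleculeGraph"
  g
}

#' @export
print.MoleculeGraph <- function(x, ...) {
  cat(sprintf("<MoleculeGraph> %s: %d atoms, %d bonds, %d node features\n",
              x$smiles, nrow(x$node_features), nrow(x$bond_list),
              ncol(x$node_features)))
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param graph a `MoleculeGraph`.
#' @return integer atom count.
#' @export
n_atoms <- function(graph) nrow(graph$node_features)

#' Create a mask specification
#'
#' A mask keeps the listed atoms; all other atom feature rows are zeroed.
#' A bond is unmasked iff both endpoints are unmasked.
#'
#' @param unmasked_atoms integer vector of atom indices (1-based) to keep.
#' @return object of class `MaskSpec`.
#' @export
mask_spec <- function(unmasked_atoms) {
  u <- sort(unique(as.integer(unmasked_atoms)))
  structure(list(unmasked_atoms = u), class = "MaskSpec")
}

#' Zero-feature masking of a molecular graph
#'
#' Returns a copy of `graph` with node feature rows outside
#' `spec$unmasked_atoms` set to zero and bond feature rows zeroed unless both
#' endpoints are unmasked. Adjacency and bond list are untouched: masked
#' content stays in the graph so message passing sees the original topology.
#'
#' @param graph a `MoleculeGraph`.
#' @param spec a `MaskSpec` (or integer vector of atoms to keep).
#' @return a new `MoleculeGraph`.
#' @export
apply_mask <- function(graph, spec) {
  if (!inherits(spec, "MaskSpec")) spec <- mask_spec(spec)
  m <- n_atoms(graph)
  u <- spec$unmasked_atoms
  if (length(u) && (min(u) < 1L || max(u) > m)) {
    stop("mask atom index out of range 1..", m)
  }
  out <- graph
  masked <- setdiff(seq_len(m), u)
  if (length(masked)) out$node_features[masked, ] <- 0
  if (nrow(graph$bond_list) > 0) {
    keep <- graph$bond_list[, 1] %in% u & graph$bond_list[, 2] %in% u
    if (any(!keep)) out$bond_features[!keep, ] <- 0
  }
  out$masked_atoms <- masked
  out
}

#' Atoms reachable within L bonds of a seed set
#'
#' Breadth-first search over the adjacency matrix; returns atoms at graph
#' distance 1..L from any seed atom, excluding the seeds themselves.
#'
#' @param graph a `MoleculeGraph` (or adjacency matrix).
#' @param seed_atoms integer vector of seed atom indices (1-based).
#' @param L maximum bond distance (non-negative integer).
#' @return sorted integer vector of atom indices.
#' @export
reachable_atoms <- function(graph, seed_atoms, L) {
  A <- if (is.matrix(graph)) graph else graph$adjacency
  m <- nrow(A)
  seeds <- unique(as.integer(seed_atoms))
  if (length(seeds) == 0L) stop("seed_atoms must be nonempty")
  if (min(seeds) < 1L || max(seeds) > m) stop("seed atom index out of range")
  if (L < 0) stop("L must be >= 0")
  dist <- rep(NA_integer_, m)
  dist[seeds] <- 0L
  frontier <- seeds
  d <- 0L
  while (length(frontier) && d < L) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] != 0)
      new <- nb[is.na(dist[nb])]
      dist[new] <- d
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  sort(which(!is.na(dist) & dist >= 1L))
}

#' Graph diameter of a molecule
#'
#' Longest shortest-path bond distance between any two atoms (BFS from each
#' atom; molecules are small). Useful for choosing an `L` that makes the
#' locality-restricted Shapley game equal to the full game.
#'
#' @param graph a `MoleculeGraph` or adjacency matrix.
#' @return integer diameter (0 for a single atom).
#' @export
graph_diameter <- function(graph) {
  A <- if (is.matrix(graph)) graph else graph$adjacency
  m <- nrow(A)
  if (m == 1L) return(0L)
  dmax <- 0L
  for (s in seq_len(m)) {
    dist <- rep(NA_integer_, m); dist[s] <- 0L
    frontier <- s; d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] != 0)
        new <- nb[is.na(dist[nb])]
        dist[new] <- d
        nxt <- c(nxt, new)
      }
      frontier <- nxt
    }
    dmax <- max(dmax, max(dist, na.rm = TRUE))
  }
  dmax
}

#' Read a SMILES table from delimited text
#'
#' Expects a header with a `smiles` column and either `value` (regression)
#' or `label` (classification). Separator is sniffed from the header line
#' (comma or tab). Duplicate SMILES keep the first occurrence with a warning.
#'
#' @param path file path.
#' @param target_kind `"regression"` or `"classification"`.
#' @return data.frame with columns `smiles` and `value` or `label`,
#'   preserving file order.
#' @export
read_smiles_table <- function(path,
                              target_kind = c("regression", "classification")) {
  target_kind <- match.arg(target_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  names(df) <- tolower(names(df))
  tcol <- if (target_kind == "regression") "value" else "label"
  if (!"smiles" %in% names(df)) stop("missing required column 'smiles'")
  if (!tcol %in% names(df)) {
    stop("missing required column '", tcol, "' for ", target_kind)
  }
  raw <- df[[tcol]]
  tgt <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(tgt))
  if (length(bad)) {
    stop(sprintf("unparsable %s '%s' in row %d", tcol, raw[bad[1]], bad[1]))
  }
  if (target_kind == "classification" && !all(tgt %in% c(0, 1))) {
    bad <- which(!tgt %in% c(0, 1))[1]
    stop(sprintf("label must be 0/1; got '%s' in row %d", raw[bad], bad))
  }
  dup <- duplicated(df$smiles)
  if (any(dup)) {
    warning(sprintf("%d duplicate SMILES dropped (first occurrence kept)",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
    tgt <- tgt[!dup]
  }
  out <- data.frame(smiles = df$smiles, stringsAsFactors = FALSE)
  out[[tcol]] <- if (target_kind == "classification") as.integer(tgt) else tgt
  rownames(out) <- NULL
  out
}
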