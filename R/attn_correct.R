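# Attention correction: re-attribute the global attention map to original
# atoms by composing the per-layer local attention (contribution) matrices,
# then add the composite back (residual scheme). The decomposition tracks
# attention mass only — per-layer linear transforms, batch normalization and
# nonlinearities are deliberately ignored; that approximation is the method.

.check_row_stochastic <- function(M, tol = 1e-5, what = "matrix") {
  rs <- rowSums(M)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    stop(sprintf("%s row %d sums to %.6f (not row-stochastic)",
                 what, bad[1], rs[bad[1]]))
  }
  if (any(M < -tol)) stop(what, " has negative entries")
  invisible(TRUE)
}

#' Per-layer contribution matrix
#'
#' Accepts one local attention matrix or a list of per-head matrices (mean
#' over heads, which preserves row-stochasticity). Rows must sum to 1.
#'
#' @param trace_layer m x m matrix or list of such matrices.
#' @param tol row-sum tolerance.
#' @return m x m row-stochastic contribution matrix `C_l`.
#' @export
layer_contribution <- function(trace_layer, tol = 1e-5) {
  if (is.list(trace_layer)) {
    for (h in seq_along(trace_layer)) {
      .check_row_stochastic(trace_layer[[h]], tol,
                            sprintf("attention head %d", h))
    }
    Reduce(`+`, trace_layer) / length(trace_layer)
  } else {
    .check_row_stochastic(trace_layer, tol, "attention matrix")
    trace_layer
  }
}

#' Composite contribution matrix
#'
#' Multiplies the per-layer contribution matrices last-to-first,
#' `C = C_L %*% ... %*% C_1`, so row i of `C` expresses the final
#' representation of atom i as a convex combination of original atoms.
#'
#' @param per_layer list of m x m row-stochastic matrices, ordered first
#'   layer to last.
#' @return m x m row-stochastic composite matrix `C`.
#' @export
compose_contributions <- function(per_layer) {
  stopifnot(is.list(per_layer), length(per_layer) >= 1L)
  m <- nrow(per_layer[[1]])
  for (l in seq_along(per_layer)) {
    Cl <- per_layer[[l]]
    if (!is.matrix(Cl) || nrow(Cl) != m || ncol(Cl) != m) {
      stop("layer ", l, " matrix is not ", m, "x", m)
    }
    .check_row_stochastic(Cl, what = sprintf("C_%d", l))
  }
  C <- per_layer[[1]]
  for (l in seq_along(per_layer)[-1]) C <- per_layer[[l]] %*% C
  .check_row_stochastic(C, tol = 1e-8 * m + 1e-8, what = "composite C")
  C
}

#' Correct the global attention map
#'
#' Averages the global attention heads, multiplies with the composite
#' contribution matrix and adds the composite back (residual scheme):
#' `M = A_avg %*% C + C`. Every row of `M` sums to 2. Per-atom scores are
#' the column means of `M` divided by 2 (the attention mass received by each
#' original atom, averaged over query atoms), renormalized to sum to 1.
#'
#' @param global_heads list of N m x m row-stochastic global attention
#'   matrices.
#' @param C composite contribution matrix from [compose_contributions()].
#' @return object of class `CorrectedAttention`: list with `matrix` (M),
#'   `atom_scores` (length m, sums to 1) and `A_avg`.
#' @export
correct_attention <- function(global_heads, C) {
  if (!is.list(global_heads)) global_heads <- list(global_heads)
  stopifnot(length(global_heads) >= 1L)
  m <- nrow(C)
  for (h in seq_along(global_heads)) {
    Ah <- global_heads[[h]]
    if (!is.matrix(Ah) || any(dim(Ah) != m)) {
      stop("global head ", h, " is not ", m, "x", m)
    }
    .check_row_stochastic(Ah, what = sprintf("global head %d", h))
  }
  A_avg <- Reduce(`+`, global_heads) / length(global_heads)
  M <- A_avg %*% C + C
  scores <- colMeans(M) / 2
  scores <- scores / sum(scores)
  structure(list(matrix = M, atom_scores = scores, A_avg = A_avg),
            class = "CorrectedAttention")
}

#' Corrected per-atom attention scores for one molecule
#'
#' Convenience wrapper: runs a capturing forward pass and applies
#' [layer_contribution()], [compose_contributions()] and
#' [correct_attention()].
#'
#' @param state a `gat_model`.
#' @param graph a `MoleculeGraph`.
#' @return a `CorrectedAttention` (with the trace attached as `$trace`).
#' @export
corrected_atom_scores <- function(state, graph) {
  res <- forward(state, graph, capture = TRUE)
  Cl <- lapply(res$trace$local, layer_contribution)
  C <- compose_contributions(Cl)
  out <- correct_attention(res$trace$global, C)
  out$trace <- res$trace
  out
}

#' Select candidate substructures from atom scores
#'
#' Default policy: atoms scoring strictly above the molecule mean form the
#' seed set; seeds are split into connected components; each component is
#' capped at `max_atoms` by repeatedly removing its lowest-score atom whose
#' removal keeps the component connected. Deterministic given the scores.
#'
#' @param graph a `MoleculeGraph`.
#' @param atom_scores numeric vector, one score per atom.
#' @param max_atoms component size cap.
#' @return list of `Substructure` objects (list with `atoms`, `smarts`,
#'   `score`), ordered by decreasing mean score. Empty seed set returns an
#'   empty list with a warning.
#' @export
select_substructures <- function(graph, atom_scores, max_atoms = 8L) {
  m <- n_atoms(graph)
  if (length(atom_scores) != m) stop("scores length != atom count")
  seeds <- which(atom_scores > mean(atom_scores))
  if (length(seeds) == 0L) {
    warning("no atom scores strictly above the mean; empty selection")
    return(list())
  }
  A <- graph$adjacency
  # connected components of the induced seed subgraph
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seeds) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- intersect(which(A[v, ] != 0), seeds)
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  subs <- list()
  for (k in seq_len(cid)) {
    atoms <- which(!is.na(comp) & comp == k)
    while (length(atoms) > max_atoms) {
      ord <- order(atom_scores[atoms], -atoms)  # lowest score first
      removed <- FALSE
      for (cand in atoms[ord]) {
        rest <- setdiff(atoms, cand)
        if (.is_connected(A, rest)) {
          atoms <- rest
          removed <- TRUE
          break
        }
      }
      if (!removed) break  # every removal disconnects; keep as is
    }
    subs[[k]] <- structure(list(
      atoms = atoms,
      smarts = substructure_smarts(graph$mol, atoms),
      score = mean(atom_scores[atoms])
    ), class = "Substructure")
  }
  subs[order(-vapply(subs, `[[`, numeric(1), "score"))]
}

.is_connected <- function(A, atoms) {
  if (length(atoms) <= 1L) return(TRUE)
  seen <- atoms[1]
  queue <- atoms[1]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- intersect(which(A[v, ] != 0), atoms)
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  length(seen) == length(atoms)
}

#' @export
print.Substructure <- function(x, ...) {
  cat(sprintf("<Substructure> %s (atoms %s)\n", x$smarts,
              paste(x$atoms, collapse = ",")))
  invisible(x)
}
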