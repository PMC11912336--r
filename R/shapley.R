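# Locality-restricted masked Shapley values. A substructure is one player;
# the individual atoms reachable within L bonds are the other players; atoms
# outside that radius are permanently zero-masked in every evaluation.
# Coalition members are unmasked, everything else is masked with zero
# features rather than removed, so the model always sees the original
# topology.

#' Build a coalition game for a substructure
#'
#' @param graph a `MoleculeGraph`.
#' @param substructure a `Substructure` (from [select_substructures()]) or an
#'   integer vector of atom indices (1-based); must induce a connected
#'   subgraph.
#' @param L bond radius restricting the player set (default 4).
#' @param value_kind what the value function returns: `"auto"` (classifier
#'   logit for classification models, raw output for regression),
#'   `"regression-output"`, `"classifier-logit"` or
#'   `"classifier-probability"`.
#' @return object of class `CoalitionGame`: list with `graph`, `s_atoms`,
#'   `context` (the gamma individual atom players), `L`, `value_kind`.
#' @export
build_game <- function(graph, substructure, L = 4L,
                       value_kind = c("auto", "regression-output",
                                      "classifier-logit",
                                      "classifier-probability")) {
  value_kind <- match.arg(value_kind)
  s_atoms <- if (inherits(substructure, "Substructure")) {
    substructure$atoms
  } else {
    as.integer(substructure)
  }
  m <- n_atoms(graph)
  if (length(s_atoms) == 0L) stop("substructure is empty")
  if (min(s_atoms) < 1L || max(s_atoms) > m) {
    stop("substructure atom index out of range")
  }
  if (!.is_connected(graph$adjacency, s_atoms)) {
    stop("substructure atoms do not induce a connected subgraph")
  }
  context <- reachable_atoms(graph, s_atoms, L)
  structure(list(
    graph = graph, s_atoms = sort(unique(s_atoms)), context = context,
    L = as.integer(L), value_kind = value_kind
  ), class = "CoalitionGame")
}

#' @export
print.CoalitionGame <- function(x, ...) {
  cat(sprintf(
    "<CoalitionGame> |S_i| = %d, gamma = %d context atoms, L = %d (%s)\n",
    length(x$s_atoms), length(x$context), x$L, x$value_kind))
  invisible(x)
}

.resolve_value_kind <- function(state, value_kind) {
  if (value_kind != "auto") return(value_kind)
  hk <- tryCatch(state$config$head_kind, error = function(e) NULL)
  if (identical(hk, "binary-classification")) "classifier-logit"
  else "regression-output"
}

.apply_value_kind <- function(y, value_kind) {
  if (value_kind == "classifier-probability") stats::plogis(y) else y
}

# Evaluate the model on many masked variants of one graph.
# unmasked_list: list of integer vectors (atoms kept). Batched for gat
# models; falls back to per-coalition forward otherwise.
.eval_coalitions <- function(state, graph, unmasked_list, value_kind,
                             chunk_nodes = 20000L) {
  n <- length(unmasked_list)
  graphs <- lapply(unmasked_list, function(u) apply_mask(graph, u))
  y <- predict_batch(state, graphs, chunk_nodes = chunk_nodes)
  .apply_value_kind(y, value_kind)
}

#' Value function of a coalition
#'
#' Evaluates the model on the graph with exactly `E` (plus the substructure
#' when `include_S`) unmasked; atoms outside the game's player set are always
#' masked.
#'
#' @param state a model.
#' @param game a `CoalitionGame`.
#' @param E integer vector, subset of `game$context`.
#' @param include_S include the substructure in the coalition.
#' @return numeric scalar on the scale selected by the game's `value_kind`.
#' @export
value_function <- function(state, game, E = integer(0), include_S = TRUE) {
  E <- as.integer(E)
  if (length(setdiff(E, game$context))) {
    stop("E must be a subset of the game's context atoms")
  }
  vk <- .resolve_value_kind(state, game$value_kind)
  unmasked <- if (include_S) c(E, game$s_atoms) else E
  .eval_coalitions(state, game$graph, list(unmasked), vk)
}

# subset bitmask helpers: masks 0..2^g-1 over `players`
.mask_members <- function(mask, players) {
  players[bitwAnd(bitwShiftR(mask, seq_along(players) - 1L), 1L) == 1L]
}

.popcount <- function(masks, g) {
  out <- integer(length(masks))
  for (b in seq_len(g) - 1L) {
    out <- out + bitwAnd(bitwShiftR(masks, b), 1L)
  }
  out
}

#' Exact Shapley value of a substructure
#'
#' Enumerates all coalitions of the gamma context players:
#' `phi = sum_E |E|! (|T|-|E|-1)! / |T|! * (v(E + S_i) - v(E))`.
#' Coalition evaluations are batched; the result is independent of
#' evaluation order and batching.
#'
#' @param state a model.
#' @param game a `CoalitionGame` from [build_game()].
#' @param exact_cap maximum gamma for exact enumeration (default 14, i.e. at
#'   most 2^15 model evaluations); larger games must use
#'   [shapley_sampled()].
#' @return object of class `ShapleyResult`: list with `phi`,
#'   `n_evaluations`, `method = "exact"`, `value_kind`, `L`, `s_atoms`,
#'   `context`.
#' @export
shapley <- function(state, game, exact_cap = 14L) {
  g <- length(game$context)
  if (g > exact_cap) {
    stop("gamma = ", g, " exceeds exact_cap = ", exact_cap,
         "; use shapley_sampled() for games this large")
  }
  vk <- .resolve_value_kind(state, game$value_kind)
  masks <- 0:(2^g - 1)
  sizes <- .popcount(masks, g)
  sets0 <- lapply(masks, .mask_members, players = game$context)
  sets1 <- lapply(sets0, function(E) c(E, game$s_atoms))
  vals <- .eval_coalitions(state, game$graph, c(sets0, sets1), vk)
  v0 <- vals[seq_along(masks)]
  v1 <- vals[length(masks) + seq_along(masks)]
  # weight k!(g-k)!/(g+1)!
  w <- exp(lfactorial(sizes) + lfactorial(g - sizes) - lfactorial(g + 1))
  phi <- sum(w * (v1 - v0))
  structure(list(
    phi = phi, n_evaluations = 2L * length(masks), method = "exact",
    value_kind = vk, L = game$L, s_atoms = game$s_atoms,
    context = game$context, exact_cap = exact_cap, seed = NULL, se = NULL
  ), class = "ShapleyResult")
}

#' @export
print.ShapleyResult <- function(x, ...) {
  cat(sprintf("<ShapleyResult> phi = %.6g (%s, %s, %d evaluations%s)\n",
              x$phi, x$method, x$value_kind, x$n_evaluations,
              if (!is.null(x$se)) sprintf(", se %.3g", x$se) else ""))
  invisible(x)
}

#' Permutation-sampled Shapley value
#'
#' Unbiased estimator: for each random ordering of the gamma + 1 players, the
#' marginal contribution of the substructure is `v(E + S_i) - v(E)` with `E`
#' the context players preceding it. Coalition values are cached, so repeated
#' orderings cost nothing extra.
#'
#' @inheritParams shapley
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed RNG seed; fixed seed reproduces the estimate exactly.
#' @return `ShapleyResult` with `method = "permutation-sampled"`, standard
#'   error in `se`.
#' @export
shapley_sampled <- function(state, game, n_permutations = 256L, seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  g <- length(game$context)
  vk <- .resolve_value_kind(state, game$value_kind)
  # position of S uniform among g+1 slots; E = context atoms before S
  Es <- withr_seed(seed, {
    lapply(seq_len(n_permutations), function(i) {
      perm <- sample(c(0L, game$context))  # 0 marks the substructure
      pos <- which(perm == 0L)
      if (pos > 1L) perm[seq_len(pos - 1L)] else integer(0)
    })
  })
  keys <- vapply(Es, function(E) paste(sort(E), collapse = ","), character(1))
  uniq <- !duplicated(keys)
  sets0 <- Es[uniq]
  sets1 <- lapply(sets0, function(E) c(E, game$s_atoms))
  vals <- .eval_coalitions(state, game$graph, c(sets0, sets1), vk)
  nu <- length(sets0)
  marg_u <- vals[nu + seq_len(nu)] - vals[seq_len(nu)]
  marg <- marg_u[match(keys, keys[uniq])]
  phi <- mean(marg)
  se <- if (n_permutations > 1L) stats::sd(marg) / sqrt(n_permutations) else NA_real_
  structure(list(
    phi = phi, n_evaluations = 2L * nu, method = "permutation-sampled",
    value_kind = vk, L = game$L, s_atoms = game$s_atoms,
    context = game$context, seed = seed, se = se,
    n_permutations = as.integer(n_permutations)
  ), class = "ShapleyResult")
}

#' Shapley values of every player in a game
#'
#' Computes the exact Shapley value of the substructure player and of each
#' context atom from a single table of all coalition values. Used to verify
#' the efficiency axiom: the values sum to
#' `v(all players unmasked) - v(everything masked)`.
#'
#' @inheritParams shapley
#' @return list with `phi_s` (substructure), `phi_context` (named by atom),
#'   `total`, `v_grand`, `v_empty`.
#' @export
shapley_all_players <- function(state, game, exact_cap = 14L) {
  g <- length(game$context)
  if (g + 1L > exact_cap + 1L) stop("game too large for exact enumeration")
  vk <- .resolve_value_kind(state, game$value_kind)
  np <- g + 1L
  masks <- 0:(2^np - 1)  # bit 1 = substructure, bits 2..np = context atoms
  players <- c(list(game$s_atoms), as.list(game$context))
  sets <- lapply(masks, function(msk) {
    unlist(players[bitwAnd(bitwShiftR(msk, seq_len(np) - 1L), 1L) == 1L])
  })
  vals <- .eval_coalitions(state, game$graph, sets, vk)
  sizes <- .popcount(masks, np)
  phi <- numeric(np)
  for (p in seq_len(np)) {
    bit <- bitwShiftL(1L, p - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    k <- sizes[without + 1L]
    w <- exp(lfactorial(k) + lfactorial(np - k - 1L) - lfactorial(np))
    phi[p] <- sum(w * (vals[bitwOr(without, bit) + 1L] - vals[without + 1L]))
  }
  list(
    phi_s = phi[1L],
    phi_context = stats::setNames(phi[-1L], game$context),
    total = sum(phi),
    v_grand = vals[length(vals)],
    v_empty = vals[1L]
  )
}

#' Brute-force full-molecule Shapley value (testing oracle)
#'
#' Exact Shapley value of the substructure with ALL non-substructure atoms as
#' individual players: no L restriction and nothing permanently masked.
#' Exponential in molecule size; guarded to `m - k <= 16`.
#'
#' @param state a model.
#' @param graph a `MoleculeGraph`.
#' @param s_atoms substructure atom indices (1-based).
#' @param value_kind as in [build_game()].
#' @return numeric scalar phi.
#' @export
brute_force_full_shapley <- function(state, graph, s_atoms,
                                     value_kind = "auto") {
  s_atoms <- sort(unique(as.integer(s_atoms)))
  m <- n_atoms(graph)
  others <- setdiff(seq_len(m), s_atoms)
  g <- length(others)
  if (g > 16L) stop("m - k = ", g, " too large for brute force (max 16)")
  vk <- .resolve_value_kind(state, value_kind)
  phi <- 0
  # direct definition, one coalition at a time (independent of the batched
  # bitmask path in shapley())
  vals0 <- numeric(2^g)
  vals1 <- numeric(2^g)
  for (msk in 0:(2^g - 1)) {
    E <- others[bitwAnd(bitwShiftR(msk, seq_len(g) - 1L), 1L) == 1L]
    vals0[msk + 1] <- forward(state, apply_mask(graph, E))
    vals1[msk + 1] <- forward(state, apply_mask(graph, c(E, s_atoms)))
    k <- length(E)
    w <- exp(lfactorial(k) + lfactorial(g - k) - lfactorial(g + 1))
    phi <- phi + w * (.apply_value_kind(vals1[msk + 1], vk) -
                        .apply_value_kind(vals0[msk + 1], vk))
  }
  phi
}
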