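# End-to-end structural-alert discovery: explain molecules with the toxicity
# and lipophilicity models, classify substructures into element categories,
# flag specific-mode-of-action candidates by cross-model Shapley signs, and
# quantify distributional similarity by KDE overlap.

#' Alert pipeline configuration
#'
#' @param min_support minimum number of supporting molecules per alert.
#' @param L Shapley bond radius.
#' @param max_atoms substructure size cap for [select_substructures()].
#' @param max_substructures_per_mol score only the top-scoring components.
#' @param exact_cap exact Shapley enumeration cap on gamma; larger games fall
#'   back to permutation sampling.
#' @param n_permutations permutations for the sampled fallback.
#' @param max_molecules cap on the number of dataset molecules explained
#'   (compute budget; `Inf` = all).
#' @param seed seed for the sampled fallback.
#' @return list of class `AlertConfig`.
#' @export
alert_config <- function(min_support = 2L, L = 4L, max_atoms = 8L,
                         max_substructures_per_mol = 3L, exact_cap = 12L,
                         n_permutations = 256L, max_molecules = Inf,
                         seed = 1L) {
  structure(list(
    min_support = min_support, L = as.integer(L),
    max_atoms = as.integer(max_atoms),
    max_substructures_per_mol = as.integer(max_substructures_per_mol),
    exact_cap = as.integer(exact_cap),
    n_permutations = as.integer(n_permutations),
    max_molecules = max_molecules, seed = as.integer(seed)
  ), class = "AlertConfig")
}

.shapley_auto <- function(state, game, config) {
  if (length(game$context) <= config$exact_cap) {
    shapley(state, game, exact_cap = config$exact_cap)
  } else {
    shapley_sampled(state, game, n_permutations = config$n_permutations,
                    seed = config$seed)
  }
}

#' Explain one molecule with both models
#'
#' Substructures are selected from the toxicity model's corrected attention;
#' each is scored by its Shapley value under the toxicity model (classifier
#' logit) and under the lipophilicity model (regression output), with
#' identical masks (same player set and radius).
#'
#' @param tox_state classification model.
#' @param lipo_state regression model.
#' @param smiles molecule to explain.
#' @param config an [alert_config()].
#' @param substructures optional list of `Substructure` objects or integer
#'   atom vectors to score instead of deriving candidates from the corrected
#'   attention (used for mock models, which carry no attention trace, and for
#'   scoring known patterns).
#' @return data.frame with one row per substructure: `smarts`, `atoms`
#'   (comma-separated), `phi_tox`, `phi_lipo`, `category`; empty when the
#'   corrected scores select nothing.
#' @export
explain_molecule <- function(tox_state, lipo_state, smiles,
                             config = alert_config(), substructures = NULL) {
  if (!is.null(tox_state$n_node_features) &&
      !is.null(lipo_state$n_node_features) &&
      tox_state$n_node_features != lipo_state$n_node_features) {
    stop("models use different featurization layouts")
  }
  graph <- featurize(smiles)
  if (is.null(substructures)) {
    ca <- corrected_atom_scores(tox_state, graph)
    subs <- withCallingHandlers(
      select_substructures(graph, ca$atom_scores, max_atoms = config$max_atoms),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(subs) > config$max_substructures_per_mol) {
      subs <- subs[seq_len(config$max_substructures_per_mol)]
    }
  } else {
    subs <- lapply(substructures, function(su) {
      if (inherits(su, "Substructure")) return(su)
      structure(list(atoms = as.integer(su),
                     smarts = substructure_smarts(graph$mol, su),
                     score = NA_real_), class = "Substructure")
    })
  }
  if (length(subs) == 0L) {
    return(data.frame(smarts = character(0), atoms = character(0),
                      phi_tox = numeric(0), phi_lipo = numeric(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(subs, function(su) {
    game_tox <- build_game(graph, su, L = config$L,
                           value_kind = "classifier-logit")
    game_lipo <- build_game(graph, su, L = config$L,
                            value_kind = "regression-output")
    data.frame(
      smarts = su$smarts,
      atoms = paste(su$atoms, collapse = ","),
      phi_tox = .shapley_auto(tox_state, game_tox, config)$phi,
      phi_lipo = .shapley_auto(lipo_state, game_lipo, config)$phi,
      category = categorize_substructure(su, graph),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Element category of a substructure
#'
#' Precedence: contains N and S -> `"nitrogen-sulfur"`; only N (no S, no
#' halogen) -> `"nitrogen"`; only S (no N, no halogen) -> `"sulfur"`;
#' contains Cl/Br/I with no N and no S -> `"halogen"`; anything else ->
#' `"other"`.
#'
#' @param substructure `Substructure` or integer atom vector.
#' @param graph the `MoleculeGraph` it lives in.
#' @return category string.
#' @export
categorize_substructure <- function(substructure, graph) {
  atoms <- if (inherits(substructure, "Substructure")) substructure$atoms
           else as.integer(substructure)
  if (length(atoms) == 0L) stop("empty substructure")
  els <- graph$mol$atoms$element[atoms]
  has_n <- "N" %in% els
  has_s <- "S" %in% els
  has_hal <- any(els %in% c("Cl", "Br", "I", "F"))
  if (has_n && has_s) "nitrogen-sulfur"
  else if (has_n && !has_hal) "nitrogen"
  else if (has_s && !has_hal) "sulfur"
  else if (has_hal && !has_n && !has_s) "halogen"
  else "other"
}

#' Aggregate structural alerts over a dataset
#'
#' Explains each molecule, canonicalizes substructures to SMARTS, groups by
#' canonical form, keeps groups with mean `phi_tox > 0` and support >=
#' `min_support`, and sorts by mean `phi_tox` descending (ties: support,
#' then SMARTS). A record is flagged `specific-moa-candidate` iff mean
#' `phi_tox > 0` and mean `phi_lipo < 0`, else `baseline-consistent`.
#'
#' @param dataset data.frame with a `smiles` column.
#' @param tox_state classification model.
#' @param lipo_state regression model.
#' @param config an [alert_config()].
#' @return data.frame of `AlertRecord`s: `smarts`, `category`, `phi_tox`,
#'   `phi_lipo`, `support`, `moa_flag`, `examples`.
#' @export
aggregate_alerts <- function(dataset, tox_state, lipo_state,
                             config = alert_config()) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  smiles <- dataset$smiles
  if (is.finite(config$max_molecules) &&
      length(smiles) > config$max_molecules) {
    smiles <- smiles[seq_len(config$max_molecules)]
  }
  rows <- lapply(smiles, function(s) {
    df <- explain_molecule(tox_state, lipo_state, s, config)
    if (nrow(df)) df$smiles <- s
    df
  })
  rows <- rows[vapply(rows, nrow, integer(1)) > 0]
  if (length(rows) == 0L) {
    return(data.frame(smarts = character(0), category = character(0),
                      phi_tox = numeric(0), phi_lipo = numeric(0),
                      support = integer(0), moa_flag = character(0),
                      examples = character(0), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, rows)
  # canonical SMARTS as grouping key (sorted for row-order invariance)
  keys <- sort(unique(all$smarts))
  recs <- lapply(keys, function(k) {
    sel <- all[all$smarts == k, , drop = FALSE]
    sel <- sel[order(sel$smiles), , drop = FALSE]
    data.frame(
      smarts = k,
      category = sel$category[1],
      phi_tox = mean(sel$phi_tox),
      phi_lipo = mean(sel$phi_lipo),
      support = length(unique(sel$smiles)),
      examples = paste(utils::head(unique(sel$smiles), 3), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  out <- out[out$phi_tox > 0 & out$support >= config$min_support, ,
             drop = FALSE]
  if (nrow(out)) {
    out$moa_flag <- ifelse(out$phi_lipo < 0, "specific-moa-candidate",
                           "baseline-consistent")
    out <- out[order(-out$phi_tox, -out$support, out$smarts), , drop = FALSE]
  } else {
    out$moa_flag <- character(0)
  }
  rownames(out) <- NULL
  out[, c("smarts", "category", "phi_tox", "phi_lipo", "support",
          "moa_flag", "examples")]
}

#' Score a known pattern as a structural alert across a dataset
#'
#' Evaluates a candidate alert given as a SMARTS/SMILES fragment: every
#' distinct match in every dataset molecule is scored by its Shapley value
#' under both models, and the matches are aggregated into a single
#' `AlertRecord` (mean contributions, support, mode-of-action flag). This is
#' the pattern-first counterpart of the attention-first [aggregate_alerts()].
#'
#' @param dataset data.frame with a `smiles` column.
#' @param pattern SMARTS/SMILES fragment in the package's restricted dialect.
#' @param tox_state classification model.
#' @param lipo_state regression model.
#' @param config an [alert_config()].
#' @return one-row data.frame (`AlertRecord`) with `smarts`, `category`,
#'   `phi_tox`, `phi_lipo`, `support`, `moa_flag`; zero rows if the pattern
#'   never matches.
#' @export
score_pattern_alert <- function(dataset, pattern, tox_state, lipo_state,
                                config = alert_config()) {
  pat <- parse_smiles(pattern)
  phi_tox <- numeric(0)
  phi_lipo <- numeric(0)
  supp <- character(0)
  smarts <- NULL
  category <- NULL
  smiles <- dataset$smiles
  if (is.finite(config$max_molecules) &&
      length(smiles) > config$max_molecules) {
    smiles <- smiles[seq_len(config$max_molecules)]
  }
  for (s in smiles) {
    graph <- featurize(s)
    hits <- match_pattern(graph$mol, pat)
    if (length(hits) == 0L) next
    df <- explain_molecule(tox_state, lipo_state, s, config,
                           substructures = hits)
    phi_tox <- c(phi_tox, df$phi_tox)
    phi_lipo <- c(phi_lipo, df$phi_lipo)
    supp <- c(supp, s)
    if (is.null(smarts)) {
      smarts <- df$smarts[1]
      category <- df$category[1]
    }
  }
  if (length(supp) == 0L) {
    return(data.frame(smarts = character(0), category = character(0),
                      phi_tox = numeric(0), phi_lipo = numeric(0),
                      support = integer(0), moa_flag = character(0),
                      stringsAsFactors = FALSE))
  }
  mt <- mean(phi_tox)
  ml <- mean(phi_lipo)
  data.frame(
    smarts = smarts, category = category, phi_tox = mt, phi_lipo = ml,
    support = length(unique(supp)),
    moa_flag = if (mt > 0 && ml < 0) "specific-moa-candidate"
               else "baseline-consistent",
    stringsAsFactors = FALSE
  )
}

#' Overlap of two sample distributions
#'
#' Gaussian kernel density estimates (Silverman reference bandwidth) for each
#' sample set, evaluated on a shared grid spanning both ranges extended by
#' three bandwidths; the overlap is the integral of the pointwise minimum,
#' clipped to `[0, 1]`. Symmetric in its arguments.
#'
#' @param samples_a,samples_b numeric vectors with at least 5 points each.
#' @param n_grid grid resolution.
#' @return overlap coefficient in `[0, 1]`.
#' @export
distribution_overlap <- function(samples_a, samples_b, n_grid = 512L) {
  if (length(samples_a) < 5L || length(samples_b) < 5L) {
    stop("need at least 5 points per sample set")
  }
  bw <- function(x) {
    if (stats::sd(x) == 0) {
      warning("degenerate zero-variance sample; widened minimal bandwidth")
      return(0.9 * max(abs(x[1]), 1) * length(x)^-0.2)
    }
    b <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
    if (!is.finite(b) || b <= 0) b <- 0.9 * stats::sd(x) * length(x)^-0.2
    b
  }
  ba <- bw(samples_a); bb <- bw(samples_b)
  pad <- 3 * max(ba, bb)
  lo <- min(samples_a, samples_b) - pad
  hi <- max(samples_a, samples_b) + pad
  grid <- seq(lo, hi, length.out = n_grid)
  kde <- function(x, b) {
    vapply(grid, function(g) mean(stats::dnorm(g, x, b)), numeric(1))
  }
  pa <- kde(samples_a, ba)
  pb <- kde(samples_b, bb)
  h <- grid[2] - grid[1]
  ov <- sum(pmin(pa, pb)) * h
  min(max(ov, 0), 1)
}
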