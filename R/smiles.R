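# Minimal SMILES machinery: parser, substructure matching, canonical SMARTS
# export. Covers the organic subset plus bracket atoms (charge, explicit H,
# @/@@ chirality tags). Aromaticity is taken from lowercase input (no
# kekulized-ring perception); rings emitted by the synthetic generator and
# typical hand-written test molecules are written aromatic.

.ELEMENTS <- c("C", "N", "O", "S", "P", "B", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

# Pauling electronegativities (H included for implicit hydrogens).
.ELECTRONEG <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, P = 2.19,
  S = 2.58, F = 3.98, Cl = 3.16, Br = 2.96, I = 2.66
)

.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1, Cl = 1, Br = 1, I = 1
)

.bond_order_num <- function(order) {
  switch(order,
    single = 1, double = 2, triple = 3, aromatic = 1.5,
    stop("unknown bond order: ", order)
  )
}

#' Parse a SMILES string into an internal molecule object
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic lowercase
#' atoms, branches, ring-closure digits (including `%nn`), bond symbols
#' `- = # :` (directional `/ \` are read as single bonds with a stereo mark)
#' and bracket atoms with charge, explicit hydrogen count and `@`/`@@` tags.
#' Multi-fragment inputs (`.`) are rejected unless
#' `keep_largest_fragment = TRUE`.
#'
#' @param smiles character scalar.
#' @param keep_largest_fragment keep the largest connected component of a
#'   multi-fragment SMILES instead of failing.
#' @return an object of class `toxgat_mol`: a list with data frames `atoms`
#'   (element, aromatic, charge, n_h, degree, hybrid, in_ring, chiral) and
#'   `bonds` (i, j, order, in_ring, conjugated, stereo), 1-based indices with
#'   i < j.
#' @export
parse_smiles <- function(smiles, keep_largest_fragment = FALSE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("SMILES must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  fail <- function(msg, pos = NA) {
    stop(sprintf("invalid SMILES '%s': %s%s", smiles, msg,
                 if (is.na(pos)) "" else sprintf(" (at position %d)", pos)),
         call. = FALSE)
  }

  el <- character(0); arom <- logical(0); chg <- integer(0)
  exph <- integer(0)  # -1 = not specified (compute implicit)
  chiral <- character(0)
  bi <- integer(0); bj <- integer(0); bord <- character(0)
  bstereo <- character(0)
  frag <- integer(0)  # fragment id per atom

  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NA_character_  # explicit bond symbol awaiting next atom
  pending_stereo <- FALSE
  ring_open <- list()            # digit -> list(atom, bond, stereo)
  cur_frag <- 1L

  add_atom <- function(sym, aromatic, charge = 0L, hcount = -1L,
                       chiral_tag = "none", pos = NA) {
    el <<- c(el, sym); arom <<- c(arom, aromatic); chg <<- c(chg, charge)
    exph <<- c(exph, hcount); chiral <<- c(chiral, chiral_tag)
    frag <<- c(frag, cur_frag)
    idx <- length(el)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) ord <- if (arom[prev] && aromatic) "aromatic" else "single"
      bi <<- c(bi, prev); bj <<- c(bj, idx); bord <<- c(bord, ord)
      bstereo <<- c(bstereo, if (pending_stereo) "directional" else "none")
    }
    pending_bond <<- NA_character_
    pending_stereo <<- FALSE
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(key, pos) {
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      if (op$atom == prev) fail("ring bond to self", pos)
      ord <- pending_bond
      if (is.na(ord)) ord <- op$bond
      if (is.na(ord)) ord <- if (arom[op$atom] && arom[prev]) "aromatic" else "single"
      bi <<- c(bi, op$atom); bj <<- c(bj, prev); bord <<- c(bord, ord)
      bstereo <<- c(bstereo,
                    if (pending_stereo || isTRUE(op$stereo)) "directional" else "none")
      pending_bond <<- NA_character_
      pending_stereo <<- FALSE
    } else {
      if (is.na(prev)) fail("ring closure before any atom", pos)
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond,
                                stereo = pending_stereo)
      pending_bond <<- NA_character_
      pending_stereo <<- FALSE
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
        paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE, pos = i)
      i <- i + 2L
    } else if (ch %in% .ELEMENTS) {
      add_atom(ch, FALSE, pos = i)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_OK) {
      add_atom(toupper(ch), TRUE, pos = i)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed bracket atom", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?([+-][0-9]*|[+]+|[-]+)?$",
        body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0) fail(paste0("cannot parse bracket atom [", body, "]"), i)
      sym <- parts[3]
      aromatic <- sym %in% .AROMATIC_OK
      sym_std <- if (aromatic) toupper(sym) else sym
      if (!sym_std %in% .ELEMENTS) {
        fail(paste0("unsupported element '", sym, "'"), i)
      }
      tag <- parts[4]
      chiral_tag <- if (identical(tag, "@@")) "cw" else if (identical(tag, "@")) "ccw" else "none"
      hc <- if (nzchar(parts[5])) {
        if (nzchar(parts[6])) as.integer(parts[6]) else 1L
      } else 0L
      charge <- 0L
      cs <- parts[7]
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(substring(cs, 2L))
          if (substring(cs, 1L, 1L) == "-") charge <- -charge
        } else {
          charge <- nchar(cs)
          if (substring(cs, 1L, 1L) == "-") charge <- -charge
        }
      }
      add_atom(sym_std, aromatic, charge, hc, chiral_tag, pos = i)
      i <- j + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- switch(ch, "-" = "single", "=" = "double",
                             "#" = "triple", ":" = "aromatic")
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- "single"
      pending_stereo <- TRUE
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) fail("truncated %nn ring closure", i)
      key <- paste0(chars[i + 1L], chars[i + 2L])
      if (!grepl("^[0-9]{2}$", key)) fail("bad %nn ring closure", i)
      close_ring(key, i)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      cur_frag <- cur_frag + 1L
      i <- i + 1L
    } else {
      fail(paste0("unexpected character '", ch, "'"), i)
    }
  }
  if (length(stack) > 0L) fail("unclosed branch '('")
  if (length(ring_open) > 0L) fail("unclosed ring bond")
  if (length(el) == 0L) fail("no atoms")

  m_atoms <- length(el)
  if (cur_frag > 1L || length(unique(frag)) > 1L) {
    # fragments may also arise implicitly; detect via connectivity below
  }

  # Connectivity / fragment handling
  comp <- .components(m_atoms, bi, bj)
  if (max(comp) > 1L) {
    if (!keep_largest_fragment) {
      fail(sprintf("molecule has %d disconnected fragments; set keep_largest_fragment = TRUE to keep the largest",
                   max(comp)))
    }
    sizes <- tabulate(comp)
    keep <- which(comp == which.max(sizes))
    remap <- match(seq_len(m_atoms), keep)
    sel <- !is.na(remap[bi]) & !is.na(remap[bj])
    bi <- remap[bi[sel]]; bj <- remap[bj[sel]]
    bord <- bord[sel]; bstereo <- bstereo[sel]
    el <- el[keep]; arom <- arom[keep]; chg <- chg[keep]
    exph <- exph[keep]; chiral <- chiral[keep]
    m_atoms <- length(keep)
  }

  # normalize bond orientation i < j, drop duplicates
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  key <- paste(bi, bj)
  if (anyDuplicated(key)) fail("duplicate bond")

  degree <- tabulate(c(bi, bj), nbins = m_atoms)

  # bond order sum per atom (aromatic counts 1.5)
  ordnum <- vapply(bord, .bond_order_num, numeric(1))
  bsum <- numeric(m_atoms)
  for (b in seq_along(bi)) {
    bsum[bi[b]] <- bsum[bi[b]] + ordnum[b]
    bsum[bj[b]] <- bsum[bj[b]] + ordnum[b]
  }

  n_h <- integer(m_atoms)
  for (a in seq_len(m_atoms)) {
    if (exph[a] >= 0L) {
      n_h[a] <- exph[a]
    } else {
      val <- .DEFAULT_VALENCE[[el[a]]]
      eff <- switch(el[a],
        C = val - abs(chg[a]),
        B = val - chg[a],
        N = , P = , O = , S = val + chg[a],
        val + chg[a]
      )
      used <- ceiling(round(bsum[a], 6))
      n_h[a] <- max(0L, as.integer(eff - used))
    }
  }

  ring_bond <- .ring_bonds(m_atoms, bi, bj)
  atom_in_ring <- logical(m_atoms)
  if (any(ring_bond)) {
    atom_in_ring[unique(c(bi[ring_bond], bj[ring_bond]))] <- TRUE
  }

  n_double <- n_triple <- integer(m_atoms)
  for (b in seq_along(bi)) {
    if (bord[b] == "double") {
      n_double[bi[b]] <- n_double[bi[b]] + 1L
      n_double[bj[b]] <- n_double[bj[b]] + 1L
    } else if (bord[b] == "triple") {
      n_triple[bi[b]] <- n_triple[bi[b]] + 1L
      n_triple[bj[b]] <- n_triple[bj[b]] + 1L
    }
  }
  hybrid <- ifelse(n_triple > 0 | n_double >= 2, "sp",
            ifelse(arom | n_double == 1, "sp2", "sp3"))

  conj <- logical(length(bi))
  for (b in seq_along(bi)) {
    conj[b] <- bord[b] == "aromatic" ||
      (hybrid[bi[b]] %in% c("sp", "sp2") && hybrid[bj[b]] %in% c("sp", "sp2"))
  }

  mol <- list(
    smiles = smiles,
    atoms = data.frame(
      element = el, aromatic = arom, charge = chg, n_h = n_h,
      degree = degree, hybrid = hybrid, in_ring = atom_in_ring,
      chiral = chiral, stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      i = bi, j = bj, order = bord, in_ring = ring_bond,
      conjugated = conj, stereo = bstereo, stringsAsFactors = FALSE
    )
  )
  class(mol) <- "toxgat_mol"
  mol
}

# connected components over atoms 1..m given bond endpoints
.components <- function(m, bi, bj) {
  comp <- integer(m)
  adj <- vector("list", m)
  for (b in seq_along(bi)) {
    adj[[bi[b]]] <- c(adj[[bi[b]]], bj[b])
    adj[[bj[b]]] <- c(adj[[bj[b]]], bi[b])
  }
  cid <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# a bond is a ring bond iff its endpoints stay connected after removing it
.ring_bonds <- function(m, bi, bj) {
  nb <- length(bi)
  out <- logical(nb)
  if (nb == 0L) return(out)
  for (b in seq_len(nb)) {
    comp <- .components(m, bi[-b], bj[-b])
    out[b] <- comp[bi[b]] == comp[bj[b]]
  }
  out
}

#' @export
print.toxgat_mol <- function(x, ...) {
  cat(sprintf("<toxgat_mol> %s: %d atoms, %d bonds\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

.mol_to_igraph <- function(mol) {
  m <- nrow(mol$atoms)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  g
}

# integer colors for VF2: element id * 2 + aromatic
.atom_colors <- function(mol) {
  eid <- match(mol$atoms$element, .ELEMENTS)
  as.integer(eid * 2L + as.integer(mol$atoms$aromatic))
}

.bond_colors <- function(mol) {
  as.integer(match(mol$bonds$order, c("single", "double", "triple", "aromatic")))
}

#' Match a substructure pattern against a molecule
#'
#' The pattern is given as a SMILES/SMARTS fragment in the restricted dialect
#' this package reads: atoms match on element and aromaticity, bonds on order
#' (aromatic counted as its own order). Charges and hydrogen counts in the
#' pattern are ignored for matching.
#'
#' @param mol a `toxgat_mol` (or SMILES string).
#' @param pattern pattern SMILES/SMARTS fragment (or parsed `toxgat_mol`).
#' @param unique_sets if TRUE (default) return matches deduplicated by the
#'   set of matched atoms (automorphic re-orderings collapsed).
#' @return list of integer vectors; element k is the molecule atom matched to
#'   pattern atom k.
#' @export
match_pattern <- function(mol, pattern, unique_sets = TRUE) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.character(pattern)) pattern <- parse_smiles(pattern)
  gm <- .mol_to_igraph(mol)
  gp <- .mol_to_igraph(pattern)
  if (igraph::vcount(gp) > igraph::vcount(gm)) return(list())
  maps <- igraph::subgraph_isomorphisms(
    gp, gm, method = "vf2",
    vertex.color1 = .atom_colors(mol), vertex.color2 = .atom_colors(pattern),
    edge.color1 = .bond_colors(mol), edge.color2 = .bond_colors(pattern)
  )
  hits <- lapply(maps, function(mp) as.integer(mp))
  if (unique_sets && length(hits) > 1L) {
    keys <- vapply(hits, function(h) paste(sort(h), collapse = ","), character(1))
    hits <- hits[!duplicated(keys)]
  }
  hits
}

#' Count distinct occurrences of a pattern in a molecule
#' @inheritParams match_pattern
#' @return integer count of distinct matched atom sets.
#' @export
count_pattern <- function(mol, pattern) {
  length(match_pattern(mol, pattern, unique_sets = TRUE))
}

# canonical atom order of an induced subgraph (BLISS with element colors)
.canonical_order <- function(mol, atoms) {
  sub <- .induced_mol(mol, atoms)
  g <- .mol_to_igraph(sub)
  colors <- .atom_colors(sub)
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  # perm maps old -> new label; we want atoms listed in canonical label order
  order(perm)
}

# induced submolecule on `atoms` (1-based molecule indices), atoms reindexed
.induced_mol <- function(mol, atoms) {
  atoms <- as.integer(atoms)
  remap <- match(seq_len(nrow(mol$atoms)), atoms)
  keep_b <- !is.na(remap[mol$bonds$i]) & !is.na(remap[mol$bonds$j])
  bonds <- mol$bonds[keep_b, , drop = FALSE]
  bi <- remap[bonds$i]; bj <- remap[bonds$j]
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  bonds$i <- bi; bonds$j <- bj
  out <- list(
    smiles = NA_character_,
    atoms = mol$atoms[atoms, , drop = FALSE],
    bonds = bonds
  )
  rownames(out$atoms) <- NULL
  rownames(out$bonds) <- NULL
  class(out) <- "toxgat_mol"
  out
}

#' Canonical SMARTS for an induced substructure
#'
#' Produces a deterministic SMARTS string for the subgraph induced by
#' `atoms`: canonical atom order via colored canonical labeling, then a DFS
#' writer. Aromatic atoms are written lowercase with explicit `:` bonds;
#' double/triple bonds as `=`/`#`. The same substructure embedded in
#' different molecules (same elements/aromaticity/bond orders) yields the
#' same string, which is what the alert pipeline groups on.
#'
#' @param mol a `toxgat_mol` or SMILES string.
#' @param atoms integer vector of atom indices (1-based) inducing a connected
#'   subgraph.
#' @return SMARTS string.
#' @export
substructure_smarts <- function(mol, atoms) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  atoms <- as.integer(atoms)
  if (length(atoms) == 0L) stop("empty substructure")
  sub <- .induced_mol(mol, atoms)
  comp <- .components(nrow(sub$atoms), sub$bonds$i, sub$bonds$j)
  if (max(comp) > 1L) stop("substructure atoms do not induce a connected subgraph")
  ord <- .canonical_order(mol, atoms)
  sub2 <- .induced_mol(sub, ord)
  .write_smiles(sub2)
}

# deterministic DFS SMILES/SMARTS writer (starts at atom 1, neighbors in
# index order); handles rings via closure digits
.write_smiles <- function(mol) {
  m <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  adj <- vector("list", m)
  bond_of <- matrix(0L, m, m)
  for (b in seq_len(nb)) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    bond_of[i, j] <- b; bond_of[j, i] <- b
  }
  bsym <- function(b) switch(mol$bonds$order[b],
                             single = "", double = "=", triple = "#",
                             aromatic = ":")
  asym <- function(a) {
    e <- mol$atoms$element[a]
    s <- if (mol$atoms$aromatic[a]) tolower(e) else e
    q <- mol$atoms$charge[a]
    if (q != 0L) {
      qs <- if (q > 0) paste0("+", if (q > 1) q else "") else
        paste0("-", if (q < -1) -q else "")
      s <- paste0("[", s, qs, "]")
    }
    s
  }
  visited <- logical(m)
  used <- logical(nb)
  children <- vector("list", m)   # tree children in traversal order
  ring_marks <- vector("list", m) # closure tokens appended after atom symbol
  digit <- 0L
  dfs <- function(a) {
    visited[a] <<- TRUE
    for (w in sort(adj[[a]])) {
      b <- bond_of[a, w]
      if (used[b]) next
      if (visited[w]) {
        used[b] <<- TRUE
        digit <<- digit + 1L
        tok <- if (digit > 9L) sprintf("%%%02d", digit) else as.character(digit)
        ring_marks[[a]] <<- c(ring_marks[[a]], paste0(bsym(b), tok))
        ring_marks[[w]] <<- c(ring_marks[[w]], paste0(bsym(b), tok))
      } else {
        used[b] <<- TRUE
        children[[a]] <<- c(children[[a]], w)
        dfs(w)
      }
    }
  }
  dfs(1L)
  emit <- function(a, via_bond) {
    out <- if (is.na(via_bond)) asym(a) else paste0(bsym(via_bond), asym(a))
    out <- paste0(out, paste(ring_marks[[a]], collapse = ""))
    kids <- children[[a]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        child <- emit(kids[k], bond_of[a, kids[k]])
        out <- if (k < length(kids)) paste0(out, "(", child, ")")
               else paste0(out, child)
      }
    }
    out
  }
  emit(1L, NA_integer_)
}

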