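#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Parses daylight-dialect SMILES covering the organic subset (B, C, N, O, P,
#' S, F, Cl, Br, I, Si, Se and their aromatic forms), bracket atoms with
#' explicit hydrogen counts, formal charges and atom maps, branches, ring
#' closures (including `%nn`), and multi-fragment inputs separated by `.`.
#' Hydrogens are implicit: the graph holds heavy atoms only and the total
#' hydrogen count is an atom attribute, so an acid and its conjugate base
#' share an identical skeleton. Stereo marks (`/ \ @`) and isotopes are
#' accepted and ignored; pKa is modeled as insensitive to them.
#'
#' For multi-fragment inputs (salts) the largest organic fragment is retained
#' with a warning, since a pKa refers to a single species.
#'
#' @param smiles A single SMILES string.
#' @return A `pka_mol` object: a list with `atoms` (tibble: `element`,
#'   `aromatic`, `charge`, `n_h`, `map`), `bonds` (tibble: `i`, `j`, `order`
#'   in single/double/triple/aromatic) and the source string.
#' @export
#' @examples
#' m <- parse_smiles("CC(=O)O")   # acetic acid
#' m$atoms
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0)
  exh <- integer(0); has_exh <- logical(0); amap <- integer(0)
  bi <- integer(0); bj <- integer(0); bo <- character(0)

  prev <- NA_integer_          # previous atom index
  stack <- integer(0)          # branch stack
  pending <- NA_character_     # pending bond symbol
  rings <- list()              # ring-closure table: label -> list(atom, bond)

  add_atom <- function(sym, aromatic, charge, hcount, has_h, map) {
    el   <<- c(el, sym);       arom <<- c(arom, aromatic)
    chg  <<- c(chg, charge);   exh  <<- c(exh, hcount)
    has_exh <<- c(has_exh, has_h); amap <<- c(amap, map)
    idx <- length(el)
    if (!is.na(prev)) {
      ord <- bond_order_from_symbol(pending, arom[prev] && aromatic)
      bi <<- c(bi, prev); bj <<- c(bj, idx); bo <<- c(bo, ord)
    }
    pending <<- NA_character_
    prev <<- idx
    idx
  }

  close_ring <- function(label) {
    key <- as.character(label)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending)
      pending <<- NA_character_
    } else {
      open <- rings[[key]]; rings[[key]] <<- NULL
      sym <- if (!is.na(pending)) pending else open$bond
      ord <- bond_order_from_symbol(sym, arom[open$atom] && arom[prev])
      bi <<- c(bi, open$atom); bj <<- c(bj, prev); bo <<- c(bo, ord)
      pending <<- NA_character_
    }
  }

  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; k <- k + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); k <- k + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES at position ", k,
                                    ": ", s, call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      k <- k + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_character_; k <- k + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); k <- k + 1L
    } else if (ch == "%") {
      if (k + 2L > n) stop("truncated %nn ring closure in SMILES: ", s, call. = FALSE)
      close_ring(paste0(chars[k + 1L], chars[k + 2L])); k <- k + 3L
    } else if (ch == "[") {
      close_k <- k
      while (close_k <= n && chars[close_k] != "]") close_k <- close_k + 1L
      if (close_k > n) stop("unclosed bracket atom in SMILES: ", s, call. = FALSE)
      body <- substr(s, k + 1L, close_k - 1L)
      at <- parse_bracket_atom(body, s)
      add_atom(at$symbol, at$aromatic, at$charge, at$hcount, TRUE, at$map)
      k <- close_k + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (k < n) paste0(ch, chars[k + 1L]) else ""
      if (two %in% c("Cl", "Br", "Si", "Se")) {
        add_atom(two, FALSE, 0L, 0L, FALSE, NA_integer_); k <- k + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, 0L, 0L, FALSE, NA_integer_); k <- k + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, 0L, 0L, FALSE, NA_integer_); k <- k + 1L
      } else {
        stop("unsupported atom symbol '", ch, "' at position ", k,
             " in SMILES: ", s, call. = FALSE)
      }
    } else {
      stop("unexpected character '", ch, "' at position ", k,
           " in SMILES: ", s, call. = FALSE)
    }
  }
  if (length(rings) > 0L) stop("unclosed ring bond in SMILES: ", s, call. = FALSE)
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", s, call. = FALSE)

  atoms <- tibble::tibble(element = el, aromatic = arom, charge = chg,
                          n_h = exh, explicit_h = has_exh, map = amap)
  bonds <- tibble::tibble(i = bi, j = bj, order = bo)
  mol <- structure(list(atoms = atoms, bonds = bonds, smiles = s),
                   class = "pka_mol")
  mol <- keep_largest_fragment(mol)
  assign_implicit_hydrogens(mol)
}

bond_order_from_symbol <- function(sym, both_aromatic) {
  if (is.na(sym)) {
    if (both_aromatic) "aromatic" else "single"
  } else {
    switch(sym,
           "-" = "single", "/" = "single", "\\" = "single",
           "=" = "double", "#" = "triple", ":" = "aromatic",
           stop("unknown bond symbol: ", sym, call. = FALSE))
  }
}

parse_bracket_atom <- function(body, smiles) {
  rest <- sub("^[0-9]*", "", body)  # drop isotope
  mm <- regexpr("^([A-Z][a-z]?|[a-z][a-e]?|\\*)", rest)
  if (mm == -1L) stop("cannot parse bracket atom [", body, "] in SMILES: ",
                      smiles, call. = FALSE)
  sym_raw <- regmatches(rest, mm)
  rest <- substr(rest, attr(mm, "match.length") + 1L, nchar(rest))
  aromatic <- grepl("^[a-z]", sym_raw)
  symbol <- paste0(toupper(substr(sym_raw, 1, 1)), substring(sym_raw, 2))
  rest <- gsub("@+", "", rest)  # ignore chirality
  hcount <- 0L
  hm <- regexpr("H[0-9]*", rest)
  if (hm != -1L) {
    htxt <- regmatches(rest, hm)
    hcount <- if (htxt == "H") 1L else as.integer(substring(htxt, 2))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regexpr("(\\+\\+|--|[+-][0-9]*)", rest)
  if (cm != -1L) {
    ctxt <- regmatches(rest, cm)
    charge <- if (ctxt %in% c("+", "-", "++", "--")) {
      c("+" = 1L, "-" = -1L, "++" = 2L, "--" = -2L)[[ctxt]]
    } else {
      sgn <- if (substr(ctxt, 1, 1) == "+") 1L else -1L
      sgn * as.integer(substring(ctxt, 2))
    }
    rest <- sub("(\\+\\+|--|[+-][0-9]*)", "", rest)
  }
  map <- NA_integer_
  mp <- regexpr(":[0-9]+", rest)
  if (mp != -1L) map <- as.integer(substring(regmatches(rest, mp), 2))
  list(symbol = symbol, aromatic = aromatic, charge = charge,
       hcount = hcount, map = map)
}

# Allowed valence states per element; the smallest state that accommodates
# the bond-order sum is used when computing implicit hydrogen counts.
allowed_valences <- function(element, charge) {
  base <- switch(element,
                 H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
                 Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L),
                 Cl = 1L, Se = c(2L, 4L, 6L), Br = 1L, I = 1L,
                 stop("unsupported element: ", element, call. = FALSE))
  if (charge == 0L) return(base)
  if (element %in% c("N", "O", "S", "P", "Se") && charge > 0L) return(base + charge)
  if (element == "B" && charge < 0L) return(base + abs(charge))
  pmax(base - abs(charge), 0L)
}

assign_implicit_hydrogens <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  ordval <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  bsum <- numeric(nrow(a))
  if (nrow(b) > 0) {
    v <- ordval[b$order]
    for (k in seq_len(nrow(b))) {
      bsum[b$i[k]] <- bsum[b$i[k]] + v[k]
      bsum[b$j[k]] <- bsum[b$j[k]] + v[k]
    }
  }
  # an aromatic atom always participates in the pi system: round the 1.5s down
  bsum <- floor(bsum + 1e-9)
  for (k in seq_len(nrow(a))) {
    if (a$explicit_h[k]) next  # bracket atoms carry their stated H count
    vals <- allowed_valences(a$element[k], a$charge[k])
    val <- vals[vals >= bsum[k]][1]
    a$n_h[k] <- if (is.na(val)) 0L else as.integer(val - bsum[k])
  }
  mol$atoms <- a
  mol
}

keep_largest_fragment <- function(mol) {
  g <- mol_graph(mol)
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(mol)
  keep <- which.max(comp$csize)
  warning("multi-fragment SMILES; keeping the largest fragment (",
          comp$csize[keep], " of ", nrow(mol$atoms), " heavy atoms): ",
          mol$smiles, call. = FALSE)
  sel <- which(comp$membership == keep)
  subset_molecule(mol, sel)
}

# igraph view of the heavy-atom skeleton
mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds) > 0) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

subset_molecule <- function(mol, sel) {
  newidx <- rep(NA_integer_, nrow(mol$atoms))
  newidx[sel] <- seq_along(sel)
  b <- mol$bonds[mol$bonds$i %in% sel & mol$bonds$j %in% sel, , drop = FALSE]
  b$i <- newidx[b$i]; b$j <- newidx[b$j]
  mol$atoms <- mol$atoms[sel, , drop = FALSE]
  mol$bonds <- b
  mol
}

#' Reorder the atoms of a molecule
#'
#' Relabels atoms by a permutation (`perm[k]` is the old index placed at new
#' position `k`), keeping bonds consistent. Used to relocate the ionization
#' center and to generate randomized isomorphs.
#'
#' @param mol A `pka_mol`.
#' @param perm Integer permutation of the atom indices.
#' @return The relabeled `pka_mol`.
#' @export
permute_molecule <- function(mol, perm) {
  stopifnot(length(perm) == nrow(mol$atoms), !anyDuplicated(perm))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mol$atoms <- mol$atoms[perm, , drop = FALSE]
  mol$bonds$i <- inv[mol$bonds$i]
  mol$bonds$j <- inv[mol$bonds$j]
  mol
}

#' @export
print.pka_mol <- function(x, ...) {
  cat("<pka_mol> ", x$smiles, " (", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, net charge ", net_charge(x), ")\n", sep = "")
  invisible(x)
}

#' Molecule-level bookkeeping helpers
#'
#' `net_charge()` sums formal charges; `heavy_degree()` counts heavy-atom
#' neighbors; `bond_distances()` returns per-atom graph distance in bonds
#' from a center atom (`Inf` for disconnected atoms).
#'
#' @param mol A `pka_mol`.
#' @param center Atom index (1-based).
#' @return See details.
#' @export
net_charge <- function(mol) sum(mol$atoms$charge)

#' @rdname net_charge
#' @export
heavy_degree <- function(mol) {
  d <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    t1 <- table(factor(mol$bonds$i, levels = seq_len(nrow(mol$atoms))))
    t2 <- table(factor(mol$bonds$j, levels = seq_len(nrow(mol$atoms))))
    d <- as.integer(t1 + t2)
  }
  d
}

#' @rdname net_charge
#' @export
bond_distances <- function(mol, center) {
  stopifnot(center >= 1, center <= nrow(mol$atoms))
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  dist <- rep(Inf, n)
  dist[center] <- 0
  frontier <- center
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- nxt
  }
  dist
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Ring and hybridization perception
#'
#' `smallest_ring_sizes()` returns, per atom, the size of the smallest ring
#' containing it (0 if acyclic), capped at `cap` so the feature range stays
#' bounded; the smallest cycle through an atom is the minimum over its
#' incident edges of (shortest path between the edge's endpoints avoiding
#' that edge) + 1. `hybridizations()` classifies each atom as
#' sp/sp2/sp3/other from its bond pattern: a triple bond or two doubles
#' gives sp, any double or aromatic bond sp2, other bondable main-group
#' atoms sp3 (hypervalent S/P/Se centers with three or more heavy neighbors
#' stay sp3); halogens are "other".
#'
#' @param mol A `pka_mol`.
#' @param cap Ring-size cap (default 8).
#' @return Integer vector (`smallest_ring_sizes`) or character vector
#'   (`hybridizations`), one entry per atom.
#' @export
smallest_ring_sizes <- function(mol, cap = 8L) {
  n <- nrow(mol$atoms)
  out <- integer(n)
  if (nrow(mol$bonds) == 0) return(out)
  g <- mol_graph(mol)
  # cycle rank 0: acyclic, nothing to search
  if (nrow(mol$bonds) - n + igraph::components(g)$no == 0L) return(out)
  ring <- rep(Inf, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    d <- igraph::distances(g2, v = i, to = j)[1, 1]
    if (is.finite(d)) {
      len <- d + 1
      ring[i] <- min(ring[i], len); ring[j] <- min(ring[j], len)
    }
  }
  out <- ifelse(is.finite(ring), pmin(ring, cap), 0)
  as.integer(out)
}

# Lone-pair fine structure (e.g. amide N planarity) is not perceived; the
# conjugation bond feature carries that information instead.
#' @rdname smallest_ring_sizes
#' @export
hybridizations <- function(mol) {
  n <- nrow(mol$atoms)
  dcount <- integer(n); tcount <- integer(n); acount <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    for (v in c(mol$bonds$i[k], mol$bonds$j[k])) {
      if (o == "double") dcount[v] <- dcount[v] + 1L
      if (o == "triple") tcount[v] <- tcount[v] + 1L
      if (o == "aromatic") acount[v] <- acount[v] + 1L
    }
  }
  out <- character(n)
  deg <- heavy_degree(mol)
  for (v in seq_len(n)) {
    el <- mol$atoms$element[v]
    out[v] <-
      if (el %in% c("S", "P", "Se") && deg[v] >= 3L) "sp3"  # hypervalent centers
      else if (tcount[v] >= 1L || dcount[v] >= 2L) "sp"
      else if (dcount[v] >= 1L || acount[v] >= 1L || mol$atoms$aromatic[v]) "sp2"
      else if (el %in% c("B", "C", "N", "O", "P", "S", "Si", "Se")) "sp3"
      else "other"
  }
  out
}
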