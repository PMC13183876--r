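# Substructure pattern matching over pka_mol graphs.
#
# Implements the SMARTS subset needed by the ionizable-group rule table:
#   atoms   : bare organic-subset symbols (aromatic lowercase), '*', or
#             bracket expressions [p1;p2,p3;...] where ';' is AND over
#             clauses, ',' is OR within a clause and '&' is AND within an
#             alternative. Primitives: element symbol (uppercase = aliphatic,
#             lowercase = aromatic), #n (atomic number), A/a, Hn, Dn (heavy
#             degree), R/R0 (ring membership), charge (+, -, +n, -n, +0),
#             '*', $(...) recursive environment, and '!' negation of any
#             primitive. ':n' marks the mapped (site) atom.
#   bonds   : default (single-or-aromatic), '-', '=', '#', ':', '~'.
#   topology: branches and numeric ring closures.
#
# Matching is plain backtracking with an injectivity constraint; molecules
# here are tens of atoms, so no indexing sophistication is warranted.

parse_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  atoms <- list(); bi <- integer(0); bj <- integer(0); bt <- character(0)
  prev <- NA_integer_; stack <- integer(0); pending <- NA_character_
  rings <- list()

  add_atom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    idx <- length(atoms)
    if (!is.na(prev)) {
      bi <<- c(bi, prev); bj <<- c(bj, idx)
      bt <<- c(bt, if (is.na(pending)) "default" else pending)
    }
    pending <<- NA_character_; prev <<- idx
    idx
  }

  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch; k <- k + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); k <- k + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; k <- k + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, bond = pending)
      } else {
        open <- rings[[key]]; rings[[key]] <- NULL
        sym <- if (!is.na(pending)) pending else open$bond
        bi <- c(bi, open$atom); bj <- c(bj, prev)
        bt <- c(bt, if (is.na(sym)) "default" else sym)
      }
      pending <- NA_character_; k <- k + 1L
    } else if (ch == "[") {
      depth <- 1L; close_k <- k
      while (depth > 0L) {
        close_k <- close_k + 1L
        if (close_k > n) stop("unclosed '[' in pattern: ", pattern, call. = FALSE)
        if (chars[close_k] == "[") depth <- depth + 1L
        if (chars[close_k] == "]") depth <- depth - 1L
      }
      add_atom(parse_atom_expr(substr(pattern, k + 1L, close_k - 1L), pattern))
      k <- close_k + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (k < n) paste0(ch, chars[k + 1L]) else ""
      if (two %in% c("Cl", "Br", "Si", "Se")) {
        add_atom(list(clauses = list(list(list(type = "element", value = two,
                                               aromatic = FALSE, negate = FALSE))),
                      map = NA_integer_))
        k <- k + 2L
      } else if (ch == "*") {
        add_atom(list(clauses = list(), map = NA_integer_)); k <- k + 1L
      } else {
        arom <- grepl("[a-z]", ch)
        add_atom(list(clauses = list(list(list(type = "element",
                                               value = toupper(ch),
                                               aromatic = arom, negate = FALSE))),
                      map = NA_integer_))
        k <- k + 1L
      }
    } else {
      stop("unexpected character '", ch, "' in pattern: ", pattern, call. = FALSE)
    }
  }
  if (length(rings) > 0L) stop("unclosed ring bond in pattern: ", pattern, call. = FALSE)
  list(atoms = atoms,
       bonds = data.frame(i = bi, j = bj, type = bt,
                          stringsAsFactors = FALSE),
       pattern = pattern)
}

# Split at top level (outside $(...) parentheses) on a single character.
split_top <- function(s, sep) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; out <- character(0); cur <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

parse_atom_expr <- function(body, pattern) {
  map <- NA_integer_
  mp <- regexpr(":[0-9]+$", body)
  if (mp != -1L) {
    map <- as.integer(substring(regmatches(body, mp), 2))
    body <- sub(":[0-9]+$", "", body)
  }
  clauses <- lapply(split_top(body, ";"), function(clause) {
    lapply(split_top(clause, ","), function(alt) {
      prims <- split_top(alt, "&")
      lapply(prims, parse_primitive, pattern = pattern)
    })
  })
  # flatten: each clause is a list of alternatives; each alternative a list of prims
  list(clauses = clauses, map = map)
}

parse_primitive <- function(p, pattern) {
  negate <- FALSE
  if (startsWith(p, "!")) { negate <- TRUE; p <- substring(p, 2) }
  out <-
    if (p == "*") list(type = "any")
    else if (p == "A") list(type = "aliphatic")
    else if (p == "a") list(type = "aromatic")
    else if (p == "R") list(type = "ring", value = TRUE)
    else if (p == "R0") list(type = "ring", value = FALSE)
    else if (grepl("^H[0-9]*$", p))
      list(type = "hcount", value = if (p == "H") 1L else as.integer(substring(p, 2)))
    else if (grepl("^D[0-9]+$", p))
      list(type = "degree", value = as.integer(substring(p, 2)))
    else if (grepl("^#[0-9]+$", p))
      list(type = "atomic_number", value = as.integer(substring(p, 2)))
    else if (grepl("^[+-][0-9]*$", p)) {
      v <- if (nchar(p) == 1L) 1L else as.integer(substring(p, 2))
      list(type = "charge", value = if (substr(p, 1, 1) == "+") v else -v)
    }
    else if (grepl("^\\$\\(.*\\)$", p))
      list(type = "recursive",
           value = parse_pattern(substr(p, 3, nchar(p) - 1L)))
    else if (grepl("^[A-Z][a-z]?$", p))
      list(type = "element", value = p, aromatic = FALSE)
    else if (grepl("^[a-z]$", p))
      list(type = "element", value = toupper(p), aromatic = TRUE)
    else stop("cannot parse primitive '", p, "' in pattern: ", pattern,
              call. = FALSE)
  out$negate <- negate
  out
}

# Precomputed per-atom properties used by the predicates.
mol_match_context <- function(mol) {
  list(mol = mol,
       degree = heavy_degree(mol),
       ring = smallest_ring_sizes(mol) > 0,
       atomic_number = element_property(mol$atoms$element, "atomic_number"))
}

atom_matches <- function(ctx, v, spec) {
  for (clause in spec$clauses) {
    ok <- FALSE
    for (alt in clause) {
      alt_ok <- TRUE
      for (prim in alt) {
        r <- primitive_ok(ctx, v, prim)
        if (isTRUE(prim$negate)) r <- !r
        if (!r) { alt_ok <- FALSE; break }
      }
      if (alt_ok) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

primitive_ok <- function(ctx, v, prim) {
  a <- ctx$mol$atoms
  switch(prim$type,
    any           = TRUE,
    aliphatic     = !a$aromatic[v],
    aromatic      = a$aromatic[v],
    ring          = ctx$ring[v] == prim$value,
    hcount        = a$n_h[v] == prim$value,
    degree        = ctx$degree[v] == prim$value,
    atomic_number = ctx$atomic_number[v] == prim$value,
    charge        = a$charge[v] == prim$value,
    element       = a$element[v] == prim$value &&
                    a$aromatic[v] == prim$aromatic,
    recursive     = length(match_pattern_impl(ctx, prim$value,
                                              anchor = v, first_only = TRUE)) > 0,
    stop("unknown primitive type: ", prim$type, call. = FALSE))
}

bond_type_ok <- function(order, type) {
  switch(type,
    default  = order %in% c("single", "aromatic"),
    "-"      = order == "single",
    "="      = order == "double",
    "#"      = order == "triple",
    ":"      = order == "aromatic",
    "~"      = TRUE,
    stop("unknown bond type: ", type, call. = FALSE))
}

# All injective embeddings of `pat` into the molecule. Returns a list of
# integer vectors (pattern atom -> molecule atom). With `anchor`, pattern
# atom 1 is pinned to that molecule atom (recursive environments).
match_pattern_impl <- function(ctx, pat, anchor = NULL, first_only = FALSE) {
  mol <- ctx$mol
  np <- length(pat$atoms)
  nb <- nrow(pat$bonds)
  results <- list()

  # adjacency of the pattern
  padj <- vector("list", np)
  for (k in seq_len(nb)) {
    i <- pat$bonds$i[k]; j <- pat$bonds$j[k]
    padj[[i]] <- c(padj[[i]], k); padj[[j]] <- c(padj[[j]], k)
  }
  # molecule bond lookup
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  bond_of <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(mol$bonds)))
    assign(key(mol$bonds$i[k], mol$bonds$j[k]), mol$bonds$order[k], envir = bond_of)
  madj <- adjacency_list(mol)

  assignment <- rep(NA_integer_, np)
  used <- rep(FALSE, nrow(mol$atoms))

  consistent <- function(p, v) {
    if (!atom_matches(ctx, v, pat$atoms[[p]])) return(FALSE)
    for (bk in padj[[p]]) {
      q <- if (pat$bonds$i[bk] == p) pat$bonds$j[bk] else pat$bonds$i[bk]
      if (!is.na(assignment[q])) {
        ord <- get0(key(v, assignment[q]), envir = bond_of, ifnotfound = NULL)
        if (is.null(ord) || !bond_type_ok(ord, pat$bonds$type[bk])) return(FALSE)
      }
    }
    TRUE
  }

  extend <- function() {
    if (first_only && length(results) > 0) return()
    p <- which(is.na(assignment))[1]
    if (is.na(p)) { results[[length(results) + 1L]] <<- assignment; return() }
    # prefer a pattern atom adjacent to an assigned one to prune candidates
    cands <- NULL
    for (pp in which(is.na(assignment))) {
      for (bk in padj[[pp]]) {
        q <- if (pat$bonds$i[bk] == pp) pat$bonds$j[bk] else pat$bonds$i[bk]
        if (!is.na(assignment[q])) { p <- pp; cands <- madj[[assignment[q]]]; break }
      }
      if (!is.null(cands)) break
    }
    if (is.null(cands)) cands <- seq_len(nrow(mol$atoms))
    for (v in cands) {
      if (used[v] || !consistent(p, v)) next
      assignment[p] <<- v; used[v] <<- TRUE
      extend()
      assignment[p] <<- NA_integer_; used[v] <<- FALSE
      if (first_only && length(results) > 0) return()
    }
  }

  if (!is.null(anchor)) {
    if (consistent(1L, anchor)) {
      assignment[1L] <- anchor; used[anchor] <- TRUE
      extend()
    }
  } else {
    extend()
  }
  results
}

#' Match a substructure pattern against a molecule
#'
#' @param mol A `pka_mol`.
#' @param pattern A pattern string in the supported SMARTS subset.
#' @return A list of integer vectors, one per embedding, mapping pattern
#'   atoms to molecule atom indices.
#' @export
#' @examples
#' match_pattern(parse_smiles("NCC(=O)O"), "[O;D1;H1]-[C]=[O]")
match_pattern <- function(mol, pattern) {
  pat <- if (is.character(pattern)) parse_pattern(pattern) else pattern
  match_pattern_impl(mol_match_context(mol), pat)
}
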