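#' Circular (Morgan-style) fingerprints
#'
#' Hashed circular fingerprints computed directly on the heavy-atom graph.
#' Initial atom invariants are (atomic number, heavy degree, formal charge,
#' hydrogen count, aromaticity, ring membership); at each iteration up to
#' `radius`, an atom's identifier is rehashed together with the sorted
#' (bond-order, neighbor-identifier) pairs, so the result is independent of
#' atom input order and two SMILES spellings of one molecule give the same
#' fingerprint. All identifiers across radii are folded into `n_bits` bits.
#'
#' @param mol A `pka_mol` or SMILES string.
#' @param n_bits Fingerprint length (default 2048).
#' @param radius Circular radius in bonds (default 2, ECFP4-like).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
#' @examples
#' sum(morgan_fingerprint("CC(=O)O"))
morgan_fingerprint <- function(mol, n_bits = 2048L, radius = 2L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  n <- nrow(mol$atoms)
  deg <- heavy_degree(mol)
  ring <- smallest_ring_sizes(mol) > 0
  zn <- element_property(mol$atoms$element, "atomic_number")
  ids <- vapply(seq_len(n), function(v) hash_ints(c(
    zn[v], deg[v], mol$atoms$charge[v], mol$atoms$n_h[v],
    as.integer(mol$atoms$aromatic[v]), as.integer(ring[v]))), numeric(1))
  bond_code <- c(single = 1, aromatic = 2, double = 3, triple = 4)
  nb <- lapply(seq_len(n), function(v) {
    sel <- mol$bonds$i == v | mol$bonds$j == v
    other <- ifelse(mol$bonds$i[sel] == v, mol$bonds$j[sel], mol$bonds$i[sel])
    cbind(code = bond_code[mol$bonds$order[sel]], other = other)
  })
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(v) {
      pairs <- nb[[v]]
      if (nrow(pairs) == 0) return(hash_ints(c(r, ids[v])))
      o <- order(pairs[, "code"], ids[pairs[, "other"]])
      hash_ints(c(r, ids[v],
                  as.vector(t(cbind(pairs[o, "code"], ids[pairs[o, "other"]])))))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  fp <- integer(n_bits)
  fp[unique(all_ids %% n_bits) + 1L] <- 1L
  fp
}

# Deterministic integer-vector hash into [0, 2^31 - 2].
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1009 + (x %% 65536) + 7919) %% 2147483629
  h
}

#' Tanimoto similarity between binary fingerprints
#'
#' @param a,b Binary fingerprint vectors.
#' @return Similarity in `[0, 1]` (1 for two empty fingerprints).
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' @rdname tanimoto
#' @param fps A matrix of fingerprints (rows = molecules) or list of vectors.
#' @return `tanimoto_matrix()`: the full pairwise similarity matrix.
#' @export
tanimoto_matrix <- function(fps) {
  if (is.list(fps)) fps <- do.call(rbind, fps)
  m <- fps %*% t(fps)
  pop <- diag(m)
  uni <- outer(pop, pop, "+") - m
  out <- ifelse(uni == 0, 1, m / pmax(uni, 1e-12))
  diag(out) <- 1
  out
}
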