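#' Default feature toggles
#'
#' Every chemistry-principle feature can be switched off individually to run
#' ablation studies. Keys follow an `atom.`/`bond.` prefix convention in
#' configuration files (e.g. `atom.hardness: off`); here they are logical
#' flags. The element one-hot block is off by default: the physical atom
#' properties already carry the element identity that matters for pKa.
#'
#' @return Named list of logical flags.
#' @export
default_toggles <- function() {
  list(
    atom.electronegativity = TRUE,
    atom.hardness          = TRUE,
    atom.atomic_diameter   = TRUE,
    atom.formal_charge     = TRUE,
    atom.hybridization     = TRUE,
    atom.ring_size         = TRUE,
    atom.n_hydrogens       = TRUE,
    atom.element           = FALSE,
    bond.order             = TRUE,
    bond.conjugation       = TRUE,
    bond.polarization      = TRUE
  )
}

merge_toggles <- function(toggles = NULL) {
  out <- default_toggles()
  if (!is.null(toggles)) {
    unknown <- setdiff(names(toggles), names(out))
    if (length(unknown) > 0)
      stop("unknown feature toggle(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out[names(toggles)] <- lapply(toggles, isTRUE)
  }
  out
}

#' Compute chemistry-principle atom features
#'
#' One feature row per heavy atom: normalized Pauling electronegativity,
#' Pearson absolute hardness, atomic diameter (inductive-effect handles),
#' formal charge, hybridization one-hot (sp/sp2/sp3/other), normalized
#' smallest-ring size (0 if acyclic, capped at 8) and normalized total
#' hydrogen count, plus an optional element one-hot block over the registry.
#' Switched-off features contribute zero columns (ablation semantics).
#'
#' @param mol A `pka_mol`.
#' @param toggles Feature switches (see [default_toggles()]).
#' @return Numeric matrix, atoms x features, with named columns.
#' @export
#' @examples
#' featurize_atoms(parse_smiles("CC(=O)O"))
featurize_atoms <- function(mol, toggles = NULL) {
  tg <- merge_toggles(toggles)
  a <- mol$atoms
  cols <- list()
  if (tg$atom.electronegativity)
    cols$electronegativity <- normalize_feature(
      element_property(a$element, "electronegativity"), "electronegativity")
  if (tg$atom.hardness)
    cols$hardness <- normalize_feature(
      element_property(a$element, "hardness_ev"), "hardness")
  if (tg$atom.atomic_diameter)
    cols$atomic_diameter <- normalize_feature(
      element_property(a$element, "diameter_a"), "atomic_diameter")
  if (tg$atom.formal_charge)
    cols$formal_charge <- as.numeric(a$charge)
  if (tg$atom.hybridization) {
    hyb <- hybridizations(mol)
    for (h in c("sp", "sp2", "sp3", "other"))
      cols[[paste0("hyb_", h)]] <- as.numeric(hyb == h)
  }
  if (tg$atom.ring_size)
    cols$ring_size <- normalize_feature(smallest_ring_sizes(mol), "ring_size")
  if (tg$atom.n_hydrogens)
    cols$n_hydrogens <- normalize_feature(a$n_h, "n_hydrogens")
  if (tg$atom.element) {
    reg <- element_registry()
    for (el in reg$symbol)
      cols[[paste0("elem_", el)]] <- as.numeric(a$element == el)
  }
  # validate elements even when all property features are toggled off
  element_property(a$element, "electronegativity")
  m <- do.call(cbind, cols)
  if (is.null(m)) m <- matrix(0, nrow(a), 0)
  rownames(m) <- NULL
  m
}

#' Revised conjugation perception
#'
#' Flags each bond with two indicators. `conjugated`: the bond lies in an
#' alternating multiple-bond / lone-pair-donor path (both endpoints are
#' pi-system atoms or lone-pair donors, and at least one is a pi atom).
#' `enhanced_resonance`: the bond belongs to a delocalized anionic group — a
#' single bond from a negatively charged lone-pair donor (N, O, S, Se) to a
#' pi-system atom, together with that pi atom's double bonds to heteroatoms.
#' Conventional conjugation perception marks a carboxylic acid and its
#' carboxylate identically, yet delocalization is stronger in the anion; the
#' enhanced flag restores that distinction, and bonds carrying it are treated
#' as a symmetric delocalized group by the bond-order and polarization
#' features (both C-O bonds of acetate come out feature-identical).
#'
#' @param mol A `pka_mol`.
#' @return A list: `flags` (bonds x 2 matrix: conjugated, enhanced_resonance),
#'   `delocalized` (logical per bond), `core` (integer per bond: the pi-core
#'   atom of a delocalized group, `NA` elsewhere).
#' @export
revised_conjugation <- function(mol) {
  b <- mol$bonds
  m <- nrow(b)
  a <- mol$atoms
  multiple <- b$order %in% c("double", "triple", "aromatic")
  pi_atom <- a$aromatic
  for (k in seq_len(m)) if (multiple[k]) {
    pi_atom[b$i[k]] <- TRUE; pi_atom[b$j[k]] <- TRUE
  }
  donor <- a$element %in% c("N", "O", "S", "Se", "F", "Cl", "Br", "I") |
    a$charge < 0
  conj <- logical(m); enh <- logical(m); core <- rep(NA_integer_, m)
  for (k in seq_len(m)) {
    u <- b$i[k]; v <- b$j[k]
    conj[k] <- (pi_atom[u] || donor[u]) && (pi_atom[v] || donor[v]) &&
      (pi_atom[u] || pi_atom[v])
  }
  # delocalized anionic groups
  anion <- which(a$charge < 0 & a$element %in% c("N", "O", "S", "Se") &
                   !a$aromatic)
  for (x in anion) {
    inc <- which((b$i == x | b$j == x) & b$order == "single")
    for (k in inc) {
      other <- if (b$i[k] == x) b$j[k] else b$i[k]
      if (!pi_atom[other]) next
      enh[k] <- TRUE; conj[k] <- TRUE; core[k] <- other
      if (a$aromatic[other]) next  # aromatic ring bonds keep their own flags
      dbl <- which((b$i == other | b$j == other) & b$order == "double")
      for (k2 in dbl) {
        far <- if (b$i[k2] == other) b$j[k2] else b$i[k2]
        if (a$element[far] %in% c("N", "O", "S", "Se")) {
          enh[k2] <- TRUE; conj[k2] <- TRUE; core[k2] <- other
        }
      }
    }
  }
  flags <- cbind(conjugated = as.numeric(conj),
                 enhanced_resonance = as.numeric(enh))
  list(flags = flags, delocalized = enh, core = core)
}

#' Directed bond polarization
#'
#' Signed electronegativity difference per bond, directed away from the
#' ionization center: for a bond whose atoms sit at different graph distances
#' from the center, the value is EN(farther atom) - EN(closer atom), so an
#' electron-withdrawing substituent "pulls" with a positive value regardless
#' of which side of the molecule it sits on. Equidistant endpoints (odd
#' cycles) give 0. Within a delocalized anionic group the direction relative
#' to the center is ill-defined; those bonds are directed away from the
#' group's pi-core atom instead.
#'
#' @param mol A `pka_mol`.
#' @param center Ionization-center atom index.
#' @param conj Optional result of [revised_conjugation()] (recomputed if
#'   missing).
#' @return Numeric vector, one signed Pauling-unit difference per bond.
#' @export
directed_polarization <- function(mol, center, conj = NULL) {
  if (is.null(conj)) conj <- revised_conjugation(mol)
  en <- element_property(mol$atoms$element, "electronegativity")
  dist <- bond_distances(mol, center)
  b <- mol$bonds
  out <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (any(is.infinite(dist[c(i, j)])))
      stop("bond between atoms disconnected from the ionization center",
           call. = FALSE)
    if (conj$delocalized[k]) {
      other <- if (conj$core[k] == i) j else i
      out[k] <- en[other] - en[conj$core[k]]
    } else if (dist[i] == dist[j]) {
      out[k] <- 0
    } else if (dist[i] < dist[j]) {
      out[k] <- en[j] - en[i]
    } else {
      out[k] <- en[i] - en[j]
    }
  }
  out
}

#' Per-form bond feature block
#'
#' Bond-order one-hot (single/aromatic/double/triple; delocalized-anion
#' bonds land in the aromatic slot), the two conjugation indicators, and
#' directed polarization — 7 columns per form under default toggles.
#'
#' @param mol A `pka_mol`.
#' @param center Ionization-center atom index.
#' @param toggles Feature switches (see [default_toggles()]).
#' @return Numeric matrix, bonds x features.
#' @export
featurize_bonds <- function(mol, center, toggles = NULL) {
  tg <- merge_toggles(toggles)
  b <- mol$bonds
  conj <- revised_conjugation(mol)
  cols <- list()
  if (tg$bond.order) {
    ord <- b$order
    ord[conj$delocalized] <- "aromatic"
    for (o in c("single", "aromatic", "double", "triple"))
      cols[[paste0("bond_", o)]] <- as.numeric(ord == o)
  }
  if (tg$bond.conjugation) {
    cols$conjugated <- conj$flags[, "conjugated"]
    cols$enhanced_resonance <- conj$flags[, "enhanced_resonance"]
  }
  if (tg$bond.polarization)
    cols$polarization <- directed_polarization(mol, center, conj)
  m <- do.call(cbind, cols)
  if (is.null(m)) m <- matrix(0, nrow(b), 0)
  rownames(m) <- NULL
  m
}

#' Assemble a paired acid/base molecular graph
#'
#' Builds the model input for one ionization site: the acid form and its
#' conjugate base share one heavy-atom skeleton (they differ by a single
#' proton), the ionization center is relocated to atom index 1, and the
#' per-atom / per-bond feature blocks of the two forms are concatenated.
#' `mode` controls the bond-feature layout: `"full"` keeps both forms'
#' blocks (14 bond features under default toggles), `"focused"` treats acid
#' and base bond orders as equivalent and drops the base-form bond-order
#' one-hot (10 features), `"acid_only"`/`"base_only"` keep a single form's
#' atom and bond blocks. Two molecular features — net charge of the base form
#' and the center's formal charge — ride along for the post-pooling stage of
#' the model.
#'
#' @param acid,base `pka_mol` objects for the conjugate pair.
#' @param center Ionization-center atom index (in the input ordering).
#' @param mode One of `"full"`, `"focused"`, `"acid_only"`, `"base_only"`.
#' @param toggles Feature switches (see [default_toggles()]).
#' @return A `pka_graph`: list with `x` (atom features), `edges`, `e_attr`
#'   (bond features), `bond_dist`, `mol_feats`, `mode`, `n_atoms`.
#' @export
#' @examples
#' g <- build_paired_graph(parse_smiles("CC(=O)O"), parse_smiles("CC(=O)[O-]"),
#'                         center = 4)
#' ncol(g$e_attr)  # 14
build_paired_graph <- function(acid, base, center,
                               mode = c("full", "focused", "acid_only", "base_only"),
                               toggles = NULL) {
  mode <- match.arg(mode)
  na <- nrow(acid$atoms)
  skeleton_ok <- nrow(base$atoms) == na &&
    identical(acid$atoms$element, base$atoms$element) &&
    nrow(acid$bonds) == nrow(base$bonds) &&
    identical(acid$bonds[, c("i", "j")], base$bonds[, c("i", "j")])
  if (!skeleton_ok)
    stop("structural mismatch: acid and base forms must share an identical ",
         "heavy-atom skeleton", call. = FALSE)
  if (sum(acid$atoms$n_h) - sum(base$atoms$n_h) != 1L)
    stop("structural mismatch: acid form must carry exactly one more ",
         "hydrogen than the base form", call. = FALSE)
  stopifnot(center >= 1, center <= na)

  # relocate the ionization center to index 1
  perm <- c(center, setdiff(seq_len(na), center))
  acid <- permute_molecule(acid, perm)
  base <- permute_molecule(base, perm)

  xa <- featurize_atoms(acid, toggles)
  xb <- featurize_atoms(base, toggles)
  ba <- featurize_bonds(acid, 1L, toggles)
  bb <- featurize_bonds(base, 1L, toggles)
  x <- switch(mode,
              full = , focused = cbind(xa, xb),
              acid_only = xa, base_only = xb)
  colnames(x) <- switch(mode,
    full = , focused = c(paste0("acid_", colnames(xa)), paste0("base_", colnames(xb))),
    acid_only = paste0("acid_", colnames(xa)),
    base_only = paste0("base_", colnames(xb)))
  e_attr <- switch(mode,
    full = {
      m <- cbind(ba, bb)
      colnames(m) <- c(paste0("acid_", colnames(ba)), paste0("base_", colnames(bb)))
      m
    },
    focused = {
      keep <- !grepl("^bond_", colnames(bb))
      m <- cbind(ba, bb[, keep, drop = FALSE])
      colnames(m) <- c(paste0("acid_", colnames(ba)),
                       paste0("base_", colnames(bb)[keep]))
      m
    },
    acid_only = { colnames(ba) <- paste0("acid_", colnames(ba)); ba },
    base_only = { colnames(bb) <- paste0("base_", colnames(bb)); bb })

  dist <- bond_distances(base, 1L)
  structure(list(
    x = x,
    edges = cbind(i = base$bonds$i, j = base$bonds$j),
    e_attr = e_attr,
    bond_dist = dist,
    mol_feats = c(net_charge = net_charge(base),
                  center_charge = base$atoms$charge[1]),
    mode = mode,
    n_atoms = na,
    label = NA_real_,
    smiles = base$smiles
  ), class = "pka_graph")
}

#' @export
print.pka_graph <- function(x, ...) {
  cat("<pka_graph> ", x$n_atoms, " atoms, ", nrow(x$edges), " bonds, mode=",
      x$mode, ", ", ncol(x$x), " atom features, ", ncol(x$e_attr),
      " bond features\n", sep = "")
  invisible(x)
}

#' Readout mask over a paired graph
#'
#' Atoms within `mask_size` bonds of the ionization center are included in
#' the model's readout; more distant atoms still pass messages but are
#' concealed from the pooled embedding. The center itself is always included.
#'
#' @param graph A `pka_graph`.
#' @param mask_size Non-negative integer `m`.
#' @return Logical vector, one flag per atom.
#' @export
compute_mask <- function(graph, mask_size) {
  if (!is.numeric(mask_size) || length(mask_size) != 1 || mask_size < 0)
    stop("mask_size must be a non-negative integer", call. = FALSE)
  graph$bond_dist <= mask_size
}

#' Randomize the atom order of a paired graph
#'
#' Draws a random permutation of the atom indices that fixes the ionization
#' center at index 1 and relabels the feature rows, edges and distances
#' consistently, yielding an isomorphic graph. Used for data augmentation:
#' the same molecule is presented to the model under many equivalent matrix
#' representations. Uses the current R random stream.
#'
#' @param graph A `pka_graph`.
#' @return A `pka_graph` isomorphic to the input.
#' @export
randomize_graph <- function(graph) {
  n <- graph$n_atoms
  if (n < 2) return(graph)
  perm <- c(1L, 1L + sample(n - 1L))          # new -> old
  inv <- integer(n); inv[perm] <- seq_len(n)  # old -> new
  graph$x <- graph$x[perm, , drop = FALSE]
  graph$bond_dist <- graph$bond_dist[perm]
  graph$edges <- cbind(i = inv[graph$edges[, "i"]], j = inv[graph$edges[, "j"]])
  graph
}
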