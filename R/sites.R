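#' Default ionizable-group rule table
#'
#' Loads and validates the shipped table of named substructure patterns that
#' define which atoms count as ionizable. The philosophy mirrors how a
#' chemist triages a structure: carboxylic and other oxyacids, phenols,
#' thiols, sulfonamide/imide N-H and azole N-H are acidic; aliphatic amines,
#' pyridine-type ring nitrogens, amidines/guanidines and imines are basic.
#' Deliberate exclusions: simple alcohols on sp3 carbons (pKa typically
#' above 14) and terminal (non-activated) amides are not ionization centers.
#' Activated C-H centers (e.g. 1,3-dicarbonyls) are matched only when
#' carbon sites are requested. Users may supply their own table with the
#' same columns (`name`, `role`, `group_class`, `requires_carbon`,
#' `pattern`); every pattern is parsed at load time so a malformed entry
#' fails immediately, not during matching.
#'
#' @param path Optional path to an alternative rule table (TSV).
#' @return A tibble of rules with parsed patterns attached.
#' @export
ionization_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ionizable_groups.tsv", package = "pkagraph")
  rules <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("name", "role", "group_class", "requires_carbon", "pattern")
  if (!all(required %in% names(rules)))
    stop("rule table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (!all(rules$role %in% c("acidic", "basic")))
    stop("rule roles must be 'acidic' or 'basic'", call. = FALSE)
  rules$parsed <- lapply(rules$pattern, function(p) {
    tryCatch(parse_pattern(p),
             error = function(e) stop("malformed pattern for rule '",
                                      rules$name[rules$pattern == p][1], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  rules
}

#' Detect ionizable sites in a molecule
#'
#' Runs every rule of the pattern table against the molecule and returns the
#' matched site atoms. A site atom matched by several rules is reported once
#' under the first matching rule in table order. Carbon acidic centers are
#' only reported when `include_carbon = TRUE`. Matches are additionally
#' screened for chemical actionability: an acidic site must currently carry
#' a proton or a negative charge, a basic site must be able to accept a
#' proton (neutral) or currently hold one (protonated, with at least one H).
#'
#' @param mol A `pka_mol` (or SMILES string).
#' @param rules A rule table from [ionization_rules()].
#' @param include_carbon Also report activated carbon acidic centers?
#' @return A tibble: `atom_index`, `role`, `group_class`, `rule`, `element`.
#' @export
#' @examples
#' find_ionizable_sites(parse_smiles("NCC(=O)O"))   # glycine: 2 sites
#' find_ionizable_sites(parse_smiles("CCO"))        # ethanol: none
find_ionizable_sites <- function(mol, rules = ionization_rules(),
                                 include_carbon = FALSE) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  ctx <- mol_match_context(mol)
  seen <- integer(0)
  out <- list()
  for (r in seq_len(nrow(rules))) {
    if (rules$requires_carbon[r] && !include_carbon) next
    pat <- rules$parsed[[r]]
    site_pos <- which(vapply(pat$atoms, function(a)
      identical(a$map, 1L), logical(1)))
    if (length(site_pos) == 0) site_pos <- 1L
    matches <- match_pattern_impl(ctx, pat)
    for (mt in matches) {
      atom <- mt[site_pos[1]]
      if (atom %in% seen) next
      role <- rules$role[r]
      a <- mol$atoms[atom, ]
      actionable <- if (role == "acidic") a$n_h >= 1 || a$charge < 0
                    else a$charge <= 0 || (a$charge > 0 && a$n_h >= 1)
      if (!actionable) next
      seen <- c(seen, atom)
      out[[length(out) + 1L]] <- tibble::tibble(
        atom_index = atom, role = role,
        group_class = rules$group_class[r], rule = rules$name[r],
        element = a$element)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(atom_index = integer(0), role = character(0),
                          group_class = character(0), rule = character(0),
                          element = character(0)))
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$atom_index)
}

#' Protonation-state transforms
#'
#' `remove_proton()` takes one hydrogen off the site atom and lowers its
#' formal charge by one; `add_proton()` is the exact inverse. The heavy-atom
#' skeleton is untouched, so the two forms of a conjugate pair remain
#' index-compatible. Preconditions are enforced: removal needs at least one
#' hydrogen on the atom, addition refuses an already positively charged
#' center.
#'
#' @param mol A `pka_mol`.
#' @param atom Site atom index.
#' @return The transformed `pka_mol`.
#' @export
#' @examples
#' acetate <- remove_proton(parse_smiles("CC(=O)O"), 4)
remove_proton <- function(mol, atom) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(atom >= 1, atom <= nrow(mol$atoms))
  if (mol$atoms$n_h[atom] < 1)
    stop("cannot remove a proton from atom ", atom,
         " (no hydrogens attached)", call. = FALSE)
  mol$atoms$n_h[atom] <- mol$atoms$n_h[atom] - 1L
  mol$atoms$charge[atom] <- mol$atoms$charge[atom] - 1L
  mol
}

#' @rdname remove_proton
#' @export
add_proton <- function(mol, atom) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(atom >= 1, atom <= nrow(mol$atoms))
  if (mol$atoms$charge[atom] > 0)
    stop("cannot protonate atom ", atom,
         " (already positively charged)", call. = FALSE)
  mol$atoms$n_h[atom] <- mol$atoms$n_h[atom] + 1L
  mol$atoms$charge[atom] <- mol$atoms$charge[atom] + 1L
  mol
}

#' Fully deprotonate every detected site
#'
#' Produces the starting microstate of the iterative protonation protocol:
#' each acidic site loses its proton (becoming anionic) and each currently
#' protonated basic site is returned to its neutral form, so no detected
#' site carries a dissociable proton.
#'
#' @param mol A `pka_mol`.
#' @param sites Site table from [find_ionizable_sites()] (detected afresh if
#'   missing).
#' @return The fully deprotonated `pka_mol`.
#' @export
fully_deprotonate <- function(mol, sites = NULL) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.null(sites)) sites <- find_ionizable_sites(mol)
  for (k in seq_len(nrow(sites))) {
    atom <- sites$atom_index[k]
    if (sites$role[k] == "acidic") {
      if (mol$atoms$n_h[atom] >= 1 && mol$atoms$charge[atom] >= 0)
        mol <- remove_proton(mol, atom)
    } else {
      if (mol$atoms$charge[atom] > 0 && mol$atoms$n_h[atom] >= 1)
        mol <- remove_proton(mol, atom)
    }
  }
  mol
}
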