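#' Build the conjugate acid/base pair for one site
#'
#' Given a molecule in some protonation state and an ionizable site, returns
#' the `pka_graph` for the pair (base form, base form + one proton at the
#' site). For an acidic site currently carrying its proton, the input is the
#' acid form and the base is obtained by deprotonation; for an unprotonated
#' site the input is the base form and the acid is obtained by protonation.
#'
#' @param mol A `pka_mol` or SMILES string.
#' @param atom Site atom index.
#' @param role `"acidic"` or `"basic"` (how the site was matched; determines
#'   which form the current state represents when ambiguous).
#' @param mode,toggles Passed to [build_paired_graph()].
#' @return A `pka_graph`.
#' @export
paired_graph_for_site <- function(mol, atom, role = "acidic",
                                  mode = "full", toggles = NULL) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  a <- mol$atoms[atom, ]
  input_is_acid <- if (role == "acidic") a$n_h >= 1 && a$charge >= 0
                   else a$charge > 0 && a$n_h >= 1
  if (input_is_acid) {
    acid <- mol; base <- remove_proton(mol, atom)
  } else {
    base <- mol; acid <- add_proton(mol, atom)
  }
  build_paired_graph(acid, base, center = atom, mode = mode, toggles = toggles)
}

#' Map a molecule's full ionization profile
#'
#' Implements the iterative multi-center protocol: all potential ionizable
#' sites are identified and the fully deprotonated microstate is generated;
#' then, repeatedly, every remaining unprotonated site is scored in the
#' current microstate, the most basic one (highest predicted pKa) is
#' protonated and its value recorded, until all sites are protonated. Sites
#' are rescored at every iteration because protonating one center shifts the
#' microscopic pKa of the others. Ties are broken toward the lowest atom
#' index for determinism.
#'
#' @param mol A `pka_mol` or SMILES string.
#' @param scorer A function `(mol, site)` returning the predicted pKa of the
#'   unprotonated `site` (one row of the site table) in microstate `mol` —
#'   typically [model_scorer()] wrapping a trained model, or a rule-based
#'   scorer in tests.
#' @param pH Reference pH for the reported dominant state (default 7.4,
#'   physiological).
#' @param rules,include_carbon Passed to [find_ionizable_sites()].
#' @return A `pka_profile`: ordered steps (site, pKa, net charge after
#'   protonation), the reference pH, and the fully deprotonated state.
#' @export
#' @examples
#' scorer <- rule_scorer(c(amine = 9.8, carboxylic_acid = 2.3))
#' pr <- infer_ionization_profile("NCC(=O)O", scorer, pH = 7)
#' tidy(pr)
infer_ionization_profile <- function(mol, scorer, pH = 7.4,
                                     rules = ionization_rules(),
                                     include_carbon = FALSE) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  sites <- find_ionizable_sites(mol, rules, include_carbon)
  state <- fully_deprotonate(mol, sites)
  base_state <- state
  remaining <- seq_len(nrow(sites))
  steps <- list()
  while (length(remaining) > 0) {
    pkas <- vapply(remaining, function(k) {
      val <- tryCatch(scorer(state, sites[k, ]), error = function(e)
        stop("scorer failed on microstate ", state$smiles, " (net charge ",
             net_charge(state), ") at atom ", sites$atom_index[k], ": ",
             conditionMessage(e), call. = FALSE))
      if (!is.finite(val)) stop("scorer returned a non-finite pKa at atom ",
                                sites$atom_index[k], call. = FALSE)
      val
    }, numeric(1))
    pick <- remaining[order(-pkas, sites$atom_index[remaining])][1]
    pka_pick <- pkas[match(pick, remaining)]
    state <- add_proton(state, sites$atom_index[pick])
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L,
      atom_index = sites$atom_index[pick],
      role = sites$role[pick],
      group_class = sites$group_class[pick],
      pka = pka_pick,
      net_charge_after = net_charge(state))
    remaining <- setdiff(remaining, pick)
  }
  steps <- if (length(steps) > 0) dplyr::bind_rows(steps) else
    tibble::tibble(step = integer(0), atom_index = integer(0),
                   role = character(0), group_class = character(0),
                   pka = numeric(0), net_charge_after = numeric(0))
  structure(list(steps = steps, ph_reference = pH, base_state = base_state,
                 smiles = mol$smiles, sites = sites),
            class = "pka_profile")
}

#' Dominant protonation state at a pH
#'
#' Sites whose recorded microscopic pKa exceeds the pH hold their proton;
#' the rest are deprotonated. For glycine at pH 7 this returns the
#' zwitterion (ammonium up at 9.8, carboxylate down at 2.3).
#'
#' @param profile A `pka_profile`.
#' @param pH Numeric pH (defaults to the profile's reference pH).
#' @return A list: `mol` (the protonation state as a `pka_mol`), `sites`
#'   (step table with a `protonated` flag), `net_charge`.
#' @export
state_at_pH <- function(profile, pH = profile$ph_reference) {
  stopifnot(inherits(profile, "pka_profile"))
  st <- profile$steps
  st$protonated <- st$pka > pH
  mol <- profile$base_state
  for (k in seq_len(nrow(st)))
    if (st$protonated[k]) mol <- add_proton(mol, st$atom_index[k])
  list(mol = mol, sites = st, net_charge = net_charge(mol), pH = pH)
}

#' Rule-based pKa scorer (for tests and quick triage)
#'
#' Returns a scorer assigning a fixed pKa per functional-group class —
#' useful for exercising the iterative protocol without a trained model.
#'
#' @param values Named numeric vector, names are group classes.
#' @param default Value for classes not listed.
#' @return A scorer function `(mol, site) -> pKa`.
#' @export
rule_scorer <- function(values, default = 7) {
  force(values); force(default)
  function(mol, site) {
    v <- values[[site$group_class]]
    if (is.null(v) || is.na(v)) default else v
  }
}

#' @export
print.pka_profile <- function(x, ...) {
  cat("<pka_profile> ", x$smiles, " — ", nrow(x$steps), " ionizable site(s)\n",
      sep = "")
  if (nrow(x$steps) > 0) print(x$steps)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pka_profile <- function(x, ...) x$steps

#' @importFrom generics glance
#' @export
glance.pka_profile <- function(x, ...) {
  st <- state_at_pH(x)
  tibble::tibble(smiles = x$smiles, n_sites = nrow(x$steps),
                 ph_reference = x$ph_reference,
                 net_charge_at_ph = st$net_charge)
}

#' Plot an ionization profile
#'
#' A titration ladder: one horizontal level per recorded microscopic pKa,
#' labelled by site, with the reference pH drawn as a dashed line.
#'
#' @param object A `pka_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pka_profile <- function(object, ...) {
  st <- object$steps
  st$site <- paste0(st$group_class, " (atom ", st$atom_index, ")")
  ggplot2::ggplot(st, ggplot2::aes(x = .data$step, y = .data$pka)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$step, yend = -Inf),
                          linetype = "dotted", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$ph_reference, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$site), vjust = -1, size = 3) +
    ggplot2::scale_x_continuous(breaks = st$step) +
    ggplot2::labs(x = "protonation step (most basic first)",
                  y = "microscopic pKa",
                  title = object$smiles) +
    ggplot2::theme_minimal()
}
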