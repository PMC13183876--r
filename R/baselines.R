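#' Fingerprint / descriptor specifications for baseline models
#'
#' The baseline comparison surface: classical molecule-level featurizations
#' feeding tree regressors that predict a single macro-pKa per molecule.
#' Supported kinds: `"2D-descriptors"` (a documented set of 16 whole-molecule
#' counts and fractions), `"MACCS"` (the standard 166-key vector, computed
#' by OpenBabel through ChemmineOB), `"Estate"` (presence of electrotopological
#' atom types), `"EstateSum"` (summed Kier–Hall E-state values per atom type),
#' `"2D+MACCS"` (concatenation) and `"Morgan"` (circular fingerprint,
#' `n_bits` and `radius` configurable; "Morgan 1024-2" is radius 2, 1024
#' bits).
#'
#' @param kind One of the kinds above.
#' @param n_bits,radius Morgan parameters (ignored otherwise).
#' @return A `fingerprint_spec`.
#' @export
fingerprint_spec <- function(kind = c("Morgan", "2D-descriptors", "MACCS",
                                      "Estate", "EstateSum", "2D+MACCS"),
                             n_bits = 1024L, radius = 2L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint_spec")
}

#' Featurize a molecule for the baselines
#'
#' @param mol A `pka_mol` or SMILES string.
#' @param spec A [fingerprint_spec()].
#' @return A named numeric vector of documented length.
#' @export
#' @examples
#' length(featurize_fingerprint("CC(=O)O", fingerprint_spec("Morgan")))
featurize_fingerprint <- function(mol, spec = fingerprint_spec()) {
  if (is.character(mol)) {
    smi <- mol
    mol <- parse_smiles(mol)
  } else smi <- mol$smiles
  switch(spec$kind,
         "Morgan" = {
           v <- morgan_fingerprint(mol, spec$n_bits, spec$radius)
           names(v) <- paste0("morgan_", seq_along(v)); v
         },
         "2D-descriptors" = descriptors_2d(mol),
         "MACCS" = maccs_fingerprint(smi),
         "Estate" = estate_fingerprint(mol, sum_values = FALSE),
         "EstateSum" = estate_fingerprint(mol, sum_values = TRUE),
         "2D+MACCS" = c(descriptors_2d(mol), maccs_fingerprint(smi)),
         stop("unsupported fingerprint kind: ", spec$kind, call. = FALSE))
}

# 16 whole-molecule 2D descriptors. Rotatable bonds: acyclic single bonds
# between two non-terminal heavy atoms.
descriptors_2d <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  deg <- heavy_degree(mol)
  ring <- smallest_ring_sizes(mol)
  in_ring_bond <- if (nrow(b) > 0) vapply(seq_len(nrow(b)), function(k) {
    g <- mol_graph(mol)
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$i[k], b$j[k])))
    is.finite(igraph::distances(g2, v = b$i[k], to = b$j[k])[1, 1])
  }, logical(1)) else logical(0)
  rotatable <- sum(b$order == "single" & !in_ring_bond &
                     deg[b$i] > 1 & deg[b$j] > 1)
  c(n_heavy = nrow(a),
    mol_weight = sum(element_property(a$element, "mass")) + 1.008 * sum(a$n_h),
    n_nitrogen = sum(a$element == "N"),
    n_oxygen = sum(a$element == "O"),
    n_sulfur = sum(a$element == "S"),
    n_halogen = sum(a$element %in% c("F", "Cl", "Br", "I")),
    n_aromatic = sum(a$aromatic),
    n_rings = nrow(b) - nrow(a) + igraph::components(mol_graph(mol))$no,
    n_rotatable = rotatable,
    hbd = sum(a$element %in% c("N", "O") & a$n_h > 0),
    hba = sum(a$element %in% c("N", "O")),
    net_charge = sum(a$charge),
    frac_sp3_carbon = if (sum(a$element == "C") == 0) 0 else
      sum(a$element == "C" & hybridizations(mol) == "sp3") /
      sum(a$element == "C"),
    n_double = sum(b$order == "double"),
    n_triple = sum(b$order == "triple"),
    max_ring_size = if (length(ring) > 0) max(ring) else 0)
}

# Kier-Hall electrotopological state values aggregated over a fixed atom-type
# vocabulary (element x aromatic x has-hydrogen over the registry elements):
# I = ((2/N)^2 * deltav + 1) / delta, perturbed by (I_i - I_j)/(d_ij + 1)^2.
estate_fingerprint <- function(mol, sum_values = FALSE) {
  reg <- element_registry()
  types <- as.vector(outer(reg$symbol, c("", ".ar"), paste0))
  types <- as.vector(outer(types, c(".H0", ".H"), paste0))
  a <- mol$atoms
  n <- nrow(a)
  delta <- pmax(heavy_degree(mol), 1)
  deltav <- element_property(a$element, "n_valence_electrons") - a$n_h
  N <- element_property(a$element, "principal_quantum_number")
  I <- ((2 / N)^2 * deltav + 1) / delta
  S <- I
  if (n > 1) {
    d <- igraph::distances(mol_graph(mol))
    for (i in seq_len(n)) {
      pert <- (I[i] - I[-i]) / (d[i, -i] + 1)^2
      S[i] <- S[i] + sum(pert[is.finite(pert)])
    }
  }
  key <- paste0(a$element, ifelse(a$aromatic, ".ar", ""),
                ifelse(a$n_h > 0, ".H", ".H0"))
  out <- stats::setNames(numeric(length(types)), paste0("estate_", types))
  for (k in seq_len(n)) {
    slot <- paste0("estate_", key[k])
    out[slot] <- if (sum_values) out[slot] + S[k] else 1
  }
  out
}

# Standard 166-key MACCS vector via OpenBabel (ChemmineOB); key 0 of the
# 256-bit padded output is dropped along with the padding.
maccs_fingerprint <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("MACCS fingerprints need the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  v <- as.numeric(ChemmineR::as.matrix(fp)[1, seq_len(166)])
  names(v) <- paste0("maccs_", seq_len(166))
  v
}

#' Train a baseline macro-pKa regressor
#'
#' Fits a random forest or gradient-boosted tree model on molecule-level
#' fingerprints. Baselines see no ionization center: they predict one global
#' macro-pKa per molecule, which is exactly the comparison the graph model
#' is meant to beat. 500 trees (or 300 boosting rounds, depth 6, eta 0.1),
#' seeded and single-threaded for reproducibility.
#'
#' @param records Record tibble with `smiles` and `pka`.
#' @param algo `"random-forest"` or `"gradient-boosted-trees"`.
#' @param spec A [fingerprint_spec()].
#' @param seed Integer seed.
#' @return A `pka_baseline` model usable with [evaluate_model()].
#' @export
train_baseline <- function(records,
                           algo = c("random-forest", "gradient-boosted-trees"),
                           spec = fingerprint_spec(), seed = 1L) {
  algo <- match.arg(algo)
  X <- do.call(rbind, lapply(records$smiles, featurize_fingerprint, spec = spec))
  y <- records$pka
  fit <- withr::with_seed(seed, {
    if (algo == "random-forest") {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("random-forest baseline needs the randomForest package",
             call. = FALSE)
      randomForest::randomForest(x = X, y = y, ntree = 500)
    } else {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("gradient-boosted-trees baseline needs the xgboost package",
             call. = FALSE)
      xgboost::xgboost(x = X, y = y, nrounds = 300, max_depth = 6,
                       learning_rate = 0.1, nthreads = 1, verbosity = 0,
                       seed = seed)
    }
  })
  structure(list(fit = fit, algo = algo, spec = spec, seed = seed,
                 feature_names = colnames(X)),
            class = "pka_baseline")
}

#' @export
predict.pka_baseline <- function(object, newdata, ...) {
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  X <- do.call(rbind, lapply(smiles, featurize_fingerprint,
                             spec = object$spec))
  as.numeric(stats::predict(object$fit, X))
}

#' @export
print.pka_baseline <- function(x, ...) {
  cat("<pka_baseline> ", x$algo, " on ", x$spec$kind,
      " (macro-pKa, no ionization center)\n", sep = "")
  invisible(x)
}

#' Run the baseline comparison grid
#'
#' Trains every algorithm x featurization combination on the training split
#' and evaluates on the test split, mirroring the classical-baseline
#' comparison table.
#'
#' @param records Record tibble with a `split` column.
#' @param algos,kinds Grid axes.
#' @param seed Integer seed.
#' @return A tidy tibble: `algo`, `features`, `mae`, `rmse`.
#' @export
baseline_grid <- function(records,
                          algos = c("random-forest", "gradient-boosted-trees"),
                          kinds = c("2D-descriptors", "Estate", "EstateSum",
                                    "Morgan"),
                          seed = 1L) {
  train <- records[records$split == "train", ]
  test <- records[records$split == "test", ]
  rows <- list()
  for (algo in algos) for (kind in kinds) {
    model <- train_baseline(train, algo, fingerprint_spec(kind), seed)
    ev <- evaluate_model(model, test)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      algo = algo, features = kind, mae = ev$mae, rmse = ev$rmse)
  }
  dplyr::bind_rows(rows)
}
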