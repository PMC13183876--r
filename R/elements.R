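#' Per-element property registry
#'
#' Tabulated scalar properties of the elements supported by the featurizer:
#' Pauling electronegativity, Pearson absolute hardness (eV), the single-bond
#' covalent radius (Angstrom; the atomic diameter feature is twice this
#' value), atomic mass, valence-electron count and principal quantum number.
#' The registry is shipped as a versioned CSV so that featurization is fully
#' dataset-independent: normalization bounds are fixed over this table, never
#' recomputed from a training set. Model checkpoints embed the registry
#' version and refuse to score under a mismatched one.
#'
#' @return A tibble with one row per supported element.
#' @export
#' @examples
#' element_registry()
element_registry <- function() {
  reg <- the$registry
  if (is.null(reg)) {
    path <- system.file("extdata", "element_properties.csv", package = "pkagraph")
    reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    reg$diameter_a <- 2 * reg$covalent_radius_a
    the$registry <- reg
  }
  reg
}

# package-local mutable state (registry cache)
the <- new.env(parent = emptyenv())

#' @rdname element_registry
#' @export
registry_version <- function() "1.0"

# Look up one registry column for a vector of element symbols.
# Unknown elements raise an explicit error rather than returning zeros.
element_property <- function(symbols, property) {
  reg <- element_registry()
  idx <- match(symbols, reg$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unsupported element(s) not in the property registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reg[[property]][idx]
}

# Fixed (min, max) normalization bounds per interval-valued feature,
# taken over the shipped registry (not per-dataset).
feature_bounds <- function() {
  reg <- element_registry()
  list(
    electronegativity = range(reg$electronegativity),
    hardness          = range(reg$hardness_ev),
    atomic_diameter   = range(reg$diameter_a),
    ring_size         = c(0, 8),
    n_hydrogens       = c(0, 4)
  )
}

#' Normalize a raw feature value to [0, 1]
#'
#' Interval-valued atom features (electronegativity, hardness, atomic
#' diameter, ring size, hydrogen count) are mapped to `[0, 1]` by min-max
#' scaling against fixed per-feature bounds registered over the shipped
#' element table. Values outside the bounds are clipped.
#'
#' @param value Numeric vector of raw values.
#' @param feature_name One of `"electronegativity"`, `"hardness"`,
#'   `"atomic_diameter"`, `"ring_size"`, `"n_hydrogens"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' normalize_feature(2.55, "electronegativity") # carbon
normalize_feature <- function(value, feature_name) {
  bounds <- feature_bounds()
  if (!feature_name %in% names(bounds)) {
    stop("unknown feature name: ", feature_name,
         " (registered: ", paste(names(bounds), collapse = ", "), ")",
         call. = FALSE)
  }
  b <- bounds[[feature_name]]
  pmin(1, pmax(0, (value - b[1]) / (b[2] - b[1])))
}
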