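#' Read and write pKa record tables
#'
#' Records are CSV with required columns `smiles` and `pka`, an optional
#' `center` (1-based atom index of the labeled ionization center) and an
#' optional `split` label. On read, every SMILES is parsed; unparseable
#' entries are collected into a rejects report attached as the `"rejects"`
#' attribute (and reported with a warning) rather than silently dropped.
#' Duplicate SMILES with conflicting labels are kept once (first occurrence)
#' and logged in the `"label_conflicts"` attribute.
#'
#' @param path CSV file path.
#' @return A tibble of records with attributes `rejects` and
#'   `label_conflicts`.
#' @export
read_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("smiles", "pka") %in% names(df)))
    stop("record file must have columns 'smiles' and 'pka': ", path,
         call. = FALSE)
  if (!"center" %in% names(df)) df$center <- NA_integer_
  if (!"split" %in% names(df)) df$split <- "none"
  ok <- logical(nrow(df)); reason <- character(nrow(df))
  for (k in seq_len(nrow(df))) {
    res <- tryCatch({
      suppressWarnings(parse_smiles(df$smiles[k])); TRUE
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) ok[k] <- TRUE else reason[k] <- res
  }
  rejects <- tibble::tibble(row = which(!ok), smiles = df$smiles[!ok],
                            reason = reason[!ok])
  if (nrow(rejects) > 0)
    warning(nrow(rejects), " record(s) rejected (unparseable SMILES); see ",
            "attr(, 'rejects')", call. = FALSE)
  out <- tibble::as_tibble(df[ok, , drop = FALSE])
  dup <- duplicated(out$smiles)
  conflicts <- tibble::tibble(smiles = character(0), kept = numeric(0),
                              dropped = numeric(0))
  if (any(dup)) {
    for (s in unique(out$smiles[dup])) {
      vals <- out$pka[out$smiles == s]
      if (length(unique(vals)) > 1)
        conflicts <- dplyr::bind_rows(conflicts, tibble::tibble(
          smiles = s, kept = vals[1], dropped = vals[-1]))
    }
    if (nrow(conflicts) > 0)
      warning(nrow(conflicts), " duplicate SMILES with conflicting pKa; ",
              "first occurrence kept (attr 'label_conflicts')", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  attr(out, "rejects") <- rejects
  attr(out, "label_conflicts") <- conflicts
  out
}

#' @rdname read_records
#' @param records A record tibble.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records[, intersect(c("smiles", "pka", "center", "split"),
                                       names(records))], path)
  invisible(path)
}

#' Random train/test split
#'
#' Seeded uniform assignment of records to train and test. Exposed alongside
#' [cluster_split()] so the memorization-versus-learning comparison (random
#' splits look better because test molecules resemble training ones) is
#' reproducible.
#'
#' @param records Record tibble.
#' @param test_fraction Fraction assigned to test.
#' @param seed Integer seed.
#' @return Records with a `split` column (`"train"`/`"test"`).
#' @export
random_split <- function(records, test_fraction, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction <= 1)
  n <- nrow(records)
  n_test <- round(n * test_fraction)
  withr::with_seed(seed, {
    idx <- sample(n, n_test)
  })
  records$split <- "train"
  records$split[idx] <- "test"
  records
}

#' Similarity-capped cluster split
#'
#' Splits records so that no test molecule resembles any training molecule
#' above the Tanimoto cap. Molecules are fingerprinted with 2048-bit
#' circular fingerprints (radius 2), clustered by single-linkage at the cap
#' (connected components of the "similarity > cap" graph — the transitive
#' closure of sphere exclusion, which is the weakest clustering that can
#' guarantee the cap exactly), and whole clusters are assigned greedily
#' (largest first) to reach the requested test fraction. The achieved
#' fraction must land within 5 percentage points of the request; otherwise
#' the split is infeasible and the blocking (largest) cluster is named.
#'
#' @param records Record tibble.
#' @param similarity_cap Maximum allowed train/test Tanimoto (default 0.65).
#' @param test_fraction Requested test fraction.
#' @param seed Integer seed (order among equally sized clusters).
#' @return Records with a `split` column; attribute `"split_report"` holds
#'   cluster sizes, the exhaustively verified maximum cross-set similarity
#'   and the achieved fraction.
#' @export
cluster_split <- function(records, similarity_cap = 0.65,
                          test_fraction = 0.2, seed = 1L) {
  if (!(similarity_cap > 0 && similarity_cap < 1))
    stop("similarity_cap must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(records)
  fps <- do.call(rbind, lapply(records$smiles, morgan_fingerprint))
  sim <- tanimoto_matrix(fps)
  adj <- sim > similarity_cap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  target <- round(n * test_fraction)
  ord <- withr::with_seed(seed, order(-sizes, stats::runif(length(sizes))))
  test_clusters <- integer(0)
  n_test <- 0L
  for (cl in ord) {
    if (abs((n_test + sizes[cl]) - target) <= abs(n_test - target)) {
      test_clusters <- c(test_clusters, cl)
      n_test <- n_test + sizes[cl]
    }
  }
  achieved <- n_test / n
  if (abs(achieved - test_fraction) > 0.05) {
    biggest <- which.max(sizes)
    stop("cluster split infeasible: achieved test fraction ",
         sprintf("%.3f", achieved), " vs requested ", test_fraction,
         "; blocking cluster has ", sizes[biggest], " of ", n,
         " molecules", call. = FALSE)
  }
  records$split <- ifelse(comp$membership %in% test_clusters, "test", "train")
  is_test <- records$split == "test"
  max_cross <- if (any(is_test) && any(!is_test))
    max(sim[is_test, !is_test, drop = FALSE]) else 0
  attr(records, "split_report") <- list(
    n_clusters = comp$no,
    cluster_sizes = sort(sizes, decreasing = TRUE),
    similarity_cap = similarity_cap,
    max_cross_similarity = max_cross,
    achieved_test_fraction = achieved)
  records
}

#' Graph-randomization data augmentation
#'
#' Each input graph yields `n_copies` randomized isomorphic copies (atom
#' indices permuted, ionization center kept first) in addition to the
#' original, with the label carried over — the default 50 copies virtually
#' expands the training set and makes the model indifferent to the matrix
#' representation of a molecule.
#'
#' @param graphs List of `pka_graph` objects.
#' @param n_copies Randomized copies per graph (default 50).
#' @param seed Integer seed.
#' @return A list of graphs: for each input, the original followed by its
#'   copies; attribute `"source"` maps each output to its input index.
#' @export
augment <- function(graphs, n_copies = 50L, seed = 1L) {
  stopifnot(n_copies >= 0)
  out <- vector("list", length(graphs) * (n_copies + 1L))
  src <- integer(length(out))
  withr::with_seed(seed, {
    pos <- 1L
    for (gidx in seq_along(graphs)) {
      out[[pos]] <- graphs[[gidx]]; src[pos] <- gidx; pos <- pos + 1L
      for (cp in seq_len(n_copies)) {
        out[[pos]] <- randomize_graph(graphs[[gidx]])
        src[pos] <- gidx; pos <- pos + 1L
      }
    }
  })
  attr(out, "source") <- src
  out
}
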