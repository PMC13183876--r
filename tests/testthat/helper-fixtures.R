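# Shared fixtures, built once per test run.

fixtures <- new.env(parent = emptyenv())

# A small trained model on a 40-molecule synthetic set (few epochs; used by
# tests that need *a* trained model, not an accurate one).
tiny_model <- function() {
  if (is.null(fixtures$tiny_model)) {
    lib <- generate_synthetic_library(synthetic_spec(n_molecules = 40,
                                                     seed = 11))
    gs <- graphs_from_records(lib)
    cfg <- model_config(n_gat_layers = 2, mask_size = 3, n_heads = 2,
                        hidden_dim = 16, dropout = 0, learning_rate = 3e-3,
                        batch_size = 16, n_epochs = 10, seed = 42)
    fixtures$tiny_model <- train_gnn(gs, cfg)
    fixtures$tiny_graphs <- gs
  }
  fixtures$tiny_model
}

tiny_graphs <- function() {
  tiny_model()
  fixtures$tiny_graphs
}

# Conjugate pair builder for convenience.
acid_base_pair <- function(acid_smiles, center) {
  acid <- parse_smiles(acid_smiles)
  list(acid = acid, base = remove_proton(acid, center), center = center)
}

# Brute-force graph isomorphism oracle on edge lists (via igraph VF2).
graphs_isomorphic <- function(g1, g2) {
  mk <- function(g) igraph::graph_from_edgelist(
    cbind(g$edges[, "i"], g$edges[, "j"]), directed = FALSE)
  igraph::isomorphic(mk(g1), mk(g2), method = "vf2")
}

# Full-scale parameter-recovery study (built once, shared across files):
# 2000 synthetic molecules under the default attenuation model (rho 0.4,
# label noise 0.1), similarity-capped cluster split, and three seeded
# replicate models at the L = 3, m = 4 configuration.
study_fixture <- function() {
  if (is.null(fixtures$study)) {
    lib <- generate_synthetic_library(
      synthetic_spec(n_molecules = 2000, rho = 0.4, noise_sd = 0.1,
                     seed = 202))
    lib <- cluster_split(lib, similarity_cap = 0.65, test_fraction = 0.2,
                         seed = 202)
    train <- graphs_from_records(lib[lib$split == "train", ])
    test <- graphs_from_records(lib[lib$split == "test", ])
    models <- list(); maes <- numeric(0)
    for (seed in 1:3) {
      cfg <- model_config(n_gat_layers = 3, mask_size = 4, n_heads = 4,
                          hidden_dim = 64, dropout = 0, learning_rate = 3e-3,
                          batch_size = 64, n_epochs = 60, seed = seed)
      fit <- train_gnn(train, cfg)
      models[[seed]] <- fit
      maes[seed] <- evaluate_model(fit, test)$mae
    }
    median_seed <- order(maes)[2]
    fixtures$study <- list(records = lib, test_graphs = test,
                           models = models, maes = maes,
                           median_mae = stats::median(maes),
                           median_model = models[[median_seed]])
  }
  fixtures$study
}

# All permutations of 1..k (tiny k only).
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1))
    for (pos in 0:(k - 1))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}
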