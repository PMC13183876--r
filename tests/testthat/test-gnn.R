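test_that("config invariants are enforced", {
  cfg <- model_config(n_gat_layers = 1, mask_size = 6)
  expect_equal(cfg$n_gat_layers + cfg$mask_size, 7)
  expect_error(model_config(n_gat_layers = 0), "n_gat_layers")
  expect_error(model_config(hidden_dim = 10, n_heads = 4), "hidden_dim")
  expect_error(model_config(mask_size = -1), "mask_size")
})

test_that("analytic gradients match numerical differentiation", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 6, seed = 4))
  gs <- graphs_from_records(lib)
  cfg <- model_config(n_gat_layers = 2, mask_size = 3, n_heads = 2,
                      hidden_dim = 8, dropout = 0, seed = 7)
  set.seed(7)
  params <- pkagraph:::init_params(cfg, ncol(gs[[1]]$x), ncol(gs[[1]]$e_attr))
  batch <- pkagraph:::build_batch(gs, cfg$mask_size)
  fwd <- pkagraph:::gnn_forward(params, batch, cfg)
  dyhat <- sign(fwd$yhat - batch$labels) / length(batch$labels)
  grads <- pkagraph:::gnn_backward(params, batch, cfg, fwd, dyhat)
  loss <- function(p) {
    f <- pkagraph:::gnn_forward(p, batch, cfg)
    mean(abs(f$yhat - batch$labels))
  }
  eps <- 1e-6
  probe <- function(getter, setter, g) {
    set.seed(1)
    for (ii in sample(length(getter(params)), 4)) {
      pp <- params; x <- getter(pp); x[ii] <- x[ii] + eps; pp <- setter(pp, x)
      pm <- params; x <- getter(pm); x[ii] <- x[ii] - eps; pm <- setter(pm, x)
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_lt(abs(num - g[ii]) / max(1e-6, abs(num) + abs(g[ii])), 1e-3)
    }
  }
  probe(function(p) p$layers[[1]]$Wsrc,
        function(p, x) { p$layers[[1]]$Wsrc <- x; p }, grads$layers[[1]]$Wsrc)
  probe(function(p) p$layers[[2]]$Wedge,
        function(p, x) { p$layers[[2]]$Wedge <- x; p }, grads$layers[[2]]$Wedge)
  probe(function(p) p$layers[[2]]$a,
        function(p, x) { p$layers[[2]]$a <- x; p }, grads$layers[[2]]$a)
  probe(function(p) p$W1, function(p, x) { p$W1 <- x; p }, grads$W1)
})

test_that("forward is total, finite and permutation-invariant", {
  model <- tiny_model()
  g <- tiny_graphs()[[1]]
  y0 <- predict(model, g)
  expect_true(is.finite(y0))
  for (rep in 1:20) {
    set.seed(rep)
    yr <- predict(model, randomize_graph(g))
    expect_lt(abs(yr - y0), 1e-5)
  }
})

test_that("predictions are invariant to edits beyond the receptive radius", {
  # L = 1, m = 6: receptive radius 7 bonds from the center
  chain <- function(tail) paste0("OC(=O)", tail)
  base <- chain("CCCCCCCC")           # chain carbons at distances 2..9 from O
  edit7 <- chain("CCCCCNCC")          # N at bond distance 7
  edit8 <- chain("CCCCCCNC")          # N at bond distance 8
  mk <- function(smi) {
    mol <- parse_smiles(smi)
    paired_graph_for_site(mol, 1, "acidic")
  }
  g0 <- mk(base); g7 <- mk(edit7); g8 <- mk(edit8)
  expect_equal(g0$bond_dist[9], 7)    # the edited positions sit where claimed
  expect_equal(g0$bond_dist[10], 8)
  cfg <- model_config(n_gat_layers = 1, mask_size = 6, n_heads = 2,
                      hidden_dim = 16, dropout = 0, n_epochs = 1,
                      batch_size = 2, seed = 3)
  g0$label <- 4.8
  model <- train_gnn(list(g0), cfg)
  p0 <- predict(model, g0); p7 <- predict(model, g7); p8 <- predict(model, g8)
  expect_false(identical(p0, p7))     # 7 bonds away: inside the radius
  expect_identical(p0, p8)            # 8 bonds away: bitwise unchanged
  # and generally: invariance holds exactly beyond L + m for other configs
  cfg2 <- model_config(n_gat_layers = 2, mask_size = 5, n_heads = 2,
                       hidden_dim = 16, dropout = 0, n_epochs = 1,
                       batch_size = 2, seed = 3)
  model2 <- train_gnn(list(g0), cfg2)
  expect_identical(predict(model2, g0), predict(model2, g8))
  expect_false(identical(predict(model2, g0), predict(model2, g7)))
})

test_that("training is seeded-deterministic and detects bad inputs", {
  gs <- tiny_graphs()[1:10]
  cfg <- model_config(n_gat_layers = 1, mask_size = 2, n_heads = 2,
                      hidden_dim = 8, n_epochs = 3, batch_size = 4, seed = 5)
  a <- train_gnn(gs, cfg); b <- train_gnn(gs, cfg)
  expect_identical(a$training_log, b$training_log)
  expect_identical(a$params, b$params)
  expect_error(train_gnn(list(), cfg), "empty")
  bad <- gs; bad[[1]]$label <- NA_real_
  expect_error(train_gnn(bad, cfg), "label")
})

test_that("a constant-label dataset collapses to a constant predictor", {
  gs <- tiny_graphs()[1:12]
  for (k in seq_along(gs)) gs[[k]]$label <- 5
  cfg <- model_config(n_gat_layers = 1, mask_size = 2, n_heads = 2,
                      hidden_dim = 8, n_epochs = 20, batch_size = 6,
                      learning_rate = 3e-3, dropout = 0, seed = 5)
  fit <- train_gnn(gs, cfg)
  ev <- evaluate_model(fit, gs)
  expect_lt(ev$mae, 0.05)
})

test_that("evaluation reports MAE and RMSE closed forms", {
  registerS3method("predict", "stub_scorer",
                   function(object, graphs, ...) object$values,
                   envir = asNamespace("stats"))
  stub <- function(v) structure(list(values = v), class = "stub_scorer")
  gs <- tiny_graphs()[1:2]
  gs[[1]]$label <- 1; gs[[2]]$label <- 1
  # predictions equal to labels
  ev0 <- evaluate_model(stub(c(1, 1)), gs)
  expect_equal(ev0$mae, 0); expect_equal(ev0$rmse, 0)
  # residuals (+1, -1): MAE 1, RMSE 1
  ev1 <- evaluate_model(stub(c(2, 0)), gs)
  expect_equal(ev1$mae, 1); expect_equal(ev1$rmse, 1)
  # residuals (0, 2): MAE 1, RMSE sqrt(2)
  ev2 <- evaluate_model(stub(c(1, 3)), gs)
  expect_equal(ev2$mae, 1); expect_equal(ev2$rmse, sqrt(2))
})

test_that("grid search is exhaustive with a documented tie-break", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 30,
                                                   seed = 21))
  gs <- graphs_from_records(lib)
  tr <- gs[1:20]; va <- gs[21:30]
  base <- model_config(n_gat_layers = 1, mask_size = 2, n_heads = 2,
                       hidden_dim = 8, n_epochs = 2, batch_size = 8, seed = 1)
  # singleton grid returns that config
  single <- grid_search(data.frame(learning_rate = 2e-3), tr, va, base)
  expect_equal(single$learning_rate, 2e-3)
  expect_error(grid_search(data.frame(), tr, va, base), "empty grid")
  # a planted dominating configuration (30 epochs vs 1) wins
  grid <- data.frame(n_epochs = c(1L, 30L))
  best <- grid_search(grid, tr, va, base)
  expect_equal(best$n_epochs, 30L)
  res <- attr(best, "grid_results")
  expect_equal(nrow(res), 2)
  expect_lt(res$val_mae[2], res$val_mae[1])
  # exact ties return the first config in grid order
  tie <- grid_search(data.frame(n_epochs = c(2L, 2L)), tr, va, base)
  expect_equal(attr(tie, "grid_results")$val_mae[1],
               attr(tie, "grid_results")$val_mae[2])
})

test_that("checkpoints round-trip and guard against registry drift", {
  model <- tiny_model()
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  g <- tiny_graphs()[[3]]
  expect_equal(predict(back, g), predict(model, g))
  expect_equal(back$config$n_gat_layers, model$config$n_gat_layers)
  # corrupt the embedded registry version: loading must refuse
  txt <- readLines(path)
  writeLines(gsub('"registry_version":"1.0"',
                  '"registry_version":"0.9"', txt), path)
  expect_error(load_model(path), "registry")
})

test_that("feature-width mismatches raise shape errors naming the block", {
  model <- tiny_model()
  p <- acid_base_pair("CC(=O)O", 4)
  wrong <- build_paired_graph(p$acid, p$base, p$center, mode = "focused")
  expect_error(predict(model, wrong), "bond feature block")
  wrong2 <- build_paired_graph(p$acid, p$base, p$center, mode = "acid_only")
  expect_error(predict(model, wrong2), "atom feature block")
})
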