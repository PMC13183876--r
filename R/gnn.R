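#' Model configuration
#'
#' Hyperparameters of the masked graph-attention pKa regressor. `n_gat_layers`
#' (L) attention layers run on the full graph; the readout then pools only
#' atoms within `mask_size` (m) bonds of the ionization center, so the
#' effective receptive radius is L + m bonds — the "1-6" configuration sees
#' atoms seven bonds out. The two molecular features (net charge, center
#' formal charge) are appended after pooling and processed by two fully
#' connected layers. The seed fully determines weight initialization, data
#' order and dropout.
#'
#' @param n_gat_layers Number of GATv2 layers (L >= 1).
#' @param mask_size Readout mask radius in bonds (m >= 0).
#' @param n_heads Attention heads per layer (must divide `hidden_dim`).
#' @param hidden_dim Total embedding width across heads.
#' @param dropout Dropout probability between graph layers during training.
#' @param learning_rate,batch_size,n_epochs Optimizer settings (Adam).
#' @param loss `"L1"` (trains toward MAE, the reported metric) or `"MSE"`.
#' @param mode Paired-graph mode: `"full"`, `"focused"`, `"acid_only"`,
#'   `"base_only"`.
#' @param toggles Feature switches ([default_toggles()]).
#' @param seed Integer seed.
#' @return A `pka_model_config`.
#' @export
model_config <- function(n_gat_layers = 3L, mask_size = 4L, n_heads = 4L,
                         hidden_dim = 64L, dropout = 0.1,
                         learning_rate = 1e-3, batch_size = 32L,
                         n_epochs = 60L, loss = c("L1", "MSE"),
                         mode = c("full", "focused", "acid_only", "base_only"),
                         toggles = NULL, seed = 1L) {
  loss <- match.arg(loss); mode <- match.arg(mode)
  stopifnot(n_gat_layers >= 1, mask_size >= 0, n_heads >= 1,
            hidden_dim %% n_heads == 0, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, n_epochs >= 1)
  structure(list(n_gat_layers = as.integer(n_gat_layers),
                 mask_size = as.integer(mask_size),
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), loss = loss, mode = mode,
                 toggles = merge_toggles(toggles), seed = as.integer(seed)),
            class = "pka_model_config")
}

#' @export
print.pka_model_config <- function(x, ...) {
  cat("<pka_model_config> L=", x$n_gat_layers, " m=", x$mask_size,
      " (receptive radius ", x$n_gat_layers + x$mask_size, "), heads=",
      x$n_heads, ", hidden=", x$hidden_dim, ", mode=", x$mode, "\n", sep = "")
  invisible(x)
}

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

init_params <- function(config, d_atom, d_edge) {
  D <- config$hidden_dim
  layers <- lapply(seq_len(config$n_gat_layers), function(l) {
    din <- if (l == 1) d_atom else D
    list(Wsrc = glorot(din, D), Wdst = glorot(din, D),
         Wedge = glorot(d_edge, D), b = numeric(D),
         a = stats::runif(D, -1, 1) * sqrt(3 / D))
  })
  list(layers = layers,
       W1 = glorot(D + 2L, D), b1 = numeric(D),
       W2 = glorot(D, 1L), b2 = numeric(1))
}

# Collate a list of pka_graphs into one block-diagonal batch. Directed edges
# (both orientations per bond) plus one self-loop per atom with a zero edge
# feature row; edges are ordered by destination for deterministic grouping.
build_batch <- function(graphs, mask_size) {
  nb <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offs <- c(0L, cumsum(nb))
  N <- sum(nb)
  X <- do.call(rbind, lapply(graphs, function(g) g$x))
  d_edge <- ncol(graphs[[1]]$e_attr)
  src <- integer(0); dst <- integer(0)
  Elist <- list()
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]; o <- offs[k]
    if (nrow(g$edges) > 0) {
      src <- c(src, g$edges[, "i"] + o, g$edges[, "j"] + o)
      dst <- c(dst, g$edges[, "j"] + o, g$edges[, "i"] + o)
      Elist[[length(Elist) + 1L]] <- rbind(g$e_attr, g$e_attr)
    }
    src <- c(src, seq_len(nb[k]) + o)  # self loops
    dst <- c(dst, seq_len(nb[k]) + o)
    Elist[[length(Elist) + 1L]] <- matrix(0, nb[k], d_edge)
  }
  E <- do.call(rbind, Elist)
  o <- order(dst, src)
  src <- src[o]; dst <- dst[o]; E <- E[o, , drop = FALSE]
  list(X = X, src = src, dst = dst, E = E,
       graph_id = rep(seq_along(graphs), nb),
       mask = as.numeric(unlist(lapply(graphs, function(g)
         g$bond_dist <= mask_size))),
       mol_feats = do.call(rbind, lapply(graphs, function(g) g$mol_feats)),
       labels = vapply(graphs, function(g) as.numeric(g$label), numeric(1)),
       n_graphs = length(graphs), N = N)
}

lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# Grouped max by contiguous integer groups 1..N (edges sorted by dst).
group_max <- function(S, groups, ngroups) {
  out <- matrix(-Inf, ngroups, ncol(S))
  for (k in seq_len(ncol(S)))
    out[, k] <- vapply(split(S[, k], groups), max, numeric(1))
  out
}

gnn_forward <- function(params, batch, config, training = FALSE) {
  K <- config$n_heads; D <- config$hidden_dim; dh <- D / K
  colmap <- rep(seq_len(K), each = dh)
  H <- batch$X
  caches <- list()
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    Zs <- H %*% p$Wsrc; Zd <- H %*% p$Wdst; Ze <- batch$E %*% p$Wedge
    U <- Zs[batch$src, , drop = FALSE] + Zd[batch$dst, , drop = FALSE] + Ze +
      matrix(p$b, nrow(Ze), D, byrow = TRUE)
    G <- lrelu(U)
    Amask <- matrix(0, D, K); Amask[cbind(seq_len(D), colmap)] <- p$a
    S <- G %*% Amask
    gm <- group_max(S, batch$dst, batch$N)
    expS <- exp(S - gm[batch$dst, , drop = FALSE])
    denom <- rowsum(expS, batch$dst)
    alpha <- expS / denom[batch$dst, , drop = FALSE]
    V <- Zs[batch$src, , drop = FALSE]
    Msg <- V * alpha[, colmap, drop = FALSE]
    P <- rowsum(Msg, batch$dst)
    Hnew <- elu(P)
    drop_mask <- NULL
    if (training && config$dropout > 0) {
      drop_mask <- matrix(stats::rbinom(length(Hnew), 1, 1 - config$dropout) /
                            (1 - config$dropout), nrow(Hnew), ncol(Hnew))
      Hnew <- Hnew * drop_mask
    }
    caches[[l]] <- list(H = H, Zs = Zs, U = U, G = G, S = S, alpha = alpha,
                        V = V, P = P, drop_mask = drop_mask)
    H <- Hnew
  }
  Hm <- H * batch$mask
  R <- rowsum(Hm, batch$graph_id)
  Rm <- cbind(R, batch$mol_feats)
  A1pre <- Rm %*% params$W1 + matrix(params$b1, nrow(Rm), length(params$b1),
                                     byrow = TRUE)
  A1 <- pmax(A1pre, 0)
  yhat <- drop(A1 %*% params$W2) + params$b2
  list(yhat = yhat, caches = caches, Hfinal = H, Rm = Rm, A1pre = A1pre,
       A1 = A1)
}

gnn_backward <- function(params, batch, config, fwd, dyhat) {
  K <- config$n_heads; D <- config$hidden_dim; dh <- D / K
  colmap <- rep(seq_len(K), each = dh)
  grads <- list(layers = vector("list", length(params$layers)))
  dyhat <- matrix(dyhat, ncol = 1)
  grads$W2 <- t(fwd$A1) %*% dyhat
  grads$b2 <- sum(dyhat)
  dA1 <- dyhat %*% t(params$W2)
  dA1pre <- dA1 * (fwd$A1pre > 0)
  grads$W1 <- t(fwd$Rm) %*% dA1pre
  grads$b1 <- colSums(dA1pre)
  dRm <- dA1pre %*% t(params$W1)
  dR <- dRm[, seq_len(D), drop = FALSE]
  dH <- dR[batch$graph_id, , drop = FALSE] * batch$mask

  Fold <- matrix(0, D, K); Fold[cbind(seq_len(D), colmap)] <- 1
  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]; ch <- fwd$caches[[l]]
    if (!is.null(ch$drop_mask)) dH <- dH * ch$drop_mask
    dP <- dH * ifelse(ch$P > 0, 1, exp(pmin(ch$P, 0)))
    dMsg <- dP[batch$dst, , drop = FALSE]
    alpha_exp <- ch$alpha[, colmap, drop = FALSE]
    dV <- dMsg * alpha_exp
    dalpha <- (dMsg * ch$V) %*% Fold
    tmat <- ch$alpha * dalpha
    grpsum <- rowsum(tmat, batch$dst)
    dS <- tmat - ch$alpha * grpsum[batch$dst, , drop = FALSE]
    arep <- matrix(p$a, nrow(dS), D, byrow = TRUE)
    dG <- dS[, colmap, drop = FALSE] * arep
    da <- colSums(ch$G * dS[, colmap, drop = FALSE])
    dU <- dG * ifelse(ch$U > 0, 1, 0.2)
    db <- colSums(dU)
    dWedge <- t(batch$E) %*% dU
    dZs <- rowsum(dU, batch$src) + rowsum(dV, batch$src)
    dZd <- rowsum(dU, batch$dst)
    grads$layers[[l]] <- list(
      Wsrc = t(ch$H) %*% dZs, Wdst = t(ch$H) %*% dZd,
      Wedge = dWedge, b = db, a = da)
    dH <- dZs %*% t(p$Wsrc) + dZd %*% t(p$Wdst)
  }
  grads
}

# Flatten/unflatten parameter trees for the optimizer and serialization.
param_walk <- function(params, grads, fun) {
  out <- params
  for (l in seq_along(params$layers))
    for (nm in names(params$layers[[l]]))
      out$layers[[l]][[nm]] <- fun(params$layers[[l]][[nm]],
                                   grads$layers[[l]][[nm]],
                                   paste0("L", l, ".", nm))
  for (nm in c("W1", "b1", "W2", "b2"))
    out[[nm]] <- fun(params[[nm]], grads[[nm]], nm)
  out
}

#' Train the masked graph-attention regressor
#'
#' Minibatch Adam on the L1 (or MSE) loss, fully determined by the config
#' seed: initialization, shuffling and dropout all draw from one seeded
#' stream, so the same config and data reproduce the same training log
#' bitwise. When a validation set is supplied the weights with the best
#' validation MAE are kept (fixed epoch budget, no early stopping);
#' otherwise the final weights are returned.
#'
#' @param graphs List of labeled `pka_graph`s (see [graphs_from_records()]).
#' @param config A [model_config()].
#' @param val_graphs Optional validation graphs.
#' @param verbose Print per-epoch losses?
#' @return A `pka_model` with weights, config and per-epoch `training_log`.
#' @export
train_gnn <- function(graphs, config = model_config(), val_graphs = NULL,
                      verbose = FALSE) {
  if (length(graphs) == 0) stop("empty training set", call. = FALSE)
  if (any(vapply(graphs, function(g) is.na(g$label), logical(1))))
    stop("all training graphs need labels", call. = FALSE)
  if (length(unique(vapply(graphs, function(g) ncol(g$x), integer(1)))) != 1)
    stop("training graphs have inconsistent atom-feature widths; check that ",
         "all were built under one mode and toggle set", call. = FALSE)
  d_atom <- ncol(graphs[[1]]$x); d_edge <- ncol(graphs[[1]]$e_attr)
  n <- length(graphs)
  log_rows <- vector("list", config$n_epochs)
  best <- list(mae = Inf, params = NULL)
  val_batch <- if (!is.null(val_graphs))
    build_batch(val_graphs, config$mask_size)

  withr::with_seed(config$seed, {
    params <- init_params(config, d_atom, d_edge)
    # start the output head at the label mean: the net only has to learn shifts
    params$b2 <- mean(vapply(graphs, function(g) g$label, numeric(1)))
    mstate <- param_walk(params, params, function(p, g, nm) p * 0)
    vstate <- mstate
    step <- 0L
    for (epoch in seq_len(config$n_epochs)) {
      # cosine decay to zero over the epoch budget (no restarts)
      lr_epoch <- config$learning_rate *
        0.5 * (1 + cos(pi * (epoch - 1) / config$n_epochs))
      ord <- sample(n)
      epoch_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        batch <- build_batch(graphs[idx], config$mask_size)
        fwd <- gnn_forward(params, batch, config, training = TRUE)
        resid <- fwd$yhat - batch$labels
        loss <- if (config$loss == "L1") mean(abs(resid)) else mean(resid^2)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch,
               "; try a lower learning rate", call. = FALSE)
        dyhat <- if (config$loss == "L1") sign(resid) / length(resid)
                 else 2 * resid / length(resid)
        grads <- gnn_backward(params, batch, config, fwd, dyhat)
        step <- step + 1L
        adam <- adam_update(params, grads, mstate, vstate, step, lr_epoch)
        params <- adam$params; mstate <- adam$m; vstate <- adam$v
        epoch_loss <- epoch_loss + loss; nb <- nb + 1L
      }
      val_mae <- NA_real_
      if (!is.null(val_batch)) {
        vf <- gnn_forward(params, val_batch, config, training = FALSE)
        val_mae <- mean(abs(vf$yhat - val_batch$labels))
        if (val_mae < best$mae) best <- list(mae = val_mae, params = params)
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss / nb, val_mae = val_mae)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val MAE %s", epoch,
                        epoch_loss / nb,
                        if (is.na(val_mae)) "-" else sprintf("%.4f", val_mae)))
    }
  })
  if (!is.null(best$params)) params <- best$params
  structure(list(params = params, config = config, d_atom = d_atom,
                 d_edge = d_edge, registry_version = registry_version(),
                 training_log = dplyr::bind_rows(log_rows)),
            class = "pka_model")
}

adam_update <- function(params, grads, m, v, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  new_m <- param_walk(m, grads, function(mm, g, nm) beta1 * mm + (1 - beta1) * g)
  new_v <- param_walk(v, grads, function(vv, g, nm) beta2 * vv + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
  upd <- param_walk(new_m, new_v, function(mm, vv, nm)
    mm / bc1 / (sqrt(vv / bc2) + eps))
  list(params = param_walk(params, upd, function(p, u, nm) p - lr * u),
       m = new_m, v = new_v)
}

#' Predict pKa values for paired graphs
#'
#' A pure function of the trained weights and the input graphs: no random
#' stream is consumed, so repeated calls are bitwise identical.
#'
#' @param object A `pka_model`.
#' @param graphs A `pka_graph` or list of them.
#' @param ... Ignored.
#' @return Numeric vector of predicted pKa values.
#' @export
predict.pka_model <- function(object, graphs, ...) {
  if (inherits(graphs, "pka_graph")) graphs <- list(graphs)
  d <- vapply(graphs, function(g) ncol(g$x), integer(1))
  if (any(d != object$d_atom))
    stop("atom-feature width ", d[d != object$d_atom][1], " does not match ",
         "the model's ", object$d_atom, " (atom feature block); rebuild the ",
         "graphs with the model's mode and toggles", call. = FALSE)
  de <- vapply(graphs, function(g) ncol(g$e_attr), integer(1))
  if (any(de != object$d_edge))
    stop("bond-feature width ", de[de != object$d_edge][1],
         " does not match the model's ", object$d_edge,
         " (bond feature block)", call. = FALSE)
  batch <- build_batch(graphs, object$config$mask_size)
  gnn_forward(object$params, batch, object$config, training = FALSE)$yhat
}

#' @export
print.pka_model <- function(x, ...) {
  np <- sum(unlist(lapply(x$params$layers, function(l)
    vapply(l, length, integer(1))))) +
    length(x$params$W1) + length(x$params$b1) +
    length(x$params$W2) + length(x$params$b2)
  cat("<pka_model> L=", x$config$n_gat_layers, " m=", x$config$mask_size,
      ", ", np, " parameters, trained ", nrow(x$training_log), " epochs\n",
      sep = "")
  invisible(x)
}

#' Evaluate a model on labeled graphs
#'
#' @param model A `pka_model` (or any object with a `predict` method over
#'   the same data, e.g. a `pka_baseline`).
#' @param graphs Labeled `pka_graph` list, or a record tibble with `pka`
#'   labels for baseline models.
#' @return A list: `mae`, `rmse`, and `residuals` (tibble with predictions).
#' @export
evaluate_model <- function(model, graphs) {
  preds <- predict(model, graphs)
  labels <- if (is.data.frame(graphs)) as.numeric(graphs$pka)
            else vapply(graphs, function(g) as.numeric(g$label), numeric(1))
  resid <- preds - labels
  list(mae = mean(abs(resid)), rmse = sqrt(mean(resid^2)),
       residuals = tibble::tibble(label = labels, prediction = preds,
                                  residual = resid))
}

#' Exhaustive grid search over model configurations
#'
#' Trains one model per grid row and returns the configuration with the
#' lowest validation MAE (ties broken toward the first row in grid order).
#' The full result table is attached as attribute `"grid_results"`.
#'
#' @param grid A data frame whose columns are [model_config()] arguments
#'   (see [default_grid()]), or a list of `pka_model_config`s.
#' @param train_graphs,val_graphs Labeled graph lists.
#' @param base_config Config supplying the fields the grid does not vary.
#' @return The winning `pka_model_config`.
#' @export
grid_search <- function(grid, train_graphs, val_graphs,
                        base_config = model_config()) {
  configs <- if (is.data.frame(grid)) {
    if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
    lapply(seq_len(nrow(grid)), function(r) {
      args <- as.list(grid[r, , drop = FALSE])
      cfg <- base_config
      cfg[names(args)] <- args
      do.call(model_config, cfg[names(formals(model_config))[
        names(formals(model_config)) %in% names(cfg)]])
    })
  } else {
    if (length(grid) == 0) stop("empty grid", call. = FALSE)
    grid
  }
  maes <- vapply(seq_along(configs), function(k) {
    fit <- train_gnn(train_graphs, configs[[k]], val_graphs)
    evaluate_model(fit, val_graphs)$mae
  }, numeric(1))
  best <- which.min(maes)   # first minimum in grid order
  out <- configs[[best]]
  results <- dplyr::bind_rows(lapply(seq_along(configs), function(k)
    tibble::tibble(config = k, val_mae = maes[k])))
  attr(out, "grid_results") <- results
  out
}

#' @rdname grid_search
#' @export
default_grid <- function() {
  expand.grid(learning_rate = c(1e-3, 3e-4), hidden_dim = c(64L, 128L),
              dropout = c(0, 0.2), batch_size = c(32L, 64L),
              KEEP.OUT.ATTRS = FALSE)
}

#' Wrap a trained model as a site scorer
#'
#' Adapts a `pka_model` to the scorer interface of
#' [infer_ionization_profile()]: for each candidate site the current
#' microstate is taken as the base form, the site is protonated to give the
#' acid form, and the paired graph is scored under the model's own mode and
#' feature toggles.
#'
#' @param model A `pka_model`.
#' @return A function `(mol, site) -> pKa`.
#' @export
model_scorer <- function(model) {
  force(model)
  function(mol, site) {
    g <- paired_graph_for_site(mol, site$atom_index, site$role,
                               mode = model$config$mode,
                               toggles = model$config$toggles)
    predict(model, g)
  }
}

#' Save / load model checkpoints
#'
#' Checkpoints are JSON (text, portable) carrying the weights at full
#' precision, the config and the element-registry version. Loading refuses
#' a checkpoint whose registry version differs from the installed one, since
#' feature values would silently drift.
#'
#' @param model A `pka_model`.
#' @param path File path.
#' @return `load_model()` returns the restored `pka_model`.
#' @export
save_model <- function(model, path) {
  ser <- list(
    registry_version = model$registry_version,
    config = unclass(model$config),
    d_atom = model$d_atom, d_edge = model$d_edge,
    training_log = model$training_log,
    params = rapply(model$params, function(x)
      list(dim = dim(x), data = as.numeric(x)), how = "list"))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ser$registry_version, registry_version()))
    stop("checkpoint was built against element registry version ",
         ser$registry_version, " but the installed registry is ",
         registry_version(), "; refusing to load", call. = FALSE)
  restore <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      data <- as.numeric(unlist(x$data))
      dm <- as.integer(unlist(x$dim))
      if (length(dm) == 2) matrix(data, dm[1], dm[2]) else data
    } else if (is.list(x)) lapply(x, restore) else x
  }
  cfg <- lapply(ser$config, function(v)
    if (is.list(v)) lapply(v, identity) else v)
  config <- do.call(model_config, cfg[names(cfg) %in%
                                        names(formals(model_config))])
  tl <- jsonlite::fromJSON(path)$training_log
  structure(list(params = restore(ser$params), config = config,
                 d_atom = ser$d_atom[[1]], d_edge = ser$d_edge[[1]],
                 registry_version = ser$registry_version,
                 training_log = tibble::as_tibble(tl)),
            class = "pka_model")
}

#' @importFrom generics tidy
#' @export
tidy.pka_model <- function(x, ...) x$training_log

#' @importFrom generics glance
#' @export
glance.pka_model <- function(x, ...) {
  lg <- x$training_log
  tibble::tibble(n_gat_layers = x$config$n_gat_layers,
                 mask_size = x$config$mask_size,
                 receptive_radius = x$config$n_gat_layers + x$config$mask_size,
                 hidden_dim = x$config$hidden_dim,
                 n_epochs = nrow(lg),
                 final_train_loss = lg$train_loss[nrow(lg)],
                 best_val_mae = if (all(is.na(lg$val_mae))) NA_real_
                                else min(lg$val_mae, na.rm = TRUE))
}

#' Plot a training log
#'
#' @param object A `pka_model`.
#' @param ... Ignored.
#' @return A ggplot of per-epoch training loss and validation MAE.
#' @export
autoplot.pka_model <- function(object, ...) {
  lg <- tidyr::pivot_longer(object$training_log, -"epoch",
                            names_to = "metric", values_to = "value")
  lg <- lg[is.finite(lg$value), ]
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss / MAE (pKa units)") +
    ggplot2::theme_minimal()
}
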