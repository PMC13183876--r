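#' Read and validate a run configuration
#'
#' Run configurations are YAML with up to six sections: `model`
#' ([model_config()] arguments, including `toggles` keyed like
#' `atom.hardness: false`), `synthetic` ([synthetic_spec()] scalar
#' arguments), `split` (`method` `"cluster"` or `"random"`,
#' `similarity_cap`, `test_fraction`, `seed`), `augment` (`n_copies`,
#' `seed`), `ph`, `seeds` (the replicate training seeds) and `paths`
#' (`data`, `checkpoint`, `report`). The file is validated against this
#' schema before any work: an unknown section or key fails immediately with
#' its name.
#'
#' @param path YAML file path.
#' @param overrides Optional named list merged over the file contents.
#' @return A validated `pka_run_config` list with defaults filled in.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (!is.null(overrides)) raw <- utils::modifyList(raw, overrides)
  schema <- list(
    model = names(formals(model_config)),
    synthetic = c("chain_lengths", "rho", "noise_sd", "n_molecules", "seed"),
    split = c("method", "similarity_cap", "test_fraction", "seed"),
    augment = c("n_copies", "seed"),
    ph = NULL, seeds = NULL,
    paths = c("data", "checkpoint", "report"))
  bad_sections <- setdiff(names(raw), names(schema))
  if (length(bad_sections) > 0)
    stop("unknown configuration section(s): ",
         paste(bad_sections, collapse = ", "), call. = FALSE)
  for (sec in intersect(names(raw), c("model", "synthetic", "split",
                                      "augment", "paths"))) {
    if (!is.list(raw[[sec]]))
      stop("configuration section '", sec, "' must be a mapping", call. = FALSE)
    keys <- names(raw[[sec]])
    if (sec == "model" && "toggles" %in% keys) {
      tg <- raw$model$toggles
      unknown <- setdiff(names(tg), names(default_toggles()))
      if (length(unknown) > 0)
        stop("unknown feature toggle key(s) in model.toggles: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(keys, schema[[sec]])
    if (length(bad) > 0)
      stop("unknown key(s) in configuration section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    model = do.call(model_config, raw$model %||% list()),
    synthetic = do.call(synthetic_spec, raw$synthetic %||% list()),
    split = utils::modifyList(list(method = "cluster", similarity_cap = 0.65,
                                   test_fraction = 0.2, seed = 1L),
                              raw$split %||% list()),
    augment = utils::modifyList(list(n_copies = 0L, seed = 1L),
                                raw$augment %||% list()),
    ph = raw$ph %||% 7.4,
    seeds = raw$seeds %||% NULL,
    paths = raw$paths %||% list())
  if (is.null(cfg$seeds)) cfg$seeds <- cfg$model$seed + 0:2
  if (!cfg$split$method %in% c("cluster", "random"))
    stop("split.method must be 'cluster' or 'random'", call. = FALSE)
  structure(cfg, class = "pka_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
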