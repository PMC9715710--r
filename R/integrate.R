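#' Read a run configuration from YAML
#'
#' Flat or nested YAML whose fields mirror the arguments of
#' [prepare_inputs()] and [uotvae()]; unknown fields raise an error with the
#' offending field path so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c(names(formals(uotvae)), "input_x", "input_y", "out_dir",
               "cell_types_x", "cell_types_y", "paired")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Run the full integration workflow
#'
#' Preprocess two datasets, fit the coupled VAE with transport alignment,
#' embed all cells, score the integration (when cell types are available) and
#' write every artifact to `out_dir`: `embedding_<id>.csv`, `loss_history.csv`,
#' `checkpoint.rds`, `metrics.json` (if computable), `plan.mtx` (when the
#' global plan is enabled) and a `manifest.json` recording the configuration,
#' its hash, the package version and the seed — enough to reconstruct the
#' run.
#'
#' @param input_x,input_y [sc_dataset()]s, or file paths readable by
#'   [read_cell_matrix()].
#' @param out_dir Output directory (created if missing).
#' @param config Named list overriding [uotvae()] arguments (e.g. from
#'   [read_run_config()]).
#' @param paired Score FOSCTTM assuming row pairing (default `FALSE`).
#' @param seed Seed forwarded to the fit (default 0).
#' @return The [uotvae()] fit, invisibly, with attribute `"artifacts"`.
#' @export
run_integrate <- function(input_x, input_y, out_dir, config = list(),
                          paired = FALSE, seed = 0) {
  ds_x <- if (inherits(input_x, "sc_dataset")) input_x
          else read_cell_matrix(input_x, "x")
  ds_y <- if (inherits(input_y, "sc_dataset")) input_y
          else read_cell_matrix(input_y, "y")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  config$seed <- seed
  fit_args <- config[intersect(names(config), names(formals(uotvae)))]
  fit <- do.call(uotvae, c(list(x = ds_x, y = ds_y), fit_args))

  ids <- fit$partition$dataset_ids
  paths <- character(0)
  for (i in 1:2) {
    emb <- predict(fit, dataset_id = ids[i], type = "latent")
    p <- file.path(out_dir, paste0("embedding_", ids[i], ".csv"))
    utils::write.table(
      data.frame(cell_id = fit$partition$cell_ids[[i]], emb),
      p, sep = ",", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "loss_history.csv")
  utils::write.table(fit$history, p, sep = ",", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "checkpoint.rds")
  saveRDS(list(schema_version = 1L, model = fit$model,
               config = fit$config), p)
  paths <- c(paths, p)
  if (!is.null(fit$global_plan)) {
    p <- file.path(out_dir, "plan.mtx")
    write_plan(fit$global_plan, p)
    paths <- c(paths, p)
  }
  ct <- fit$partition$cell_types
  if (!is.null(ct[[1]]) && !is.null(ct[[2]])) {
    emb_x <- predict(fit, dataset_id = ids[1], type = "latent")
    emb_y <- predict(fit, dataset_id = ids[2], type = "latent")
    rep_ <- metric_report(emb_x, emb_y, ct[[1]], ct[[2]], paired = paired,
                          seed = seed)
    p <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(rep_, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "uotvae",
    version = as.character(utils::packageVersion("uotvae")),
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(
      local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
    artifacts = basename(paths),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(fit, "artifacts") <- c(paths, file.path(out_dir, "manifest.json"))
  invisible(fit)
}
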