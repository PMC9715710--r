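# Synthetic-study configuration shared by the acceptance checks: generator
# defaults (600 + 600 cells, 3 types, 300 common / 150 specific genes,
# dropout 0.3), a compact encoder and a fixed 2,000-iteration budget
# (patience set high so the budget, not early stopping, ends the run).
# Fits are cached so checks that share a scenario do not retrain.

.fit_cache <- new.env(parent = emptyenv())

experiment_fit <- function(key, sim = NULL, gp = NULL, seed = 1,
                           global_plan = FALSE, lambda_kl = 0.5) {
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  if (is.null(gp))
    gp <- prepare_inputs(sim$x, sim$y, n_common_hvg = 300,
                         n_specific_hvg = 150, filter = FALSE)
  fit <- suppressMessages(
    uotvae(gp, hidden_dims = c(256, 64), max_iterations = 2000,
           patience = 10000, seed = seed, global_plan = global_plan,
           lambda_kl = lambda_kl))
  out <- list(sim = sim, gp = gp, fit = fit)
  assign(key, out, .fit_cache)
  out
}

embeddings_of <- function(fit) {
  ids <- fit$partition$dataset_ids
  list(x = predict(fit, dataset_id = ids[1], type = "latent"),
       y = predict(fit, dataset_id = ids[2], type = "latent"))
}

balanced_run <- function(seed) {
  sim <- simulate_multiome(seed = seed)
  experiment_fit(paste0("balanced", seed), sim, seed = seed)
}

# hold out a fraction of the common genes from the integration input; they
# join x's specific decoder, and y's withheld measurements are the truth
imputation_holdout <- function(gp, frac = 0.2, seed = 1) {
  set.seed(seed)
  held <- sort(sample(seq_along(gp$common_genes),
                      round(frac * length(gp$common_genes))))
  hg <- gp$common_genes[held]
  truth <- gp$Y_c[, hg, drop = FALSE]
  gp2 <- gp
  gp2$common_genes <- gp$common_genes[-held]
  gp2$X_s <- cbind(gp$X_s, gp$X_c[, hg, drop = FALSE])
  gp2$specific_genes[[1]] <- c(gp$specific_genes[[1]], hg)
  gp2$X_c <- gp$X_c[, -held, drop = FALSE]
  gp2$Y_c <- gp$Y_c[, -held, drop = FALSE]
  list(gp = gp2, held_genes = hg, truth = truth)
}
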