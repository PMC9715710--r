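#' Epoch-cycling minibatch sampler
#'
#' Draws duplicate-free index sets without replacement within an epoch's
#' shuffled permutation; when fewer than `batch_size` indices remain the
#' permutation is reshuffled (partial batches are dropped, since batches of
#' fewer than two cells break batch normalization). The two datasets are
#' cycled independently during a fit.
#'
#' @param n Number of items.
#' @param batch_size Batch size (2 <= batch_size <= n).
#' @return A sampler object; draw from it with [next_batch()].
#' @export
minibatch_sampler <- function(n, batch_size) {
  if (batch_size > n) stop("batch_size (", batch_size, ") exceeds n (", n, ")")
  if (batch_size < 2) stop("batch_size must be >= 2")
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$b <- batch_size
  env$perm <- sample.int(n)
  env$pos <- 1L
  structure(env, class = "minibatch_sampler")
}

#' @rdname minibatch_sampler
#' @param sampler A [minibatch_sampler()].
#' @return `next_batch()`: an integer vector of `batch_size` indices.
#' @export
next_batch <- function(sampler) {
  stopifnot(inherits(sampler, "minibatch_sampler"))
  if (sampler$pos + sampler$b - 1L > sampler$n) {
    sampler$perm <- sample.int(sampler$n)
    sampler$pos <- 1L
  }
  idx <- sampler$perm[sampler$pos:(sampler$pos + sampler$b - 1L)]
  sampler$pos <- sampler$pos + sampler$b
  idx
}

# Adam with L2 weight decay folded into the gradient (single parameter group)
adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]] + weight_decay * par[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

#' Fit the coupled VAE with transport alignment
#'
#' The main fitting function. Preprocessed common-gene profiles of both
#' datasets pass through one shared probabilistic encoder; per iteration a
#' minibatch from each dataset is encoded, reparameterized and reconstructed
#' (common decoder through the dataset's own batch-normalization branch,
#' plus the dataset's specific decoder), the transport cost between the two
#' sets of latent Gaussians is built, the entropic unbalanced transport plan
#' is solved, and one Adam step minimizes
#' \deqn{L = -ELBO^* + \gamma\, L_{UOT}}
#' with the plan held fixed. Training stops after `max_iterations` or when
#' the epoch-mean loss has not improved (relatively, by more than
#' `improvement`) for `patience` epochs; the parameters of the best epoch are
#' returned. An epoch is `ceiling(max(n_x, n_y) / batch)` iterations.
#'
#' @param x Either an [sc_dataset()] (then `y` is required and
#'   [prepare_inputs()] is run with the preprocessing arguments below) or a
#'   ready `gene_partition`.
#' @param y Second [sc_dataset()], or `NULL` when `x` is a `gene_partition`.
#' @param n_common_hvg,n_specific_hvg,min_genes_per_cell,min_cells_per_gene,filter
#'   Passed to [prepare_inputs()] when raw datasets are given.
#' @param latent_dim Latent dimension K (default 16).
#' @param hidden_dims Encoder hidden sizes (default `c(1024, 128)`).
#' @param lambda_kl,lambda_s,gamma Loss weights, see [loss_weights()].
#' @param epsilon,rho Transport regularization parameters (defaults 0.1, 1).
#' @param recenter_plan Use the plan-recentered proximal transport solver
#'   during training (default `FALSE`; see [solve_uot()]).
#' @param batch_size Minibatch size per dataset (default 256, capped at the
#'   smaller dataset size).
#' @param max_iterations Maximum number of iterations (default 30000).
#' @param learning_rate Adam learning rate (default 2e-4).
#' @param weight_decay Adam L2 weight decay (default 5e-4).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param improvement Relative improvement threshold for early stopping.
#' @param global_plan Accumulate the dense `n_x` x `n_y` transport plan
#'   (default `FALSE`; a message reports the memory footprint).
#' @param marginal_weights Optional `list(x =, y =)` of non-negative per-cell
#'   weights for unbalanced populations; see [set_marginal_weights()].
#' @param seed Integer seed controlling initialization, minibatch order and
#'   reparameterization draws (default 0). The caller's RNG state is
#'   restored on exit.
#' @param verbose Print a progress line per 50 epochs.
#'
#' @return An object of class `uotvae_fit` with elements `model` (the
#'   `coupled_vae`), `history` (per-iteration loss data frame), `partition`,
#'   `global_plan` (or `NULL`), `best_epoch`, `stopped_early` and `config`.
#'   Methods: [predict.uotvae_fit()], [plot.uotvae_fit()],
#'   [residuals.uotvae_fit()], `print`, `summary`, `coef`.
#' @export
uotvae <- function(x, y = NULL,
                   n_common_hvg = 2000, n_specific_hvg = 2000,
                   min_genes_per_cell = 200, min_cells_per_gene = 3,
                   filter = TRUE,
                   latent_dim = 16, hidden_dims = c(1024, 128),
                   lambda_kl = 0.5, lambda_s = 0.5, gamma = 1,
                   epsilon = 0.1, rho = 1, recenter_plan = FALSE,
                   batch_size = 256, max_iterations = 30000,
                   learning_rate = 2e-4, weight_decay = 5e-4,
                   patience = 30, improvement = 1e-4,
                   global_plan = FALSE, marginal_weights = NULL,
                   seed = 0, verbose = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cl <- match.call()
  if (inherits(x, "gene_partition")) {
    gp <- x
  } else {
    if (is.null(y)) stop("`y` is required when `x` is a raw dataset")
    gp <- prepare_inputs(x, y, n_common_hvg, n_specific_hvg,
                         min_genes_per_cell, min_cells_per_gene, filter)
  }
  ids <- gp$dataset_ids
  xc <- as.matrix(gp$X_c); yc <- as.matrix(gp$Y_c)
  xs <- as.matrix(gp$X_s); ys <- as.matrix(gp$Y_s)
  n_x <- nrow(xc); n_y <- nrow(yc)
  b <- min(batch_size, n_x, n_y)
  if (b < 2) stop("need at least 2 cells per dataset")
  weights <- loss_weights(lambda_kl, lambda_s, gamma)

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  model <- init_coupled_vae(
    n_common = ncol(xc),
    n_specific = stats::setNames(c(ncol(xs), ncol(ys)), ids),
    latent_dim = latent_dim, hidden_dims = hidden_dims)
  model$genes <- list(common = gp$common_genes, specific = gp$specific_genes)
  par <- model$par; bn <- model$bn
  opt <- adam_init(par)

  mw <- if (is.null(marginal_weights)) NULL
        else set_marginal_weights(marginal_weights$x, marginal_weights$y)
  # minibatch plans feed a (noisy) gradient, so a moderate solver tolerance
  # suffices inside the loop; direct solve_uot() calls keep tight defaults
  uot_cfg <- list(epsilon = epsilon, rho = rho, recenter = recenter_plan,
                  a = NULL, b = NULL,
                  outer_iters = if (recenter_plan) 20L else 150L,
                  tol = if (recenter_plan) 1e-6 else 1e-5)

  Tg <- NULL
  if (global_plan) {
    message(sprintf("allocating dense global plan: %d x %d (%.1f MB)",
                    n_x, n_y, n_x * n_y * 8 / 2^20))
    Tg <- matrix(1 / (n_x * n_y), n_x, n_y,
                 dimnames = list(gp$cell_ids[[1]], gp$cell_ids[[2]]))
  }

  samp_x <- minibatch_sampler(n_x, b)
  samp_y <- minibatch_sampler(n_y, b)
  epoch_len <- ceiling(max(n_x, n_y) / b)
  hist_it <- integer(0); hist_elbo <- hist_uot <- hist_total <- numeric(0)
  best_loss <- Inf; best_epoch <- NA_integer_
  best_par <- par; best_bn <- bn
  stall <- 0L; stopped_early <- FALSE
  epoch <- 0L; it <- 0L; epoch_acc <- numeric(0)

  while (it < max_iterations) {
    it <- it + 1L
    I <- next_batch(samp_x); J <- next_batch(samp_y)
    noise_x <- matrix(stats::rnorm(b * latent_dim), b, latent_dim)
    noise_y <- matrix(stats::rnorm(b * latent_dim), b, latent_dim)
    if (!is.null(mw)) {
      uot_cfg$a <- mw$a[I] / sum(mw$a[I])
      uot_cfg$b <- mw$b[J] / sum(mw$b[J])
    }
    plan_init <- if (!is.null(Tg) && recenter_plan) {
      tb <- Tg[I, J, drop = FALSE]
      tb / sum(tb)
    } else NULL
    step <- if (engine == "cpp") {
      .cvae_step_cpp(xc[I, , drop = FALSE], xs[I, , drop = FALSE],
                     yc[J, , drop = FALSE], ys[J, , drop = FALSE],
                     par, bn, ids,
                     weights$lambda_kl, weights$lambda_s, weights$gamma,
                     uot_cfg$epsilon, uot_cfg$rho,
                     as.integer(uot_cfg$outer_iters), 1L, uot_cfg$tol,
                     isTRUE(uot_cfg$recenter), uot_cfg$a, uot_cfg$b,
                     noise_x, noise_y, plan_init, TRUE, BN_MOMENTUM)
    } else {
      cvae_step(par, bn, xc[I, , drop = FALSE], xs[I, , drop = FALSE],
                yc[J, , drop = FALSE], ys[J, , drop = FALSE],
                ids, weights, uot_cfg, noise_x, noise_y,
                plan_init = plan_init)
    }
    if (!is.finite(step$loss_total))
      stop(sprintf("non-finite loss at iteration %d (elbo %g, uot %g)",
                   it, step$loss_elbo, step$loss_uot))
    bn <- step$bn
    upd <- adam_step(par, step$grads, opt, learning_rate, weight_decay)
    par <- upd$par; opt <- upd$state
    if (!is.null(Tg)) Tg <- update_global_plan(Tg, step$plan, I, J)

    hist_it[it] <- it
    hist_elbo[it] <- step$loss_elbo
    hist_uot[it] <- step$loss_uot
    hist_total[it] <- step$loss_total
    epoch_acc <- c(epoch_acc, step$loss_total)

    if (it %% epoch_len == 0L) {
      epoch <- epoch + 1L
      em <- mean(epoch_acc); epoch_acc <- numeric(0)
      if (em < best_loss * (1 - improvement) || !is.finite(best_loss)) {
        best_loss <- em; best_epoch <- epoch
        best_par <- par; best_bn <- bn
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) { stopped_early <- TRUE; break }
      }
      if (verbose && epoch %% 50 == 0)
        message(sprintf("epoch %d (iter %d): loss %.4f (elbo %.4f, uot %.4f)",
                        epoch, it, em, step$loss_elbo, step$loss_uot))
    }
  }

  model$par <- best_par
  model$bn <- best_bn
  structure(
    list(model = model, partition = gp,
         history = data.frame(iteration = hist_it, elbo_star = hist_elbo,
                              uot = hist_uot, total = hist_total),
         global_plan = Tg,
         best_epoch = best_epoch, best_loss = best_loss,
         stopped_early = stopped_early, iterations = it,
         config = list(latent_dim = latent_dim, hidden_dims = hidden_dims,
                       weights = weights, epsilon = epsilon, rho = rho,
                       recenter_plan = recenter_plan, batch_size = b,
                       max_iterations = max_iterations,
                       learning_rate = learning_rate,
                       weight_decay = weight_decay, patience = patience,
                       improvement = improvement, seed = seed),
         call = cl),
    class = "uotvae_fit")
}

#' Embed cells into the shared latent space
#'
#' Evaluation-mode encoder pass returning the posterior means, the
#' embedding used for all downstream analyses. Columns of `x` must carry the
#' model's common genes (matched by name when dimnames are present).
#'
#' @param object A [uotvae()] fit or `coupled_vae`.
#' @param x Cell-by-common-gene matrix in \[0, 1\]. When `NULL` and `object`
#'   is a fit, the stored training matrix of `dataset_id` is used.
#' @param dataset_id Which dataset the cells belong to (used only for
#'   retrieving stored data; the encoder itself is dataset-free).
#' @return Cell-by-K matrix of posterior means.
#' @export
embed_cells <- function(object, x = NULL, dataset_id = NULL) {
  model <- as_coupled_vae(object)
  if (is.null(x)) {
    if (!inherits(object, "uotvae_fit") || is.null(dataset_id))
      stop("supply `x`, or a fit plus `dataset_id`")
    x <- training_matrix(object, dataset_id, "common")
  }
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(model$genes$common)) {
    missing <- setdiff(model$genes$common, colnames(x))
    if (length(missing))
      stop("input is missing model genes: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)",
                                            length(missing) - 5) else "")
    x <- x[, model$genes$common, drop = FALSE]
  }
  encode(model, x)$mu
}

# internal: stored (scaled) training matrix for one dataset
training_matrix <- function(fit, dataset_id, which = c("common", "specific")) {
  which <- match.arg(which)
  gp <- fit$partition
  i <- match(dataset_id, gp$dataset_ids)
  if (is.na(i)) stop("unknown dataset_id '", dataset_id, "'")
  if (which == "common") list(gp$X_c, gp$Y_c)[[i]]
  else list(gp$X_s, gp$Y_s)[[i]]
}
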