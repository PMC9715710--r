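## Coupled variational autoencoder.
##
## One dataset-free probabilistic encoder maps common-gene profiles to
## diagonal-Gaussian posteriors (mu, sigma) in a K-dimensional latent space.
## A single common decoder reconstructs the common genes through a
## dataset-specific batch-normalization (DSBN) branch per registered dataset,
## and one specific decoder per dataset reconstructs that dataset's own
## highly variable genes. All decoders end in a sigmoid, matching inputs
## scaled to [0, 1]; reconstruction log-likelihoods are Bernoulli
## (binary cross-entropy). Forward and backward passes are written
## explicitly on base matrices so a fit has no compiled dependencies.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
# add a per-column bias vector to a matrix (column-major recycling)
addb <- function(x, b) x + rep(b, each = nrow(x))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LOGVAR_CLAMP <- 10

kaiming_uniform <- function(fan_in, fan_out) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

#' Initialize a coupled VAE
#'
#' Builds the parameter container: shared encoder (two ReLU hidden layers,
#' then linear heads for the posterior mean and log-variance), a common
#' decoder (single linear layer + per-dataset batch normalization + sigmoid)
#' and per-dataset specific decoders (single linear layer + sigmoid, no
#' hidden layer). Weights are Kaiming-uniform, biases zero; batch-norm scale
#' starts at 1 and shift at 0. Draws come from the current RNG state, so
#' seed beforehand for reproducibility.
#'
#' @param n_common Number of common (encoder input / common decoder output)
#'   genes.
#' @param n_specific Named integer vector: specific-gene count per dataset
#'   id; exactly one decoder and one DSBN branch is registered per name.
#' @param latent_dim Latent dimension K (default 16).
#' @param hidden_dims Encoder hidden layer sizes (default `c(1024, 128)`).
#' @return An object of class `coupled_vae`.
#' @export
init_coupled_vae <- function(n_common, n_specific, latent_dim = 16,
                             hidden_dims = c(1024, 128)) {
  if (is.null(names(n_specific)) || any(names(n_specific) == ""))
    stop("`n_specific` must be a named vector of dataset ids")
  ids <- names(n_specific)
  h1 <- hidden_dims[1]; h2 <- hidden_dims[2]; K <- latent_dim
  par <- list(
    enc_W1 = kaiming_uniform(n_common, h1), enc_b1 = numeric(h1),
    enc_W2 = kaiming_uniform(h1, h2),       enc_b2 = numeric(h2),
    enc_Wmu = kaiming_uniform(h2, K),       enc_bmu = numeric(K),
    enc_Wlv = kaiming_uniform(h2, K),       enc_blv = numeric(K),
    dec_W = kaiming_uniform(K, n_common),   dec_b = numeric(n_common)
  )
  bn <- list()
  for (id in ids) {
    par[[paste0("bn_gamma_", id)]] <- rep(1, n_common)
    par[[paste0("bn_beta_", id)]] <- numeric(n_common)
    par[[paste0("spec_W_", id)]] <- kaiming_uniform(K, n_specific[[id]])
    par[[paste0("spec_b_", id)]] <- numeric(n_specific[[id]])
    bn[[id]] <- list(mean = numeric(n_common), var = rep(1, n_common))
  }
  structure(list(par = par, bn = bn,
                 dims = list(n_common = n_common, n_specific = n_specific,
                             latent_dim = K, hidden_dims = hidden_dims),
                 dataset_ids = ids, genes = NULL),
            class = "coupled_vae")
}

#' @export
print.coupled_vae <- function(x, ...) {
  cat(sprintf(paste0("<coupled_vae> %d common genes -> encoder (%s) -> K=%d\n",
                     "  datasets: %s (specific genes: %s)\n"),
              x$dims$n_common, paste(x$dims$hidden_dims, collapse = "-"),
              x$dims$latent_dim, paste(x$dataset_ids, collapse = ", "),
              paste(x$dims$n_specific, collapse = ", ")))
  invisible(x)
}

# internal encoder forward with caches for backprop
encode_fwd <- function(par, x) {
  h1 <- relu(addb(x %*% par$enc_W1, par$enc_b1))
  h2 <- relu(addb(h1 %*% par$enc_W2, par$enc_b2))
  mu <- addb(h2 %*% par$enc_Wmu, par$enc_bmu)
  lv_raw <- addb(h2 %*% par$enc_Wlv, par$enc_blv)
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(h1 = h1, h2 = h2, mu = mu, lv = lv,
       clamp_mask = (lv_raw > -LOGVAR_CLAMP) & (lv_raw < LOGVAR_CLAMP),
       sigma = exp(0.5 * lv))
}

#' Encode cells into latent Gaussians
#'
#' Deterministic (evaluation-mode) pass through the shared encoder. The
#' encoder carries no dataset-specific parameters, so identical inputs from
#' different datasets map to identical posteriors.
#'
#' @param model A `coupled_vae` (see [init_coupled_vae()]) or [uotvae()] fit.
#' @param x Cell-by-common-gene matrix in \[0, 1\]; column count must equal
#'   the model's common-gene dimension.
#' @return A [latent_gaussian()] with `mu` and `sigma`.
#' @export
encode <- function(model, x) {
  model <- as_coupled_vae(model)
  x <- as.matrix(x)
  if (ncol(x) != model$dims$n_common)
    stop("input has ", ncol(x), " genes; encoder expects ",
         model$dims$n_common)
  fw <- encode_fwd(model$par, x)
  lg <- latent_gaussian(fw$mu, fw$sigma)
  rownames(lg$mu) <- rownames(x); rownames(lg$sigma) <- rownames(x)
  lg
}

#' Reparameterize a latent Gaussian
#'
#' Draws `z = mu + sigma * nu` with `nu ~ N(0, I)`. Supply `noise` to make
#' the draw explicit (e.g. for gradient checks); otherwise `nu` comes from
#' the current RNG state.
#'
#' @param lg A [latent_gaussian()].
#' @param noise Optional standard-normal matrix of matching dimension.
#' @return The [latent_gaussian()] with its `z` slot filled.
#' @export
reparameterize <- function(lg, noise = NULL) {
  stopifnot(inherits(lg, "latent_gaussian"))
  if (is.null(noise))
    noise <- matrix(stats::rnorm(length(lg$mu)), nrow(lg$mu), ncol(lg$mu))
  if (!all(dim(noise) == dim(lg$mu))) stop("noise dimension mismatch")
  lg$z <- lg$mu + lg$sigma * noise
  lg
}

# internal common-decoder forward; train_stats: use batch statistics and
# return caches; otherwise the branch's running statistics are used
decode_common_fwd <- function(par, bn, z, id, train_stats = FALSE) {
  u <- addb(z %*% par$dec_W, par$dec_b)
  g <- par[[paste0("bn_gamma_", id)]]
  be <- par[[paste0("bn_beta_", id)]]
  if (train_stats) {
    m <- colMeans(u)
    v <- colMeans(u^2) - m^2       # biased batch variance
    v <- pmax(v, 0)
  } else {
    m <- bn[[id]]$mean
    v <- bn[[id]]$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  uhat <- (u - rep(m, each = nrow(u))) * rep(inv, each = nrow(u))
  a <- addb(uhat * rep(g, each = nrow(u)), be)
  list(p = sigmoid(a), u = u, uhat = uhat, inv = inv, m = m, v = v)
}

#' Decode common genes through a dataset branch
#'
#' Linear map from the latent space, the dataset's batch-normalization
#' branch, then a sigmoid; output lies in (0, 1). In evaluation mode
#' (default) the branch's running statistics are used, so the output is
#' deterministic per cell.
#'
#' @param model A `coupled_vae` or [uotvae()] fit.
#' @param z Cell-by-K latent matrix.
#' @param dataset_id Registered dataset id selecting the DSBN branch.
#' @param train_mode Use batch statistics instead of running statistics.
#' @return Cell-by-common-gene matrix of reconstructions.
#' @export
decode_common <- function(model, z, dataset_id, train_mode = FALSE) {
  model <- as_coupled_vae(model)
  check_dataset_id(model, dataset_id)
  z <- as.matrix(z)
  if (ncol(z) != model$dims$latent_dim) stop("latent dimension mismatch")
  out <- decode_common_fwd(model$par, model$bn, z, dataset_id,
                           train_stats = train_mode)$p
  colnames(out) <- model$genes$common
  rownames(out) <- rownames(z)
  out
}

#' Decode dataset-specific genes
#'
#' Direct linear map from the latent space to the dataset's specific genes
#' followed by a sigmoid (no hidden layer, no batch normalization).
#'
#' @inheritParams decode_common
#' @return Cell-by-specific-gene matrix of reconstructions.
#' @export
decode_specific <- function(model, z, dataset_id) {
  model <- as_coupled_vae(model)
  check_dataset_id(model, dataset_id)
  z <- as.matrix(z)
  if (ncol(z) != model$dims$latent_dim) stop("latent dimension mismatch")
  out <- sigmoid(addb(z %*% model$par[[paste0("spec_W_", dataset_id)]],
                      model$par[[paste0("spec_b_", dataset_id)]]))
  colnames(out) <- model$genes$specific[[dataset_id]]
  rownames(out) <- rownames(z)
  out
}

check_dataset_id <- function(model, id) {
  if (!id %in% model$dataset_ids)
    stop("unknown dataset_id '", id, "'; registered: ",
         paste(model$dataset_ids, collapse = ", "))
}

as_coupled_vae <- function(x) {
  if (inherits(x, "uotvae_fit")) return(x$model)
  if (inherits(x, "coupled_vae")) return(x)
  stop("expected a coupled_vae or uotvae_fit object")
}

#' KL divergence of the posterior from the standard-normal prior
#'
#' Per cell, `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#' 0.5 * sum_d (mu_d^2 + sigma_d^2 - 1 - 2 log sigma_d)`; always >= 0, with
#' equality iff `mu = 0`, `sigma = 1`.
#'
#' @param lg A [latent_gaussian()], or a mean matrix when `sigma` is given.
#' @param sigma Optional standard-deviation matrix (when `lg` is a matrix).
#' @return Numeric vector of per-cell divergences.
#' @export
kl_gaussian <- function(lg, sigma = NULL) {
  if (inherits(lg, "latent_gaussian")) {
    mu <- lg$mu; sigma <- lg$sigma
  } else {
    mu <- as.matrix(lg)
  }
  if (any(sigma <= 0)) stop("`sigma` must be > 0")
  rowSums(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma)))
}

# binary cross-entropy, summed over features, per cell
bce_per_cell <- function(target, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -rowSums(target * log(p) + (1 - target) * log1p(-p))
}

#' Loss weights for the coupled VAE
#'
#' @param lambda_kl Weight on the KL regularizer (paper grid
#'   \{0.5, 1, 5\}; default 0.5).
#' @param lambda_s Weight on the specific-gene reconstruction terms (grid
#'   \{0.5, 1\}; default 0.5).
#' @param gamma Weight on the transport alignment loss (grid \{0.5, 1\};
#'   default 1).
#' @return A named list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_kl = 0.5, lambda_s = 0.5, gamma = 1) {
  stopifnot(lambda_kl >= 0, lambda_s >= 0, gamma >= 0,
            is.finite(lambda_kl), is.finite(lambda_s), is.finite(gamma))
  structure(list(lambda_kl = lambda_kl, lambda_s = lambda_s, gamma = gamma),
            class = "loss_weights")
}

#' Negative modified evidence lower bound
#'
#' The coupled-VAE objective on a joint minibatch:
#' \deqn{-ELBO^* = \sum_{d \in \{x, y\}} \mathrm{mean}_{cells}\big[
#'   BCE(d^c, \hat d^c) + \lambda_s BCE(d^s, \hat d^s)
#'   + \lambda\, KL_d \big]}
#' where each BCE is the Bernoulli negative log-likelihood summed over
#' features, each cell's common genes are reconstructed through its own
#' dataset's DSBN branch, and the KL is summed over latent dimensions.
#' Reduction is mean over cells within a dataset, summed across the two
#' datasets, so the weights keep their meaning for unequal batch sizes.
#'
#' @param x_common,y_common Target common-gene matrices in \[0, 1\].
#' @param x_specific,y_specific Target specific-gene matrices in \[0, 1\].
#' @param recon_common List with elements `x`, `y`: reconstructions in (0,1).
#' @param recon_specific List with elements `x`, `y`.
#' @param lg_x,lg_y [latent_gaussian()] posteriors of the two batches.
#' @param weights A [loss_weights()].
#' @return Scalar loss (the quantity minimized, i.e. \eqn{-ELBO^*}).
#' @export
elbo_star_loss <- function(x_common, y_common, x_specific, y_specific,
                           recon_common, recon_specific, lg_x, lg_y,
                           weights = loss_weights()) {
  for (m in list(x_common, y_common, x_specific, y_specific))
    if (any(m < 0) || any(m > 1)) stop("targets must lie in [0, 1]")
  term <- function(tc, ts, rc, rs, lg) {
    mean(bce_per_cell(tc, rc)) +
      weights$lambda_s * mean(bce_per_cell(ts, rs)) +
      weights$lambda_kl * mean(kl_gaussian(lg))
  }
  term(x_common, x_specific, recon_common$x, recon_specific$x, lg_x) +
    term(y_common, y_specific, recon_common$y, recon_specific$y, lg_y)
}

## ---------------------------------------------------------------------------
## Joint forward/backward pass for one training step.
##
## Returns the loss pieces, analytic gradients for every trainable parameter
## (same names as `par`), updated running batch-norm statistics, the
## minibatch plan and the posteriors. The transport plan is detached:
## gradients flow through the cost matrix only. `noise_x`/`noise_y` are the
## reparameterization draws, passed in so the pass is a deterministic
## function of its arguments (finite-difference checkable).
cvae_step <- function(par, bn, xc, xs, yc, ys, ids, weights, uot_cfg,
                      noise_x, noise_y, plan_init = NULL,
                      update_bn = TRUE) {
  grads <- lapply(par, function(p) p * 0)
  sides <- list(
    x = list(c = xc, s = xs, id = ids[1], noise = noise_x),
    y = list(c = yc, s = ys, id = ids[2], noise = noise_y))
  fw <- list()

  ## forward
  for (nm in names(sides)) {
    sd <- sides[[nm]]
    enc <- encode_fwd(par, sd$c)
    z <- enc$mu + enc$sigma * sd$noise
    dc <- decode_common_fwd(par, bn, z, sd$id, train_stats = TRUE)
    us <- addb(z %*% par[[paste0("spec_W_", sd$id)]],
               par[[paste0("spec_b_", sd$id)]])
    ps <- sigmoid(us)
    if (update_bn) {
      nB <- nrow(sd$c)
      unb <- if (nB > 1) nB / (nB - 1) else 1
      bn[[sd$id]]$mean <- (1 - BN_MOMENTUM) * bn[[sd$id]]$mean +
        BN_MOMENTUM * dc$m
      bn[[sd$id]]$var <- (1 - BN_MOMENTUM) * bn[[sd$id]]$var +
        BN_MOMENTUM * dc$v * unb
    }
    fw[[nm]] <- list(enc = enc, z = z, dc = dc, ps = ps)
  }

  ## transport plan on the posteriors (detached)
  Cm <- sqdist(fw$x$enc$mu, fw$y$enc$mu) +
    sqdist(fw$x$enc$sigma, fw$y$enc$sigma)
  plan <- solve_uot(Cm, a = uot_cfg$a, b = uot_cfg$b,
                    epsilon = uot_cfg$epsilon, rho = uot_cfg$rho,
                    recenter = isTRUE(uot_cfg$recenter),
                    outer_iters = if (is.null(uot_cfg$outer_iters))
                      { if (isTRUE(uot_cfg$recenter)) 20L else 500L }
                      else uot_cfg$outer_iters,
                    tol = if (is.null(uot_cfg$tol)) 1e-8 else uot_cfg$tol,
                    plan_init = plan_init)
  loss_uot <- sum(Cm * plan)

  ## loss pieces
  loss_elbo <- 0
  for (nm in names(sides)) {
    sd <- sides[[nm]]; f <- fw[[nm]]
    kl <- kl_gaussian(latent_gaussian(f$enc$mu, f$enc$sigma))
    loss_elbo <- loss_elbo + mean(bce_per_cell(sd$c, f$dc$p)) +
      weights$lambda_s * mean(bce_per_cell(sd$s, f$ps)) +
      weights$lambda_kl * mean(kl)
  }
  loss_total <- loss_elbo + weights$gamma * loss_uot

  ## backward
  rs <- rowSums(plan); cs <- colSums(plan)
  for (nm in names(sides)) {
    sd <- sides[[nm]]; f <- fw[[nm]]
    nB <- nrow(sd$c)
    enc <- f$enc

    # common reconstruction head (BCE + sigmoid + batch norm)
    dA <- (f$dc$p - sd$c) / nB
    g <- par[[paste0("bn_gamma_", sd$id)]]
    grads[[paste0("bn_gamma_", sd$id)]] <-
      grads[[paste0("bn_gamma_", sd$id)]] + colSums(dA * f$dc$uhat)
    grads[[paste0("bn_beta_", sd$id)]] <-
      grads[[paste0("bn_beta_", sd$id)]] + colSums(dA)
    duh <- dA * rep(g, each = nB)
    s1 <- colSums(duh); s2 <- colSums(duh * f$dc$uhat)
    dU <- (duh - rep(s1 / nB, each = nB) -
             f$dc$uhat * rep(s2 / nB, each = nB)) * rep(f$dc$inv, each = nB)
    grads$dec_W <- grads$dec_W + crossprod(f$z, dU)
    grads$dec_b <- grads$dec_b + colSums(dU)
    dz <- dU %*% t(par$dec_W)

    # specific reconstruction head
    dUs <- weights$lambda_s * (f$ps - sd$s) / nB
    grads[[paste0("spec_W_", sd$id)]] <-
      grads[[paste0("spec_W_", sd$id)]] + crossprod(f$z, dUs)
    grads[[paste0("spec_b_", sd$id)]] <-
      grads[[paste0("spec_b_", sd$id)]] + colSums(dUs)
    dz <- dz + dUs %*% t(par[[paste0("spec_W_", sd$id)]])

    # reparameterization: z = mu + sigma * nu
    dmu <- dz
    dsig <- dz * sd$noise

    # KL term
    dmu <- dmu + weights$lambda_kl * enc$mu / nB
    dlv_kl <- weights$lambda_kl * 0.5 * (enc$sigma^2 - 1) / nB

    # transport cost term (plan detached)
    if (nm == "x") {
      dmu <- dmu + weights$gamma * 2 * (enc$mu * rs - plan %*% fw$y$enc$mu)
      dsig <- dsig + weights$gamma * 2 *
        (enc$sigma * rs - plan %*% fw$y$enc$sigma)
    } else {
      dmu <- dmu + weights$gamma * 2 * (enc$mu * cs - crossprod(plan, fw$x$enc$mu))
      dsig <- dsig + weights$gamma * 2 *
        (enc$sigma * cs - crossprod(plan, fw$x$enc$sigma))
    }

    # sigma = exp(0.5 * lv), clamp gradient outside the logvar window
    dlv <- (dsig * 0.5 * enc$sigma + dlv_kl) * enc$clamp_mask

    # encoder heads and trunk
    grads$enc_Wmu <- grads$enc_Wmu + crossprod(enc$h2, dmu)
    grads$enc_bmu <- grads$enc_bmu + colSums(dmu)
    grads$enc_Wlv <- grads$enc_Wlv + crossprod(enc$h2, dlv)
    grads$enc_blv <- grads$enc_blv + colSums(dlv)
    dh2 <- (dmu %*% t(par$enc_Wmu) + dlv %*% t(par$enc_Wlv)) * (enc$h2 > 0)
    grads$enc_W2 <- grads$enc_W2 + crossprod(enc$h1, dh2)
    grads$enc_b2 <- grads$enc_b2 + colSums(dh2)
    dh1 <- (dh2 %*% t(par$enc_W2)) * (enc$h1 > 0)
    grads$enc_W1 <- grads$enc_W1 + crossprod(sd$c, dh1)
    grads$enc_b1 <- grads$enc_b1 + colSums(dh1)
  }

  list(loss_total = loss_total, loss_elbo = loss_elbo, loss_uot = loss_uot,
       grads = grads, bn = bn, plan = plan,
       lg_x = latent_gaussian(fw$x$enc$mu, fw$x$enc$sigma, fw$x$z),
       lg_y = latent_gaussian(fw$y$enc$mu, fw$y$enc$sigma, fw$y$z))
}
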