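# Small deterministic fixtures shared across test files.

toy_dataset <- function(m = NULL, id = "rna", types = NULL) {
  if (is.null(m)) {
    set.seed(101)
    m <- matrix(rpois(60, 3), 6, 10)
  }
  sc_dataset(m, id, cell_types = types)
}

small_sim <- function(seed = 5, ...) {
  simulate_multiome(n_cells = c(80, 80), n_celltypes = 3, latent_dim = 4,
                    n_common_genes = 40, n_specific_genes = c(20, 20),
                    seed = seed, ...)
}

small_partition <- function(seed = 5, ...) {
  sim <- small_sim(seed, ...)
  prepare_inputs(sim$x, sim$y, n_common_hvg = 40, n_specific_hvg = 20,
                 filter = FALSE)
}

small_fit <- function(seed = 5, iters = 40, ...) {
  gp <- small_partition(seed)
  uotvae(gp, hidden_dims = c(16, 8), latent_dim = 4,
         max_iterations = iters, patience = 1000, batch_size = 40,
         seed = seed, ...)
}

# unbalanced-transport objective of a plan (the quantity the solver minimizes)
uot_objective <- function(Tm, C, a, b, epsilon, rho) {
  gkl <- function(u, v) sum(u * log(u / v) - u + v)
  H <- -sum(Tm * (log(Tm) - 1))
  sum(C * Tm) - epsilon * H + rho * gkl(rowSums(Tm), a) +
    rho * gkl(colSums(Tm), b)
}

# independent numerical minimizer of the same objective (BFGS over log-plan)
uot_oracle <- function(C, a, b, epsilon, rho) {
  bx <- nrow(C); by <- ncol(C)
  fn <- function(th) uot_objective(matrix(exp(th), bx, by), C, a, b,
                                   epsilon, rho)
  gr <- function(th) {
    Tm <- matrix(exp(th), bx, by)
    g <- C + epsilon * log(Tm) + rho * log(rowSums(Tm) / a) +
      rep(rho * log(colSums(Tm) / b), each = bx)
    as.vector(g * Tm)
  }
  stats::optim(as.vector(log(outer(a, b))), fn, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))$value
}
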