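#' Latent Gaussian container
#'
#' Per-cell diagonal Gaussian posteriors: a mean matrix `mu`, a standard
#' deviation matrix `sigma` (both cells x latent dimensions) and, optionally,
#' a sampled latent matrix `z`.
#'
#' @param mu,sigma Numeric matrices of equal dimension; `sigma` must be
#'   strictly positive.
#' @param z Optional sampled latent matrix of the same dimension.
#' @return An object of class `latent_gaussian`.
#' @export
latent_gaussian <- function(mu, sigma, z = NULL) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  if (!all(dim(mu) == dim(sigma)))
    stop("`mu` and `sigma` must have identical dimensions")
  if (any(sigma <= 0)) stop("`sigma` must be > 0 elementwise")
  structure(list(mu = mu, sigma = sigma, z = z), class = "latent_gaussian")
}

#' @export
print.latent_gaussian <- function(x, ...) {
  cat(sprintf("<latent_gaussian> %d cells x %d dims%s\n", nrow(x$mu),
              ncol(x$mu), if (is.null(x$z)) "" else " (sampled)"))
  invisible(x)
}

# internal: pairwise squared Euclidean distances between rows of two matrices
sqdist <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

#' Transport cost between latent Gaussians
#'
#' `C[i, j] = ||mu_x[i,] - mu_y[j,]||^2 + ||sigma_x[i,] - sigma_y[j,]||^2`,
#' the squared 2-Wasserstein distance between the two diagonal Gaussian
#' posteriors.
#'
#' @param lg_x,lg_y [latent_gaussian()] batches with the same latent
#'   dimension.
#' @return Non-negative `nrow(lg_x$mu)` x `nrow(lg_y$mu)` cost matrix.
#' @export
gaussian_cost <- function(lg_x, lg_y) {
  stopifnot(inherits(lg_x, "latent_gaussian"), inherits(lg_y, "latent_gaussian"))
  if (ncol(lg_x$mu) != ncol(lg_y$mu))
    stop("latent dimensions differ: ", ncol(lg_x$mu), " vs ", ncol(lg_y$mu))
  sqdist(lg_x$mu, lg_y$mu) + sqdist(lg_x$sigma, lg_y$sigma)
}

#' Normalize user-supplied marginal weights
#'
#' Turns non-negative per-cell weights into the marginal vectors `a`, `b` of
#' the unbalanced transport problem (each normalized to sum 1). Used when
#' cell populations are not uniformly matched across datasets.
#'
#' @param weights_x,weights_y Non-negative numeric vectors, not all zero.
#' @return `list(a, b)` of normalized weights.
#' @export
set_marginal_weights <- function(weights_x, weights_y) {
  norm1 <- function(w, side) {
    if (any(w < 0)) stop("negative weights on side ", side)
    s <- sum(w)
    if (s <= 0) stop("weights on side ", side, " must not be all zero")
    w / s
  }
  list(a = norm1(weights_x, "x"), b = norm1(weights_y, "y"))
}

#' Solve the entropic unbalanced optimal-transport problem
#'
#' Computes the minibatch plan
#' \deqn{T^* = \arg\min_{T \ge 0} \langle C, T\rangle - \epsilon H(T)
#'   + \rho KL(T 1 \| a) + \rho KL(T^\top 1 \| b)}
#' with \eqn{H(T) = -\sum_{ij} T_{ij}(\log T_{ij} - 1)} by alternating
#' multiplicative scaling: \eqn{\alpha = (a / (G\beta))^{\rho/(\rho+\epsilon)}},
#' \eqn{\beta = (b / (G^\top\alpha))^{\rho/(\rho+\epsilon)}} (Gauss-Seidel
#' order), \eqn{T = \mathrm{diag}(\alpha)\, G \,\mathrm{diag}(\beta)}.
#'
#' With the default `recenter = FALSE` the kernel is fixed at
#' \eqn{G = e^{-C/\epsilon}} and the iteration converges to the unique
#' minimizer of the strictly convex objective above. `recenter = TRUE`
#' re-centers the kernel at the current plan after every outer iteration
#' (\eqn{G = T^{(l)} \odot e^{-C/\epsilon}}, the inexact proximal-point /
#' IPOT scheme), which anneals the entropic smoothing away and drives the
#' plan toward the unregularized unbalanced optimum; it is provided for
#' users who want sharper plans.
#'
#' @param C Non-negative cost matrix (see [gaussian_cost()]).
#' @param a,b Marginal weight vectors (default uniform `1/nrow`, `1/ncol`);
#'   see [set_marginal_weights()].
#' @param epsilon Entropic regularization strength (> 0, default 0.1).
#' @param rho Marginal relaxation strength (> 0, default 1); large values
#'   approach balanced entropic transport.
#' @param outer_iters Outer iterations; default 500 fixed-kernel sweeps, or
#'   20 proximal re-centerings when `recenter = TRUE`.
#' @param inner_iters Scaling sweeps per outer iteration (default 1).
#' @param tol Relative Frobenius change of the plan declaring convergence.
#' @param recenter Use the plan-recentered proximal kernel (default `FALSE`).
#' @param plan_init Optional initial plan (used by the re-centered scheme,
#'   e.g. a slice of a global plan); default `a %o% b`.
#' @return The converged plan `T*` (non-negative matrix), with attribute
#'   `"iterations"`.
#' @export
solve_uot <- function(C, a = NULL, b = NULL, epsilon = 0.1, rho = 1,
                      outer_iters = if (recenter) 20L else 500L,
                      inner_iters = 1L, tol = 1e-8, recenter = FALSE,
                      plan_init = NULL) {
  C <- as.matrix(C)
  if (any(!is.finite(C)) || any(C < 0)) stop("`C` must be finite and >= 0")
  if (epsilon <= 0 || rho <= 0) stop("`epsilon` and `rho` must be > 0")
  bx <- nrow(C); by <- ncol(C)
  if (is.null(a)) a <- rep(1 / bx, bx)
  if (is.null(b)) b <- rep(1 / by, by)
  if (length(a) != bx || length(b) != by) stop("marginal length mismatch")
  if (any(a <= 0) || any(b <= 0)) stop("marginals must be > 0")
  K <- exp(-C / epsilon)
  K <- pmax(K, 1e-300)
  if (!any(is.finite(K)) || max(K) <= 1e-300)
    stop(sprintf("kernel underflow: C/epsilon spans [%g, %g]",
                 min(C) / epsilon, max(C) / epsilon))
  f <- rho / (rho + epsilon)
  Tm <- if (is.null(plan_init)) outer(a, b) else as.matrix(plan_init)
  beta <- rep(1 / bx, by)
  iters <- 0L
  frob2 <- function(m) sum(m * m)
  # matvec results are clamped away from zero so partial kernel underflow
  # (cost entries far beyond epsilon's scale) cannot spin the scaling
  # vectors to Inf; in well-scaled problems the clamp is never active
  scale_up <- function(G, bta) (a / pmax(as.vector(G %*% bta), 1e-280))^f
  scale_dn <- function(G, alp) (b / pmax(as.vector(crossprod(G, alp)),
                                         1e-280))^f
  if (recenter) {
    # proximal scheme: re-center the kernel at the current plan, check the
    # plan's relative change after every outer iteration
    for (l in seq_len(outer_iters)) {
      G <- pmax(Tm * K, 1e-300)
      for (i in seq_len(inner_iters)) {
        alpha <- scale_up(G, beta)
        beta <- scale_dn(G, alpha)
      }
      Tn <- alpha * G * rep(beta, each = bx)
      rel2 <- frob2(Tn - Tm) / max(frob2(Tm), 1e-300)
      Tm <- Tn
      iters <- l
      if (rel2 < tol^2) break
    }
  } else {
    # fixed kernel: iterate only the scaling vectors; convergence is declared
    # on their relative change (which controls the plan change), and the plan
    # is formed once at the end
    check_every <- 10L
    l <- 0L
    max_sweeps <- outer_iters * inner_iters
    beta_chk <- beta
    while (l < max_sweeps) {
      for (i in seq_len(min(check_every, max_sweeps - l))) {
        alpha <- scale_up(K, beta)
        beta <- scale_dn(K, alpha)
        l <- l + 1L
      }
      rel <- max(abs(beta / beta_chk - 1))   # scale-free, overflow-safe
      beta_chk <- beta
      iters <- l
      if (rel < tol) break
    }
    Tm <- alpha * K * rep(beta, each = bx)
  }
  if (any(!is.finite(Tm)))
    stop(sprintf("non-finite plan after %d iterations (C/epsilon in [%g, %g])",
                 iters, min(C) / epsilon, max(C) / epsilon))
  attr(Tm, "iterations") <- iters
  Tm
}

#' Transport alignment loss
#'
#' `sum(C * T_star)`. During training the plan is treated as a constant:
#' gradients flow only through the cost matrix.
#'
#' @param C Cost matrix.
#' @param T_star Transport plan of matching dimension.
#' @return Scalar loss.
#' @export
uot_loss <- function(C, T_star) {
  if (!all(dim(C) == dim(T_star))) stop("dimension mismatch")
  sum(C * T_star)
}

#' Write a minibatch plan into the global plan
#'
#' Overwrites the `I` x `J` block of the accumulated global plan with the
#' converged minibatch plan; all other entries are untouched. The global plan
#' is initialized at `1/(n_x * n_y)` everywhere.
#'
#' @param T_global Global `n_x` x `n_y` plan.
#' @param T_B Minibatch plan (`length(I)` x `length(J)`).
#' @param I,J Duplicate-free row / column index vectors.
#' @return The updated global plan.
#' @export
update_global_plan <- function(T_global, T_B, I, J) {
  if (anyDuplicated(I) || anyDuplicated(J))
    stop("index sets must be duplicate-free")
  if (any(I < 1) || any(I > nrow(T_global)) ||
      any(J < 1) || any(J > ncol(T_global)))
    stop("indices out of range")
  if (nrow(T_B) != length(I) || ncol(T_B) != length(J))
    stop("minibatch plan dimension mismatch")
  T_global[I, J] <- T_B
  T_global
}

#' Export a global transport plan to disk
#'
#' Either a sparse MatrixMarket triplet after thresholding small entries, or
#' a dense CSV with cell-id row/column headers.
#'
#' @param T_global Plan matrix with rownames/colnames set to cell ids.
#' @param path Output path (`.mtx` or `.csv`).
#' @param mass_cutoff Entries `<= mass_cutoff` are dropped in MTX output
#'   (default 0).
#' @return `path`, invisibly.
#' @export
write_plan <- function(T_global, path, mass_cutoff = 0) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Tt <- T_global
    Tt[Tt <= mass_cutoff] <- 0
    Matrix::writeMM(methods::as(Matrix::Matrix(Tt, sparse = TRUE),
                                "generalMatrix"), path)
  } else if (ext == "csv") {
    df <- data.frame(cell_id = rownames(T_global), T_global,
                     check.names = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else stop("unsupported plan format '", ext, "'")
  invisible(path)
}
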