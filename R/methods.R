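#' @export
print.uotvae_fit <- function(x, ...) {
  cat("Coupled-VAE / unbalanced-OT integration fit\n")
  cat(sprintf("  datasets: %s (%d and %d cells)\n",
              paste(x$partition$dataset_ids, collapse = " + "),
              nrow(x$partition$X_c), nrow(x$partition$Y_c)))
  cat(sprintf("  genes: %d common, %s specific\n",
              length(x$partition$common_genes),
              paste(lengths(x$partition$specific_genes), collapse = "/")))
  cat(sprintf("  latent dim %d, encoder %s\n", x$config$latent_dim,
              paste(x$config$hidden_dims, collapse = "-")))
  cat(sprintf("  %d iterations%s; best epoch %d (loss %.4f)\n",
              x$iterations,
              if (x$stopped_early) " (early stop)" else "",
              x$best_epoch, x$best_loss))
  invisible(x)
}

#' @export
summary.uotvae_fit <- function(object, ...) {
  h <- object$history
  n <- nrow(h)
  tail_n <- min(50, n)
  out <- list(
    dataset_ids = object$partition$dataset_ids,
    n_cells = c(nrow(object$partition$X_c), nrow(object$partition$Y_c)),
    n_common = length(object$partition$common_genes),
    n_specific = lengths(object$partition$specific_genes),
    iterations = object$iterations,
    stopped_early = object$stopped_early,
    best_epoch = object$best_epoch,
    best_loss = object$best_loss,
    final_loss = mean(h$total[(n - tail_n + 1):n]),
    final_elbo_star = mean(h$elbo_star[(n - tail_n + 1):n]),
    final_uot = mean(h$uot[(n - tail_n + 1):n]),
    weights = object$config$weights,
    has_global_plan = !is.null(object$global_plan))
  class(out) <- "summary.uotvae_fit"
  out
}

#' @export
print.summary.uotvae_fit <- function(x, ...) {
  cat("Coupled-VAE / unbalanced-OT integration fit\n\n")
  cat(sprintf("Datasets: %s with %d / %d cells\n",
              paste(x$dataset_ids, collapse = ", "),
              x$n_cells[1], x$n_cells[2]))
  cat(sprintf("Genes: %d common, %s specific\n", x$n_common,
              paste(x$n_specific, collapse = " / ")))
  cat(sprintf("Training: %d iterations%s, best epoch %d\n", x$iterations,
              if (x$stopped_early) " (early stop)" else "", x$best_epoch))
  cat(sprintf("Loss (mean of last %s iters): total %.4f = -ELBO* %.4f + %g x UOT %.4f\n",
              "50", x$final_loss, x$final_elbo_star,
              x$weights$gamma, x$final_uot))
  if (x$has_global_plan) cat("Global transport plan: accumulated\n")
  invisible(x)
}

#' @export
coef.uotvae_fit <- function(object, ...) object$model$par

#' Predict from a fitted integration model
#'
#' @param object A [uotvae()] fit.
#' @param newdata Cell-by-common-gene matrix in \[0, 1\] (columns matched by
#'   name to the model's common genes when named). Default: the stored
#'   training matrix of `dataset_id`.
#' @param dataset_id Dataset id selecting the stored data and, for
#'   reconstruction types, the decoder branch.
#' @param type `"latent"` (posterior means; the integrated embedding),
#'   `"common"` (reconstructed common genes through the dataset's DSBN
#'   branch) or `"specific"` (the dataset's specific genes).
#' @param ... Unused.
#' @return A numeric matrix of the requested quantity.
#' @export
predict.uotvae_fit <- function(object, newdata = NULL, dataset_id = NULL,
                               type = c("latent", "common", "specific"),
                               ...) {
  type <- match.arg(type)
  if (is.null(dataset_id)) {
    if (type != "latent")
      stop("`dataset_id` is required for reconstruction predictions")
    if (is.null(newdata)) stop("supply `newdata` or `dataset_id`")
  }
  if (is.null(newdata))
    newdata <- training_matrix(object, dataset_id, "common")
  if (type == "latent") return(embed_cells(object, newdata))
  z <- embed_cells(object, newdata)
  if (type == "common") decode_common(object, z, dataset_id)
  else decode_specific(object, z, dataset_id)
}

#' Reconstruction residuals
#'
#' Training-data residuals `observed - reconstructed` for one dataset's
#' common genes (evaluation mode).
#'
#' @param object A [uotvae()] fit.
#' @param dataset_id Which dataset.
#' @param ... Unused.
#' @return Cell-by-gene residual matrix.
#' @export
residuals.uotvae_fit <- function(object, dataset_id = NULL, ...) {
  if (is.null(dataset_id)) dataset_id <- object$partition$dataset_ids[1]
  obs <- training_matrix(object, dataset_id, "common")
  obs - predict(object, dataset_id = dataset_id, type = "common")
}

#' Plot training loss history
#'
#' Per-iteration total loss, the negative modified evidence lower bound and
#' the (gamma-weighted) transport loss.
#'
#' @param x A [uotvae()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.uotvae_fit <- function(x, ...) {
  h <- x$history
  g <- x$config$weights$gamma
  graphics::matplot(h$iteration, cbind(h$total, h$elbo_star, g * h$uot),
                    type = "l", lty = 1, col = c("black", "steelblue",
                                                 "firebrick"),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", c("total", "-ELBO*", "gamma x UOT"),
                   col = c("black", "steelblue", "firebrick"), lty = 1,
                   bty = "n")
  invisible(x)
}
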