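#' Simulate an unpaired (or paired) two-modality dataset
#'
#' Generates two cell-by-gene count matrices sharing latent cell populations,
#' the ground truth needed to validate every stage of the pipeline. Each cell
#' type has a latent centroid in a `latent_dim`-dimensional state space; a
#' cell's state is its centroid plus isotropic Gaussian noise. Common genes
#' load both modalities through one shared non-negative loading matrix;
#' specific genes load only their own modality. Modality `y` additionally
#' passes through a monotone gene-wise gain distortion and an additive
#' gene-wise shift on the log scale, both scaled by `batch_effect_scale`,
#' emulating a systematic modality/batch effect. Counts are Poisson draws
#' from the exp-link means, thinned by Bernoulli dropout. Cell types listed
#' in `removed_celltypes` are dropped from the stated modality, creating
#' unbalanced populations. With `paired = TRUE` the same latent draws (and
#' row order) are used for both modalities, enabling FOSCTTM evaluation.
#'
#' @param n_cells Length-2 vector of cells per modality (default 600, 600).
#' @param n_celltypes Number of cell types (default 3).
#' @param latent_dim Latent state dimension (default 10).
#' @param n_common_genes Number of shared genes (default 300).
#' @param n_specific_genes Length-2 vector of modality-specific genes
#'   (default 150, 150).
#' @param batch_effect_scale Standard deviation of the log-scale shift and
#'   strength of the gain distortion on modality `y` (default 0.5).
#' @param dropout_rate Bernoulli dropout probability in \[0, 1) (default
#'   0.3).
#' @param removed_celltypes List with optional elements `x` and/or `y` naming
#'   cell types to drop from that modality.
#' @param paired Use identical latent draws for both modalities (default
#'   `FALSE`; forces equal cell counts).
#' @param seed Optional seed (the caller's RNG state is restored).
#' @param centroid_sd,cell_noise_sd Latent geometry: centroid spread and
#'   within-type noise (defaults 1 and 0.4).
#' @param base_log_mean Mean of the gene intercepts on the log scale
#'   (default `log(50)`), setting the count depth; deep enough that Poisson
#'   noise does not drown the latent signal.
#' @param loading_scale Multiplier on the half-normal gene loadings
#'   (default 2).
#' @return `list(x, y, ground_truth)` where `x`, `y` are [sc_dataset()]s
#'   (genes named `cg*`, `xs*` / `ys*`; cell types attached) and
#'   `ground_truth` carries the latent states, labels, pairing, loadings,
#'   intercepts and distortion parameters.
#' @export
simulate_multiome <- function(n_cells = c(600, 600), n_celltypes = 3,
                              latent_dim = 10, n_common_genes = 300,
                              n_specific_genes = c(150, 150),
                              batch_effect_scale = 0.5, dropout_rate = 0.3,
                              removed_celltypes = list(), paired = FALSE,
                              seed = NULL, centroid_sd = 1,
                              cell_noise_sd = 0.4, base_log_mean = log(50),
                              loading_scale = 2) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)")
  types <- paste0("type", seq_len(n_celltypes))
  bad <- setdiff(unlist(removed_celltypes), types)
  if (length(bad)) stop("removed_celltypes not in the celltype set: ",
                        paste(bad, collapse = ", "))
  if (paired && n_cells[1] != n_cells[2])
    stop("paired simulation requires equal cell counts")
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  centroids <- matrix(stats::rnorm(n_celltypes * latent_dim, sd = centroid_sd),
                      n_celltypes, latent_dim)
  draw_latent <- function(n) {
    lab <- sample(types, n, replace = TRUE)
    z <- centroids[match(lab, types), , drop = FALSE] +
      matrix(stats::rnorm(n * latent_dim, sd = cell_noise_sd), n, latent_dim)
    list(z = z, lab = lab)
  }
  lx <- draw_latent(n_cells[1])
  ly <- if (paired) lx else draw_latent(n_cells[2])

  half_normal <- function(d, g)
    matrix(abs(stats::rnorm(d * g)) * loading_scale / sqrt(d), d, g)
  W_common <- half_normal(latent_dim, n_common_genes)
  W_sx <- half_normal(latent_dim, n_specific_genes[1])
  W_sy <- half_normal(latent_dim, n_specific_genes[2])
  ic <- stats::rnorm(n_common_genes, base_log_mean, 0.3)
  isx <- stats::rnorm(n_specific_genes[1], base_log_mean, 0.3)
  isy <- stats::rnorm(n_specific_genes[2], base_log_mean, 0.3)
  shift <- stats::rnorm(n_common_genes, 0, batch_effect_scale)
  gain <- stats::runif(n_common_genes, 1 - 0.25 * batch_effect_scale,
                       1 + 0.25 * batch_effect_scale)

  counts <- function(log_mean, dropout) {
    n <- nrow(log_mean); g <- ncol(log_mean)
    m <- matrix(stats::rpois(n * g, exp(log_mean)), n, g)
    if (dropout > 0)
      m <- m * matrix(stats::rbinom(n * g, 1, 1 - dropout), n, g)
    m
  }
  lm_xc <- addb(lx$z %*% W_common, ic)
  lm_xs <- addb(lx$z %*% W_sx, isx)
  lm_yc <- addb((ly$z %*% W_common) * rep(gain, each = nrow(ly$z)), ic + shift)
  lm_ys <- addb(ly$z %*% W_sy, isy)

  gx <- c(paste0("cg", seq_len(n_common_genes)),
          paste0("xs", seq_len(n_specific_genes[1])))
  gy <- c(paste0("cg", seq_len(n_common_genes)),
          paste0("ys", seq_len(n_specific_genes[2])))
  mx <- cbind(counts(lm_xc, dropout_rate), counts(lm_xs, dropout_rate))
  my <- cbind(counts(lm_yc, dropout_rate), counts(lm_ys, dropout_rate))
  colnames(mx) <- gx; colnames(my) <- gy
  rownames(mx) <- paste0("x_cell", seq_len(nrow(mx)))
  rownames(my) <- paste0("y_cell", seq_len(nrow(my)))

  keep_x <- !(lx$lab %in% removed_celltypes$x)
  keep_y <- !(ly$lab %in% removed_celltypes$y)
  pairing <- if (paired) which(keep_x & keep_y) else NULL
  ds_x <- sc_dataset(mx[keep_x, , drop = FALSE], "x",
                     cell_types = lx$lab[keep_x])
  ds_y <- sc_dataset(my[keep_y, , drop = FALSE], "y",
                     cell_types = ly$lab[keep_y])

  list(x = ds_x, y = ds_y,
       ground_truth = list(
         latent_x = lx$z[keep_x, , drop = FALSE],
         latent_y = ly$z[keep_y, , drop = FALSE],
         labels_x = lx$lab[keep_x], labels_y = ly$lab[keep_y],
         pairing = pairing, centroids = centroids,
         W_common = W_common, W_specific_x = W_sx, W_specific_y = W_sy,
         intercept_common = ic, intercept_specific_x = isx,
         intercept_specific_y = isy, shift_y = shift, gain_y = gain,
         celltypes = types, paired = paired))
}

#' Simulate spatial spots as mixtures of profiled cells
#'
#' Builds pseudo-spots by summing the count profiles of randomly drawn cells
#' from a reference [sc_dataset()], recording the true cell-type composition
#' of every spot — the ground truth for deconvolution benchmarks.
#'
#' @param reference An [sc_dataset()] with `cell_types` set (e.g. the `x`
#'   modality of [simulate_multiome()]).
#' @param n_spots Number of spots (default 100).
#' @param cells_per_spot Length-2 range; each spot draws a uniform number of
#'   cells in this range, with replacement across spots (default 5-15).
#' @param seed Optional seed (caller's RNG state restored).
#' @return `list(spots, proportions, members)`: an [sc_dataset()] of spot
#'   profiles (dataset id `"spot"`), the true spot-by-celltype proportion
#'   matrix (rows summing to 1) and the list of member cell indices.
#' @export
simulate_spots <- function(reference, n_spots = 100,
                           cells_per_spot = c(5, 15), seed = NULL) {
  stopifnot(inherits(reference, "sc_dataset"))
  if (is.null(reference$cell_types))
    stop("`reference` must carry cell_types")
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  m <- dense_matrix(reference)
  types <- sort(unique(reference$cell_types))
  members <- vector("list", n_spots)
  spots <- matrix(0, n_spots, ncol(m),
                  dimnames = list(paste0("spot", seq_len(n_spots)),
                                  colnames(m)))
  props <- matrix(0, n_spots, length(types),
                  dimnames = list(rownames(spots), types))
  for (s in seq_len(n_spots)) {
    k <- sample(seq(cells_per_spot[1], cells_per_spot[2]), 1)
    idx <- sample.int(nrow(m), k, replace = FALSE)
    members[[s]] <- idx
    spots[s, ] <- colSums(m[idx, , drop = FALSE])
    tb <- table(factor(reference$cell_types[idx], levels = types))
    props[s, ] <- as.numeric(tb) / k
  }
  list(spots = sc_dataset(spots, "spot"), proportions = props,
       members = members)
}
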