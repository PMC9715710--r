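#' Filter cells and genes by detection thresholds
#'
#' Removes cells with fewer than `min_genes_per_cell` detected (nonzero)
#' genes, then genes detected in fewer than `min_cells_per_gene` of the
#' surviving cells. Thresholds use strict "fewer than" semantics, so a cell
#' with exactly `min_genes_per_cell` detected genes is kept. The gene filter
#' is applied after the cell filter and the original ordering of survivors is
#' preserved.
#'
#' @param ds An [sc_dataset()].
#' @param min_genes_per_cell Minimum number of detected genes per cell
#'   (default 200).
#' @param min_cells_per_gene Minimum number of cells a gene must be detected
#'   in (default 3).
#' @return The filtered [sc_dataset()].
#' @export
filter_cells_genes <- function(ds, min_genes_per_cell = 200,
                               min_cells_per_gene = 3) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    stop("thresholds must be >= 0")
  nz <- ds$matrix != 0
  keep_cells <- which(Matrix::rowSums(nz) >= min_genes_per_cell)
  if (length(keep_cells) == 0L)
    stop("all cells filtered: no cell has >= ", min_genes_per_cell,
         " detected genes")
  nz <- nz[keep_cells, , drop = FALSE]
  keep_genes <- which(Matrix::colSums(nz) >= min_cells_per_gene)
  if (length(keep_genes) == 0L)
    stop("all genes filtered: no gene is detected in >= ",
         min_cells_per_gene, " cells")
  subset_dataset(ds, cells = keep_cells, genes = keep_genes)
}

#' Normalize per-cell total counts
#'
#' Rescales each cell so its counts sum to `target_sum`. With
#' `target_sum = "auto"` the target is the median of the pre-normalization
#' per-cell totals (computed over cells with nonzero totals). All-zero cells
#' are left unchanged.
#'
#' @param ds An [sc_dataset()] with non-negative entries.
#' @param target_sum Positive number, or `"auto"` (default).
#' @return The normalized [sc_dataset()].
#' @export
normalize_total <- function(ds, target_sum = "auto") {
  stopifnot(inherits(ds, "sc_dataset"))
  totals <- Matrix::rowSums(ds$matrix)
  if (any(totals < 0)) stop("negative entries are not allowed")
  if (identical(target_sum, "auto")) {
    pos <- totals[totals > 0]
    if (length(pos) == 0L) return(ds)
    target_sum <- stats::median(pos)
  }
  if (!is.numeric(target_sum) || target_sum <= 0)
    stop("`target_sum` must be positive or \"auto\"")
  fac <- ifelse(totals > 0, target_sum / totals, 0)
  m <- ds$matrix
  if (methods::is(m, "sparseMatrix")) {
    m <- Matrix::Diagonal(x = fac) %*% m
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- dimnames(ds$matrix)
  } else {
    m <- m * fac
  }
  # zero rows stay zero (fac = 0 there, values already 0)
  ds$matrix <- m
  ds
}

#' Log-transform with an offset of 1
#'
#' Elementwise natural `log(1 + x)`; the standard variance-stabilizing step
#' applied after total-count normalization.
#'
#' @param ds An [sc_dataset()] with non-negative entries.
#' @return The transformed [sc_dataset()].
#' @export
log1p_transform <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  m <- ds$matrix
  if (methods::is(m, "sparseMatrix")) {
    m@x <- log1p(m@x)
  } else {
    if (any(m < 0)) stop("negative entries are not allowed")
    m <- log1p(m)
  }
  ds$matrix <- m
  ds
}

# internal: per-gene normalized dispersion on log1p-transformed data
# (the widely used "seurat" flavor: statistics on expm1-backtransformed
# values, dispersion = var/mean, z-scored within 20 quantile bins of the mean)
dispersion_zscores <- function(mat, n_bins = 20) {
  n <- nrow(mat)
  e <- expm1(as.matrix(mat))
  mu <- colMeans(e)
  v <- if (n > 1) (colSums(e^2) - n * mu^2) / (n - 1) else rep(0, ncol(e))
  v <- pmax(v, 0)
  disp <- ifelse(mu > 0, v / mu, 0)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
         else factor(rep(1L, length(mu)))
  bm <- tapply(disp, bin, mean)[bin]
  bs <- tapply(disp, bin, stats::sd)[bin]
  z <- (disp - bm) / bs
  z[!is.finite(z)] <- 0
  names(z) <- colnames(mat)
  z
}

#' Select highly variable genes
#'
#' Ranks genes by a mean-binned normalized dispersion computed on
#' log-normalized data (statistics taken on `expm1`-backtransformed values,
#' dispersion = variance/mean, z-scored within 20 quantile bins of the mean).
#' With `shared_with` supplied, candidates are restricted to the gene-id
#' intersection of the two datasets, the dispersion z-score is computed in
#' each dataset separately and genes are ranked by the sum of their
#' per-dataset ranks — the "highly variable common genes" used as the shared
#' encoder input. Ties are broken by lexicographic gene id, so the selection
#' is deterministic and invariant to cell order.
#'
#' @param ds An [sc_dataset()] holding log-normalized values.
#' @param n_top Number of genes to select (default 2000).
#' @param shared_with Optional second [sc_dataset()]; restricts candidates to
#'   the intersection and combines scores across the two datasets.
#' @param n_bins Number of mean bins for dispersion normalization.
#' @return Character vector of selected gene ids, most variable first.
#' @export
select_hvg <- function(ds, n_top = 2000, shared_with = NULL, n_bins = 20) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (n_top < 1) stop("`n_top` must be >= 1")
  if (is.null(shared_with)) {
    cand <- ds$gene_ids
    if (length(cand) == 0L) stop("no candidate genes")
    z <- dispersion_zscores(ds$matrix, n_bins)
    ord <- order(-z, names(z))
    ranked <- names(z)[ord]
  } else {
    stopifnot(inherits(shared_with, "sc_dataset"))
    cand <- intersect(ds$gene_ids, shared_with$gene_ids)
    if (length(cand) == 0L) stop("no candidate genes in the intersection")
    z1 <- dispersion_zscores(ds$matrix[, cand, drop = FALSE], n_bins)
    z2 <- dispersion_zscores(shared_with$matrix[, cand, drop = FALSE], n_bins)
    r1 <- seq_along(cand)[order(order(-z1, cand))]
    r2 <- seq_along(cand)[order(order(-z2, cand))]
    comb <- r1 + r2
    ranked <- cand[order(comb, cand)]
  }
  if (length(ranked) < n_top) {
    warning("only ", length(ranked), " candidate genes available (asked for ",
            n_top, "); returning all")
    n_top <- length(ranked)
  }
  ranked[seq_len(n_top)]
}

#' Scale each gene to the range 0-1
#'
#' Divides every gene column by its maximum absolute value; all-zero columns
#' are left unchanged. With non-negative input the result lies in \[0, 1\],
#' the range required by the Bernoulli decoders.
#'
#' @param ds An [sc_dataset()].
#' @return The scaled [sc_dataset()] (dense matrix).
#' @export
maxabs_scale <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  m <- dense_matrix(ds)
  mx <- apply(abs(m), 2, max)
  fac <- ifelse(mx > 0, 1 / mx, 1)
  ds$matrix <- sweep(m, 2, fac, "*")
  ds
}

#' TF-IDF weighting followed by truncated SVD (LSI)
#'
#' Utility for peak-level chromatin accessibility: term frequency per cell
#' times log inverse document frequency per peak,
#' `IDF = log(1 + n_cells / (1 + n_cells_with_peak))`, followed by a
#' truncated singular-value decomposition. Returns the cell embedding
#' `U[, 1:n] %*% diag(d[1:n])`. Not on the default training path.
#'
#' @param ds An [sc_dataset()] with a binary or count peak matrix.
#' @param n_components Number of SVD components; must be smaller than both
#'   matrix dimensions.
#' @return Cell-by-component numeric matrix.
#' @export
tfidf_lsi <- function(ds, n_components = 50) {
  stopifnot(inherits(ds, "sc_dataset"))
  m <- dense_matrix(ds)
  if (n_components >= min(dim(m)))
    stop("`n_components` must be < min(dim(matrix))")
  rs <- rowSums(m)
  tf <- m / ifelse(rs > 0, rs, 1)
  idf <- log(1 + nrow(m) / (1 + colSums(m != 0)))
  x <- sweep(tf, 2, idf, "*")
  sv <- svd(x, nu = n_components, nv = 0)
  emb <- sv$u * rep(sv$d[seq_len(n_components)], each = nrow(m))
  rownames(emb) <- ds$cell_ids
  emb
}

#' Prepare model inputs from two raw datasets
#'
#' Runs the fixed preprocessing pipeline on each dataset — filter (optional)
#' -> total-count normalization -> log1p -> highly-variable-gene selection ->
#' per-gene 0-1 scaling — and assembles the common-gene and dataset-specific
#' views the coupled VAE consumes.
#'
#' @param x,y Two [sc_dataset()]s with distinct `dataset_id`s.
#' @param n_common_hvg Number of highly variable common genes (default 2000).
#' @param n_specific_hvg Number of dataset-specific highly variable genes per
#'   dataset (default 2000).
#' @param min_genes_per_cell,min_cells_per_gene Detection filters applied
#'   when `filter = TRUE` (defaults 200 and 3).
#' @param filter Apply [filter_cells_genes()] first? Default `TRUE`.
#' @param target_sum Passed to [normalize_total()].
#' @return An object of class `gene_partition`: common gene list, per-dataset
#'   specific gene lists, and the scaled submatrices `X_c`, `Y_c`, `X_s`,
#'   `Y_s` (values in \[0, 1\]; `X_c` and `Y_c` share column order), plus the
#'   processed datasets and their cell types.
#' @export
prepare_inputs <- function(x, y, n_common_hvg = 2000, n_specific_hvg = 2000,
                           min_genes_per_cell = 200, min_cells_per_gene = 3,
                           filter = TRUE, target_sum = "auto") {
  stopifnot(inherits(x, "sc_dataset"), inherits(y, "sc_dataset"))
  if (identical(x$dataset_id, y$dataset_id))
    stop("the two datasets must have distinct dataset_ids")
  pipe <- function(ds) {
    if (filter) ds <- filter_cells_genes(ds, min_genes_per_cell,
                                         min_cells_per_gene)
    ds <- normalize_total(ds, target_sum)
    log1p_transform(ds)
  }
  x <- pipe(x); y <- pipe(y)
  common <- select_hvg(x, n_common_hvg, shared_with = y)
  spec_x <- select_hvg(x, n_specific_hvg)
  spec_y <- select_hvg(y, n_specific_hvg)
  sx <- maxabs_scale(subset_dataset(x, genes = match(common, x$gene_ids)))
  sy <- maxabs_scale(subset_dataset(y, genes = match(common, y$gene_ids)))
  ssx <- maxabs_scale(subset_dataset(x, genes = match(spec_x, x$gene_ids)))
  ssy <- maxabs_scale(subset_dataset(y, genes = match(spec_y, y$gene_ids)))
  structure(
    list(common_genes = common,
         specific_genes = stats::setNames(list(spec_x, spec_y),
                                          c(x$dataset_id, y$dataset_id)),
         X_c = sx$matrix, Y_c = sy$matrix,
         X_s = ssx$matrix, Y_s = ssy$matrix,
         dataset_ids = c(x$dataset_id, y$dataset_id),
         cell_types = stats::setNames(list(x$cell_types, y$cell_types),
                                      c(x$dataset_id, y$dataset_id)),
         cell_ids = stats::setNames(list(x$cell_ids, y$cell_ids),
                                    c(x$dataset_id, y$dataset_id))),
    class = "gene_partition"
  )
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf(paste0("<gene_partition> %d common genes; specific: %s\n",
                     "  %s: %d cells, %s: %d cells\n"),
              length(x$common_genes),
              paste(sprintf("%s=%d", names(x$specific_genes),
                            lengths(x$specific_genes)), collapse = ", "),
              x$dataset_ids[1], nrow(x$X_c), x$dataset_ids[2], nrow(x$Y_c)))
  invisible(x)
}
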