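## Integration-quality metrics, computed on a caller-supplied embedding
## (typically the latent posterior means or a 2-D UMAP of them; this package
## never computes UMAP itself).

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions:
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])` evaluated through the standard
#' contingency-table formula. 1 for identical partitions, ~0 for random
#' labelling; invariant to applying one permutation to both label vectors.
#'
#' @param truth,pred Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label length mismatch")
  tab <- table(truth, pred)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(truth))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' `NMI(U, V) = 2 I(U; V) / (H(U) + H(V))` with Shannon entropies in nats.
#' Defined as 0 when either partition is a single class (degenerate entropy).
#'
#' @inheritParams adjusted_rand_index
#' @return Scalar in \[0, 1\].
#' @export
normalized_mutual_info <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label length mismatch")
  n <- length(truth)
  tab <- table(truth, pred) / n
  pu <- rowSums(tab); pv <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hu <- ent(pu); hv <- ent(pv)
  if (hu == 0 || hv == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pu, pv)[nz]))
  2 * mi / (hu + hv)
}

#' Macro-averaged F1 score
#'
#' Per class, `F1 = 2PR/(P+R)` from precision and recall (0 when undefined),
#' averaged over the union of observed classes.
#'
#' @inheritParams adjusted_rand_index
#' @return Scalar in \[0, 1\].
#' @export
macro_f1 <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label length mismatch")
  classes <- sort(union(unique(truth), unique(pred)))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(f1s)
}

# deterministic k-nearest-neighbour classifier (majority vote; distance ties
# resolved by index order, vote ties by lexicographic class order)
knn_predict <- function(ref, labels, query, k) {
  d2 <- sqdist(query, ref)
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- table(labels[nn])
    min(names(votes)[votes == max(votes)])
  })
}

#' kNN label-transfer scores
#'
#' Fits a k-nearest-neighbour classifier on the reference embedding and its
#' cell-type labels, predicts the query cells' types in the same space, and
#' scores the prediction against the query's own annotations with ARI, NMI
#' and macro-averaged F1 — the standard readout of whether an integration
#' placed matching populations together.
#'
#' @param ref_embedding,query_embedding Matrices in the same space.
#' @param ref_labels,query_labels Cell-type labels.
#' @param k_neighbors Neighbourhood size (default 5).
#' @return Named numeric vector `c(ari, nmi, f1)`, with the predicted labels
#'   as attribute `"predicted"`.
#' @export
knn_transfer_scores <- function(ref_embedding, ref_labels,
                                query_embedding, query_labels,
                                k_neighbors = 5) {
  ref_embedding <- as.matrix(ref_embedding)
  query_embedding <- as.matrix(query_embedding)
  if (length(ref_labels) != nrow(ref_embedding) ||
      length(query_labels) != nrow(query_embedding))
    stop("label/embedding length mismatch")
  if (!length(intersect(unique(ref_labels), unique(query_labels))))
    warning("reference and query label sets are disjoint; ",
            "scores computed on the union")
  pred <- knn_predict(ref_embedding, as.character(ref_labels),
                      query_embedding, k_neighbors)
  out <- c(ari = adjusted_rand_index(query_labels, pred),
           nmi = normalized_mutual_info(query_labels, pred),
           f1 = macro_f1(query_labels, pred))
  attr(out, "predicted") <- pred
  out
}

#' Scaled silhouette coefficient
#'
#' Mean over cells of `(b - a) / max(a, b)` — `a` the mean distance to the
#' cell's own cluster, `b` the smallest mean distance to another cluster —
#' rescaled to \[0, 1\] via `(s + 1) / 2`. Computed over cell-type labels to
#' quantify separation of biological populations after integration. The 0/0
#' case (all points identical) is taken as 0, giving 0.5 after rescaling.
#'
#' @param embedding Numeric matrix of cells.
#' @param labels Cluster (cell-type) labels; at least two clusters, each with
#'   at least two members.
#' @return Scalar in \[0, 1\].
#' @export
silhouette_scaled <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  if (length(labels) != nrow(embedding)) stop("label length mismatch")
  cls <- unique(labels)
  if (length(cls) < 2) stop("silhouette needs >= 2 clusters")
  if (any(table(labels) < 2)) stop("every cluster needs >= 2 members")
  d <- sqrt(sqdist(embedding, embedding))
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- sum(d[i, own]) / (sum(own) - 1)      # exclude self
    b <- min(vapply(cls[cls != labels[i]],
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    m <- max(a, b)
    if (m == 0) 0 else (b - a) / m
  }, numeric(1))
  mean((s + 1) / 2)
}

#' Batch entropy score
#'
#' Regional dataset-mixing entropy: restricted to cells of cell types shared
#' across batches (when a mask is given), `n_probes` cells are sampled; for
#' each, the batch proportions `p_i` in its `k_neighbors`-nearest-neighbour
#' region are corrected by the global batch proportions `P_i`,
#' `p'_i = (p_i / P_i) / sum(p_i / P_i)`, and the region's entropy
#' `E = sum p'_i log p'_i` is accumulated. The reported score is the mean of
#' `-E / log(n_batches)` over probes, so perfect mixing scores 1 and pure
#' regions score 0.
#'
#' @param embedding Numeric matrix of cells.
#' @param batch_ids Dataset-of-origin labels (>= 2 batches).
#' @param common_celltype_mask Optional logical vector restricting the
#'   computation to cells of cell types present in every batch.
#' @param n_probes Number of sampled probe cells (default 100).
#' @param k_neighbors Region size (default 50).
#' @param seed Optional seed for probe sampling.
#' @return Scalar in \[0, 1\].
#' @export
batch_entropy <- function(embedding, batch_ids, common_celltype_mask = NULL,
                          n_probes = 100, k_neighbors = 50, seed = NULL) {
  embedding <- as.matrix(embedding)
  batch_ids <- as.character(batch_ids)
  if (length(batch_ids) != nrow(embedding)) stop("batch length mismatch")
  if (!is.null(common_celltype_mask)) {
    embedding <- embedding[common_celltype_mask, , drop = FALSE]
    batch_ids <- batch_ids[common_celltype_mask]
  }
  n <- nrow(embedding)
  batches <- sort(unique(batch_ids))
  if (length(batches) < 2) stop("need >= 2 batches")
  if (n < k_neighbors) stop("fewer cells (", n, ") than k_neighbors")
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  Pg <- table(factor(batch_ids, levels = batches)) / n
  probes <- sample.int(n, min(n_probes, n))
  d2 <- sqdist(embedding[probes, , drop = FALSE], embedding)
  scores <- vapply(seq_along(probes), function(i) {
    nn <- order(d2[i, ])[seq_len(k_neighbors)]
    p <- table(factor(batch_ids[nn], levels = batches)) / k_neighbors
    pp <- (p / Pg); pp <- pp / sum(pp)
    pp <- pp[pp > 0]
    -sum(pp * log(pp)) / log(length(batches))
  }, numeric(1))
  mean(scores)
}

#' Fraction of samples closer than the true match
#'
#' For row-paired embeddings `z_x`, `z_y` (row `i` of each is the same cell
#' measured in the two modalities), counts how many cells sit closer to a
#' query than its true cross-modality match:
#' `s_i = #\{j: d(z_x[j], z_y[i]) < d(z_x[i], z_y[i])\}`,
#' `t_i = #\{j: d(z_x[i], z_y[j]) < d(z_x[i], z_y[i])\}`, and
#' `FOSCTTM = (sum s_i / n + sum t_i / n) / (2n)` with Euclidean distances.
#' 0 is perfect correspondence; 0.5 is the random-embedding expectation.
#'
#' @param z_x,z_y Row-paired embedding matrices with equal row counts.
#' @return Scalar in \[0, 1\].
#' @export
foscttm <- function(z_x, z_y) {
  z_x <- as.matrix(z_x); z_y <- as.matrix(z_y)
  if (nrow(z_x) != nrow(z_y)) stop("paired embeddings must have equal n")
  n <- nrow(z_x)
  d <- sqdist(z_x, z_y)            # d[i, j] = d(z_x i, z_y j)^2
  true <- diag(d)
  s <- vapply(seq_len(n), function(i) sum(d[, i] < true[i]), numeric(1))
  t_ <- vapply(seq_len(n), function(i) sum(d[i, ] < true[i]), numeric(1))
  (sum(s / n) + sum(t_ / n)) / (2 * n)
}

#' Assemble a metric report
#'
#' Convenience wrapper computing the full suite on an integrated embedding:
#' kNN-transfer ARI/NMI/F1 (reference -> query), scaled silhouette over cell
#' types, batch entropy over dataset ids and, for row-paired runs, FOSCTTM.
#'
#' @param emb_x,emb_y Embeddings of the two datasets in the shared space.
#' @param types_x,types_y Optional cell-type labels.
#' @param paired Are rows of `emb_x`/`emb_y` the same cells?
#' @param k_neighbors Passed to [knn_transfer_scores()].
#' @param seed Passed to [batch_entropy()].
#' @param batch_ids Optional explicit batch labels (default: dataset of
#'   origin).
#' @return Named list of metric values (class `metric_report`).
#' @export
metric_report <- function(emb_x, emb_y, types_x = NULL, types_y = NULL,
                          paired = FALSE, k_neighbors = 5, seed = 0,
                          batch_ids = NULL) {
  emb <- rbind(as.matrix(emb_x), as.matrix(emb_y))
  if (is.null(batch_ids))
    batch_ids <- rep(c("x", "y"), c(nrow(emb_x), nrow(emb_y)))
  out <- list()
  if (!is.null(types_x) && !is.null(types_y)) {
    kt <- knn_transfer_scores(emb_x, types_x, emb_y, types_y, k_neighbors)
    out$ari <- unname(kt["ari"]); out$nmi <- unname(kt["nmi"])
    out$f1 <- unname(kt["f1"])
    types <- c(types_x, types_y)
    if (length(unique(types)) >= 2 && !any(table(types) < 2))
      out$silhouette_scaled <- silhouette_scaled(emb, types)
    shared <- intersect(unique(types_x), unique(types_y))
    mask <- types %in% shared
    kn <- min(50, sum(mask) - 1)
    out$batch_entropy <- batch_entropy(emb, batch_ids, mask,
                                       k_neighbors = kn, seed = seed)
  } else {
    out$batch_entropy <- batch_entropy(emb, batch_ids,
                                       k_neighbors = min(50, nrow(emb) - 1),
                                       seed = seed)
  }
  if (paired) out$foscttm <- foscttm(emb_x, emb_y)
  structure(out, class = c("metric_report", "list"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
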