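test_that("cell/gene filtering keeps exactly the detected survivors", {
  # 4 cells x 3 genes; cell 2 is empty, gene 3 is seen in one cell only
  m <- rbind(c(1, 2, 0),
             c(0, 0, 0),
             c(3, 0, 1),
             c(2, 5, 0))
  ds <- sc_dataset(m, "a")
  out <- filter_cells_genes(ds, min_genes_per_cell = 1, min_cells_per_gene = 2)
  # hand check: cells 1,3,4 survive; gene 3 detected in 1 cell -> dropped
  expect_equal(out$cell_ids, c("cell1", "cell3", "cell4"))
  expect_equal(out$gene_ids, c("gene1", "gene2"))
  expect_equal(unname(as.matrix(out$matrix)),
               rbind(c(1, 2), c(3, 0), c(2, 5)))
})

test_that("zero thresholds are a no-op and empty results error", {
  ds <- toy_dataset()
  out <- filter_cells_genes(ds, 0, 0)
  expect_identical(as.matrix(out$matrix), as.matrix(ds$matrix))
  expect_error(filter_cells_genes(ds, 1e6, 0), "all cells filtered")
  expect_error(filter_cells_genes(ds, 0, 1e6), "all genes filtered")
  expect_error(filter_cells_genes(ds, -1, 0), ">= 0")
})

test_that("strict 'fewer than' semantics keep boundary cells and genes", {
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1))
  ds <- sc_dataset(m, "a")
  # cell 2 has exactly 1 detected gene, gene 3 exactly 1 cell: both kept at
  # thresholds (1, 1) because only strictly-fewer are removed
  out <- filter_cells_genes(ds, 1, 1)
  expect_equal(dim(out$matrix), c(3L, 3L))
})

test_that("total-count normalization hits the target and the auto median", {
  ds <- sc_dataset(rbind(c(2, 2, 4), c(1, 1, 8)), "a")
  out <- normalize_total(ds, target_sum = 1)
  expect_equal(unname(as.matrix(out$matrix)[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(out$matrix)), c(1, 1))

  # rows summing to 10 and 40 -> auto target = median {10, 40} = 25
  ds2 <- sc_dataset(rbind(c(10, 0), c(30, 10)), "a")
  out2 <- normalize_total(ds2)
  expect_equal(unname(rowSums(out2$matrix)), c(25, 25))

  # all-zero row untouched, no NaN
  ds3 <- sc_dataset(rbind(c(0, 0), c(2, 6)), "a")
  out3 <- normalize_total(ds3, 4)
  expect_equal(unname(as.matrix(out3$matrix)[1, ]), c(0, 0))
  expect_false(anyNA(as.matrix(out3$matrix)))
})

test_that("normalization preserves within-cell proportions", {
  ds <- toy_dataset()
  out <- normalize_total(ds, 100)
  m0 <- as.matrix(ds$matrix); m1 <- as.matrix(out$matrix)
  for (i in seq_len(nrow(m0)))
    expect_equal(m1[i, ] / sum(m1[i, ]), m0[i, ] / sum(m0[i, ]))
})

test_that("log1p transform is exact and round-trips through expm1", {
  ds <- toy_dataset()
  out <- log1p_transform(ds)
  expect_equal(as.matrix(out$matrix), log1p(as.matrix(ds$matrix)))
  expect_equal(expm1(as.matrix(out$matrix)), as.matrix(ds$matrix))
  expect_equal(as.matrix(log1p_transform(
    sc_dataset(matrix(exp(1) - 1, 1, 2), "a"))$matrix)[1, ],
    c(gene1 = 1, gene2 = 1))
})

test_that("HVG ranking equals a brute-force dispersion computation", {
  set.seed(3)
  m <- matrix(rpois(200 * 5, lambda = rep(c(1, 5, 2, 8, 3), each = 200)),
              200, 5)
  m[, 2] <- m[, 2] * rbinom(200, 1, 0.5)       # inflate dispersion
  ds <- log1p_transform(sc_dataset(m, "a"))
  got <- select_hvg(ds, n_top = 5, n_bins = 2)

  # independent recomputation: dispersion var/mean on expm1 scale, z-scored
  # within 2 quantile bins of the mean, ranked descending
  x <- expm1(as.matrix(ds$matrix))
  mu <- colMeans(x); v <- apply(x, 2, var); disp <- v / mu
  br <- unique(quantile(mu, c(0, .5, 1)))
  bin <- cut(mu, br, include.lowest = TRUE)
  z <- (disp - tapply(disp, bin, mean)[bin]) / tapply(disp, bin, sd)[bin]
  z[!is.finite(z)] <- 0
  gids <- colnames(ds$matrix)
  want <- gids[order(-z, gids)]
  expect_equal(got, want)
})

test_that("HVG selection is cell-permutation invariant and handles edge cases", {
  sim <- small_sim()
  ds <- log1p_transform(normalize_total(sim$x))
  h1 <- select_hvg(ds, 10)
  perm <- sample(nrow(ds$matrix))
  ds2 <- sc_dataset(ds$matrix[perm, ], "x")
  expect_identical(select_hvg(ds2, 10), h1)

  # zero-variance gene is never selected ahead of varying genes
  m <- cbind(matrix(rpois(40 * 4, 4), 40, 4), rep(2, 40))
  colnames(m) <- paste0("g", 1:5)
  dz <- log1p_transform(sc_dataset(m, "a"))
  expect_false("g5" %in% select_hvg(dz, 4))
  expect_warning(got <- select_hvg(dz, 99), "returning all")
  expect_equal(length(got), 5L)
})

test_that("common HVG selection restricts to the intersection", {
  sim <- small_sim()
  dx <- log1p_transform(normalize_total(sim$x))
  dy <- log1p_transform(normalize_total(sim$y))
  common <- select_hvg(dx, 20, shared_with = dy)
  expect_true(all(common %in% intersect(dx$gene_ids, dy$gene_ids)))
  expect_equal(length(common), 20L)
})

test_that("max-abs scaling maps every nonzero gene onto [0, 1] with max 1", {
  ds <- toy_dataset()
  out <- maxabs_scale(ds)
  m <- as.matrix(out$matrix)
  expect_true(all(m >= 0 & m <= 1))
  nz <- colSums(as.matrix(ds$matrix)) > 0
  expect_equal(unname(apply(m[, nz], 2, max)), rep(1, sum(nz)))
  # entry 1 under column max 4 -> 0.25; all-zero column untouched
  ds2 <- sc_dataset(cbind(c(1, 4), c(0, 0)), "a")
  m2 <- as.matrix(maxabs_scale(ds2)$matrix)
  expect_equal(unname(m2[, 1]), c(0.25, 1))
  expect_equal(unname(m2[, 2]), c(0, 0))
})

test_that("TF-IDF/LSI matches a dense SVD oracle", {
  set.seed(9)
  m <- matrix(rbinom(12 * 8, 1, 0.4), 12, 8)
  m[3, ] <- 0                                   # an empty cell
  ds <- sc_dataset(m, "atac")
  emb <- tfidf_lsi(ds, n_components = 3)
  # oracle: explicit TF-IDF then full svd
  tf <- m / ifelse(rowSums(m) > 0, rowSums(m), 1)
  idf <- log(1 + nrow(m) / (1 + colSums(m != 0)))
  x <- sweep(tf, 2, idf, "*")
  sv <- svd(x)
  want <- sv$u[, 1:3] %*% diag(sv$d[1:3])
  # singular vectors are sign-ambiguous; compare column spans via |cor|
  for (j in 1:3)
    expect_equal(abs(cor(emb[, j], want[, j])), 1, tolerance = 1e-8)
  expect_equal(unname(emb[3, ]), rep(0, 3))     # zero row -> zero embedding
  expect_error(tfidf_lsi(ds, n_components = 8), "n_components")
})

test_that("the preprocessing pipeline is deterministic and within bounds", {
  sim <- small_sim()
  gp1 <- prepare_inputs(sim$x, sim$y, 30, 15, filter = FALSE)
  gp2 <- prepare_inputs(sim$x, sim$y, 30, 15, filter = FALSE)
  expect_identical(gp1, gp2)
  expect_true(all(gp1$X_c >= 0 & gp1$X_c <= 1))
  expect_true(all(gp1$Y_s >= 0 & gp1$Y_s <= 1))
  expect_identical(colnames(gp1$X_c), colnames(gp1$Y_c))
  expect_identical(colnames(gp1$X_c), gp1$common_genes)
  expect_true(all(gp1$common_genes %in%
                    intersect(sim$x$gene_ids, sim$y$gene_ids)))
})
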