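test_that("ARI/NMI/F1 match hand formulas on the 2-class confusion instance", {
  # confusion matrix [[3, 1], [1, 3]]
  truth <- rep(c("a", "b"), each = 4)
  pred <- c("a", "a", "a", "b", "a", "b", "b", "b")
  expect_equal(macro_f1(truth, pred), 0.75)
  # pair-counting oracle for ARI
  ch2 <- function(x) x * (x - 1) / 2
  tab <- table(truth, pred)
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  n2 <- ch2(8)
  want_ari <- (sij - sa * sb / n2) / ((sa + sb) / 2 - sa * sb / n2)
  expect_equal(adjusted_rand_index(truth, pred), want_ari)
  # entropy oracle for NMI
  ent <- function(p) -sum(p * log(p))
  pu <- rowSums(tab) / 8; pv <- colSums(tab) / 8; pj <- tab / 8
  mi <- sum(pj * log(pj / outer(pu, pv)))
  expect_equal(normalized_mutual_info(truth, pred),
               2 * mi / (ent(pu) + ent(pv)))
})

test_that("perfect predictions score 1 and degenerate labels score 0", {
  lab <- sample(letters[1:3], 30, TRUE)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  expect_equal(normalized_mutual_info(lab, lab), 1)
  expect_equal(macro_f1(lab, lab), 1)
  one <- rep("a", 10)
  expect_equal(normalized_mutual_info(one, one), 0)   # degenerate entropy
})

test_that("metric implementations agree with independent library oracles", {
  skip_if_not_installed("mclust")
  skip_if_not_installed("igraph")
  set.seed(30)
  u <- sample(1:4, 60, TRUE); v <- sample(1:3, 60, TRUE)
  expect_equal(adjusted_rand_index(u, v), mclust::adjustedRandIndex(u, v))
  expect_equal(normalized_mutual_info(u, v),
               igraph::compare(u, v, method = "nmi"))
})

test_that("ARI is invariant to shared permutations of labels", {
  set.seed(31)
  u <- sample(letters[1:3], 40, TRUE); v <- sample(letters[1:3], 40, TRUE)
  p <- sample(40)
  expect_equal(adjusted_rand_index(u[p], v[p]), adjusted_rand_index(u, v))
})

test_that("kNN transfer scores a clean two-cluster geometry perfectly", {
  set.seed(32)
  ref <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  qry <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 10), 10, 2))
  rl <- rep(c("A", "B"), each = 20); ql <- rep(c("A", "B"), each = 10)
  sc <- knn_transfer_scores(ref, rl, qry, ql)
  expect_equal(unname(sc), c(1, 1, 1), ignore_attr = TRUE)
  expect_warning(knn_transfer_scores(ref, rl, qry, rep(c("C", "D"), each = 10)),
                 "disjoint")
})

test_that("scaled silhouette matches an exhaustive pairwise oracle", {
  emb <- rbind(c(0, 0), c(0, 1), c(1, 0),
               c(10, 10), c(10, 11), c(11, 10))
  lab <- rep(c("p", "q"), each = 3)
  got <- silhouette_scaled(emb, lab)
  # brute force
  d <- as.matrix(dist(emb))
  s <- vapply(1:6, function(i) {
    a <- sum(d[i, lab == lab[i]]) / 2   # mean over the two same-cluster others
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got, mean((s + 1) / 2))
  expect_gt(got, 0.9)                    # well-separated clusters -> near 1
  # all points identical: 0/0 convention gives (0+1)/2
  expect_equal(silhouette_scaled(matrix(1, 4, 2), rep(c("p", "q"), 2)), 0.5)
  expect_error(silhouette_scaled(emb, rep("p", 6)), ">= 2 clusters")
})

test_that("scaled silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(33)
  emb <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  lab <- rep(1:2, each = 20)
  want <- mean(cluster::silhouette(lab, dist(emb))[, "sil_width"])
  expect_equal(silhouette_scaled(emb, lab), (want + 1) / 2, tolerance = 1e-8)
})

test_that("batch entropy hits its endpoints and a loop oracle", {
  # perfectly alternating equal batches on a line: every 10-NN region is
  # half/half -> normalized score 1
  n <- 100
  emb <- cbind(seq_len(n), 0)
  alt <- rep(c("b1", "b2"), n / 2)
  expect_equal(batch_entropy(emb, alt, n_probes = 20, k_neighbors = 10,
                             seed = 1), 1, tolerance = 1e-9)
  # pure regions -> 0
  sep <- rep(c("b1", "b2"), each = n / 2)
  emb2 <- rbind(cbind(seq_len(n / 2), 0), cbind(seq_len(n / 2) + 1e4, 0))
  expect_equal(batch_entropy(emb2, sep, n_probes = 20, k_neighbors = 10,
                             seed = 1), 0)
  # 3-batch instance vs direct loop computation
  set.seed(34)
  emb3 <- matrix(rnorm(60 * 2), 60, 2)
  b3 <- sample(c("u", "v", "w"), 60, TRUE)
  got <- batch_entropy(emb3, b3, n_probes = 15, k_neighbors = 12, seed = 7)
  # oracle with the same probe draw
  set.seed(7)
  probes <- sample.int(60, 15)
  Pg <- table(factor(b3)) / 60
  d <- as.matrix(dist(emb3))
  want <- mean(vapply(probes, function(i) {
    nn <- order(d[i, ])[1:12]
    p <- table(factor(b3[nn], levels = names(Pg))) / 12
    pp <- (p / Pg) / sum(p / Pg); pp <- pp[pp > 0]
    -sum(pp * log(pp)) / log(3)
  }, numeric(1)))
  expect_equal(got, want)
  expect_error(batch_entropy(emb3, rep("u", 60)), ">= 2 batches")
  expect_error(batch_entropy(emb3[1:5, ], b3[1:5], k_neighbors = 50),
               "fewer cells")
})

test_that("batch entropy is seed-reproducible with shrinking probe variance", {
  set.seed(35)
  emb <- matrix(rnorm(400), 200, 2)
  b <- sample(c("b1", "b2"), 200, TRUE)
  e1 <- batch_entropy(emb, b, n_probes = 50, k_neighbors = 20, seed = 5)
  e2 <- batch_entropy(emb, b, n_probes = 50, k_neighbors = 20, seed = 5)
  expect_identical(e1, e2)
  v_small <- var(vapply(1:20, function(s)
    batch_entropy(emb, b, n_probes = 5, k_neighbors = 20, seed = s),
    numeric(1)))
  v_large <- var(vapply(1:20, function(s)
    batch_entropy(emb, b, n_probes = 100, k_neighbors = 20, seed = s),
    numeric(1)))
  expect_lt(v_large, v_small)
})

test_that("FOSCTTM is 0 for identical embeddings and hand-countable on a grid", {
  set.seed(36)
  z <- matrix(rnorm(40), 20, 2)
  expect_equal(foscttm(z, z), 0)
  # 1-D increasing grid vs its reverse, n = 4: full distance-table count
  zx <- matrix(c(1, 2, 3, 4), 4, 1)
  zy <- matrix(c(4, 3, 2, 1), 4, 1)
  d <- abs(outer(zx[, 1], zy[, 1], "-"))
  true <- diag(d)
  s <- sapply(1:4, function(i) sum(d[, i] < true[i]))
  t_ <- sapply(1:4, function(i) sum(d[i, ] < true[i]))
  expect_equal(foscttm(zx, zy), (sum(s / 4) + sum(t_ / 4)) / 8)
  expect_equal(foscttm(zx, zy), 0.5)   # hand count: (1+2+2+1)*2/(4*8)... = 0.5
  expect_error(foscttm(zx, zy[1:3, , drop = FALSE]), "equal n")
})

test_that("FOSCTTM of independent random embeddings is near one half", {
  vals <- vapply(1:10, function(s) {
    set.seed(100 + s)
    foscttm(matrix(rnorm(400), 200, 2), matrix(rnorm(400), 200, 2))
  }, numeric(1))
  expect_true(all(abs(vals - 0.5) < 0.05))
})

test_that("metrics are invariant to rigid rotation of the embedding", {
  set.seed(37)
  emb <- matrix(rnorm(200), 100, 2)
  lab <- sample(c("A", "B"), 100, TRUE)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  embr <- emb %*% R
  expect_equal(silhouette_scaled(emb, lab), silhouette_scaled(embr, lab))
  b <- rep(c("b1", "b2"), 50)
  expect_equal(batch_entropy(emb, b, n_probes = 30, k_neighbors = 10, seed = 2),
               batch_entropy(embr, b, n_probes = 30, k_neighbors = 10, seed = 2))
  zx <- matrix(rnorm(60), 30, 2); zy <- matrix(rnorm(60), 30, 2)
  expect_equal(foscttm(zx %*% R, zy %*% R), foscttm(zx, zy))
})

test_that("the metric report assembles the suite", {
  set.seed(38)
  ex <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(30, 5), 15, 2))
  ey <- ex + rnorm(60, sd = 0.1)
  tl <- rep(c("A", "B"), each = 15)
  rep_ <- metric_report(ex, ey, tl, tl, paired = TRUE, seed = 1)
  expect_named(rep_, c("ari", "nmi", "f1", "silhouette_scaled",
                       "batch_entropy", "foscttm"))
  expect_equal(rep_$ari, 1)
  expect_lt(rep_$foscttm, 0.05)
})
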