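test_that("K-means clustering is deterministic under a fixed seed", {
  set.seed(1)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 6), 10))
  e <- schicbench:::new_embedding(x, sprintf("c%02d", 1:20), list())
  cl <- kmeans_cluster(e, 2, seed = 3)
  expect_equal(cl$label[1:10], rep(cl$label[1], 10))
  expect_equal(cl$label[11:20], rep(cl$label[11], 10))
  expect_identical(kmeans_cluster(e, 2, seed = 3), cl)
  clN <- kmeans_cluster(e, 20, seed = 1)
  expect_equal(length(unique(clN$label)), 20L)
  expect_error(kmeans_cluster(e, 25, seed = 1), "exceed")
})

test_that("ARI matches hand values and the exhaustive pair-count oracle", {
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(4)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    u <- sample(1:3, n, replace = TRUE)
    v <- sample(1:3, n, replace = TRUE)
    expect_equal(ari(u, v), ari_oracle(u, v), tolerance = 1e-12)
  }
  # agreement with an independent library implementation
  skip_if_not_installed("mclust")
  set.seed(5)
  u <- sample(1:4, 50, replace = TRUE)
  v <- sample(1:4, 50, replace = TRUE)
  expect_equal(ari(u, v), mclust::adjustedRandIndex(u, v), tolerance = 1e-12)
  expect_error(ari(1:3, 1:4), "length")
})

test_that("NMI uses arithmetic-mean entropy normalization", {
  expect_equal(nmi(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  # 2x2 contingency with all cells = 1: direct formula evaluation
  u <- c(1, 1, 2, 2)
  v <- c(1, 2, 1, 2)
  expect_equal(nmi(u, v), nmi_oracle(u, v), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    u <- sample(1:3, n, replace = TRUE)
    v <- sample(1:3, n, replace = TRUE)
    expect_equal(nmi(u, v), nmi_oracle(u, v), tolerance = 1e-12)
    expect_equal(nmi(u, v), nmi(v, u), tolerance = 1e-12)
    relab <- c(7, 5, 9)[u]
    expect_equal(nmi(relab, v), nmi(u, v), tolerance = 1e-12)
  }
})

test_that("cosine ASW behaves on antipodal clusters and permutation nulls", {
  set.seed(7)
  a <- cbind(1 + rnorm(15, sd = 0.01), rnorm(15, sd = 0.01))
  b <- cbind(-1 + rnorm(15, sd = 0.01), rnorm(15, sd = 0.01))
  e <- schicbench:::new_embedding(rbind(a, b), sprintf("c%02d", 1:30), list())
  lab <- rep(1:2, each = 15)
  expect_gt(asw(e, lab), 0.9)
  nulls <- vapply(1:20, function(i) asw(e, sample(lab)), numeric(1))
  expect_lt(max(abs(nulls)), 0.2)
  expect_error(asw(e, rep(1, 30)), "classes")
})

test_that("ASW agrees with the cluster-package silhouette on cosine distances", {
  skip_if_not_installed("cluster")
  set.seed(8)
  x <- matrix(rnorm(40), 10, 4)
  lab <- rep(1:2, 5)
  e <- schicbench:::new_embedding(x, sprintf("c%02d", 1:10), list())
  nrm <- sqrt(rowSums(x^2))
  D <- as.dist(1 - tcrossprod(x / nrm))
  sil <- cluster::silhouette(lab, D)
  expect_equal(asw(e, lab), mean(sil[, "sil_width"]), tolerance = 1e-9)
})

test_that("AvgBIO rescales ASW and averages", {
  expect_equal(avgbio(1, 1, 1), 1)
  expect_equal(avgbio(0, 0, -1), 0)
  expect_equal(avgbio(0.4, 0.6, 0), 0.5)
  expect_lt(avgbio(0.2, 0.5, 0), avgbio(0.3, 0.5, 0)) # monotone
})

test_that("repeat harness reports SEM and reproduces under derived seeds", {
  set.seed(9)
  x <- rbind(matrix(rnorm(16), 8), matrix(rnorm(16, 6), 8))
  e <- schicbench:::new_embedding(x, sprintf("c%02d", 1:16), list())
  truth <- tibble::tibble(cell_id = sprintf("c%02d", 1:16),
                          label = rep(c("u", "v"), each = 8))
  ev <- repeat_eval(e, truth, n_repeats = 4, base_seed = 2)
  expect_equal(nrow(ev), 4L)
  expect_equal(glance(ev)$ari_sem, 0) # deterministic everything
  ev2 <- repeat_eval(e, truth, n_repeats = 4, base_seed = 2)
  expect_identical(as.data.frame(ev), as.data.frame(ev2))
  ev1 <- repeat_eval(e, truth, n_repeats = 1, base_seed = 2)
  expect_true(is.na(glance(ev1)$ari_sem))
})

test_that("median percentile ranks follow rank/k with shared ties", {
  sc <- tidyr::expand_grid(method = c("A", "B", "C"),
                           dataset = c("d1", "d2", "d3"))
  sc$score <- c(0.9, 0.8, 0.7, # A best everywhere
                0.6, 0.5, 0.4,
                0.3, 0.2, 0.1)[c(1, 2, 3, 4, 5, 6, 7, 8, 9)]
  sc$score <- rep(c(0.9, 0.6, 0.3), each = 3)
  r <- median_rank_summary(sc)
  expect_equal(r$method, c("A", "B", "C"))
  expect_equal(r$median_rank, c(1, 2 / 3, 1 / 3))
  # ties share the mean of their percentile positions
  sc2 <- tibble::tibble(method = c("A", "B", "C"), dataset = "d1",
                        score = c(0.5, 0.5, 0.1))
  r2 <- median_rank_summary(sc2)
  expect_equal(sort(r2$median_rank[r2$method %in% c("A", "B")]),
               rep(mean(c(2, 3) / 3), 2))
  # missing entries are excluded from that dataset's ranking
  sc3 <- dplyr::bind_rows(sc2, tibble::tibble(method = "D", dataset = "d1",
                                              score = NA))
  expect_false("D" %in% median_rank_summary(sc3)$method)
})
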