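bins2 <- c(chr1 = 30L, chr2 = 30L)

test_that("1D coverage PCA maps identical cells to identical rows", {
  cells <- dplyr::bind_rows(
    ct("a", "chr1", c(0, 2), c(1, 5), c(3, 1)),
    ct("b", "chr1", c(0, 2), c(1, 5), c(3, 1)),
    ct("c", "chr2", c(1, 3), c(4, 8), c(2, 2))
  )
  e <- embed_1d_pca(cells, bins2, d = 2, resolution = 1e5)
  x <- embedding_coords(e)
  expect_equal(x["a", ], x["b", ])
  expect_false(isTRUE(all.equal(x["a", ], x["c", ])))
  expect_error(embed_1d_pca(cells, bins2, d = 3, resolution = 1e5), "cells")
})

test_that("stratum inner products are per-stratum Pearson correlations", {
  # two cells with reversed stratum vectors -> similarity -1
  cells <- dplyr::bind_rows(
    ct("a", "chr1", 0:2, 0:2, c(1, 2, 3)),
    ct("b", "chr1", 0:2, 0:2, c(3, 2, 1))
  )
  S <- similarity_innerproduct(cells, c(chr1 = 3L), 1e5, max_bp = 1e5)
  expect_equal(S["a", "b"], -1)
  expect_equal(S["a", "a"], 1, tolerance = 1e-9)

  # constant stratum contributes zero
  cells2 <- dplyr::bind_rows(
    ct("a", "chr1", 0:2, 0:2, c(5, 5, 5)),
    ct("b", "chr1", 0:2, 0:2, c(3, 2, 1))
  )
  S2 <- similarity_innerproduct(cells2, c(chr1 = 3L), 1e5, max_bp = 1e5)
  expect_equal(S2["a", "b"], 0)

  # uniform weights on a single stratum equal the Pearson correlation matrix
  set.seed(9)
  vals <- matrix(rpois(5 * 8, 4), 5, 8)
  cells3 <- dplyr::bind_rows(lapply(1:5, function(i) {
    ct(paste0("c", i), "chr1", 0:7, 0:7, vals[i, ])
  }))
  S3 <- similarity_innerproduct(cells3, c(chr1 = 8L), 1e5, max_bp = 1e5)
  # population-variance z-scores make this n/(n) Pearson correlation
  expect_equal(unclass(S3), unname(cor(t(vals))), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("SCC weights emphasize strata in proportion to N_s sigma_i sigma_j", {
  set.seed(11)
  cells <- dplyr::bind_rows(lapply(1:4, function(i) {
    ct(paste0("c", i), "chr1", c(0:5, 0:4), c(0:5, 1:5),
       rpois(11, 6) + 1)
  }))
  S <- similarity_innerproduct(cells, c(chr1 = 6L), 1e5, max_bp = 2e5,
                               weights = "scc")
  # oracle: accumulate the two strata by hand
  vals <- lapply(1:4, function(i) {
    df <- cells[cells$cell_id == paste0("c", i), ]
    list(s0 = df$count[df$bin2 - df$bin1 == 0],
         s1 = df$count[df$bin2 - df$bin1 == 1])
  })
  psd <- function(v) sqrt(mean(v^2) - mean(v)^2)
  z <- function(v) (v - mean(v)) / psd(v)
  num <- den <- 0
  for (s in c("s0", "s1")) {
    len <- length(vals[[1]][[s]])
    w <- len * psd(vals[[1]][[s]]) * psd(vals[[2]][[s]])
    num <- num + w * sum(z(vals[[1]][[s]]) * z(vals[[2]][[s]])) / len
    den <- den + w
  }
  expect_equal(S["c1", "c2"], num / den, tolerance = 1e-9)
})

test_that("classical MDS reproduces closed-form and metric geometries", {
  # constant off-diagonal similarity -> equilateral triangle
  rho <- 0.5
  S <- matrix(rho, 3, 3)
  diag(S) <- 1
  dimnames(S) <- list(letters[1:3], letters[1:3])
  e <- embed_mds(S, 2)
  x <- embedding_coords(e)
  side <- sqrt(2 * (1 - rho))
  expect_equal(as.numeric(dist(x)), rep(side, 3), tolerance = 1e-8)

  # all-ones similarity collapses to the origin
  S1 <- matrix(1, 3, 3)
  dimnames(S1) <- list(letters[1:3], letters[1:3])
  expect_warning(e1 <- embed_mds(S1, 2), "positive eigenvalues")
  expect_equal(max(abs(embedding_coords(e1))), 0)
})

test_that("spectral IDF embedding separates duplicated disjoint groups", {
  rows <- c(rep(1:4, each = 3), rep(5:8, each = 3))
  cols <- c(rep(1:3, 4), rep(4:6, 4))
  x <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    ct(paste0("c", rows[i]), "chr1", cols[i], cols[i] + 1, 5)
  }))
  e <- embed_spectral_idf(x, c(chr1 = 10L), d = 2, resolution = 1e5,
                          q_low = 0, q_high = 0, top_n = 10)
  xm <- embedding_coords(e)
  g1 <- xm[1:4, 1]
  g2 <- xm[5:8, 1]
  expect_lt(max(abs(g1 - g1[1])), 1e-8) # duplicated cells coincide
  expect_lt(max(abs(g2 - g2[1])), 1e-8)
  expect_gt(abs(g1[1] - g2[1]), 1e-3)   # leading coordinate splits groups
})

test_that("LDA topic proportions are simplex rows and split disjoint corpora", {
  rows <- c(rep(1:3, each = 4), rep(4:6, each = 4))
  cols <- c(rep(0:3, 3), rep(5:8, 3))
  x <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    ct(paste0("c", rows[i]), "chr1", cols[i], cols[i] + 1, 20)
  }))
  hits <- vapply(1:5, function(s) {
    e <- embed_lda(x, c(chr1 = 12L), resolution = 1e5, topics = 2,
                   iters = 100, seed = s)
    th <- embedding_coords(e)
    dom <- apply(th, 1, which.max)
    mean(dom[1:3] != dom[4:6])
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
  e1 <- embed_lda(x, c(chr1 = 12L), resolution = 1e5, topics = 3,
                  iters = 20, seed = 1)
  expect_equal(unname(rowSums(embedding_coords(e1))), rep(1, 6),
               tolerance = 1e-9)
  e0 <- embed_lda(x, c(chr1 = 12L), resolution = 1e5, topics = 1)
  expect_equal(as.numeric(embedding_coords(e0)), rep(1, 6))
})

test_that("insulation deltas are zero on uniform maps and flip at boundaries", {
  expect_equal(schicbench:::insulation_delta(matrix(1, 12, 12), 3, 2),
               rep(0, 12))
  # two-block diagonal toy: delta dips entering the boundary and rises
  # leaving it
  m <- matrix(0, 12, 12)
  m[1:6, 1:6] <- 1
  m[7:12, 7:12] <- 1
  dl <- schicbench:::insulation_delta(m, 2, 2)
  expect_lt(dl[5], 0)
  expect_gt(dl[8], 0)
})

test_that("scHiCluster with inert transforms degenerates to PCA of binarized VC matrices", {
  d <- tiny_dataset(seed = 6, n = 6, bins_per_chrom = 40)
  e <- embed_schicluster(d$contacts, d$bins, d = 2, resolution = d$resolution,
                         pcs_per_chrom = 5, top_frac = 1, box_w = 0,
                         restart_p = 1e-9)
  ids <- unique(d$contacts$cell_id)
  blocks <- list()
  for (chn in names(d$bins)) {
    ut <- upper.tri(diag(d$bins[[chn]]), diag = TRUE)
    flat <- t(vapply(ids, function(id) {
      m <- vc_sqrt_norm(contact_matrix(d$contacts, chn, d$bins, id))
      as.numeric(m[ut] > 0)
    }, numeric(sum(ut))))
    blocks[[chn]] <- schicbench:::pca_scores(flat, 5)
  }
  oracle <- schicbench:::pca_scores(do.call(cbind, blocks), 2)
  expect_equal(unname(embedding_coords(e)), oracle, tolerance = 1e-4)
})

test_that("backends are permutation-equivariant", {
  d <- tiny_dataset(seed = 8, n = 5, bins_per_chrom = 40)
  ids <- unique(d$contacts$cell_id)
  set.seed(2)
  perm <- sample(ids)
  d_perm <- d
  d_perm$contacts <- dplyr::bind_rows(lapply(perm, function(id) {
    d$contacts[d$contacts$cell_id == id, ]
  }))
  attr(d_perm$contacts, "resolution") <- d$resolution
  for (bk in c("1d_pca", "innerproduct", "spectral_idf", "insulation")) {
    e1 <- embed_dataset(d, bk, top_n = 5000)
    e2 <- embed_dataset(d_perm, bk, top_n = 5000)
    x1 <- embedding_coords(e1)
    x2 <- embedding_coords(e2)
    expect_equal(x2[ids, ], x1[ids, ], tolerance = 1e-6,
                 info = paste("backend", bk))
  }
})
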