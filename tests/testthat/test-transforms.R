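test_that("distance truncation keeps the half-open window and composes", {
  cell <- ct("a", "chr1", rep(0L, 6), 0:5, 1:6, resolution = 5e5)
  expect_equal(truncate_distance(cell, 0, Inf)$count, cell$count)
  # at 500 kb resolution a 2 Mb cap keeps strata 0..3 only
  out <- truncate_distance(cell, 0, 2e6)
  expect_equal(out$bin2, 0:3)
  # composition = window intersection
  ab <- truncate_distance(truncate_distance(cell, 5e5, 2.5e6), 1e6, 2e6)
  expect_equal(ab, truncate_distance(cell, 1e6, 2e6))
  expect_warning(truncate_distance(cell, 5e6, 6e6), "excludes")
  expect_error(truncate_distance(cell, -1, 5), "min_bp")
})

test_that("truncation zeroes strata outside the window on a strata set", {
  cell <- ct("a", "chr1", c(0, 0, 0), c(0, 1, 2), c(5, 6, 7), resolution = 1e5)
  s <- build_strata(cell, k = 3, bins = c(chr1 = 5L))
  tr <- truncate_distance(s, 0, 2e5)
  expect_equal(tr$strata$chr1[[1]][1], 5)
  expect_equal(sum(tr$strata$chr1[[3]]), 0)
  expect_equal(tr, truncate_distance(tr, 0, 2e5)) # idempotent
})

test_that("VC-sqrt normalization matches hand-computed cases", {
  expect_equal(vc_sqrt_norm(matrix(c(0, 2, 2, 0), 2)),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(vc_sqrt_norm(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_equal(vc_sqrt_norm(diag(c(4, 9))), diag(2))
  m <- rand_sym(8, 1)
  out <- vc_sqrt_norm(m)
  expect_equal(out, t(out))
  expect_true(all(out >= 0))
})

test_that("box filter equals the clipped-window mean", {
  m <- rand_sym(6, 2)
  expect_equal(box_filter(m, 0), m)
  expect_equal(box_filter(matrix(1, 3, 3), 1), matrix(1, 3, 3))
  m9 <- matrix(0, 3, 3)
  m9[2, 2] <- 9
  expect_equal(box_filter(m9, 1)[1, 1], 9 / 4)
  for (w in 1:2) {
    expect_equal(box_filter(m, w), box_filter_oracle(m, w))
  }
  expect_error(box_filter(m, 6), "smaller")
})

test_that("random walk converges to the restart closed form", {
  m <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(random_walk(m, 0.5),
               matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2),
               tolerance = 1e-6)
  expect_equal(random_walk(rand_sym(5, 3), restart_p = 1e-6), diag(5),
               tolerance = 1e-4)
  # row-stochasticity is conserved before symmetrization
  R <- random_walk(rand_sym(7, 4), symmetrize = FALSE)
  expect_equal(rowSums(R), rep(1, 7), tolerance = 1e-9)
  expect_error(random_walk(matrix(0, 2, 3)), "square")
})

test_that("IDF weighting follows log(1 + N/(1+n_j)) and keeps zeros", {
  x <- Matrix::sparseMatrix(i = c(1, 2, 3, 4, 1), j = c(1, 1, 1, 1, 2),
                            x = c(2, 1, 1, 3, 5), dims = c(4, 3),
                            dimnames = list(letters[1:4],
                                            c("chr1:0:1", "chr1:0:2", "chr1:0:3")))
  out <- idf_transform(x)
  # saturated feature gets the minimum weight log(1 + N/(1+N))
  expect_equal(out[1, 1] / x[1, 1], log(1 + 4 / 5))
  # all-zero column stays zero
  expect_equal(sum(out[, 3]), 0)
  # N = 4: idf(n=1) / idf(n=3) = log 3 / log 2
  expect_equal(log(1 + 4 / 2) / log(1 + 4 / 4), log(3) / log(2))
  expect_equal(out[1, 2] / x[1, 2], log(1 + 4 / 2))
  expect_equal(as.matrix(out != 0), as.matrix(x != 0))
})

test_that("feature selection drops quantile tails then ranks by signal", {
  mk <- function(totals) {
    x <- matrix(0, 2, length(totals))
    x[1, ] <- totals
    colnames(x) <- sprintf("chr1:0:%d", seq_along(totals))
    x
  }
  x <- mk(1:10)
  expect_equal(ncol(select_features(x, 0, 0, top_n = 10)), 10L)
  kept <- select_features(x, 0, 0, top_n = 3)
  expect_equal(unname(colSums(kept)), c(8, 9, 10))
  # one extreme feature removed by the upper quantile rule before top-N
  x2 <- mk(c(rep(1:4, 250)[1:999], 1e6))
  kept2 <- select_features(x2, 0, 0.005, top_n = 1000)
  expect_false("chr1:0:1000" %in% colnames(kept2))
  expect_error(select_features(mk(c(1, 1)), 0.6, 0.5), "q_low")
})

test_that("stratum z-scores use population variance and zero out constants", {
  cell <- ct("a", "chr1", c(0, 1, 2, 0, 1), c(0, 1, 2, 1, 2),
             c(1, 2, 3, 5, 5), resolution = 1e5)
  s <- zscore_strata(build_strata(cell, 2, bins = c(chr1 = 3L)))
  expect_equal(s$strata$chr1[[1]], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(s$strata$chr1[[2]], c(0, 0)) # constant stratum
  # postcondition: mean 0, population variance 1, or all zero
  v <- s$strata$chr1[[1]]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)
})

test_that("the per-stratum IDF profile averages observed feature weights", {
  x <- Matrix::sparseMatrix(i = c(1, 2, 1), j = 1:3, x = 1, dims = c(2, 3),
                            dimnames = list(c("a", "b"),
                                            c("chr1:0:0", "chr1:1:1", "chr1:0:5")))
  prof <- idf_stratum_profile(x)
  expect_equal(prof$stratum, c(0L, 5L))
  expect_equal(prof$mean_idf[1], log(1 + 2 / 2))
  expect_equal(prof$mean_idf[2], log(1 + 2 / 2))
})
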