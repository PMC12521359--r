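test_that("pairs parsing bins, canonicalizes, deduplicates, and drops trans", {
  dir <- withr::local_tempdir()
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e6, 1e6))

  f1 <- file.path(dir, "a.pairs.txt")
  writeLines("chr1 150 950", f1)
  out <- read_contacts(c(a = f1), sizes, resolution = 500)
  expect_equal(out$bin1, 0L)
  expect_equal(out$bin2, 1L)
  expect_equal(out$count, 1)

  f2 <- file.path(dir, "b.pairs.txt")
  writeLines(c("chr1 10 20", "chr1 20 10"), f2)
  out <- read_contacts(c(b = f2), sizes, resolution = 100)
  expect_equal(nrow(out), 1L)
  expect_equal(out$bin1, 0L)
  expect_equal(out$bin2, 0L)
  expect_equal(out$count, 2)

  f3 <- file.path(dir, "c.pairs.txt")
  writeLines(c("chr1 10 chr2 10", "chr1 10 chr1 500"), f3)
  out <- read_contacts(c(c = f3), sizes, resolution = 100)
  expect_equal(sum(out$count), 1) # trans record excluded
  expect_equal(unique(out$chrom), "chr1")
})

test_that("malformed lines and out-of-bounds positions are errors", {
  dir <- withr::local_tempdir()
  sizes <- tibble::tibble(chrom = "chr1", length = 1000)
  f <- file.path(dir, "bad.pairs.txt")
  writeLines(c("chr1 10 20", "chr1 oops 30"), f)
  expect_error(read_contacts(c(x = f), sizes, 100), "line 2")
  f2 <- file.path(dir, "far.pairs.txt")
  writeLines("chr1 10 5000", f2)
  expect_error(read_contacts(c(x = f2), sizes, 100), "bounds")
})

test_that("qc_filter applies the 5k rule strictly and the per-chromosome rule", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(100e6, 50e6))
  mk <- function(id, n1, n2) {
    ct(id, rep(c("chr1", "chr2"), c(2, 1)), c(0, 1, 0), c(5, 6, 5),
       c(n1 - 1, 1, n2))
  }
  cells <- dplyr::bind_rows(
    mk("low", 4000, 999),      # 4999 total -> filtered (low_total)
    mk("edge", 4000, 1000),    # exactly 5000 -> kept
    mk("chrfail", 99901, 99)   # 100k total but chr1-rule needs >= 100
  )
  cells <- dplyr::bind_rows(
    cells[cells$cell_id != "chrfail", ],
    ct("chrfail", c("chr1", "chr2"), c(0, 0), c(1, 1), c(99, 99901)))
  res <- qc_filter(cells, sizes, min_cis = 5000)
  expect_equal(res$report$pass, c(FALSE, TRUE, FALSE))
  expect_equal(res$report$fail_reason, c("low_total", NA, "chrom_coverage"))
  expect_setequal(unique(res$contacts$cell_id), "edge")

  # idempotent and order-invariant
  res2 <- qc_filter(res$contacts, sizes, min_cis = 5000)
  expect_equal(sort(unique(res2$contacts$cell_id)),
               sort(unique(res$contacts$cell_id)))
  shuffled <- cells[sample(nrow(cells)), ]
  res3 <- qc_filter(shuffled, sizes, min_cis = 5000)
  expect_setequal(res3$report$cell_id[res3$report$pass],
                  res$report$cell_id[res$report$pass])

  # empty input is fine
  empty <- qc_filter(cells[0, ], sizes)
  expect_equal(nrow(empty$report), 0L)
})

test_that("contact fractions match the band definitions", {
  # all at 1 Mb (10 bins at 100 kb)
  f <- contact_fractions(cell_at_distances("a", rep(10L, 5), rep(2, 5)))
  expect_equal(c(f$f_local, f$f_mitotic), c(1, 0))
  # all at 5 Mb
  f <- contact_fractions(cell_at_distances("b", rep(50L, 5), rep(2, 5)))
  expect_equal(c(f$f_local, f$f_mitotic), c(0, 1))
  # equal mass at 1 Mb and 5 Mb
  f <- contact_fractions(cell_at_distances("c", c(10L, 50L), c(5, 5)))
  expect_equal(c(f$f_local, f$f_mitotic), c(0.5, 0.5))
  # undefined when nothing beyond 25 kb (bin distance 0)
  f <- contact_fractions(ct("d", "chr1", 0, 0, 10))
  expect_true(is.na(f$f_local) && is.na(f$f_mitotic))
  # local + mitotic + remainder partitions the denominator
  cell <- cell_at_distances("e", c(5L, 30L, 130L), c(3, 4, 5))
  f <- contact_fractions(cell)
  rest <- 5 / 12
  expect_equal(f$f_local + f$f_mitotic + rest, 1, tolerance = 1e-12)
})

test_that("mitotic_filter splits extremes correctly and errors on degenerate input", {
  # scatter centered near (0.5, 0.2): local a, mitotic b, distal rest
  mix <- lapply(1:21, function(i) {
    a <- 50 + (i %% 3 - 1)
    b <- 20 + ((i + 1) %% 3 - 1)
    cell_at_distances(sprintf("m%02d", i), c(10L, 50L, 150L),
                      c(a, b, 100 - a - b))
  })
  extremes <- list(
    cell_at_distances("gs_like", c(10L, 50L, 150L), c(90, 2, 8)),
    cell_at_distances("mit_like", c(10L, 50L, 150L), c(5, 90, 5))
  )
  contacts <- dplyr::bind_rows(c(mix, extremes))
  attr(contacts, "resolution") <- 1e5
  out <- mitotic_filter(contacts, 1e5)
  expect_true("gs_like" %in% out$info$cell_id[out$info$side == "G-S"])
  expect_true("mit_like" %in% out$info$cell_id[out$info$side == "mitotic"])
  expect_equal(sort(unique(c(out$gs$cell_id, out$mitotic$cell_id))),
               sort(unique(contacts$cell_id)))

  # rank-deficient scatter
  degen <- dplyr::bind_rows(lapply(1:12, function(i) {
    cell_at_distances(sprintf("d%02d", i), c(10L, 50L), c(5, 5))
  }))
  attr(degen, "resolution") <- 1e5
  expect_error(mitotic_filter(degen, 1e5), "manual threshold")
})

test_that("mitotic_filter recovers the generating cell-cycle labels", {
  d <- generate_dataset(preset_dataset("cell-cycle-like", n_cells_per_pop = 15,
                                       bins_per_chrom = 200, seed = 7))
  out <- mitotic_filter(d$contacts, d$resolution)
  truth <- ifelse(startsWith(out$info$cell_id, "mitotic"), "mitotic", "G-S")
  expect_gte(mean(out$info$side == truth), 0.95)
})

test_that("downsampling is an exact-size hypergeometric draw", {
  cell <- ct("a", "chr1", c(0, 1, 2), c(10, 11, 12), c(4000, 3000, 3000))
  expect_equal(downsample_contacts(cell, 1, seed = 1)$count, cell$count)
  half <- downsample_contacts(cell, 0.5, seed = 1)
  expect_equal(sum(half$count), 5000)

  # hypergeometric mean of a 1000-read entry at fraction 0.2
  cell2 <- ct("a", "chr1", c(0, 1), c(10, 11), c(1000, 9000))
  kept <- vapply(1:200, function(s) {
    d <- downsample_contacts(cell2, 0.2, seed = s)
    sum(d$count[d$bin1 == 0])
  }, numeric(1))
  sd1 <- sqrt(2000 * 0.1 * 0.9 * (10000 - 2000) / (10000 - 1))
  expect_lt(abs(mean(kept) - 200), 3 * sd1 / sqrt(200))

  # composing fractions preserves the total exactly
  ab <- downsample_contacts(downsample_contacts(cell2, 0.5, seed = 2),
                            0.4, seed = 3)
  expect_equal(sum(ab$count), sum(downsample_contacts(cell2, 0.2, 4)$count))
  expect_error(downsample_contacts(cell, 0), "fraction")
  expect_error(downsample_contacts(cell, 1.2), "fraction")
})

test_that("pseudobulk sums counts additively", {
  a <- ct("a", "chr1", c(0, 1), c(2, 3), c(1, 2))
  b <- ct("b", "chr1", c(0, 5), c(2, 6), c(1, 4))
  pb <- pseudobulk(dplyr::bind_rows(a, a %>% dplyr::mutate(cell_id = "a2")))
  expect_equal(pb$count, c(2, 4)) # identical cells double
  pb2 <- pseudobulk(dplyr::bind_rows(a, b))
  expect_equal(nrow(pb2), 3L) # union of disjoint supports
  expect_equal(sum(pb2$count), sum(a$count) + sum(b$count))
})

test_that("rebinning conserves counts and coarsens distances", {
  cell <- ct("a", "chr1", c(0, 3, 10), c(5, 9, 11), c(2, 3, 4))
  rb <- rebin_contacts(cell, 2, resolution = 1e5)
  expect_equal(sum(rb$count), sum(cell$count))
  expect_equal(attr(rb, "resolution"), 2e5)
  expect_true(all(rb$bin1 <= rb$bin2))
})
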