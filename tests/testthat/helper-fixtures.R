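# Shared fixtures and independent oracles, all built in code.

# Minimal contact tibble builder.
ct <- function(cell_id, chrom, bin1, bin2, count = 1, resolution = 1e5) {
  out <- tibble::tibble(cell_id = cell_id, chrom = chrom,
                        bin1 = as.integer(bin1), bin2 = as.integer(bin2),
                        count = as.numeric(count))
  attr(out, "resolution") <- resolution
  out
}

# A cell whose contacts sit at fixed bin distances with given counts
# (single chromosome, evenly spread start bins).
cell_at_distances <- function(id, dists, counts, M = 400, chrom = "chr1",
                              resolution = 1e5) {
  b1 <- (seq_along(dists) * 7L) %% (M - max(dists) - 1L)
  ct(id, chrom, b1, b1 + dists, counts, resolution)
}

# Exhaustive pair-counting adjusted Rand index (the oracle).
ari_oracle <- function(u, v) {
  n <- length(u)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) tp <- tp + 1
      else if (!su && sv) fp <- fp + 1
      else if (su && !sv) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  npairs <- tp + fp + fn + tn
  ri <- (tp + tn) / npairs
  # expectation under the permutation model via marginal pair counts
  a <- tp + fn # same-class pairs in u
  b <- tp + fp # same-class pairs in v
  expected <- (a * b + (npairs - a) * (npairs - b)) / npairs^2 * npairs
  max_ri <- npairs # used below in adjusted form
  exp_ri <- expected / npairs
  max_adj <- 1
  if (abs(1 - exp_ri) < 1e-15) return(ifelse(ri == 1, 1, 0))
  (ri - exp_ri) / (max_adj - exp_ri)
}

# Direct evaluation of the mutual-information formula with arithmetic-mean
# entropy normalization (the oracle for nmi()).
nmi_oracle <- function(u, v) {
  n <- length(u)
  tu <- table(u)
  tv <- table(v)
  mi <- 0
  for (cu in names(tu)) {
    for (cv in names(tv)) {
      nij <- sum(u == cu & v == cv)
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (tu[[cu]] * tv[[cv]]))
    }
  }
  h <- function(tt) -sum((tt / n) * log(tt / n))
  denom <- (h(tu) + h(tv)) / 2
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

# Brute-force clipped box-filter mean (the oracle for box_filter()).
box_filter_oracle <- function(m, w) {
  M <- nrow(m)
  out <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      ri <- max(1, i - w):min(M, i + w)
      rj <- max(1, j - w):min(M, j + w)
      out[i, j] <- mean(m[ri, rj])
    }
  }
  out
}

# Random symmetric nonnegative matrix.
rand_sym <- function(M, seed) {
  set.seed(seed)
  m <- matrix(runif(M * M), M, M)
  m <- m + t(m)
  m[m < 0.4] <- 0
  m
}

# Tiny two-population dataset for fast backend tests.
tiny_dataset <- function(seed = 5, n = 12, bins_per_chrom = 80) {
  generate_dataset(preset_dataset("compartment-contrast",
                                  n_cells_per_pop = n,
                                  bins_per_chrom = bins_per_chrom,
                                  seed = seed))
}
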