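# Conventional embedding backends. All share the same contract: a contact
# tibble (plus genome geometry) in, an N x d schic_embedding out, with cell
# order preserved.

#' 1D bin-coverage PCA embedding
#'
#' Ignores the pairwise structure: each contact increments both endpoint bins
#' (intra-bin contacts increment their bin twice), the per-cell genome-wide
#' coverage vector is normalized to sum 1, and cells are embedded by PCA.
#'
#' @param contacts Contact tibble.
#' @param bins Named integer vector of bins per chromosome.
#' @param d Number of output dimensions.
#' @param resolution Bin size in bp.
#' @param min_bp,max_bp Optional distance window applied before counting.
#' @return A `schic_embedding`.
#' @export
embed_1d_pca <- function(contacts, bins, d = 2, resolution = NULL,
                         min_bp = 0, max_bp = Inf) {
  res <- contacts_resolution(contacts, resolution)
  contacts <- truncate_distance(contacts, min_bp, max_bp, res)
  ids <- cell_ids(contacts)
  if (length(ids) < 2) abort("Need at least 2 cells.")
  offs <- c(0L, cumsum(bins))[seq_along(bins)]
  names(offs) <- names(bins)
  gbin1 <- offs[contacts$chrom] + contacts$bin1
  gbin2 <- offs[contacts$chrom] + contacts$bin2
  i <- rep(match(contacts$cell_id, ids), 2L)
  j <- c(gbin1, gbin2) + 1L
  x <- rep(contacts$count, 2L)
  cov <- as.matrix(Matrix::sparseMatrix(i = i, j = j, x = x,
                                        dims = c(length(ids), sum(bins))))
  rs <- rowSums(cov)
  cov <- cov / ifelse(rs > 0, rs, 1)
  new_embedding(pca_scores(cov, d), ids,
                list(backend = "1d_pca", resolution = res, d = d,
                     min_bp = min_bp, max_bp = max_bp))
}

#' scHiCluster-style per-chromosome PCA embedding
#'
#' Per chromosome and cell: VC-sqrt normalization, box-filter smoothing,
#' random-walk imputation, then binarization of the strongest `top_frac` of
#' entries. Binarized matrices are flattened, reduced by per-chromosome PCA,
#' concatenated, and reduced again by a genome-wide PCA.
#'
#' @inheritParams embed_1d_pca
#' @param pcs_per_chrom Components kept per chromosome before the final PCA.
#' @param top_frac Fraction of strongest entries set to 1 (default 0.2); ties
#'   at the threshold are included, zeros never are.
#' @param box_w Box-filter radius.
#' @param restart_p,tol,max_iter Random-walk parameters; see [random_walk()].
#' @return A `schic_embedding`.
#' @export
embed_schicluster <- function(contacts, bins, d = 2, resolution = NULL,
                              pcs_per_chrom = 20, top_frac = 0.2, box_w = 1,
                              restart_p = 0.5, tol = 1e-6, max_iter = 30L,
                              min_bp = 0, max_bp = Inf) {
  res <- contacts_resolution(contacts, resolution)
  contacts <- truncate_distance(contacts, min_bp, max_bp, res)
  ids <- cell_ids(contacts)
  if (length(ids) < 2) abort("Need at least 2 cells.")
  blocks <- list()
  for (ch in names(bins)) {
    M <- bins[[ch]]
    if (M < 2) {
      warn(sprintf("Skipping chromosome %s with < 2 bins.", ch))
      next
    }
    ut <- upper.tri(matrix(0, M, M), diag = TRUE)
    flat <- matrix(0, length(ids), sum(ut))
    for (ci in seq_along(ids)) {
      m <- contact_matrix(contacts, ch, bins, cell = ids[ci])
      m <- vc_sqrt_norm(m)
      if (box_w > 0) m <- box_filter(m, box_w)
      m <- random_walk(m, restart_p = restart_p, tol = tol,
                       max_iter = max_iter)
      v <- m[ut]
      thr <- quantile(v, 1 - top_frac, names = FALSE)
      flat[ci, ] <- as.numeric(v >= thr & v > 0)
    }
    k <- min(pcs_per_chrom, length(ids) - 1L, ncol(flat))
    blocks[[ch]] <- pca_scores(flat, k)
  }
  if (!length(blocks)) abort("No usable chromosome.")
  concat <- do.call(cbind, blocks)
  new_embedding(pca_scores(concat, d), ids,
                list(backend = "schicluster", resolution = res, d = d,
                     min_bp = min_bp, max_bp = max_bp,
                     transforms = c("vc_sqrt_norm", "box_filter",
                                    "random_walk", "binarize")))
}

#' Stratum inner-product cell similarity
#'
#' For each chromosome and stratum `s`, the similarity of cells i and j is the
#' inner product of their z-scored stratum vectors divided by the stratum
#' length (a Pearson correlation). Uniform stratum weights give the
#' inner-product method; `weights = "scc"` weights strata by
#' `N_s * sigma_i,s * sigma_j,s` (computed on the raw strata), the
#' stratum-adjusted correlation coefficient. Chromosomes are aggregated by
#' `chrom_agg` (default median).
#'
#' @inheritParams embed_1d_pca
#' @param min_bp,max_bp Strata window: stratum `s` is used when
#'   `min_bp <= s * resolution < max_bp` (default window up to 20 Mb).
#' @param weights `"uniform"` (inner product) or `"scc"` (fastHiCRep-style).
#' @param chrom_agg `"median"` or `"mean"` across chromosomes.
#' @return A symmetric N x N similarity matrix of class `schic_similarity`.
#' @export
similarity_innerproduct <- function(contacts, bins, resolution = NULL,
                                    min_bp = 0, max_bp = 20e6,
                                    weights = c("uniform", "scc"),
                                    chrom_agg = c("median", "mean")) {
  res <- contacts_resolution(contacts, resolution)
  weights <- match.arg(weights)
  chrom_agg <- match.arg(chrom_agg)
  ids <- cell_ids(contacts)
  N <- length(ids)
  if (N < 2) abort("Need at least 2 cells.")
  per_chrom <- list()
  for (ch in names(bins)) {
    M <- bins[[ch]]
    s_all <- 0:(M - 1L)
    s_use <- s_all[s_all * res >= min_bp & s_all * res < max_bp & s_all < M - 1L]
    if (max_bp / res > M && !length(per_chrom)) {
      warn(sprintf("Stratum window clipped to %d bins on chromosome %s.",
                   M, ch))
    }
    if (!length(s_use)) next
    df <- contacts[contacts$chrom == ch, , drop = FALSE]
    dd <- df$bin2 - df$bin1
    num <- matrix(0, N, N)
    den <- if (weights == "scc") matrix(0, N, N) else 0
    for (s in s_use) {
      len <- M - s
      sel <- dd == s
      sub <- df[sel, , drop = FALSE]
      Z <- matrix(0, N, len)
      if (nrow(sub)) {
        Z[cbind(match(sub$cell_id, ids), sub$bin1 + 1L)] <- sub$count
      }
      mu <- rowMeans(Z)
      sdv <- sqrt(rowMeans(Z^2) - mu^2)
      Zs <- (Z - mu) / ifelse(sdv > 0, sdv, 1)
      Zs[sdv == 0, ] <- 0
      sim_s <- tcrossprod(Zs) / len
      if (weights == "scc") {
        w_s <- len * tcrossprod(sdv)
        num <- num + w_s * sim_s
        den <- den + w_s
      } else {
        num <- num + sim_s
        den <- den + 1
      }
    }
    sim_ch <- num / ifelse(den > 0, den, 1)
    if (is.matrix(den)) sim_ch[den == 0] <- 0
    per_chrom[[ch]] <- sim_ch
  }
  if (!length(per_chrom)) abort("No usable stratum in the window.")
  arr <- simplify2array(per_chrom)
  S <- if (length(per_chrom) == 1L) per_chrom[[1]] else {
    apply(arr, c(1, 2), if (chrom_agg == "median") median else mean)
  }
  S <- (S + t(S)) / 2
  dimnames(S) <- list(ids, ids)
  structure(S, class = c("schic_similarity", "matrix", "array"),
            kind = if (weights == "scc") "scc-weighted" else "inner-product",
            meta = list(resolution = res, min_bp = min_bp, max_bp = max_bp,
                        chrom_agg = chrom_agg))
}

#' Classical (Torgerson) MDS embedding of a similarity matrix
#'
#' Similarities are clipped to `[-1, 1]` and converted to distances
#' `sqrt(2 (1 - s))`; the doubly centered squared-distance matrix is
#' eigendecomposed and the top `d` nonnegative eigenpairs give coordinates.
#'
#' @param s A `schic_similarity` (or any symmetric similarity matrix with cell
#'   ids as dimnames).
#' @param d Number of output dimensions.
#' @return A `schic_embedding`.
#' @export
embed_mds <- function(s, d = 2) {
  S <- pmin(pmax(unclass(s), -1), 1)
  n <- nrow(S)
  D2 <- 2 * (1 - S)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  pos <- sum(ev$values > 1e-12)
  k <- min(d, pos)
  coords <- if (k > 0) {
    ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev$values[seq_len(k)]), k, k)
  } else {
    matrix(0, n, 0)
  }
  if (k < d) {
    warn(sprintf("Only %d positive eigenvalues; padding %d dims with zeros.",
                 k, d - k))
    coords <- cbind(coords, matrix(0, n, d - k))
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  meta <- attr(s, "meta") %||% list()
  meta$backend <- paste0("mds_",
                         sub("-weighted", "", attr(s, "kind") %||% "similarity"))
  meta$d <- d
  new_embedding(coords, rownames(S) %||% as.character(seq_len(n)), meta)
}

#' IDF-weighted spectral embedding of locus-pair features
#'
#' Builds the cell x locus-pair matrix within the distance window, applies
#' quantile/top-N feature selection and IDF weighting, computes the cosine
#' similarity between cells, symmetrically normalizes it, and embeds cells
#' with the top nontrivial eigenvectors.
#'
#' @inheritParams embed_1d_pca
#' @param q_low,q_high,top_n Feature selection parameters; see
#'   [select_features()].
#' @return A `schic_embedding`.
#' @export
embed_spectral_idf <- function(contacts, bins, d = 2, resolution = NULL,
                               min_bp = 0, max_bp = 20e6, q_low = 0.005,
                               q_high = 0.005, top_n = 500000) {
  res <- contacts_resolution(contacts, resolution)
  x <- feature_matrix(contacts, bins, res, min_bp, max_bp)
  x <- select_features(x, q_low, q_high, top_n)
  x <- idf_transform(x)
  rs <- Matrix::rowSums(x != 0)
  if (any(rs == 0)) {
    abort(sprintf("Cell '%s' has no features after selection.",
                  rownames(x)[which(rs == 0)[1]]))
  }
  nrm <- sqrt(Matrix::rowSums(x^2))
  xn <- x / nrm
  S <- as.matrix(Matrix::tcrossprod(xn))
  Dm <- rowSums(S)
  Shat <- S / sqrt(outer(Dm, Dm))
  ev <- eigen((Shat + t(Shat)) / 2, symmetric = TRUE)
  if (d + 1 > ncol(ev$vectors)) abort("`d` too large for the cell count.")
  # eigenvalue weighting keeps informative components from being swamped by
  # equal-norm noise eigenvectors downstream (e.g. in K-means)
  coords <- ev$vectors[, 2:(d + 1), drop = FALSE] %*%
    diag(ev$values[2:(d + 1)], d, d)
  for (j in seq_len(d)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  new_embedding(coords, rownames(x),
                list(backend = "spectral_idf", resolution = res, d = d,
                     min_bp = min_bp, max_bp = max_bp,
                     transforms = c("select_features", "idf_transform")))
}

#' Topic-model embedding of locus pairs (LDA)
#'
#' Treats each cell as a document whose words are its locus pairs and fits
#' latent Dirichlet allocation by collapsed Gibbs sampling; the embedding is
#' the smoothed per-cell topic distribution (rows sum to 1).
#'
#' @inheritParams embed_1d_pca
#' @param topics Number of topics.
#' @param alpha Document-topic prior (default `50 / topics`).
#' @param beta Topic-word prior.
#' @param iters Gibbs sweeps.
#' @param seed Integer seed for the sampler.
#' @return A `schic_embedding` with `topics` dimensions.
#' @export
embed_lda <- function(contacts, bins, resolution = NULL, min_bp = 0,
                      max_bp = 20e6, topics = 10, alpha = NULL, beta = 0.1,
                      iters = 300, seed = 1L) {
  res <- contacts_resolution(contacts, resolution)
  if (topics < 1) abort("`topics` must be >= 1.")
  alpha <- alpha %||% (50 / topics)
  x <- feature_matrix(contacts, bins, res, min_bp, max_bp)
  if (!ncol(x)) abort("Empty vocabulary.")
  ids <- rownames(x)
  if (topics == 1L) {
    return(new_embedding(matrix(1, length(ids), 1), ids,
                         list(backend = "lda", resolution = res, topics = 1)))
  }
  xt <- as(x, "TsparseMatrix")
  docs <- lapply(seq_along(ids), function(ci) {
    sel <- xt@i == ci - 1L
    cbind(xt@j[sel], as.integer(round(xt@x[sel])))
  })
  theta <- lda_gibbs(docs, ncol(x), as.integer(topics), alpha, beta,
                     as.integer(iters), as.integer(seed))
  new_embedding(theta, ids,
                list(backend = "lda", resolution = res, topics = topics,
                     min_bp = min_bp, max_bp = max_bp, seed = seed))
}

#' Insulation-score delta-vector embedding
#'
#' Per bin, aggregates contacts in a `window_w`-bin square straddling the bin,
#' log2-normalizes by the chromosome mean, takes the difference of mean
#' normalized insulation ahead of and behind each bin (`delta_w` bins), and
#' embeds the concatenated delta vectors with PCA.
#'
#' @inheritParams embed_1d_pca
#' @param window_w Insulation window radius in bins.
#' @param delta_w Delta half-window in bins.
#' @return A `schic_embedding`.
#' @export
embed_insulation <- function(contacts, bins, d = 2, resolution = NULL,
                             window_w = 10L, delta_w = 3L,
                             min_bp = 0, max_bp = Inf) {
  res <- contacts_resolution(contacts, resolution)
  contacts <- truncate_distance(contacts, min_bp, max_bp, res)
  if (window_w < 1 || delta_w < 1) abort("Window sizes must be >= 1.")
  ids <- cell_ids(contacts)
  if (length(ids) < 2) abort("Need at least 2 cells.")
  blocks <- list()
  for (ch in names(bins)) {
    M <- bins[[ch]]
    if (M < 2 * window_w + 1) {
      warn(sprintf("Skipping chromosome %s: fewer than %d bins.", ch,
                   2 * window_w + 1))
      next
    }
    delta <- matrix(0, length(ids), M)
    for (ci in seq_along(ids)) {
      m <- contact_matrix(contacts, ch, bins, cell = ids[ci])
      delta[ci, ] <- insulation_delta(m, window_w, delta_w)
    }
    blocks[[ch]] <- delta
  }
  if (!length(blocks)) abort("No usable chromosome.")
  concat <- do.call(cbind, blocks)
  new_embedding(pca_scores(concat, d), ids,
                list(backend = "insulation", resolution = res, d = d,
                     window_w = window_w, delta_w = delta_w,
                     min_bp = min_bp, max_bp = max_bp))
}

# Normalized insulation and its delta vector for one dense matrix.
insulation_delta <- function(m, w, dw) {
  M <- nrow(m)
  S <- matrix(0, M + 1, M + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  area <- function(i1, i2, j1, j2) {
    S[i2 + 1, j2 + 1] - S[i1, j2 + 1] - S[i2 + 1, j1] + S[i1, j1]
  }
  ins <- rep(NA_real_, M)
  idx <- (w + 1):(M - w)          # 1-based bins with a full window
  for (i in idx) ins[i] <- area(i - w, i - 1, i + 1, i + w)
  defined <- !is.na(ins)
  nv <- numeric(M)
  mn <- mean(ins[defined])
  if (is.finite(mn) && mn > 0) {
    pos <- defined & ins > 0
    nv[pos] <- log2(ins[pos] / mn)
  }
  delta <- numeric(M)
  for (i in seq_len(M)) {
    ahead <- intersect((i + 1):(i + dw), seq_len(M))
    behind <- intersect((i - dw):(i - 1), seq_len(M))
    if (length(ahead) && length(behind) && i > 1 && i < M) {
      delta[i] <- mean(nv[ahead]) - mean(nv[behind])
    }
  }
  delta
}
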