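# Clustering and the evaluation metric stack: K-means, ARI, NMI, cosine ASW,
# AvgBIO, the repeat harness, and the median-rank summary.

#' K-means clustering of an embedding
#'
#' @param e A `schic_embedding`.
#' @param k Number of clusters (2..N).
#' @param seed Integer seed; fixed seeds give identical labels.
#' @param nstart Number of random restarts (default 10).
#' @return Tibble with `cell_id` and integer `label`.
#' @export
kmeans_cluster <- function(e, k, seed = 1L, nstart = 10L) {
  x <- embedding_coords(e)
  if (k > nrow(x)) abort("`k` cannot exceed the number of cells.")
  if (k < 2) abort("`k` must be >= 2.")
  if (k == nrow(x)) { # trivial partition: every cell its own cluster
    return(tibble(cell_id = rownames(x), label = seq_len(k)))
  }
  fit <- with_seed(seed, kmeans(x, centers = k, nstart = nstart,
                                iter.max = 100L))
  tibble(cell_id = rownames(x), label = as.integer(fit$cluster))
}

# Align two label vectors (or tibbles with cell_id/label) into integer codes.
align_labels <- function(u, v) {
  if (is.data.frame(u)) {
    if (is.data.frame(v)) {
      v <- v$label[match(u$cell_id, v$cell_id)]
    }
    u <- u$label
  } else if (is.data.frame(v)) {
    v <- v$label
  }
  if (length(u) != length(v) || anyNA(v) || anyNA(u)) {
    abort("Label vectors must have equal length and matching cells.")
  }
  list(u = as.integer(factor(u)), v = as.integer(factor(v)))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions; 1 iff the
#' partitions are identical up to relabeling, 0 expected under random
#' labeling.
#'
#' @param u,v Label vectors (or tibbles with `cell_id` and `label`).
#' @return A number in `[-1, 1]`.
#' @export
ari <- function(u, v) {
  al <- align_labels(u, v)
  tab <- table(al$u, al$v)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  max_ri <- (sum_i + sum_j) / 2
  if (max_ri == expected) return(ifelse(sum_ij == max_ri, 1, 0))
  (sum_ij - expected) / (max_ri - expected)
}

#' Normalized mutual information
#'
#' Mutual information of the two partitions normalized by the arithmetic mean
#' of their entropies, clipped to `[0, 1]`.
#'
#' @inheritParams ari
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(u, v) {
  al <- align_labels(u, v)
  tab <- table(al$u, al$v)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  denom <- (h(pi) + h(pj)) / 2
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

#' Average silhouette width with cosine distance
#'
#' Mean silhouette coefficient over cells using the ground-truth labels and
#' cosine distance in the embedding space. Cells in singleton classes are
#' excluded from the mean.
#'
#' @param e A `schic_embedding`.
#' @param labels Label vector or tibble with `cell_id` and `label`.
#' @return A number in `[-1, 1]`.
#' @export
asw <- function(e, labels) {
  x <- embedding_coords(e)
  if (is.data.frame(labels)) {
    labels <- labels$label[match(rownames(x), labels$cell_id)]
  }
  lab <- as.integer(factor(labels))
  if (length(unique(lab)) < 2) abort("ASW needs at least 2 classes.")
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  cs <- tcrossprod(x / nrm)
  D <- 1 - pmin(pmax(cs, -1), 1)
  n <- nrow(D)
  sizes <- tabulate(lab)
  sil <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (sizes[lab[i]] < 2) next
    a <- sum(D[i, lab == lab[i]]) / (sizes[lab[i]] - 1)
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(D[i, lab == g]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil, na.rm = TRUE)
}

#' Cumulative biological-conservation score
#'
#' Mean of ARI, NMI, and (by default) ASW rescaled from `[-1, 1]` to
#' `[0, 1]` so the three terms share a scale.
#'
#' @param ari_val,nmi_val,asw_val Metric values in their native ranges.
#' @param rescale_asw Rescale ASW to `[0, 1]` before averaging.
#' @return A number.
#' @export
avgbio <- function(ari_val, nmi_val, asw_val, rescale_asw = TRUE) {
  a <- if (rescale_asw) (asw_val + 1) / 2 else asw_val
  (ari_val + nmi_val + a) / 3
}

#' Repeated evaluation of an embedding pipeline
#'
#' Re-runs the (possibly stochastic) embedding and the K-means clustering
#' `n_repeats` times with derived seeds `base_seed + i` and reports
#' ARI/NMI/ASW/AvgBIO per repeat with mean and standard error.
#'
#' @param embed_fun Function taking a single integer seed and returning a
#'   `schic_embedding`; deterministic backends may ignore the seed. A fixed
#'   `schic_embedding` may be passed instead.
#' @param truth Tibble with `cell_id` and `label` (ground truth).
#' @param k Number of clusters (default: number of truth classes).
#' @param n_repeats Number of repeats (default 5).
#' @param base_seed Base seed.
#' @return A `schic_eval` tibble: one row per repeat plus summary attributes;
#'   see [glance.schic_eval()].
#' @export
repeat_eval <- function(embed_fun, truth, k = NULL, n_repeats = 5,
                        base_seed = 1L) {
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  k <- k %||% length(unique(truth$label))
  if (inherits(embed_fun, "schic_embedding")) {
    e_fixed <- embed_fun
    embed_fun <- function(seed) e_fixed
  }
  rows <- purrr::map(seq_len(n_repeats), function(i) {
    seed <- as.integer(base_seed + i)
    e <- embed_fun(seed)
    cl <- kmeans_cluster(e, k, seed = seed)
    a <- ari(truth, cl)
    m <- nmi(truth, cl)
    s <- asw(e, truth)
    tibble(repeat_id = i, seed = seed, ari = a, nmi = m, asw = s,
           avgbio = avgbio(a, m, s))
  })
  out <- bind_rows(rows)
  class(out) <- c("schic_eval", class(out))
  out
}

#' Summary statistics of a repeated evaluation
#'
#' @param x A `schic_eval` tibble from [repeat_eval()].
#' @param ... Unused.
#' @return One-row tibble with mean and SEM of each metric (SEM is `NA` for a
#'   single repeat).
#' @export
glance.schic_eval <- function(x, ...) {
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  tibble(
    n_repeats = nrow(x),
    ari = mean(x$ari), ari_sem = sem(x$ari),
    nmi = mean(x$nmi), nmi_sem = sem(x$nmi),
    asw = mean(x$asw), asw_sem = sem(x$asw),
    avgbio = mean(x$avgbio), avgbio_sem = sem(x$avgbio)
  )
}

#' Median percentile-rank summary across datasets
#'
#' Within each dataset, methods are ranked by score and assigned percentile
#' ranks in `(0, 1]` (1 = best; ties share the mean of their percentile
#' positions; missing method/dataset cells are excluded from that dataset's
#' ranking). Each method is then summarized by its median percentile rank
#' across datasets.
#'
#' @param scores Tibble with columns `method`, `dataset`, `score`.
#' @return Tibble with `method` and `median_rank`, sorted descending.
#' @export
median_rank_summary <- function(scores) {
  ranked <- scores %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$dataset) %>%
    mutate(pct_rank = rank(.data$score, ties.method = "average") /
             dplyr::n()) %>%
    ungroup()
  ranked %>%
    group_by(.data$method) %>%
    summarise(median_rank = median(.data$pct_rank), .groups = "drop") %>%
    arrange(dplyr::desc(.data$median_rank))
}
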