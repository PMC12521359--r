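# Interpretation tools: which genomic distances carry the between-cell
# signal, where cells sit in contact-fraction space, and pseudo-bulk A/B
# compartment calls.

#' Per-stratum similarity profile of every cell
#'
#' Runs the stratum inner-product pipeline but stops before aggregating over
#' strata: for each stratum, per-chromosome z-scored inner products between
#' all cell pairs are medianed over chromosomes, and each cell is summarized
#' by its median similarity to the other cells. Columns (strata) are min-max
#' normalized to `[0, 1]`; constant columns map to 0.
#'
#' @param contacts Contact tibble (at least 3 cells).
#' @param bins Named integer vector of bins per chromosome.
#' @param k Number of strata.
#' @param resolution Bin size in bp.
#' @return Long tibble with `cell_id`, `stratum`, `similarity`.
#' @export
per_strata_heatmap <- function(contacts, bins, k, resolution = NULL) {
  res <- contacts_resolution(contacts, resolution)
  if (k < 1) abort("`k` must be >= 1.")
  ids <- cell_ids(contacts)
  N <- length(ids)
  if (N < 3) abort("Need at least 3 cells.")
  out <- matrix(NA_real_, N, k)
  for (s in seq_len(k) - 1L) {
    per_chrom <- list()
    for (ch in names(bins)) {
      M <- bins[[ch]]
      if (s >= M - 1L) next
      len <- M - s
      df <- contacts[contacts$chrom == ch &
                       contacts$bin2 - contacts$bin1 == s, , drop = FALSE]
      Z <- matrix(0, N, len)
      if (nrow(df)) {
        Z[cbind(match(df$cell_id, ids), df$bin1 + 1L)] <- df$count
      }
      mu <- rowMeans(Z)
      sdv <- sqrt(rowMeans(Z^2) - mu^2)
      Zs <- (Z - mu) / ifelse(sdv > 0, sdv, 1)
      Zs[sdv == 0, ] <- 0
      per_chrom[[ch]] <- tcrossprod(Zs) / len
    }
    if (!length(per_chrom)) next
    sim <- if (length(per_chrom) == 1L) per_chrom[[1]] else {
      apply(simplify2array(per_chrom), c(1, 2), median)
    }
    diag(sim) <- NA # median over *other* cells
    out[, s + 1L] <- apply(sim, 1, median, na.rm = TRUE)
  }
  # column min-max normalization; constant or empty columns -> 0
  for (j in seq_len(k)) {
    v <- out[, j]
    rng <- range(v, na.rm = TRUE)
    out[, j] <- if (!all(is.finite(rng)) || rng[1] == rng[2]) 0 else {
      (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  tibble(cell_id = rep(ids, k),
         stratum = rep(seq_len(k) - 1L, each = N),
         similarity = as.vector(out))
}

#' Contact-fraction scatter table
#'
#' One row per cell with its local (25 kb-2 Mb) and mitotic (2-12 Mb)
#' contact fractions; see [contact_fractions()].
#'
#' @param contacts Contact tibble.
#' @param resolution Bin size in bp.
#' @return Tibble with `cell_id`, `f_local`, `f_mitotic`.
#' @export
fraction_scatter <- function(contacts, resolution = NULL) {
  contact_fractions(contacts, resolution)
}

#' Plot the contact-fraction scatter
#'
#' @param contacts Contact tibble.
#' @param labels Optional tibble with `cell_id` and `label`.
#' @param resolution Bin size in bp.
#' @return A ggplot object.
#' @export
plot_fraction_scatter <- function(contacts, labels = NULL, resolution = NULL) {
  df <- fraction_scatter(contacts, resolution)
  if (!is.null(labels)) df <- left_join(df, labels, by = "cell_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$f_local,
                                        y = .data$f_mitotic)) +
    ggplot2::labs(x = "local contacts (25 kb-2 Mb)",
                  y = "mitotic contacts (2-12 Mb)") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(color = factor(.data$label))) +
      ggplot2::labs(color = "label")
  } else {
    p + ggplot2::geom_point()
  }
}

#' Pseudo-bulk A/B compartment call (correlation-matrix PC1)
#'
#' Per chromosome: the pooled contact matrix is normalized to
#' observed/expected by distance (expected = per-stratum mean), the Pearson
#' correlation matrix of bins is computed, and the first principal component
#' gives the compartment eigenvector. If reference compartment labels are
#' supplied the sign is oriented to correlate positively with them.
#'
#' @param contacts Pseudo-bulk contact tibble (single pooled cell).
#' @param bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @param reference Optional named list of per-chromosome reference vectors
#'   (+1/-1) used to orient the sign.
#' @return Tibble with `chrom`, `bin`, `pc1`, and the fraction of variance
#'   explained per chromosome as attribute `var_explained`.
#' @export
compartment_pc1 <- function(contacts, bins, resolution = NULL,
                            reference = NULL) {
  res <- contacts_resolution(contacts, resolution)
  rows <- list()
  varexp <- c()
  for (ch in names(bins)) {
    M <- bins[[ch]]
    m <- contact_matrix(contacts, ch, bins)
    if (all(m == 0)) {
      warn(sprintf("Chromosome %s has no contacts; skipped.", ch))
      next
    }
    if (mean(m) < 10) {
      warn(sprintf("Low pseudo-bulk depth on %s (mean %.2f per entry).",
                   ch, mean(m)))
    }
    d <- abs(outer(seq_len(M), seq_len(M), "-"))
    expd <- vapply(0:(M - 1), function(s) mean(m[d == s]), numeric(1))
    oe <- m / expd[d + 1]
    oe[!is.finite(oe)] <- 0
    cm <- suppressWarnings(cor(oe))
    cm[!is.finite(cm)] <- 0
    ev <- eigen((cm + t(cm)) / 2, symmetric = TRUE)
    pc1 <- ev$vectors[, 1]
    tot <- sum(pmax(ev$values, 0))
    ve <- if (tot > 0) max(ev$values[1], 0) / tot else 0
    if (!is.null(reference) && !is.null(reference[[ch]])) {
      if (sum(pc1 * reference[[ch]]) < 0) pc1 <- -pc1
    } else {
      i <- which.max(abs(pc1))
      if (pc1[i] < 0) pc1 <- -pc1
    }
    varexp[ch] <- ve
    rows[[ch]] <- tibble(chrom = ch, bin = seq_len(M) - 1L, pc1 = pc1)
  }
  out <- bind_rows(rows)
  attr(out, "var_explained") <- varexp
  out
}
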