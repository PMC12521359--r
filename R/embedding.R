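# The common result container of every backend: an N x d coordinate tibble
# with provenance metadata, plus broom-style accessors and an autoplot.

new_embedding <- function(coords, cell_ids, meta = list()) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) abort("Embedding coordinates must be finite.")
  colnames(coords) <- paste0("dim_", seq_len(ncol(coords)))
  out <- tibble(cell_id = cell_ids) %>% dplyr::bind_cols(as_tibble(coords))
  attr(out, "meta") <- meta
  class(out) <- c("schic_embedding", class(out))
  out
}

#' Extract the coordinate matrix of an embedding
#'
#' @param e A `schic_embedding`.
#' @return Numeric matrix (cells x dims) with cell ids as row names.
#' @export
embedding_coords <- function(e) {
  m <- as.matrix(e[, startsWith(names(e), "dim_"), drop = FALSE])
  rownames(m) <- e$cell_id
  m
}

#' @export
print.schic_embedding <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<schic_embedding> %d cells x %d dims (%s)\n", nrow(x),
              sum(startsWith(names(x), "dim_")),
              meta$backend %||% "unknown backend"))
  NextMethod()
}

#' @rdname embedding_coords
#' @param x A `schic_embedding`.
#' @param ... Unused.
#' @export
tidy.schic_embedding <- function(x, ...) {
  out <- x
  attr(out, "meta") <- NULL
  class(out) <- setdiff(class(out), "schic_embedding")
  tidyr::pivot_longer(out, dplyr::starts_with("dim_"),
                      names_to = "dimension", values_to = "value")
}

#' @rdname embedding_coords
#' @export
glance.schic_embedding <- function(x, ...) {
  meta <- attr(x, "meta") %||% list()
  tibble(
    backend = meta$backend %||% NA_character_,
    n_cells = nrow(x),
    n_dims = sum(startsWith(names(x), "dim_")),
    resolution = meta$resolution %||% NA_real_,
    min_bp = meta$min_bp %||% NA_real_,
    max_bp = meta$max_bp %||% NA_real_,
    seed = meta$seed %||% NA_integer_,
    transforms = paste(meta$transforms %||% character(), collapse = "+")
  )
}

#' Scatter plot of the first two embedding dimensions
#'
#' @param object A `schic_embedding`.
#' @param labels Optional tibble with `cell_id` and `label` used for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.schic_embedding <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  meta <- attr(object, "meta")
  if (!is.null(labels)) {
    df <- left_join(df, labels, by = "cell_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim_1, y = .data$dim_2)) +
    ggplot2::labs(title = meta$backend %||% NULL) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(color = factor(.data$label)),
                            size = 1.5) +
      ggplot2::labs(color = "label")
  } else {
    p + ggplot2::geom_point(size = 1.5)
  }
}

# PCA with the package-wide determinism convention: features centered but not
# scaled, components sign-fixed so the largest-magnitude loading is positive.
pca_scores <- function(x, d) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (d >= n) abort("`d` must be smaller than the number of cells.")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  k <- min(d, n - 1L, ncol(xc))
  sv <- svd(xc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  if (k < d) {
    warn(sprintf("Only %d informative components; padding %d with zeros.",
                 k, d - k))
    scores <- cbind(scores, matrix(0, n, d - k))
  }
  scores
}
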