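# Matrix-shaped views of contact tables: dense per-chromosome cell matrices,
# per-cell strata sets, and the sparse cell x locus-pair feature matrix.

#' Dense contact matrix for one cell and chromosome
#'
#' @param contacts Contact tibble.
#' @param chrom Chromosome name.
#' @param bins Named integer vector of bins per chromosome.
#' @param cell Cell id; may be omitted when the table holds a single cell.
#' @return A symmetric `M x M` numeric matrix of counts.
#' @export
contact_matrix <- function(contacts, chrom, bins, cell = NULL) {
  M <- bins[[chrom]]
  df <- contacts[contacts$chrom == chrom, , drop = FALSE]
  if (!is.null(cell)) df <- df[df$cell_id == cell, , drop = FALSE]
  m <- matrix(0, M, M)
  if (nrow(df)) {
    sp <- Matrix::sparseMatrix(i = df$bin1 + 1L, j = df$bin2 + 1L,
                               x = df$count, dims = c(M, M))
    m <- as.matrix(sp)
    dg <- diag(m)
    m <- m + t(m)
    diag(m) <- dg
  }
  m
}

#' Extract the first k diagonals (strata) of a cell's contact matrices
#'
#' Stratum `s` of a chromosome with `M` bins is the length `M - s` vector of
#' counts at genomic distance `s` bins.
#'
#' @param contacts Contact tibble holding a single cell (or filtered to one).
#' @param k Number of strata.
#' @param bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @return A `schic_strata` object: per chromosome, a list of `k` stratum
#'   vectors.
#' @export
build_strata <- function(contacts, k, bins, resolution = NULL) {
  res <- contacts_resolution(contacts, resolution)
  if (length(unique(contacts$cell_id)) > 1L) {
    abort("`build_strata` expects contacts for a single cell.")
  }
  if (k < 1) abort("`k` must be >= 1.")
  strata <- lapply(names(bins), function(ch) {
    M <- bins[[ch]]
    df <- contacts[contacts$chrom == ch, , drop = FALSE]
    lapply(seq_len(min(k, M)) - 1L, function(s) {
      v <- numeric(M - s)
      sel <- df$bin2 - df$bin1 == s
      if (any(sel)) v[df$bin1[sel] + 1L] <- df$count[sel]
      v
    })
  })
  names(strata) <- names(bins)
  structure(list(strata = strata, k = as.integer(k), bins = bins,
                 resolution = res),
            class = "schic_strata")
}

#' @export
print.schic_strata <- function(x, ...) {
  cat(sprintf("<schic_strata> %d strata over %d chromosome(s), %g bp bins\n",
              x$k, length(x$strata), x$resolution))
  invisible(x)
}

#' Z-score each stratum vector
#'
#' Centers and scales every stratum independently with the population (1/n)
#' variance; zero-variance strata map to zero vectors.
#'
#' @param s A `schic_strata` object.
#' @return A `schic_strata` object with standardized strata.
#' @export
zscore_strata <- function(s) {
  if (!inherits(s, "schic_strata")) abort("`s` must be a schic_strata object.")
  s$strata <- lapply(s$strata, function(ch) lapply(ch, zscore_vec))
  s
}

zscore_vec <- function(v) {
  sdv <- pop_sd(v)
  if (sdv == 0) return(numeric(length(v)))
  (v - mean(v)) / sdv
}

#' Cell-by-locus-pair feature matrix
#'
#' One column per observed locus pair (chrom, bin1, bin2) within the distance
#' window; columns ordered by chromosome then bin coordinates, named
#' `chrom:bin1:bin2`. Rows follow the cell order of the contact table.
#'
#' @param contacts Contact tibble.
#' @param bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @param min_bp,max_bp Distance window; a pair at bin distance `d` is kept
#'   when `min_bp <= d * resolution < max_bp`.
#' @return A sparse `dgCMatrix` (cells x features).
#' @export
feature_matrix <- function(contacts, bins, resolution = NULL, min_bp = 0,
                           max_bp = Inf) {
  res <- contacts_resolution(contacts, resolution)
  ids <- cell_ids(contacts)
  d_bp <- (contacts$bin2 - contacts$bin1) * res
  df <- contacts[d_bp >= min_bp & d_bp < max_bp, , drop = FALSE]
  if (!nrow(df)) abort("No contacts inside the distance window.")
  feats <- df %>%
    distinct(.data$chrom, .data$bin1, .data$bin2) %>%
    arrange(match(.data$chrom, names(bins)), .data$bin1, .data$bin2)
  keys <- paste(feats$chrom, feats$bin1, feats$bin2, sep = ":")
  j <- match(paste(df$chrom, df$bin1, df$bin2, sep = ":"), keys)
  i <- match(df$cell_id, ids)
  Matrix::sparseMatrix(i = i, j = j, x = df$count,
                       dims = c(length(ids), length(keys)),
                       dimnames = list(ids, keys))
}

# Parse the stratum (bin distance) of each feature column.
feature_strata <- function(x) {
  parts <- strsplit(colnames(x), ":", fixed = TRUE)
  b1 <- as.integer(vapply(parts, `[[`, "", 2L))
  b2 <- as.integer(vapply(parts, `[[`, "", 3L))
  b2 - b1
}
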