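# Decoupled preprocessing transforms. Each operates on one of the three data
# views (contact tibble, per-cell strata set, dense cell matrix) and can be
# chained freely before any embedding backend.

#' Restrict contacts to a genomic-distance window
#'
#' Keeps interactions with `min_bp <= distance < max_bp` where distance is
#' `(bin2 - bin1) * resolution`. Idempotent; composing two truncations equals
#' truncating to the window intersection.
#'
#' @param x A contact tibble or a `schic_strata` object.
#' @param min_bp,max_bp Distance window in base pairs (`0 <= min_bp < max_bp`).
#' @param resolution Bin size in bp (contact tibbles only; strata sets carry
#'   their own).
#' @return Object of the same type, restricted to the window.
#' @export
truncate_distance <- function(x, min_bp = 0, max_bp = Inf, resolution = NULL) {
  if (min_bp < 0 || min_bp >= max_bp) {
    abort("Need 0 <= min_bp < max_bp.")
  }
  UseMethod("truncate_distance")
}

#' @export
truncate_distance.data.frame <- function(x, min_bp = 0, max_bp = Inf,
                                         resolution = NULL) {
  res <- contacts_resolution(x, resolution)
  d <- (x$bin2 - x$bin1) * res
  out <- x[d >= min_bp & d < max_bp, , drop = FALSE]
  if (!nrow(out)) warn("Distance window excludes every contact.")
  set_resolution(out, res)
}

#' @export
truncate_distance.schic_strata <- function(x, min_bp = 0, max_bp = Inf,
                                           resolution = NULL) {
  res <- x$resolution
  for (ch in names(x$strata)) {
    for (si in seq_along(x$strata[[ch]])) {
      d <- (si - 1L) * res
      if (d < min_bp || d >= max_bp) {
        x$strata[[ch]][[si]] <- numeric(length(x$strata[[ch]][[si]]))
      }
    }
  }
  x
}

#' Vanilla-coverage square-root normalization
#'
#' `out_ij = m_ij / sqrt(r_i * r_j)` with `r` the row sums; rows with zero
#' coverage are left as zeros. Symmetry and nonnegativity are preserved.
#'
#' @param m Symmetric nonnegative contact matrix.
#' @return Normalized matrix of the same dimension.
#' @export
vc_sqrt_norm <- function(m) {
  r <- rowSums(m)
  d <- ifelse(r > 0, 1 / sqrt(r), 0)
  m * outer(d, d)
}

#' Box-filter smoothing with edge clipping
#'
#' Each entry becomes the mean of the `(2w+1) x (2w+1)` window around it,
#' clipped at the matrix edges (so corner entries average over a smaller
#' window). `w = 0` is the identity.
#'
#' @param m Square matrix.
#' @param w Window radius in bins.
#' @return Smoothed matrix.
#' @export
box_filter <- function(m, w = 1L) {
  M <- nrow(m)
  if (w < 0) abort("`w` must be >= 0.")
  if (w >= M) abort("`w` must be smaller than the matrix dimension.")
  if (w == 0) return(m)
  S <- matrix(0, M + 1, M + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) # S[i+1,j+1] = sum m[1:i,1:j]
  S <- t(S)
  i <- seq_len(M)
  lo <- pmax(i - w, 1L)
  hi <- pmin(i + w, M)
  n1 <- hi - lo + 1L
  # area sum over rows lo_i..hi_i and cols lo_j..hi_j via the integral image
  out <- S[hi + 1, hi + 1] - S[lo, hi + 1] - S[hi + 1, lo] + S[lo, lo]
  out / outer(n1, n1)
}

#' Random-walk imputation with restart
#'
#' With `P` the row-stochastic transition matrix of `m` (zero-coverage rows
#' become self-loops), iterates `R <- p R P + (1 - p) I` from the identity
#' until the largest entry change falls below `tol` or `max_iter` sweeps. The
#' fixed point is `(1 - p) (I - p P)^-1`. The result is symmetrized as
#' `(R + R^T) / 2` unless `symmetrize = FALSE`.
#'
#' @param m Square nonnegative matrix.
#' @param restart_p Walk-continuation probability `p` in (0, 1).
#' @param tol Convergence threshold on `max |Delta R|`.
#' @param max_iter Maximum number of iterations.
#' @param symmetrize Return the symmetrized result.
#' @return Imputed matrix.
#' @export
random_walk <- function(m, restart_p = 0.5, tol = 1e-6, max_iter = 30L,
                        symmetrize = TRUE) {
  if (nrow(m) != ncol(m)) abort("`m` must be square.")
  if (restart_p <= 0 || restart_p >= 1) abort("`restart_p` must be in (0, 1).")
  M <- nrow(m)
  r <- rowSums(m)
  P <- m / ifelse(r > 0, r, 1)
  zero <- which(r == 0)
  if (length(zero)) P[cbind(zero, zero)] <- 1
  I <- diag(M)
  R <- I
  for (it in seq_len(max_iter)) {
    Rn <- restart_p * (R %*% P) + (1 - restart_p) * I
    delta <- max(abs(Rn - R))
    R <- Rn
    if (delta < tol) break
  }
  if (symmetrize) (R + t(R)) / 2 else R
}

#' Inverse-document-frequency weighting of a feature matrix
#'
#' Scales feature `j` by `log(1 + N / (1 + n_j))` where `n_j` is the number of
#' cells with a nonzero entry. The weight is strictly decreasing in `n_j` and
#' the zero pattern is unchanged.
#'
#' @param x Sparse or dense cells-by-features matrix.
#' @return Matrix of the same class and zero pattern.
#' @export
idf_transform <- function(x) {
  N <- nrow(x)
  n_j <- Matrix::colSums(x != 0)
  w <- log(1 + N / (1 + n_j))
  out <- x %*% Matrix::Diagonal(x = w)
  dimnames(out) <- dimnames(x)
  out
}

#' Mean IDF weight per stratum
#'
#' Summarizes the distance bias of the IDF transform: features at distal
#' strata are present in fewer cells and so receive larger weights.
#'
#' @param x Feature matrix from [feature_matrix()].
#' @return Tibble with `stratum` and `mean_idf`.
#' @export
idf_stratum_profile <- function(x) {
  N <- nrow(x)
  n_j <- Matrix::colSums(x != 0)
  w <- log(1 + N / (1 + n_j))
  tibble(stratum = feature_strata(x), idf = w) %>%
    group_by(.data$stratum) %>%
    summarise(mean_idf = mean(.data$idf), .groups = "drop") %>%
    arrange(.data$stratum)
}

#' Quantile and top-N feature selection
#'
#' Drops features whose total count falls below the `q_low` quantile or above
#' the `1 - q_high` quantile of feature totals, then keeps the `top_n`
#' remaining features with the strongest mean signal (ties broken by feature
#' key order).
#'
#' @param x Cells-by-features matrix.
#' @param q_low,q_high Lower/upper tail quantiles to drop (defaults 0.005).
#' @param top_n Number of features to keep (default 5e5).
#' @return The filtered matrix.
#' @export
select_features <- function(x, q_low = 0.005, q_high = 0.005, top_n = 500000) {
  if (q_low < 0 || q_high < 0 || q_low >= 1 - q_high) {
    abort("Need 0 <= q_low < 1 - q_high <= 1.")
  }
  if (top_n < 1) abort("`top_n` must be >= 1.")
  totals <- Matrix::colSums(x)
  lo <- quantile(totals, q_low, names = FALSE)
  hi <- quantile(totals, 1 - q_high, names = FALSE)
  keep <- which(totals >= lo & totals <= hi)
  if (!length(keep)) abort("Feature selection removed every feature.")
  ord <- keep[order(-totals[keep], keep)]
  sel <- sort(head(ord, top_n))
  x[, sel, drop = FALSE]
}
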