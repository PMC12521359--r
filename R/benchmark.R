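# Orchestration: run embedding backends over datasets / resolutions /
# distance windows with the repeat harness, collect long-format metric
# tables, pick best resolutions, and summarize by median percentile rank.

#' Embed a dataset with a named backend
#'
#' Dispatcher over the conventional backends sharing the common contract.
#' `"innerproduct"` and `"fasthicrep"` run the stratum similarity (uniform /
#' SCC weights) followed by classical MDS.
#'
#' @param data A `schic_dataset` (or any list with `contacts`, `bins`,
#'   `resolution`).
#' @param backend One of `"1d_pca"`, `"schicluster"`, `"innerproduct"`,
#'   `"fasthicrep"`, `"spectral_idf"`, `"lda"`, `"insulation"`.
#' @param d Output dimensions (backends with an intrinsic dimension, like
#'   LDA topics, ignore this).
#' @param min_bp,max_bp Distance window in bp.
#' @param seed Seed forwarded to stochastic backends.
#' @param ... Further backend-specific arguments.
#' @return A `schic_embedding`.
#' @export
embed_dataset <- function(data, backend, d = 2, min_bp = 0, max_bp = 20e6,
                          seed = 1L, ...) {
  ct <- data$contacts
  bins <- data$bins
  res <- data$resolution
  dots <- list(...)
  call_bk <- function(fn, args) {
    keep <- dots[intersect(names(dots), setdiff(names(formals(fn)), ""))]
    do.call(fn, c(args, keep))
  }
  switch(
    backend,
    "1d_pca" = call_bk(embed_1d_pca, list(ct, bins, d = d, resolution = res,
                                          min_bp = min_bp, max_bp = max_bp)),
    "schicluster" = call_bk(embed_schicluster,
                            list(ct, bins, d = d, resolution = res,
                                 min_bp = min_bp, max_bp = max_bp)),
    "innerproduct" = embed_mds(call_bk(
      similarity_innerproduct,
      list(ct, bins, res, min_bp = min_bp, max_bp = max_bp,
           weights = "uniform")), d = d),
    "fasthicrep" = embed_mds(call_bk(
      similarity_innerproduct,
      list(ct, bins, res, min_bp = min_bp, max_bp = max_bp,
           weights = "scc")), d = d),
    "spectral_idf" = call_bk(embed_spectral_idf,
                             list(ct, bins, d = d, resolution = res,
                                  min_bp = min_bp, max_bp = max_bp)),
    "lda" = call_bk(embed_lda, list(ct, bins, resolution = res,
                                    min_bp = min_bp, max_bp = max_bp,
                                    seed = seed)),
    "insulation" = call_bk(embed_insulation,
                           list(ct, bins, d = d, resolution = res,
                                min_bp = min_bp, max_bp = max_bp)),
    abort(sprintf("Unknown backend '%s'.", backend))
  )
}

#' Names of the conventional embedding backends
#'
#' @return Character vector accepted by [embed_dataset()].
#' @export
embedding_backends <- function() {
  c("1d_pca", "schicluster", "innerproduct", "fasthicrep", "spectral_idf",
    "lda", "insulation")
}

#' Repeat-evaluate one backend on one dataset
#'
#' Convenience wrapper: builds the embedding function for [repeat_eval()]
#' from a dataset and backend name.
#'
#' @inheritParams embed_dataset
#' @param n_repeats,base_seed Repeat harness settings. Deterministic
#'   backends (all but `"lda"`) are embedded once and only the clustering is
#'   repeated, matching the usual evaluation protocol for deterministic
#'   embeddings.
#' @param k Number of clusters (default: number of truth labels).
#' @param random_walk_first Optionally apply random-walk imputation to every
#'   cell matrix (rebuilding the contact table) before the backend runs.
#' @param ... Backend arguments.
#' @return A `schic_eval` tibble (see [repeat_eval()]).
#' @export
evaluate_backend <- function(data, backend, d = 2, min_bp = 0, max_bp = 20e6,
                             n_repeats = 5, base_seed = 1L, k = NULL,
                             random_walk_first = FALSE, ...) {
  if (random_walk_first) {
    data <- impute_dataset_rw(data)
  }
  dots <- list(...)
  embed_fun <- function(seed) {
    do.call(embed_dataset, c(list(data = data, backend = backend, d = d,
                                  min_bp = min_bp, max_bp = max_bp,
                                  seed = seed), dots))
  }
  if (backend != "lda") {
    embed_fun <- embed_fun(base_seed) # deterministic: cluster repeats only
  }
  repeat_eval(embed_fun, data$labels, k = k, n_repeats = n_repeats,
              base_seed = base_seed)
}

#' Random-walk imputation of every cell in a dataset
#'
#' Applies VC-sqrt normalization, box-filter smoothing and random-walk
#' imputation to each cell's per-chromosome matrix and rebuilds a dense
#' weighted contact table (entries below `prune` of each matrix maximum are
#' dropped to keep tables sparse).
#'
#' @param data A `schic_dataset`.
#' @param restart_p,box_w Transform parameters.
#' @param prune Relative pruning threshold.
#' @return The dataset with imputed contact weights.
#' @export
impute_dataset_rw <- function(data, restart_p = 0.5, box_w = 1,
                              prune = 1e-3) {
  ids <- cell_ids(data$contacts)
  rows <- list()
  for (id in ids) {
    for (ch in names(data$bins)) {
      m <- contact_matrix(data$contacts, ch, data$bins, cell = id)
      m <- vc_sqrt_norm(m)
      if (box_w > 0) m <- box_filter(m, box_w)
      m <- random_walk(m, restart_p = restart_p)
      thr <- prune * max(m)
      idx <- which(m >= thr & upper.tri(m, diag = TRUE), arr.ind = TRUE)
      rows[[paste(id, ch)]] <- tibble(
        cell_id = id, chrom = ch, bin1 = as.integer(idx[, 1] - 1L),
        bin2 = as.integer(idx[, 2] - 1L), count = m[idx])
    }
  }
  data$contacts <- set_resolution(bind_rows(rows), data$resolution)
  data
}

#' Run a benchmark grid
#'
#' Evaluates every (dataset, backend, resolution) combination with the repeat
#' harness; failing runs are recorded and skipped. Reports the long metrics
#' table, the per-dataset best-resolution selection (maximum mean ARI), and
#' the median-percentile-rank summary over datasets (using each backend's
#' best resolution).
#'
#' @param datasets Named list of `schic_dataset` objects.
#' @param backends Character vector of backend names.
#' @param resolutions Optional numeric vector of resolutions (bp); datasets
#'   are coarsened with [rebin_contacts()] as needed. Default: native only.
#' @param d,min_bp,max_bp,n_repeats,base_seed Passed to
#'   [evaluate_backend()].
#' @param ... Extra backend arguments.
#' @return List with `metrics` (per-repeat rows), `summary` (per-run means),
#'   `best` (per dataset x backend), `ranking` (median percentile ranks),
#'   and `failures`.
#' @export
run_benchmark <- function(datasets, backends = embedding_backends(),
                          resolutions = NULL, d = 2, min_bp = 0,
                          max_bp = 20e6, n_repeats = 5, base_seed = 1L, ...) {
  metrics <- list()
  failures <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    ress <- resolutions %||% ds$resolution
    for (res in ress) {
      data <- ds
      if (res != ds$resolution) {
        fac <- res / ds$resolution
        if (fac != round(fac) || fac < 1) {
          failures[[length(failures) + 1]] <- tibble(
            dataset = ds_name, backend = NA_character_, resolution = res,
            reason = "resolution not a multiple of the native one")
          next
        }
        data$contacts <- rebin_contacts(ds$contacts, fac, ds$resolution)
        data$bins <- stats::setNames(as.integer(ceiling(ds$bins / fac)),
                                     names(ds$bins))
        data$resolution <- res
      }
      for (bk in backends) {
        ev <- tryCatch(
          evaluate_backend(data, bk, d = d, min_bp = min_bp, max_bp = max_bp,
                           n_repeats = n_repeats, base_seed = base_seed, ...),
          error = function(e) e)
        if (inherits(ev, "error")) {
          failures[[length(failures) + 1]] <- tibble(
            dataset = ds_name, backend = bk, resolution = res,
            reason = conditionMessage(ev))
          next
        }
        metrics[[length(metrics) + 1]] <- ev %>%
          mutate(dataset = ds_name, backend = bk, resolution = res)
      }
    }
  }
  metrics <- bind_rows(metrics)
  if (!nrow(metrics)) {
    return(list(metrics = metrics, summary = tibble(), best = tibble(),
                ranking = tibble(), failures = bind_rows(failures)))
  }
  summary <- metrics %>%
    group_by(.data$dataset, .data$backend, .data$resolution) %>%
    summarise(across(c("ari", "nmi", "asw", "avgbio"), mean),
              .groups = "drop")
  best <- summary %>%
    group_by(.data$dataset, .data$backend) %>%
    dplyr::slice_max(.data$ari, n = 1, with_ties = FALSE) %>%
    ungroup()
  ranking <- median_rank_summary(
    best %>% select(method = "backend", dataset = "dataset", score = "ari"))
  list(metrics = metrics, summary = summary, best = best, ranking = ranking,
       failures = bind_rows(failures))
}

#' Depth-robustness downsampling sweep
#'
#' Downsamples every cell to each fraction and re-evaluates the chosen
#' backends, mirroring sequencing-depth stress tests.
#'
#' @param data A `schic_dataset`.
#' @param fractions Read fractions to evaluate (1 = full depth).
#' @param backends Backend names.
#' @param n_repeats,base_seed,d,min_bp,max_bp See [evaluate_backend()].
#' @param ... Extra backend arguments.
#' @return Tibble with one row per (backend, fraction): mean ARI and SEM.
#' @export
downsample_sweep <- function(data, fractions = c(1, 0.2, 0.1, 0.02),
                             backends = embedding_backends(), n_repeats = 5,
                             base_seed = 1L, d = 2, min_bp = 0,
                             max_bp = 20e6, ...) {
  rows <- list()
  for (fr in fractions) {
    dd <- data
    if (fr < 1) {
      dd$contacts <- downsample_contacts(data$contacts, fr,
                                         seed = base_seed + round(1e3 * fr))
    }
    for (bk in backends) {
      ev <- evaluate_backend(dd, bk, d = d, min_bp = min_bp, max_bp = max_bp,
                             n_repeats = n_repeats, base_seed = base_seed, ...)
      gl <- glance(ev)
      rows[[paste(bk, fr)]] <- tibble(backend = bk, fraction = fr,
                                      ari = gl$ari, ari_sem = gl$ari_sem)
    }
  }
  bind_rows(rows)
}
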