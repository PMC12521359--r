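# Multiscale synthetic scHi-C generator. Cells are multinomial draws over a
# population-specific expected contact map combining power-law distance decay,
# an A/B compartment checkerboard acting beyond a minimum distance, focal loop
# enrichments, and an optional mitotic shift of probability mass into the
# 2-12 Mb band.

#' Define a synthetic cell population
#'
#' @param name Population name (used in cell ids and labels).
#' @param blocks Per-chromosome compartment assignment: named list of numeric
#'   vectors (+1 = A, -1 = B), one entry per bin.
#' @param kappa Compartment strength in `[0, 1)`: same-compartment contacts
#'   beyond `comp_min_bp` are scaled by `1 + kappa`, cross-compartment by
#'   `1 - kappa`.
#' @param loops Tibble of loop anchors (`chrom`, `bin1`, `bin2`) or `NULL`.
#' @param lambda Loop enrichment factor (>= 1).
#' @param alpha Power-law decay exponent (> 0): baseline contact probability
#'   falls as `(1 + d)^-alpha` with bin distance `d`.
#' @param mitotic Fraction of probability mass shifted into the 2-12 Mb band
#'   (mitotic-like cells), in `[0, 1)`.
#' @param comp_min_bp Minimum distance (bp) at which the compartment factor
#'   applies.
#' @return A `schic_population` list.
#' @export
population_spec <- function(name, blocks, kappa = 0, loops = NULL,
                            lambda = 1, alpha = 1, mitotic = 0,
                            comp_min_bp = 2e6) {
  if (kappa < 0 || kappa >= 1) abort("`kappa` must be in [0, 1).")
  if (lambda < 1) abort("`lambda` must be >= 1.")
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (mitotic < 0 || mitotic >= 1) abort("`mitotic` must be in [0, 1).")
  structure(list(name = name, blocks = blocks, kappa = kappa,
                 loops = loops, lambda = lambda, alpha = alpha,
                 mitotic = mitotic, comp_min_bp = comp_min_bp),
            class = "schic_population")
}

#' Expected contact matrix of a population
#'
#' `E_ij = (1 + d_ij)^-alpha * c_ij * l_ij` where `c_ij` is the compartment
#' factor (applied at distances >= `comp_min_bp`) and `l_ij` the loop factor.
#'
#' @param pop A `schic_population`.
#' @param chrom Chromosome name.
#' @param bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @return Symmetric positive `M x M` matrix of expected intensities.
#' @export
expected_matrix <- function(pop, chrom, bins, resolution) {
  M <- bins[[chrom]]
  d <- abs(outer(seq_len(M), seq_len(M), "-"))
  E <- (1 + d)^(-pop$alpha)
  if (pop$kappa > 0) {
    b <- pop$blocks[[chrom]]
    if (length(b) != M) abort("Compartment block vector length mismatch.")
    same <- outer(b, b)
    d_comp <- pop$comp_min_bp / resolution
    comp <- 1 + pop$kappa * same
    E <- E * ifelse(d >= d_comp, comp, 1)
  }
  if (!is.null(pop$loops) && pop$lambda > 1) {
    lp <- pop$loops[pop$loops$chrom == chrom, , drop = FALSE]
    if (nrow(lp)) {
      idx <- cbind(lp$bin1 + 1L, lp$bin2 + 1L)
      E[idx] <- E[idx] * pop$lambda
      E[idx[, 2:1, drop = FALSE]] <- E[idx]
    }
  }
  E
}

# Upper-triangle sampling weights of a population across all chromosomes,
# with the mitotic band shift applied. Cached per population by the
# generator.
population_weights <- function(pop, bins, resolution) {
  parts <- lapply(names(bins), function(ch) {
    M <- bins[[ch]]
    E <- expected_matrix(pop, ch, bins, resolution)
    ut <- which(upper.tri(E, diag = TRUE), arr.ind = TRUE)
    w <- E[ut]
    d_bp <- (ut[, 2] - ut[, 1]) * resolution
    tibble(chrom = ch, bin1 = as.integer(ut[, 1] - 1L),
           bin2 = as.integer(ut[, 2] - 1L), w = w,
           band = d_bp > 2e6 & d_bp < 12e6)
  })
  tab <- bind_rows(parts)
  p <- tab$w / sum(tab$w)
  if (pop$mitotic > 0 && any(tab$band)) {
    p_band <- ifelse(tab$band, p, 0)
    p_band <- p_band / sum(p_band)
    p <- (1 - pop$mitotic) * p + pop$mitotic * p_band
  }
  tab$p <- p
  tab
}

#' Sample one cell from a population
#'
#' Draws `depth` contacts from the multinomial distribution over upper
#' triangle locus pairs proportional to the population's expected map (after
#' the mitotic band shift), so `total_cis = depth` exactly.
#'
#' @param pop A `schic_population`.
#' @param depth Number of contacts (>= 1).
#' @param bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @param cell_id Cell id for the output table.
#' @param seed Optional seed (omit when calling inside a seeded generator).
#' @return A contact tibble for one cell.
#' @export
sample_cell <- function(pop, depth, bins, resolution, cell_id = pop$name,
                        seed = NULL) {
  if (depth < 1) abort("`depth` must be >= 1.")
  wt <- population_weights(pop, bins, resolution)
  draw <- function() {
    cnt <- as.vector(stats::rmultinom(1, depth, wt$p))
    sel <- cnt > 0
    tibble(cell_id = cell_id, chrom = wt$chrom[sel], bin1 = wt$bin1[sel],
           bin2 = wt$bin2[sel], count = as.numeric(cnt[sel]))
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  set_resolution(out, resolution)
}

#' Define a synthetic dataset
#'
#' @param populations List of `schic_population` objects.
#' @param n_cells Integer vector of cell counts, one per population.
#' @param bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @param depth_meanlog,depth_sdlog Log-normal per-cell depth distribution
#'   (defaults: median 20000 contacts, sdlog 0.5).
#' @param depth_min Depth floor (default 5001 so the default QC passes by
#'   construction).
#' @param seed Default generation seed.
#' @return A `schic_dataset_spec` list.
#' @export
dataset_spec <- function(populations, n_cells, bins, resolution = 1e5,
                         depth_meanlog = log(20000), depth_sdlog = 0.5,
                         depth_min = 5001, seed = 1L) {
  if (length(populations) < 1) abort("Need at least one population.")
  if (length(n_cells) != length(populations)) {
    abort("`n_cells` must match `populations`.")
  }
  structure(list(populations = populations, n_cells = as.integer(n_cells),
                 bins = bins, resolution = resolution,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 depth_min = depth_min, seed = as.integer(seed)),
            class = "schic_dataset_spec")
}

#' Generate a synthetic labeled scHi-C dataset
#'
#' Deterministic under `seed`: per-cell depths are log-normal draws floored at
#' `depth_min`, and each cell is a multinomial sample from its population's
#' expected map.
#'
#' @param spec A `schic_dataset_spec`.
#' @param seed Seed overriding the spec's default.
#' @return A `schic_dataset` list with `contacts`, `labels` (tibble of
#'   `cell_id`, `label`), `bins`, `chrom_sizes`, `resolution`, and `truth`
#'   (the population specs, for diagnostics oracles).
#' @export
generate_dataset <- function(spec, seed = NULL) {
  seed <- seed %||% spec$seed
  res <- spec$resolution
  out <- with_seed(seed, {
    cells <- list()
    labels <- list()
    for (pi in seq_along(spec$populations)) {
      pop <- spec$populations[[pi]]
      wt <- population_weights(pop, spec$bins, res)
      n <- spec$n_cells[pi]
      depths <- pmax(round(rlnorm(n, spec$depth_meanlog, spec$depth_sdlog)),
                     spec$depth_min)
      for (i in seq_len(n)) {
        id <- sprintf("%s_c%04d", pop$name, i)
        cnt <- as.vector(stats::rmultinom(1, depths[i], wt$p))
        sel <- cnt > 0
        cells[[id]] <- tibble(cell_id = id, chrom = wt$chrom[sel],
                              bin1 = wt$bin1[sel], bin2 = wt$bin2[sel],
                              count = as.numeric(cnt[sel]))
        labels[[id]] <- tibble(cell_id = id, label = pop$name)
      }
    }
    list(contacts = bind_rows(cells), labels = bind_rows(labels))
  })
  structure(list(
    contacts = set_resolution(out$contacts, res),
    labels = out$labels,
    bins = spec$bins,
    chrom_sizes = tibble(chrom = names(spec$bins),
                         length = unname(spec$bins) * res),
    resolution = res,
    truth = list(populations = spec$populations, seed = seed)
  ), class = "schic_dataset")
}

#' @export
print.schic_dataset <- function(x, ...) {
  cat(sprintf(
    "<schic_dataset> %d cells, %d populations, %d chromosome(s), %g bp bins\n",
    length(unique(x$contacts$cell_id)), length(unique(x$labels$label)),
    length(x$bins), x$resolution))
  invisible(x)
}

# Random loop anchors with short-range separations (0.3-1.9 Mb at the default
# resolution), avoiding duplicates.
random_loops <- function(bins, n_per_chrom, resolution, d_range_bp = c(3e5, 1.9e6)) {
  dmin <- max(1L, floor(d_range_bp[1] / resolution))
  dmax <- max(dmin, floor(d_range_bp[2] / resolution))
  bind_rows(lapply(names(bins), function(ch) {
    M <- bins[[ch]]
    d <- sample(dmin:dmax, n_per_chrom, replace = TRUE)
    b1 <- vapply(d, function(dd) sample.int(M - dd, 1L) - 1L, integer(1))
    distinct(tibble(chrom = ch, bin1 = b1, bin2 = b1 + d))
  }))
}

# A global A<->B sign swap leaves outer(b, b) — and so the expected contact
# map — unchanged; a distinguishable "phase" change must move the block
# boundaries, so the shifted variant offsets the checkerboard by `shift`
# bins (default half a block).
checkerboard <- function(bins, block_bins, shift = 0L) {
  out <- lapply(bins, function(M) {
    idx <- (seq_len(M) - 1L + shift) %/% block_bins
    ifelse(idx %% 2L == 0L, 1, -1)
  })
  names(out) <- names(bins)
  out
}

random_blocks <- function(bins, block_bins) {
  out <- lapply(bins, function(M) {
    nb <- ceiling(M / block_bins)
    rep(sample(c(1, -1), nb, replace = TRUE), each = block_bins)[seq_len(M)]
  })
  names(out) <- names(bins)
  out
}

#' Preset synthetic study designs
#'
#' Four fixed population contrasts probing different heterogeneity scales:
#' `"compartment-contrast"` (two populations with opposite checkerboard
#' phase, kappa = 0.4, no loops), `"loop-contrast"` (identical compartments,
#' disjoint population-specific loop sets below 2 Mb, lambda = 6),
#' `"cell-cycle-like"` (interphase-like vs mitotic-like with 50% of mass in
#' the 2-12 Mb band), `"mixed-tissue"` (three populations differing in both
#' compartment blocks and loop sets), and `"easy-mix"` (three populations
#' with strong compartment and loop differences on a compact 200 kb genome;
#' the fixture for the deep embedder).
#'
#' @param name Preset name.
#' @param n_cells_per_pop Cells per population (default 100).
#' @param bins_per_chrom,n_chroms Genome geometry (default 2 x 400 bins).
#' @param resolution Bin size in bp (default 1e5, so 2 Mb = 20 bins).
#' @param seed Seed used both for the fixed population structure (loop
#'   anchors, random blocks) and as the default generation seed.
#' @param depth_meanlog,depth_sdlog,depth_min Depth distribution; defaults:
#'   log-normal with median 20000 cis contacts per cell, floored at 5001.
#' @return A `schic_dataset_spec`.
#' @export
preset_dataset <- function(name = c("compartment-contrast", "loop-contrast",
                                    "cell-cycle-like", "mixed-tissue",
                                    "easy-mix"),
                           n_cells_per_pop = 100, bins_per_chrom = 400,
                           n_chroms = 2, resolution = 1e5, seed = 1L,
                           depth_meanlog = log(20000), depth_sdlog = 0.5,
                           depth_min = 5001) {
  name <- match.arg(name)
  if (name == "easy-mix") {
    # deep-embedder fixture: a compact genome at coarse resolution so the
    # loop-scale window fits in a small band image
    if (missing(bins_per_chrom)) bins_per_chrom <- 64
    if (missing(resolution)) resolution <- 2e5
  }
  bins <- stats::setNames(rep(as.integer(bins_per_chrom), n_chroms),
                          paste0("chr", seq_len(n_chroms)))
  block_bins <- max(1L, round(2e6 / resolution))
  pops <- with_seed(seed, switch(
    name,
    "compartment-contrast" = list(
      population_spec("popA", checkerboard(bins, block_bins), kappa = 0.4),
      population_spec("popB",
                      checkerboard(bins, block_bins,
                                   shift = block_bins %/% 2L),
                      kappa = 0.4)
    ),
    "loop-contrast" = {
      shared <- checkerboard(bins, block_bins)
      list(
        population_spec("popA", shared, kappa = 0.3,
                        loops = random_loops(bins, 50, resolution),
                        lambda = 4),
        population_spec("popB", shared, kappa = 0.3,
                        loops = random_loops(bins, 50, resolution),
                        lambda = 4)
      )
    },
    "cell-cycle-like" = {
      shared <- checkerboard(bins, block_bins)
      list(
        population_spec("interphase", shared, kappa = 0.3, mitotic = 0.02),
        population_spec("mitotic", shared, kappa = 0.3, mitotic = 0.5)
      )
    },
    "mixed-tissue" = lapply(1:3, function(i) {
      population_spec(paste0("pop", i), random_blocks(bins, block_bins),
                      kappa = 0.35,
                      loops = random_loops(bins, 75, resolution),
                      lambda = 6)
    }),
    "easy-mix" = lapply(0:2, function(i) {
      population_spec(paste0("pop", i + 1),
                      checkerboard(bins, block_bins,
                                   shift = round(i * block_bins / 3)),
                      kappa = 0.6,
                      loops = random_loops(bins, 100, resolution),
                      lambda = 8)
    })
  ))
  dataset_spec(pops, rep(n_cells_per_pop, length(pops)), bins,
               resolution = resolution, depth_meanlog = depth_meanlog,
               depth_sdlog = depth_sdlog, depth_min = depth_min, seed = seed)
}
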