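# Internal helpers shared across modules.

# Resolution is carried as an attribute on contact tibbles; functions accept an
# explicit argument that overrides it.
contacts_resolution <- function(contacts, resolution = NULL) {
  res <- resolution %||% attr(contacts, "resolution")
  if (is.null(res)) {
    abort("`resolution` must be supplied (or carried by the contact table).")
  }
  res
}

set_resolution <- function(contacts, resolution) {
  attr(contacts, "resolution") <- resolution
  contacts
}

# Unique cell ids in order of first appearance; the row/coordinate order of
# every embedding.
cell_ids <- function(contacts) unique(contacts$cell_id)

# Named integer vector of bins per chromosome from a chrom-sizes tibble.
bins_from_sizes <- function(chrom_sizes, resolution) {
  stats::setNames(as.integer(ceiling(chrom_sizes$length / resolution)),
                  chrom_sizes$chrom)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}

# Deterministic local RNG scope: saves and restores .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Population (1/n) standard deviation, the convention used for all stratum
# z-scores.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

empty_contacts <- function() {
  tibble(cell_id = character(), chrom = character(),
         bin1 = integer(), bin2 = integer(), count = numeric())
}
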