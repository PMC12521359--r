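#' Read a chromosome-sizes table
#'
#' Two whitespace-separated columns: chromosome name and length in base pairs.
#'
#' @param path Path to the file.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    abort(sprintf("Malformed chrom-sizes line %d in '%s'.", bad[1], path))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    length = as.numeric(vapply(fields, `[[`, "", 2L))
  )
  if (anyNA(out$length) || any(out$length <= 0)) {
    abort(sprintf("Non-positive or non-numeric chromosome length in '%s'.", path))
  }
  out
}

# Parse one pairs-style file into raw (chrom1, pos1, chrom2, pos2, count)
# columns. Layout is auto-detected: if the third field is numeric the file is
# (chrom, pos1, pos2[, count]); otherwise (chrom1, pos1, chrom2, pos2[, count]).
# `cols` overrides auto-detection with 1-based field indices.
parse_pairs_file <- function(path, cols = NULL) {
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (!length(fields)) {
    return(tibble(chrom1 = character(), pos1 = numeric(),
                  chrom2 = character(), pos2 = numeric(),
                  count = numeric(), barcode = character()))
  }
  nf <- lengths(fields)
  if (is.null(cols)) {
    third <- vapply(fields[nf >= 3L], `[[`, "", 3L)
    cis_layout <- length(third) == 0L || !anyNA(suppressWarnings(as.numeric(third)))
    cols <- if (cis_layout) {
      list(chrom1 = 1L, pos1 = 2L, chrom2 = 1L, pos2 = 3L, count = 4L)
    } else {
      list(chrom1 = 1L, pos1 = 2L, chrom2 = 3L, pos2 = 4L, count = 5L)
    }
  }
  need <- max(cols$chrom1, cols$pos1, cols$chrom2, cols$pos2,
              cols$barcode %||% 0L)
  bad <- which(nf < need)
  if (length(bad)) {
    abort(sprintf("Malformed line %d in '%s': expected at least %d fields.",
                  lineno[bad[1]], path, need))
  }
  grab <- function(i) vapply(fields, `[[`, "", i)
  pos1 <- suppressWarnings(as.numeric(grab(cols$pos1)))
  pos2 <- suppressWarnings(as.numeric(grab(cols$pos2)))
  bad <- which(is.na(pos1) | is.na(pos2))
  if (length(bad)) {
    abort(sprintf("Malformed line %d in '%s': non-numeric position.",
                  lineno[bad[1]], path))
  }
  count <- rep(1, length(fields))
  if (!is.null(cols$count)) {
    has <- nf >= cols$count
    cnt <- rep(NA_character_, length(fields))
    cnt[has] <- vapply(fields[has], `[[`, "", cols$count)
    cntn <- suppressWarnings(as.numeric(cnt))
    count[has & !is.na(cntn)] <- cntn[has & !is.na(cntn)]
  }
  barcode <- if (!is.null(cols$barcode)) grab(cols$barcode) else NA_character_
  tibble(chrom1 = grab(cols$chrom1), pos1 = pos1,
         chrom2 = grab(cols$chrom2), pos2 = pos2,
         count = count, barcode = barcode)
}

#' Read per-cell cis contacts from pairs-style text
#'
#' Accepts either one file per cell or a single file with a cell-barcode
#' column. Trans (inter-chromosomal) records are dropped; duplicate pairs are
#' summed after binning; positions are 1-based and bins are 0-based half-open
#' `[bin * resolution, (bin + 1) * resolution)`.
#'
#' @param paths Character vector of file paths (optionally gzip-compressed).
#'   Names are used as cell ids; unnamed paths fall back to file base names.
#' @param chrom_sizes Tibble with columns `chrom` and `length` (bp).
#'   Records on chromosomes absent from this table are dropped.
#' @param resolution Bin size in base pairs.
#' @param cols Optional list of 1-based field indices overriding layout
#'   auto-detection: `chrom1`, `pos1`, `chrom2`, `pos2`, `count`, `barcode`.
#' @param barcode_col For single-file mode, the 1-based index of the
#'   cell-barcode field.
#' @return A contact tibble with columns `cell_id`, `chrom`, `bin1`, `bin2`,
#'   `count` (`bin1 <= bin2`, counts positive, no duplicate keys) and the
#'   resolution attached as an attribute.
#' @export
read_contacts <- function(paths, chrom_sizes, resolution, cols = NULL,
                          barcode_col = NULL) {
  assert_scalar_number(resolution, "resolution")
  if (!is.null(barcode_col)) {
    if (length(paths) != 1L) {
      abort("Single-file mode (`barcode_col`) expects exactly one path.")
    }
    cols <- cols %||% list(chrom1 = 2L, pos1 = 3L, chrom2 = 4L, pos2 = 5L,
                           count = NULL)
    cols$barcode <- barcode_col
  }
  ids <- names(paths) %||% basename(paths)
  if (is.null(names(paths))) names(paths) <- ids
  raw <- purrr::map2(paths, names(paths), function(p, id) {
    df <- parse_pairs_file(p, cols = cols)
    df$cell_id <- if (is.null(barcode_col)) id else df$barcode
    df$path <- p
    df
  })
  raw <- bind_rows(raw)
  if (!nrow(raw)) {
    return(set_resolution(empty_contacts(), resolution))
  }
  # cis only, known chromosomes only
  raw <- raw[raw$chrom1 == raw$chrom2, , drop = FALSE]
  raw <- raw[raw$chrom1 %in% chrom_sizes$chrom, , drop = FALSE]
  if (!nrow(raw)) {
    return(set_resolution(empty_contacts(), resolution))
  }
  len <- stats::setNames(chrom_sizes$length, chrom_sizes$chrom)
  over <- raw$pos1 > len[raw$chrom1] | raw$pos2 > len[raw$chrom1] |
    raw$pos1 < 1 | raw$pos2 < 1
  if (any(over)) {
    i <- which(over)[1]
    abort(sprintf(
      "Position outside chromosome bounds (%s:%g-%g) in '%s'.",
      raw$chrom1[i], raw$pos1[i], raw$pos2[i], raw$path[i]))
  }
  b1 <- as.integer(floor((raw$pos1 - 1) / resolution))
  b2 <- as.integer(floor((raw$pos2 - 1) / resolution))
  out <- tibble(
    cell_id = raw$cell_id, chrom = raw$chrom1,
    bin1 = pmin(b1, b2), bin2 = pmax(b1, b2), count = raw$count
  )
  out <- out %>%
    group_by(.data$cell_id, .data$chrom, .data$bin1, .data$bin2) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$cell_id, .data$chrom, .data$bin1, .data$bin2)
  set_resolution(out, resolution)
}

#' Quality-control filter for cells
#'
#' A cell is dropped when its total cis-contact count is strictly below
#' `min_cis`, or (with `per_chrom_rule`) when any chromosome of length x Mb
#' (x = `ceiling(length / 1e6)`) holds fewer than x contacts.
#'
#' @param contacts Contact tibble.
#' @param chrom_sizes Tibble with `chrom` and `length` (bp); defines the
#'   chromosomes every cell must cover.
#' @param min_cis Minimum total cis contacts (default 5000; some deeper
#'   protocols warrant 50000 or 100000).
#' @param per_chrom_rule Apply the per-chromosome coverage rule.
#' @return A list with `contacts` (kept cells) and `report` (one row per input
#'   cell: `cell_id`, `total_cis`, `pass`, `fail_reason`).
#' @export
qc_filter <- function(contacts, chrom_sizes, min_cis = 5000,
                      per_chrom_rule = TRUE) {
  if (min_cis < 0) abort("`min_cis` must be >= 0.")
  ids <- cell_ids(contacts)
  if (!length(ids)) {
    report <- tibble(cell_id = character(), total_cis = numeric(),
                     pass = logical(), fail_reason = character())
    return(list(contacts = contacts, report = report))
  }
  totals <- contacts %>%
    group_by(.data$cell_id) %>%
    summarise(total_cis = sum(.data$count), .groups = "drop")
  totals <- totals[match(ids, totals$cell_id), ]
  fail_reason <- rep(NA_character_, length(ids))
  low <- totals$total_cis < min_cis
  fail_reason[low] <- "low_total"
  if (per_chrom_rule) {
    x_need <- ceiling(chrom_sizes$length / 1e6)
    per_chrom <- contacts %>%
      group_by(.data$cell_id, .data$chrom) %>%
      summarise(n = sum(.data$count), .groups = "drop")
    grid <- tidyr::expand_grid(cell_id = ids, chrom = chrom_sizes$chrom) %>%
      left_join(per_chrom, by = c("cell_id", "chrom")) %>%
      mutate(n = ifelse(is.na(.data$n), 0, .data$n),
             need = x_need[match(.data$chrom, chrom_sizes$chrom)])
    bad <- grid %>%
      group_by(.data$cell_id) %>%
      summarise(bad = any(.data$n < .data$need), .groups = "drop")
    bad <- bad$bad[match(ids, bad$cell_id)]
    fail_reason[is.na(fail_reason) & bad] <- "chrom_coverage"
  }
  report <- tibble(cell_id = ids, total_cis = totals$total_cis,
                   pass = is.na(fail_reason), fail_reason = fail_reason)
  kept <- contacts[contacts$cell_id %in% ids[report$pass], , drop = FALSE]
  list(contacts = set_resolution(kept, attr(contacts, "resolution")),
       report = report)
}

#' Local and mitotic contact fractions per cell
#'
#' Of contacts at genomic distance > 25 kb, `f_local` is the fraction at
#' 25 kb-2 Mb and `f_mitotic` the fraction at 2-12 Mb (both bands exclusive).
#' Distance is `(bin2 - bin1) * resolution`. Cells with no contact beyond
#' 25 kb get `NA` for both fractions.
#'
#' @param contacts Contact tibble.
#' @param resolution Bin size in bp (defaults to the table's attribute).
#' @return Tibble with `cell_id`, `f_local`, `f_mitotic`.
#' @export
contact_fractions <- function(contacts, resolution = NULL) {
  res <- contacts_resolution(contacts, resolution)
  ids <- cell_ids(contacts)
  d <- (contacts$bin2 - contacts$bin1) * res
  df <- tibble(cell_id = contacts$cell_id, count = contacts$count,
               denom = d > 25e3,
               local = d > 25e3 & d < 2e6,
               mitotic = d > 2e6 & d < 12e6)
  out <- df %>%
    group_by(.data$cell_id) %>%
    summarise(
      denom = sum(.data$count[.data$denom]),
      local = sum(.data$count[.data$local]),
      mitotic = sum(.data$count[.data$mitotic]),
      .groups = "drop"
    ) %>%
    mutate(f_local = ifelse(.data$denom > 0, .data$local / .data$denom, NA_real_),
           f_mitotic = ifelse(.data$denom > 0, .data$mitotic / .data$denom,
                              NA_real_)) %>%
    select("cell_id", "f_local", "f_mitotic")
  out[match(ids, out$cell_id), ]
}

#' Partition cells into G-S-like and mitotic-like populations
#'
#' Fits a 2-sigma covariance ellipse to the `(f_local, f_mitotic)` scatter and
#' splits cells by the line through the supplied cutoff point and the ellipse
#' center. The side containing the pure-interphase corner `(1, 0)` is labeled
#' G-S; the rest mitotic.
#'
#' @param contacts Contact tibble (at least 10 cells).
#' @param resolution Bin size in bp.
#' @param cutoff Numeric length-2 cutoff point in `(f_local, f_mitotic)` space.
#' @return List with `gs` and `mitotic` contact tibbles and `info`, a per-cell
#'   tibble of fractions and assigned side plus the fitted line parameters as
#'   attributes.
#' @export
mitotic_filter <- function(contacts, resolution = NULL,
                           cutoff = c(0.15, 0.35)) {
  res <- contacts_resolution(contacts, resolution)
  fr <- contact_fractions(contacts, res)
  if (nrow(fr) < 10) abort("mitotic_filter needs at least 10 cells.")
  if (anyNA(fr$f_local)) {
    abort("Some cells have undefined contact fractions; QC-filter first.")
  }
  pts <- cbind(fr$f_local, fr$f_mitotic)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (min(ev$values) < 1e-12) {
    abort(paste0("Degenerate (rank-deficient) fraction scatter; ",
                 "set a manual threshold instead."))
  }
  center <- colMeans(pts)
  v <- center - cutoff
  side <- function(p) v[1] * (p[, 2] - cutoff[2]) - v[2] * (p[, 1] - cutoff[1])
  s <- side(pts)
  s_ref <- side(matrix(c(1, 0), 1))
  gs <- if (s_ref >= 0) s >= 0 else s <= 0
  info <- fr %>% mutate(side = ifelse(gs, "G-S", "mitotic"))
  attr(info, "ellipse_center") <- center
  attr(info, "cutoff") <- cutoff
  attr(info, "axes_sd") <- 2 * sqrt(ev$values)
  gs_ids <- fr$cell_id[gs]
  list(
    gs = set_resolution(contacts[contacts$cell_id %in% gs_ids, ], res),
    mitotic = set_resolution(contacts[!contacts$cell_id %in% gs_ids, ], res),
    info = info
  )
}

#' Downsample reads per cell
#'
#' Retains `round(fraction * total)` unit reads per cell, sampled without
#' replacement from the multiset of contacts (multivariate hypergeometric), so
#' each entry's expected retained count is `fraction` times the original.
#'
#' @param contacts Contact tibble.
#' @param fraction Fraction of reads to keep, in (0, 1].
#' @param seed Integer seed.
#' @return A contact tibble of the same shape with reduced counts.
#' @export
downsample_contacts <- function(contacts, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].")
  }
  res <- attr(contacts, "resolution")
  out <- with_seed(seed, {
    parts <- split(seq_len(nrow(contacts)), contacts$cell_id)
    keep_counts <- numeric(nrow(contacts))
    for (rows in parts) {
      cnt <- contacts$count[rows]
      total <- sum(cnt)
      n_keep <- round(fraction * total)
      if (n_keep >= total) {
        keep_counts[rows] <- cnt
      } else if (n_keep > 0) {
        reads <- rep.int(seq_along(rows), cnt)
        sel <- sample(reads, n_keep)
        keep_counts[rows] <- tabulate(sel, nbins = length(rows))
      }
    }
    dplyr::mutate(contacts, count = keep_counts) %>%
      filter(.data$count > 0)
  })
  set_resolution(out, res)
}

#' Pool cells into a pseudo-bulk contact table
#'
#' Entrywise sum of counts across the selected cells; the pooled total equals
#' the sum of member totals.
#'
#' @param contacts Contact tibble.
#' @param cells Optional character vector of cell ids to pool (default all).
#' @param id Cell id given to the pooled pseudo-cell.
#' @return A single-cell contact tibble.
#' @export
pseudobulk <- function(contacts, cells = NULL, id = "pseudobulk") {
  res <- attr(contacts, "resolution")
  df <- if (is.null(cells)) contacts else {
    contacts[contacts$cell_id %in% cells, , drop = FALSE]
  }
  out <- df %>%
    group_by(.data$chrom, .data$bin1, .data$bin2) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(cell_id = id) %>%
    select("cell_id", "chrom", "bin1", "bin2", "count") %>%
    arrange(.data$chrom, .data$bin1, .data$bin2)
  set_resolution(out, res)
}

#' Coarsen a contact table to a larger bin size
#'
#' @param contacts Contact tibble.
#' @param factor Integer rebinning factor (new resolution = old * factor).
#' @param resolution Current bin size in bp.
#' @return Contact tibble at the coarser resolution.
#' @export
rebin_contacts <- function(contacts, factor, resolution = NULL) {
  res <- contacts_resolution(contacts, resolution)
  if (factor < 1 || factor != round(factor)) {
    abort("`factor` must be a positive integer.")
  }
  out <- contacts %>%
    mutate(bin1 = .data$bin1 %/% as.integer(factor),
           bin2 = .data$bin2 %/% as.integer(factor)) %>%
    group_by(.data$cell_id, .data$chrom, .data$bin1, .data$bin2) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  set_resolution(out, res * factor)
}

#' Write per-cell contacts as pairs-style text files
#'
#' Emits one whitespace-separated file per cell with columns chrom, pos1,
#' chrom, pos2 repeated once per unit read, positions at bin starts (1-based),
#' plus a `chrom.sizes` file.
#'
#' @param contacts Contact tibble.
#' @param dir Output directory (created if missing).
#' @param chrom_sizes Tibble with `chrom` and `length`.
#' @param resolution Bin size in bp.
#' @return Invisibly, the written file paths.
#' @export
write_pairs <- function(contacts, dir, chrom_sizes, resolution = NULL) {
  res <- contacts_resolution(contacts, resolution)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(chrom_sizes, file.path(dir, "chrom.sizes"),
                   col_names = FALSE)
  paths <- character()
  for (id in cell_ids(contacts)) {
    df <- contacts[contacts$cell_id == id, ]
    lines <- sprintf("%s\t%d\t%s\t%d\t%d", df$chrom, df$bin1 * res + 1,
                     df$chrom, df$bin2 * res + 1, as.integer(df$count))
    p <- file.path(dir, paste0(id, ".pairs.txt"))
    readr::write_lines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
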