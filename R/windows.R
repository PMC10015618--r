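#' Partition ordered blocks into fixed-size genomic windows
#'
#' Tiles non-overlapping windows of exactly `window_blocks` consecutive
#' blocks along each chromosome (windows never span chromosomes). Trailing
#' blocks that cannot fill a window are dropped and reported.
#'
#' @param blocks A tibble of blocks sorted by (`chrom`, `start`), e.g.
#'   `cut_blocks()$blocks` or any per-block table carrying `chrom` and
#'   `start`/`end`.
#' @param window_blocks Blocks per window.
#' @return The input with a `window_id` column (`NA` for dropped blocks);
#'   the per-window summary is attached as attribute `"windows"` (tibble
#'   `window_id`, `chrom`, `start`, `end`, `n_blocks`) and the dropped count
#'   as attribute `"dropped"`.
#' @examples
#' b <- tibble::tibble(chrom = "c", start = 0:9 * 64, end = 0:9 * 64 + 64)
#' attr(cut_windows(b, 5), "windows")
#' @export
cut_windows <- function(blocks, window_blocks) {
  window_blocks <- assert_count(window_blocks, "window_blocks")
  blocks <- as_tibble(blocks)
  blocks <- arrange(blocks, .data$chrom, .data$start)
  out <- blocks |>
    group_by(.data$chrom) |>
    mutate(.widx = (row_number() - 1L) %/% window_blocks,
           .full = .data$.widx < n() %/% window_blocks) |>
    ungroup()
  key <- paste(out$chrom, out$.widx)
  key[!out$.full] <- NA
  out$window_id <- match(key, unique(stats::na.omit(key)))
  dropped <- sum(!out$.full)
  if (dropped > 0) {
    inform(sprintf("%d trailing block(s) did not fill a window and were dropped",
                   dropped))
  }
  short <- out |>
    group_by(.data$chrom) |>
    summarise(nb = n(), .groups = "drop") |>
    filter(.data$nb < window_blocks)
  if (nrow(short) > 0) {
    warn(sprintf("chromosome(s) with fewer than %d blocks yield no windows: %s",
                 window_blocks, paste(short$chrom, collapse = ", ")))
  }
  full <- filter(out, !is.na(.data$window_id))
  windows <- if (nrow(full) == 0) {
    tibble(window_id = integer(), chrom = character(), start = numeric(),
           end = numeric(), n_blocks = integer())
  } else {
    full |>
      group_by(.data$window_id, .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end),
                n_blocks = n(), .groups = "drop") |>
      arrange(.data$window_id)
  }
  out <- select(out, -".widx", -".full")
  structure(out, windows = windows, dropped = dropped)
}

#' Scale the window block count to a different number of sample pairs
#'
#' Windows are defined by a block count; with fewer sampled pairs (e.g. the
#' male-only Z-chromosome analysis) the count is reduced proportionally so
#' windows keep a comparable genomic span:
#' `round(base_blocks * new_pairs / base_pairs)`.
#'
#' @param base_blocks Blocks per window in the reference analysis.
#' @param base_pairs,new_pairs Numbers of sampled diploid pairs.
#' @return The scaled block count (integer).
#' @examples
#' scale_window_block_count(30000, 42, 6) # 4286
#' @export
scale_window_block_count <- function(base_blocks, base_pairs, new_pairs) {
  base_blocks <- assert_count(base_blocks, "base_blocks")
  base_pairs <- assert_count(base_pairs, "base_pairs")
  new_pairs <- assert_count(new_pairs, "new_pairs")
  as.integer(round(base_blocks * new_pairs / base_pairs))
}

#' Aggregate per-block mutation counts into per-window tallies
#'
#' @param block_counts A per-block table with `window_id` (from
#'   [cut_windows()]) and raw count columns `hetA`, `hetB`, `hetAB`, `fixed`.
#' @param kmax Per-type truncation.
#' @return A (windows x bins) integer matrix of bin counts in canonical bin
#'   order, rownames = window ids.
#' @export
window_tallies <- function(block_counts, kmax = c(2, 2, 2, 2)) {
  kmax <- as.integer(kmax)
  bc <- filter(as_tibble(block_counts), !is.na(.data$window_id))
  idx <- bin_index(truncate_counts(bc, kmax), kmax)
  wids <- sort(unique(bc$window_id))
  m <- matrix(0L, length(wids), prod(kmax + 2L),
              dimnames = list(wids, NULL))
  tb <- table(factor(bc$window_id, levels = wids), factor(idx, levels = seq_len(ncol(m))))
  m[, ] <- as.integer(tb)
  m
}

#' Grid-scan windows for local demographic parameters
#'
#' Computes the composite lnCL of every window tally at every grid point,
#' records the maximum-composite-likelihood (MCL) point per window and the
#' conditional lnCL profile over the `me` grid (the MCL over grid points
#' sharing each fixed `me`). Ties at the maximum are broken toward smaller
#' `me`, then smaller `ne_a`.
#'
#' @param wtallies A (windows x bins) count matrix from [window_tallies()].
#' @param grid_tables An [evaluate_grid()] result.
#' @param window_info Optional tibble (`window_id`, `chrom`, `start`, `end`)
#'   joined onto the results, e.g. `attr(cut_windows(...), "windows")`.
#' @return A `window_results` tibble: per window the MCL parameters (`ne_a`,
#'   `ne_b`, `ne_anc`, `me`), `lnCL`, and a `profile` list-column of tibbles
#'   (`me`, `lnCL`) with one row per `me` grid value. Windows with empty
#'   tallies are skipped with a diagnostic.
#' @export
window_scan <- function(wtallies, grid_tables, window_info = NULL) {
  stopifnot(inherits(grid_tables, "grid_tables"))
  grid <- grid_tables$grid
  logp <- grid_tables$log_prob
  ok_pts <- which(!is.na(colSums(logp)))
  if (length(ok_pts) == 0) abort("grid cache contains no usable points")
  empty <- rowSums(wtallies) == 0
  if (any(empty)) {
    warn(sprintf("%d window(s) with empty tallies were skipped", sum(empty)))
  }
  wt <- wtallies[!empty, , drop = FALSE]
  lnCL <- wt %*% logp[, ok_pts, drop = FALSE]   # windows x points
  gpts <- grid[ok_pts, ]
  # tie-break order: smaller me, then smaller ne_a
  pref <- order(gpts$me, gpts$ne_a)
  me_values <- sort(unique(gpts$me))

  res <- purrr::map_dfr(seq_len(nrow(wt)), function(w) {
    v <- lnCL[w, ]
    best <- pref[which.max(v[pref])]
    prof <- tibble(
      me = me_values,
      lnCL = vapply(me_values, function(m) max(v[gpts$me == m]), numeric(1))
    )
    tibble(
      window_id = as.integer(rownames(wt)[w]),
      ne_a = gpts$ne_a[best], ne_b = gpts$ne_b[best],
      ne_anc = gpts$ne_anc[best], me = gpts$me[best],
      lnCL = v[best], profile = list(prof)
    )
  })
  if (!is.null(window_info)) {
    res <- left_join(res, as_tibble(window_info), by = "window_id")
  }
  structure(res, class = c("window_results", class(res)))
}

#' Flag barrier windows
#'
#' A window is a barrier iff the conditional composite likelihood at
#' `me = 0` strictly exceeds the one at the background `me` grid value
#' (the grid value nearest the genome-wide estimate); equality is not a
#' barrier.
#'
#' @param results A [window_scan()] result (needs the `profile` column).
#' @param me_background Background `me` grid value; must be on the profile.
#' @return `results` with a logical `barrier` column and
#'   `delta_lnCL_barrier = lnCL(me = 0) - lnCL(me_background)`.
#' @export
classify_barrier <- function(results, me_background) {
  stopifnot("profile" %in% names(results))
  delta <- vapply(results$profile, function(p) {
    i0 <- which(p$me == 0)
    ib <- which(p$me == me_background)
    if (length(i0) != 1 || length(ib) != 1) {
      abort("profile must contain both me = 0 and the background me value")
    }
    p$lnCL[i0] - p$lnCL[ib]
  }, numeric(1))
  results$delta_lnCL_barrier <- delta
  results$barrier <- delta > 0
  results
}

#' Per-chromosome summaries of the me scan
#'
#' Assigns each window to a chromosome, averages the window MCL `me` per
#' chromosome, reports per-chromosome barrier fractions, and computes
#' Spearman's rank correlation between chromosome length and mean `me`
#' (with exact-tie handling; an undefined correlation — e.g. constant mean
#' `me` — is reported as `NA`).
#'
#' @param results A (barrier-classified) [window_scan()] table.
#' @param assignment Optional tibble (`window_id`, `chromosome`) mapping
#'   windows onto the coordinate system of interest (e.g. the donor genome
#'   via a whole-genome alignment); if missing, the `chrom` column of
#'   `results` is used. Unassigned windows are excluded with a note.
#' @param lengths Named numeric vector of chromosome lengths.
#' @return A list with `chromosomes` (tibble `chromosome`, `n_windows`,
#'   `mean_me`, `barrier_fraction`, `length`) and `spearman`
#'   (list `rho`, `p_value`).
#' @export
summarize_chromosomes <- function(results, assignment = NULL, lengths) {
  res <- as_tibble(results)
  if (!is.null(assignment)) {
    res <- inner_join(select(res, -dplyr::any_of("chromosome")),
                      as_tibble(assignment), by = "window_id")
  } else if ("chrom" %in% names(res)) {
    res$chromosome <- res$chrom
  }
  if (!"chromosome" %in% names(res)) {
    abort("no chromosome assignment available for the windows")
  }
  n_missing <- sum(is.na(res$chromosome))
  if (n_missing > 0) {
    inform(sprintf("%d unassigned window(s) excluded", n_missing))
    res <- filter(res, !is.na(.data$chromosome))
  }
  chroms <- res |>
    group_by(.data$chromosome) |>
    summarise(
      n_windows = n(),
      mean_me = mean(.data$me),
      barrier_fraction = if ("barrier" %in% names(res)) {
        mean(.data$barrier)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(length = unname(lengths[.data$chromosome]))

  sp <- if (nrow(chroms) >= 3 && stats::sd(chroms$mean_me) > 0 &&
            stats::sd(chroms$length, na.rm = TRUE) > 0) {
    ct <- suppressWarnings(
      cor.test(chroms$length, chroms$mean_me, method = "spearman",
               exact = FALSE)
    )
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  list(chromosomes = chroms, spearman = sp)
}

#' Majority-overlap assignment of windows to the other genome's chromosomes
#'
#' Maps each window onto the chromosome of the aligned (donor) genome using
#' filtered whole-genome alignments: the window is assigned to the target
#' chromosome contributing the most aligned bases within the window span;
#' ties go to the longer alignment.
#'
#' @param windows Tibble with `window_id`, `chrom`, `start`, `end` (query
#'   genome coordinates).
#' @param alignments A [filter_alignments()] table.
#' @return Tibble (`window_id`, `chromosome`) with `NA` where no alignment
#'   overlaps the window.
#' @export
assign_windows_by_alignment <- function(windows, alignments) {
  windows <- as_tibble(windows)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    al <- alignments[alignments$qname == w$chrom &
                       alignments$qend > w$start &
                       alignments$qstart < w$end, ]
    if (nrow(al) == 0) {
      return(tibble(window_id = w$window_id, chromosome = NA_character_))
    }
    al$overlap <- pmin(al$qend, w$end) - pmax(al$qstart, w$start)
    byt <- al |>
      group_by(.data$tname) |>
      summarise(bases = sum(.data$overlap), longest = max(.data$alen),
                .groups = "drop") |>
      arrange(dplyr::desc(.data$bases), dplyr::desc(.data$longest))
    tibble(window_id = w$window_id, chromosome = byt$tname[1])
  })
}
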