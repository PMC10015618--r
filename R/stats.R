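#' Diversity and divergence summaries
#'
#' Per-individual heterozygosity (heterozygous sites / callable sites),
#' pairwise dxy between two diploids (mean per-site allele-frequency
#' difference `pA(1-pB) + pB(1-pA)` over joint-callable sites), and a
#' Hudson-style FST, `1 - Hw/Hb`, where `Hw` is the mean within-species
#' individual heterozygosity (averaged over the two species) and `Hb` the
#' mean interspecific pairwise dxy. The denominator `n_callable` is the
#' number of sites callable across all individuals; sites with any missing
#' genotype are excluded (consistent with that denominator).
#'
#' @param gt A genotype string matrix (sites x samples), e.g. from
#'   [read_vcf_tbl()]; absent sites are invariant.
#' @param n_callable Number of jointly callable sites (the denominator).
#' @param groups Named character vector mapping sample -> species (exactly
#'   two species).
#' @return A `diversity_stats` list: `het` (tibble `sample`, `species`,
#'   `heterozygosity`), `dxy_pairs` (tibble of interspecific pairs), `dxy`,
#'   `fst`, `n_callable`.
#' @export
diversity_stats <- function(gt, n_callable, groups) {
  if (n_callable <= 0) abort("`n_callable` must be positive")
  species <- unique(unname(groups))
  if (length(species) != 2) abort("`groups` must define exactly two species")
  samples <- names(groups)
  if (!all(samples %in% colnames(gt))) {
    abort("all samples in `groups` must be genotype columns")
  }
  gt <- gt[, samples, drop = FALSE]

  split_gt <- function(col) {
    m <- stringr::str_split_fixed(col, "[/|]", 2)
    suppressWarnings(matrix(as.integer(m), ncol = 2))
  }
  alle <- lapply(samples, function(s) split_gt(gt[, s]))
  names(alle) <- samples
  complete <- Reduce(`&`, lapply(alle, function(a) !is.na(a[, 1]) & !is.na(a[, 2])))

  het <- tibble(
    sample = samples,
    species = unname(groups[samples]),
    heterozygosity = unname(vapply(samples, function(s) {
      a <- alle[[s]]
      sum(a[complete, 1] != a[complete, 2]) / n_callable
    }, numeric(1)))
  )

  dosage <- vapply(samples, function(s) {
    a <- alle[[s]]
    a[, 1] + a[, 2]
  }, numeric(nrow(gt)))
  dosage <- matrix(dosage, ncol = length(samples),
                   dimnames = list(NULL, samples))

  sp_a <- samples[groups[samples] == species[1]]
  sp_b <- samples[groups[samples] == species[2]]
  pairs <- expand.grid(a = sp_a, b = sp_b, stringsAsFactors = FALSE)
  pairs$dxy <- vapply(seq_len(nrow(pairs)), function(i) {
    pa <- dosage[complete, pairs$a[i]] / 2
    pb <- dosage[complete, pairs$b[i]] / 2
    sum(pa * (1 - pb) + pb * (1 - pa)) / n_callable
  }, numeric(1))

  hw <- mean(vapply(split(het$heterozygosity, het$species), mean, numeric(1)))
  dxy <- mean(pairs$dxy)
  fst <- if (dxy > 0) 1 - hw / dxy else NA_real_

  structure(list(het = het, dxy_pairs = as_tibble(pairs), dxy = dxy,
                 fst = fst, n_callable = n_callable),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("<diversity_stats> dxy = %.4g, FST = %.4g (%d callable sites)\n",
              x$dxy, x$fst, x$n_callable))
  sp <- split(x$het$heterozygosity, x$het$species)
  for (s in names(sp)) {
    cat(sprintf("  mean heterozygosity %s = %.4g\n", s, mean(sp[[s]])))
  }
  invisible(x)
}

new_perm_test <- function(statistic, observed, null, n_perm, seed,
                          discarded = 0) {
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  structure(list(statistic = statistic, observed = observed, null = null,
                 p_value = p, n_perm = n_perm, n_used = length(null),
                 seed = seed, discarded = discarded),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s: observed = %.4g, one-tailed p = %.4g (%d of %d permutations%s)\n",
              x$statistic, x$observed, x$p_value, x$n_used, x$n_perm,
              if (x$discarded > 0) {
                sprintf(", %d discarded", x$discarded)
              } else {
                ""
              }))
  invisible(x)
}

#' Chromosome label-switching permutation test
#'
#' Tests whether windows on rearranged chromosomes have lower me (and a
#' higher barrier-window fraction) than windows on non-rearranged
#' chromosomes. Each permutation relabels whole chromosomes: `n_rearranged`
#' chromosomes are drawn uniformly without replacement and declared
#' rearranged. The statistics are the difference in mean window me
#' (non-rearranged minus rearranged; positive when rearranged chromosomes
#' have less migration) and, when a `barrier` column is present, the
#' difference in barrier-window fraction (rearranged minus non-rearranged).
#' One-tailed p-values use the add-one estimator `(1 + b) / (1 + n)`.
#'
#' @param window_table Tibble with `chromosome`, `me`, logical `rearranged`
#'   (the observed labels) and optionally logical `barrier`.
#' @param n_rearranged Size of the rearranged group in every permutation
#'   (defaults to the observed number of rearranged chromosomes).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list with elements `me` and (if available) `barrier`, each a
#'   `perm_test`.
#' @export
permute_chromosome_labels <- function(window_table, n_rearranged = NULL,
                                      n_perm = 10000, seed = 1) {
  wt <- as_tibble(window_table)
  stopifnot(all(c("chromosome", "me", "rearranged") %in% names(wt)))
  chroms <- unique(wt$chromosome)
  n_chrom <- length(chroms)
  obs_r <- unique(wt$chromosome[wt$rearranged])
  n_rearranged <- n_rearranged %||% length(obs_r)
  if (n_rearranged <= 0 || n_rearranged >= n_chrom) {
    abort("`n_rearranged` must be between 1 and the number of chromosomes - 1")
  }
  has_barrier <- "barrier" %in% names(wt)

  per_chrom <- wt |>
    group_by(.data$chromosome) |>
    summarise(n = n(), sum_me = sum(.data$me),
              sum_barrier = if (has_barrier) sum(.data$barrier) else 0,
              .groups = "drop")
  per_chrom <- per_chrom[match(chroms, per_chrom$chromosome), ]

  stat_pair <- function(is_r) {
    nr <- sum(per_chrom$n[is_r])
    nn <- sum(per_chrom$n[!is_r])
    d_me <- sum(per_chrom$sum_me[!is_r]) / nn -
      sum(per_chrom$sum_me[is_r]) / nr
    d_ba <- sum(per_chrom$sum_barrier[is_r]) / nr -
      sum(per_chrom$sum_barrier[!is_r]) / nn
    c(d_me, d_ba)
  }
  obs <- stat_pair(chroms %in% obs_r)

  null <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_pair(seq_len(n_chrom) %in% sample.int(n_chrom, n_rearranged))
    }, numeric(2))
  })

  out <- list(
    me = new_perm_test("mean me, non-rearranged minus rearranged",
                       obs[1], null[1, ], n_perm, seed)
  )
  if (has_barrier) {
    out$barrier <- new_perm_test(
      "barrier fraction, rearranged minus non-rearranged",
      obs[2], null[2, ], n_perm, seed
    )
  }
  out
}

#' Adjacent-window permutation test around rearrangement points
#'
#' Tests whether windows near rearrangement points have lower me than
#' windows elsewhere on rearranged chromosomes. For each permutation,
#' `length(matched_counts)` points are drawn uniformly from the
#' rearranged-chromosome window sequence and, around the i-th point, the
#' matched number of adjacent windows is sampled (centred on the point,
#' rolling over onto the next rearranged chromosome: the chromosomes are
#' concatenated in name order and treated circularly). Permutations that
#' sample any window more than once are discarded. The statistic is the
#' mean me of the remaining windows minus the mean me of the sampled ones
#' (positive when the sampled neighbourhoods have less migration); the
#' observed value uses the `near_point` labels.
#'
#' @param window_table Windows on rearranged chromosomes, with `chromosome`,
#'   `start`, `me` and logical `near_point` (observed labels).
#' @param matched_counts Integer vector: adjacent windows sampled per point
#'   (one entry per rearrangement point, matched to the real annotation).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_test`.
#' @export
permute_adjacent_windows <- function(window_table, matched_counts,
                                     n_perm = 1e5, seed = 1) {
  wt <- as_tibble(window_table)
  stopifnot(all(c("chromosome", "me", "near_point") %in% names(wt)))
  wt <- arrange(wt, .data$chromosome, .data$start)
  n <- nrow(wt)
  matched_counts <- as.integer(matched_counts)
  if (any(matched_counts < 1)) abort("`matched_counts` must be >= 1")
  if (sum(matched_counts) >= n) {
    abort("matched counts meet or exceed the available windows; every permutation would be discarded")
  }
  me <- wt$me
  total_me <- sum(me)
  # observed statistic through the same sum expression as the null draws, so
  # exact ties (e.g. constant me) compare as equalities
  k_obs <- sum(wt$near_point)
  s_obs <- sum(me[wt$near_point])
  obs <- (total_me - s_obs) / (n - k_obs) - s_obs / k_obs
  offsets <- lapply(matched_counts, function(k) {
    -floor((k - 1) / 2) + seq_len(k) - 1L
  })
  null <- local_seed(seed, {
    vals <- numeric(n_perm)
    keep <- logical(n_perm)
    for (i in seq_len(n_perm)) {
      pts <- sample.int(n, length(matched_counts), replace = TRUE)
      idx <- unlist(purrr::map2(pts, offsets, function(p, off) {
        (p - 1L + off) %% n + 1L
      }))
      if (anyDuplicated(idx)) next
      keep[i] <- TRUE
      s <- sum(me[idx])
      vals[i] <- (total_me - s) / (n - length(idx)) - s / length(idx)
    }
    list(vals = vals[keep], discarded = sum(!keep))
  })
  if (length(null$vals) == 0) {
    abort("all permutations were discarded; matched counts are too dense")
  }
  new_perm_test("mean me, elsewhere minus near points", obs, null$vals,
                n_perm, seed, discarded = null$discarded)
}
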