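#' Simulate raw block mutation counts under a DIV/IM history
#'
#' Draws independent (or optionally linked) block genealogies for one diploid
#' sampled from each species under the two-epoch structured coalescent and
#' Poisson mutation, and returns untruncated per-block counts of the four
#' mutation types together with pairwise difference counts for one haplotype
#' pair of each kind (between-species, within-A, within-B).
#'
#' When `config$recomb_rate > 0` consecutive blocks are linked through a
#' genealogy-renewal approximation of the sequential coalescent: the
#' genealogy persists between neighbouring blocks and is replaced by an
#' independent draw with probability `1 - exp(-r * block_span * E[L])`,
#' where `E[L]` is the expected total branch length (pilot-estimated).
#' Because the refresh is independent of the current tree, the marginal
#' distribution of each block is exactly the unlinked coalescent; only the
#' correlation structure is approximate. With `recomb_rate = 0` (default)
#' every block is an independent genealogy.
#'
#' @param params A [demography_params()].
#' @param config A [block_config()].
#' @param n_blocks Number of blocks to simulate.
#' @param seed Integer seed (required; simulation is bit-reproducible).
#' @return A tibble with integer columns `hetA`, `hetB`, `hetAB`, `fixed`
#'   (block mutation-type counts) and `cross_ab`, `within_a`, `within_b`
#'   (pairwise difference counts for haplotype pairs a1-b1, a1-a2, b1-b2).
#' @examples
#' p <- demography_params(1e5, 1e5, 1e5, split_time = 0)
#' sim <- simulate_blocks(p, block_config(), n_blocks = 100, seed = 1)
#' mean(sim$cross_ab) / 64 # ~ 4 * Ne * mu
#' @export
simulate_blocks <- function(params, config = block_config(), n_blocks,
                            seed) {
  stopifnot(inherits(params, "demography_params"),
            inherits(config, "block_config"))
  n_blocks <- assert_count(n_blocks, "n_blocks")
  assert_count(seed, "seed", min = 0)
  m <- local_seed(seed, .cpp_simulate_blocks(
    n_blocks, params$ne_a, params$ne_b, params$ne_anc, params$split_time,
    params$me, mig_source(params), params$mu, config$block_span,
    config$recomb_rate > 0, config$recomb_rate
  ))
  as_tibble(m)
}

#' Simulate a blockwise-SFS tally
#'
#' Convenience wrapper around [simulate_blocks()] that simulates
#' `n_blocks * n_pairs` blocks (every pair drawn independently), truncates the
#' counts at `config$kmax` and aggregates them into a [bsfs_tally].
#'
#' @inheritParams simulate_blocks
#' @param n_pairs Number of interspecific diploid pairs; the tally holds
#'   `n_blocks * n_pairs` blocks in total.
#' @return A [bsfs_tally].
#' @export
simulate_block_tallies <- function(params, config = block_config(), n_blocks,
                                   n_pairs = 1, seed) {
  n_blocks <- assert_count(n_blocks, "n_blocks")
  n_pairs <- assert_count(n_pairs, "n_pairs")
  sim <- simulate_blocks(params, config, n_blocks * n_pairs, seed)
  tally_from_counts(sim, kmax = config$kmax, block_span = config$block_span)
}

#' Build a bSFS tally from raw per-block counts
#'
#' @param counts A data frame / matrix with columns `hetA`, `hetB`, `hetAB`,
#'   `fixed` of raw (untruncated) per-block counts.
#' @param kmax Per-type truncation (length-4 integer vector).
#' @param block_span Callable bases per block (metadata carried on the tally).
#' @return A [bsfs_tally]: a tibble of occupied bins with a block count `n`;
#'   count values equal to `kmax + 1` denote the overflow bin of that type.
#' @export
tally_from_counts <- function(counts, kmax = c(2, 2, 2, 2), block_span = 64) {
  kmax <- as.integer(kmax)
  tc <- truncate_counts(counts, kmax)
  idx <- bin_index(tc, kmax)
  tab <- table(idx)
  bins <- mutation_bins(kmax)[as.integer(names(tab)), ]
  bins$n <- as.integer(tab)
  new_bsfs_tally(bins, kmax = kmax, block_span = block_span)
}

new_bsfs_tally <- function(df, kmax, block_span) {
  df <- as_tibble(df)
  stopifnot(all(c("hetA", "hetB", "hetAB", "fixed", "n") %in% names(df)))
  structure(df,
    kmax = as.integer(kmax), block_span = as.integer(block_span),
    n_blocks = sum(df$n),
    class = c("bsfs_tally", class(df))
  )
}

#' @export
print.bsfs_tally <- function(x, ...) {
  cat(sprintf("<bsfs_tally> %d blocks in %d occupied bins (kmax %s, span %d)\n",
              attr(x, "n_blocks"), nrow(x),
              paste(attr(x, "kmax"), collapse = ","),
              attr(x, "block_span")))
  NextMethod()
}

# dense bin-count vector in canonical bin order
tally_vector <- function(tally) {
  kmax <- attr(tally, "kmax")
  v <- numeric(prod(kmax + 2L))
  v[bin_index(tally, kmax)] <- tally$n
  v
}

#' Simulate diploid genotype data as VCF + callable-sites BED
#'
#' Simulates whole-cohort sequence data under the same two-epoch DIV/IM
#' history as [simulate_blocks()], but for arbitrarily many diploids per
#' species, and writes it in standard interchange formats so the filtering and
#' block-cutting stages can be exercised end to end. Each chromosome is tiled
#' into consecutive segments of `config$block_span` bases; every segment is an
#' independent genealogy of all sampled haplotypes, onto which mutations are
#' dropped at rate `mu` per site (each variant gets its own site, so records
#' are biallelic SNPs). Genotype calls are masked (set to `./.`) independently
#' with probability `missing_rate`.
#'
#' The VCF is v4.2 with 1-based positions; the BED of callable intervals is
#' 0-based half-open and covers the tiled portion of every chromosome.
#'
#' @inheritParams simulate_blocks
#' @param n_individuals_a,n_individuals_b Diploids sampled per species
#'   (samples are named `A1..`, `B1..`).
#' @param chrom_lengths Named integer vector of chromosome lengths (bases).
#' @param missing_rate Per-genotype missingness probability in `[0, 1)`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a list with `vcf` and `bed` paths plus the simulated
#'   genotype matrix (`gt`), variant table (`sites`) and sample table.
#' @export
simulate_vcf_bed <- function(params, config = block_config(),
                             n_individuals_a, n_individuals_b,
                             chrom_lengths, missing_rate = 0, seed,
                             dir = tempdir(), prefix = "meflow_sim") {
  stopifnot(inherits(params, "demography_params"))
  n_individuals_a <- assert_count(n_individuals_a, "n_individuals_a")
  n_individuals_b <- assert_count(n_individuals_b, "n_individuals_b")
  if (length(chrom_lengths) == 0) abort("`chrom_lengths` must be non-empty")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1)")
  }
  samples <- c(paste0("A", seq_len(n_individuals_a)),
               paste0("B", seq_len(n_individuals_b)))
  n_hap_a <- 2L * n_individuals_a
  n_hap <- n_hap_a + 2L * n_individuals_b
  span <- config$block_span

  sites <- local_seed(seed, {
    out <- list()
    for (chrom in names(chrom_lengths)) {
      n_seg <- chrom_lengths[[chrom]] %/% span
      for (s in seq_len(n_seg)) {
        br <- sim_genealogy_nsample(n_hap_a, n_hap - n_hap_a, params)
        nmut <- rpois(length(br$length), params$mu * span * br$length)
        tot <- sum(nmut)
        if (tot == 0) next
        tot <- min(tot, span)  # one segregating site per position
        carriers <- rep(seq_along(nmut), nmut)[seq_len(tot)]
        offs <- sample.int(span, tot)
        for (k in seq_len(tot)) {
          hapgt <- integer(n_hap)
          hapgt[br$desc[[carriers[k]]]] <- 1L
          out[[length(out) + 1L]] <- list(
            chrom = chrom, pos = (s - 1L) * span + offs[k], hap = hapgt
          )
        }
      }
    }
    out
  })

  if (length(sites)) {
    ord <- order(vapply(sites, function(x) x$chrom, character(1)),
                 vapply(sites, function(x) x$pos, numeric(1)))
    sites <- sites[ord]
  }
  hap <- do.call(rbind, lapply(sites, function(x) x$hap))
  site_tbl <- tibble(
    chrom = vapply(sites, function(x) x$chrom, character(1)),
    pos = vapply(sites, function(x) as.integer(x$pos), integer(1))
  )

  # diploid genotype strings, with per-call masking
  n_site <- nrow(site_tbl) %||% 0L
  gt <- matrix("0/0", nrow = max(n_site, 0L), ncol = length(samples),
               dimnames = list(NULL, samples))
  if (n_site > 0) {
    for (ind in seq_along(samples)) {
      h1 <- hap[, 2L * ind - 1L]
      h2 <- hap[, 2L * ind]
      gt[, ind] <- paste0(pmin(h1, h2), "/", pmax(h1, h2))
    }
    if (missing_rate > 0) {
      mask <- local_seed(derive_seed(seed, 1L),
                         matrix(runif(length(gt)) < missing_rate,
                                nrow = nrow(gt)))
      gt[mask] <- "./."
    }
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  bed_path <- file.path(dir, paste0(prefix, ".callable.bed"))
  write_simple_vcf(vcf_path, site_tbl, gt, samples, chrom_lengths)
  bed <- tibble(
    chrom = names(chrom_lengths),
    start = 0L,
    end = as.integer((chrom_lengths %/% span) * span)
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)

  invisible(list(vcf = vcf_path, bed = bed_path, gt = gt, sites = site_tbl,
                 samples = tibble(sample = samples,
                                  species = rep(c("A", "B"),
                                                c(n_individuals_a,
                                                  n_individuals_b)))))
}

# n-sample two-deme structured coalescent; returns branches as descendant
# haplotype index sets with lengths (generations). Haplotypes 1..n_hap_a are
# species A (deme 1), the rest species B (deme 2).
sim_genealogy_nsample <- function(n_hap_a, n_hap_b, params) {
  n <- n_hap_a + n_hap_b
  desc <- lapply(seq_len(n), identity)
  deme <- rep(1:2, c(n_hap_a, n_hap_b))
  born <- numeric(n)
  src <- mig_source(params) + 1L  # 1 = deme A, 2 = deme B, 0 = none
  out_desc <- list()
  out_len <- numeric()
  t <- 0
  ancestral <- params$split_time <= 0
  while (length(desc) > 1) {
    k <- length(desc)
    if (ancestral) {
      rc <- c(k * (k - 1) / 2 / (2 * params$ne_anc), 0)
      rm_ <- 0
    } else {
      n1 <- sum(deme == 1)
      n2 <- k - n1
      rc <- c(n1 * (n1 - 1) / 2 / (2 * params$ne_a),
              n2 * (n2 - 1) / 2 / (2 * params$ne_b))
      rm_ <- if (src > 0) sum(deme == src) * params$me else 0
    }
    tot <- sum(rc) + rm_
    dt <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (!ancestral && t + dt >= params$split_time) {
      t <- params$split_time
      ancestral <- TRUE
      next
    }
    t <- t + dt
    u <- runif(1, 0, tot)
    if (u < sum(rc)) {
      d <- if (ancestral) 0L else if (u < rc[1]) 1L else 2L
      idx <- if (ancestral) seq_len(k) else which(deme == d)
      pair <- sample(idx, 2)
      i <- min(pair); j <- max(pair)
      out_desc[[length(out_desc) + 1L]] <- desc[[i]]
      out_len <- c(out_len, t - born[i])
      out_desc[[length(out_desc) + 1L]] <- desc[[j]]
      out_len <- c(out_len, t - born[j])
      desc[[i]] <- sort(c(desc[[i]], desc[[j]]))
      born[i] <- t
      desc <- desc[-j]; deme <- deme[-j]; born <- born[-j]
    } else {
      idx <- which(deme == src)
      pick <- if (length(idx) == 1) idx else sample(idx, 1)
      deme[pick] <- 3L - src
    }
  }
  keep <- out_len > 0 & lengths(out_desc) < n
  list(desc = out_desc[keep], length = out_len[keep])
}

write_simple_vcf <- function(path, sites, gt, samples, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=meflow-simulate",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (nrow(sites) > 0) {
    body <- paste(
      sites$chrom, sites$pos, ".", "A", "T", "100", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}
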