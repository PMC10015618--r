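#' Mutation-type bins of the truncated blockwise SFS
#'
#' All joint count vectors (hetA, hetB, hetAB, fixed) with each count in
#' `0:(kmax + 1)`; the level `kmax + 1` is the marginal overflow bin that pools
#' counts above the truncation. The row order is the canonical bin order used
#' by probability tables and tally vectors (hetA varies fastest).
#'
#' @param kmax Integer vector of length 4 (per-type truncation).
#' @return A tibble with columns `hetA`, `hetB`, `hetAB`, `fixed`.
#' @examples
#' nrow(mutation_bins(c(2, 2, 2, 2))) # 4^4 = 256
#' @export
mutation_bins <- function(kmax = c(2, 2, 2, 2)) {
  kmax <- as.integer(kmax)
  stopifnot(length(kmax) == 4)
  as_tibble(expand.grid(
    hetA = 0:(kmax[1] + 1L), hetB = 0:(kmax[2] + 1L),
    hetAB = 0:(kmax[3] + 1L), fixed = 0:(kmax[4] + 1L),
    KEEP.OUT.ATTRS = FALSE
  ))
}

# 1-based canonical bin index for a matrix/df of (already truncated) counts
bin_index <- function(counts, kmax) {
  counts <- as.matrix(as.data.frame(counts)[, c("hetA", "hetB", "hetAB",
                                                "fixed"), drop = FALSE])
  D <- kmax + 2L
  1L + counts[, 1] + D[1] * (counts[, 2] + D[2] *
    (counts[, 3] + D[3] * counts[, 4]))
}

# truncate raw counts at kmax, mapping anything above into the overflow level
truncate_counts <- function(counts, kmax) {
  counts <- as.matrix(as.data.frame(counts)[, c("hetA", "hetB", "hetAB",
                                                "fixed"), drop = FALSE])
  for (t in 1:4) counts[, t] <- pmin(counts[, t], kmax[t] + 1L)
  counts
}

#' Exact bSFS probabilities under a DIV or IM history
#'
#' Computes the exact (non-Monte-Carlo) probability of every joint block
#' mutation-type vector for a 2 + 2 haplotype block under the two-epoch
#' structured coalescent described by `params`: two demes with sizes `ne_a`,
#' `ne_b` and (for IM histories) unidirectional backwards migration until the
#' split time, then a single ancestral deme of size `ne_anc`. The chain over
#' (lineage partition x deme occupancy) states, augmented with per-type
#' mutation counters truncated at `kmax` (+ absorbing overflow), is solved by
#' uniformization up to the split time and by a direct absorption sweep in the
#' ancestral epoch.
#'
#' Internally the computation is scaled to coalescent units of `2 * ne_a`
#' generations; the scaling is invisible in the returned probabilities.
#'
#' @param params A [demography_params()] object.
#' @param config A [block_config()] object (supplies `block_span` and `kmax`).
#' @return A `bsfs_prob_tbl`: a tibble with the [mutation_bins()] columns and
#'   a `prob` column summing to 1 (tolerance 1e-10), with the parameter point
#'   attached as attributes.
#' @examples
#' p <- demography_params(1e5, 2e5, 1.5e5, split_time = 4e5)
#' tab <- bsfs_probabilities(p, block_config())
#' sum(tab$prob)
#' @export
bsfs_probabilities <- function(params, config = block_config()) {
  stopifnot(inherits(params, "demography_params"),
            inherits(config, "block_config"))
  tpl <- kernel_template()
  ne_ref <- params$ne_a
  kind_rate <- c(
    1,                                    # coalescence, deme A (reference)
    ne_ref / params$ne_b,                 # coalescence, deme B
    if (params$direction == "into_A") 2 * ne_ref * params$me else 0,
    if (params$direction == "into_B") 2 * ne_ref * params$me else 0,
    ne_ref / params$ne_anc                # coalescence, ancestral deme
  )
  theta_half <- 2 * ne_ref * params$mu * config$block_span
  t_scaled <- params$split_time / (2 * ne_ref)

  prob <- .cpp_bsfs_kernel(
    tpl$e1_from - 1L, tpl$e1_to - 1L, tpl$e1_mult * kind_rate[tpl$e1_kind],
    tpl$mut1, tpl$init1 - 1L, tpl$map12 - 1L,
    tpl$e2_from - 1L, tpl$e2_to - 1L, tpl$e2_mult * kind_rate[5],
    tpl$mut2, tpl$abs2 - 1L, theta_half, t_scaled, config$kmax
  )
  if (anyNA(prob) || any(!is.finite(prob))) {
    abort(sprintf(
      "likelihood kernel failed to converge at (ne_a=%g, ne_b=%g, ne_anc=%g, T=%g, me=%g)",
      params$ne_a, params$ne_b, params$ne_anc, params$split_time, params$me
    ))
  }
  tot <- sum(prob)
  if (abs(tot - 1) > 1e-10) {
    abort(sprintf("kernel probabilities sum to %.12f, not 1 (parameter point logged above)", tot))
  }
  out <- mutation_bins(config$kmax)
  out$prob <- as.numeric(prob)
  structure(out,
    kmax = config$kmax, block_span = config$block_span, params = params,
    class = c("bsfs_prob_tbl", class(out))
  )
}

#' Composite log-likelihood of a block tally
#'
#' Treats blocks as independent draws from the bin probabilities:
#' `lnCL = sum_k n_k * log(p_k)` over occupied bins. Probabilities below
#' 1e-300 are clamped before taking logs (and the clamping is reported); a
#' bin with observed blocks but exactly zero probability yields `-Inf` with a
#' warning rather than silently.
#'
#' @param tally A [bsfs_tally] (see [simulate_block_tallies()] or
#'   [tally_blocks()]).
#' @param table A `bsfs_prob_tbl` from [bsfs_probabilities()] with the same
#'   `kmax` and `block_span`.
#' @return A single number (the composite log-likelihood).
#' @export
composite_lnCL <- function(tally, table) {
  kt <- attr(tally, "kmax")
  kp <- attr(table, "kmax")
  if (!identical(as.integer(kt), as.integer(kp))) {
    abort("tally and probability table use different `kmax` truncations")
  }
  bt <- attr(tally, "block_span")
  bp <- attr(table, "block_span")
  if (!is.null(bt) && !is.null(bp) && bt != bp) {
    abort("tally and probability table use different block spans")
  }
  if (nrow(tally) == 0) return(0)
  p <- table$prob[bin_index(tally, kt)]
  zero <- p == 0 & tally$n > 0
  if (any(zero)) {
    warn(sprintf("%d occupied bin(s) have zero probability; lnCL is -Inf",
                 sum(zero)))
    return(-Inf)
  }
  sum(tally$n * log(pmax(p, 1e-300)))
}

#' Effective migrants per generation
#'
#' Converts an effective migration rate into the expected number of effective
#' migrants arriving in the recipient population per generation,
#' `4 * ne_recipient * me`.
#'
#' @param ne_recipient Diploid effective size of the recipient species.
#' @param me Effective migration rate (per generation per lineage).
#' @return Effective migrants per generation.
#' @examples
#' migrants_per_generation(0.171e6, 1.811e-7) # ~0.124
#' @export
migrants_per_generation <- function(ne_recipient, me) {
  stopifnot(all(ne_recipient >= 0), all(me >= 0))
  4 * ne_recipient * me
}
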