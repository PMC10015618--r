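#' Demographic model card for a two-species history
#'
#' Bundles the parameters of a divergence (DIV) or isolation-with-migration
#' (IM) history for a species pair: a recipient-candidate species A, a species
#' B, and their common ancestor. Under an IM history a constant effective
#' migration rate `me` acts after the split, in one direction only; `me` is the
#' per-generation, per-lineage probability that a lineage migrates, net of
#' selection against introgression. The direction is stated forwards in time
#' (donor to recipient): `"into_A"` means gene flow from B into A.
#'
#' Backwards-in-time convention: forwards migration donor -> recipient is
#' realised in both the simulator and the likelihood kernel as
#' recipient-lineage movement into the donor deme at rate `me` per lineage per
#' generation. With `direction = "into_A"`, lineages sampled in A jump into
#' the B deme when traced backwards.
#'
#' @param ne_a,ne_b,ne_anc Diploid effective sizes (individuals) of species A,
#'   species B and the ancestral population.
#' @param split_time Species split time, in generations before present.
#' @param me Effective migration rate per generation per lineage; `0` gives a
#'   strict-divergence (DIV) history.
#' @param direction One of `"none"`, `"into_A"`, `"into_B"` (forwards-in-time
#'   recipient). Must be `"none"` iff `me == 0`.
#' @param mu Mutation rate per site per generation.
#' @param gen_time Years per generation (used only to convert split times to
#'   calendar years in summaries).
#'
#' @return An object of class `demography_params` (a named list).
#' @examples
#' demography_params(
#'   ne_a = 0.171e6, ne_b = 0.880e6, ne_anc = 1.116e6,
#'   split_time = 2.202e6, me = 1.811e-7, direction = "into_A"
#' )
#' @export
demography_params <- function(ne_a, ne_b, ne_anc, split_time, me = 0,
                              direction = c("none", "into_A", "into_B"),
                              mu = 2.9e-9, gen_time = 1) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(ne_a), is.numeric(ne_b), is.numeric(ne_anc))
  if (any(c(ne_a, ne_b, ne_anc) <= 0)) {
    abort("effective sizes `ne_a`, `ne_b`, `ne_anc` must all be > 0")
  }
  if (split_time < 0) abort("`split_time` must be >= 0")
  if (me < 0 || me >= 1) abort("`me` must lie in [0, 1)")
  if (mu < 0) abort("`mu` must be >= 0")
  if ((me == 0) != (direction == "none")) {
    abort("`direction` must be \"none\" iff `me` is 0")
  }
  structure(
    list(
      ne_a = ne_a, ne_b = ne_b, ne_anc = ne_anc,
      split_time = split_time, me = me, direction = direction,
      mu = mu, gen_time = gen_time
    ),
    class = "demography_params"
  )
}

#' @export
print.demography_params <- function(x, ...) {
  model <- if (x$me == 0) "DIV" else paste0("IM (", x$direction, ")")
  cat("<demography_params> ", model, "\n", sep = "")
  cat(sprintf("  Ne_A = %g, Ne_B = %g, Ne_anc = %g individuals\n",
              x$ne_a, x$ne_b, x$ne_anc))
  cat(sprintf("  split time = %g generations (%g years)\n",
              x$split_time, x$split_time * x$gen_time))
  if (x$me > 0) cat(sprintf("  me = %g per lineage per generation\n", x$me))
  cat(sprintf("  mu = %g per site per generation\n", x$mu))
  invisible(x)
}

#' Block construction settings
#'
#' Fixed-content sequence blocks hold exactly `block_span` callable bases but
#' may stretch over a genomic span of up to `max_span` bases to step over
#' non-callable gaps. `kmax` truncates the per-type block mutation counts of
#' the blockwise site frequency spectrum; counts above `kmax` are pooled into
#' a marginal overflow bin per type.
#'
#' @param block_span Callable bases per block.
#' @param max_span Maximum genomic span of a block, in bases.
#' @param kmax Integer vector of length 4 (hetA, hetB, hetAB, fixed), each
#'   entry >= 1.
#' @param recomb_rate Per-base per-generation recombination rate used by the
#'   simulator's linked-blocks mode; `0` (the default) simulates every block as
#'   an independent genealogy.
#'
#' @return An object of class `block_config`.
#' @examples
#' block_config() # 64 callable bases, max span 128, kmax (2,2,2,2)
#' @export
block_config <- function(block_span = 64, max_span = 128,
                         kmax = c(2, 2, 2, 2), recomb_rate = 0) {
  if (block_span <= 0 || block_span > max_span) {
    abort("need 0 < `block_span` <= `max_span`")
  }
  kmax <- as.integer(kmax)
  if (length(kmax) != 4 || any(kmax < 1)) {
    abort("`kmax` must be 4 entries, each >= 1")
  }
  if (recomb_rate < 0) abort("`recomb_rate` must be >= 0")
  structure(
    list(block_span = as.integer(block_span), max_span = as.integer(max_span),
         kmax = kmax, recomb_rate = recomb_rate),
    class = "block_config"
  )
}

#' @export
print.block_config <- function(x, ...) {
  cat(sprintf("<block_config> %d callable bases, max span %d, kmax (%s)\n",
              x$block_span, x$max_span, paste(x$kmax, collapse = ",")),
      sep = "")
  if (x$recomb_rate > 0) {
    cat(sprintf("  linked-blocks simulation, r = %g /bp/gen\n", x$recomb_rate))
  }
  invisible(x)
}

# migration source deme for the backwards-in-time process:
# 0 = lineages leave deme A, 1 = leave deme B, -1 = none
mig_source <- function(params) {
  switch(params$direction, none = -1L, into_A = 0L, into_B = 1L)
}
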