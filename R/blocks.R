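#' Classify a biallelic site for one diploid pair
#'
#' Given unphased diploid genotypes for one individual from each species,
#' assigns the site to one of the unpolarised mutation types used by the
#' blockwise SFS: heterozygous in A only (`hetA`), in B only (`hetB`), in
#' both with the same alleles (`hetAB`), opposite homozygotes (`fixed`),
#' identical homozygotes (`invariant`), or `unusable` when a genotype is
#' missing or more than two alleles segregate within the pair.
#'
#' @param gt_a,gt_b Character vectors of genotype strings (`"0/1"`, `"1|1"`,
#'   `"./."`, ...), one element per site.
#' @return A character vector of site types.
#' @examples
#' classify_site("0/1", "0/0") # hetA
#' classify_site("1/1", "0/0") # fixed
#' @export
classify_site <- function(gt_a, gt_b) {
  al <- function(gt, i) {
    a <- stringr::str_split_fixed(gt, "[/|]", 2)[, i]
    suppressWarnings(as.integer(a))
  }
  a1 <- al(gt_a, 1); a2 <- al(gt_a, 2)
  b1 <- al(gt_b, 1); b2 <- al(gt_b, 2)
  n <- length(a1)
  out <- character(n)
  miss <- is.na(a1) | is.na(a2) | is.na(b1) | is.na(b2)
  nalleles <- vapply(seq_len(n), function(i) {
    length(unique(c(a1[i], a2[i], b1[i], b2[i])))
  }, integer(1))
  het_a <- a1 != a2
  het_b <- b1 != b2
  out[miss | nalleles > 2] <- "unusable"
  ok <- !(miss | nalleles > 2)
  out[ok & het_a & !het_b] <- "hetA"
  out[ok & !het_a & het_b] <- "hetB"
  out[ok & het_a & het_b] <- "hetAB"
  out[ok & !het_a & !het_b & a1 != b1] <- "fixed"
  out[ok & !het_a & !het_b & a1 == b1] <- "invariant"
  out
}

#' Cut pairwise-callable sequence into fixed-content blocks
#'
#' Greedy left-to-right packing: starting at the leftmost unused callable
#' base, the next `block_span` callable bases form a candidate block; it is
#' emitted iff its genomic span is at most `max_span`, otherwise packing
#' restarts at the next callable base after the failed start. Blocks never
#' overlap and never span chromosomes; the procedure is deterministic.
#'
#' @param pair_callable Callable intervals for the pair (tibble `chrom`,
#'   `start`, `end`, 0-based half-open): normally the intersection of both
#'   individuals' callable masks (see [intersect_callable()]).
#' @param config A [block_config()].
#' @return A `block_set`: a list with `blocks` (tibble `block_id`, `chrom`,
#'   `start`, `end`, `span`) and `positions` (tibble `chrom`, `pos`,
#'   `block_id`, one row per member callable base; `pos` 0-based).
#' @examples
#' bs <- cut_blocks(tibble::tibble(chrom = "c", start = 0, end = 128),
#'                  block_config())
#' nrow(bs$blocks) # 2 blocks of span 64
#' @export
cut_blocks <- function(pair_callable, config = block_config()) {
  pair_callable <- as_tibble(pair_callable)
  blocks <- list()
  positions <- list()
  next_id <- 1L
  for (ch in unique(pair_callable$chrom)) {
    ci <- pair_callable[pair_callable$chrom == ch, ]
    mi <- merge_intervals(ci$start, ci$end)
    pos <- unlist(purrr::map2(mi$start, mi$end, function(s, e) seq.int(s, e - 1L)))
    if (length(pos) < config$block_span) next
    starts <- .cpp_cut_blocks(as.integer(pos), config$block_span,
                              config$max_span)
    if (length(starts) == 0) next
    member <- unlist(lapply(starts, function(s) s:(s + config$block_span - 1L)))
    ids <- next_id + rep(seq_along(starts) - 1L, each = config$block_span)
    blocks[[ch]] <- tibble(
      block_id = next_id + seq_along(starts) - 1L,
      chrom = ch,
      start = pos[starts],
      end = pos[starts + config$block_span - 1L] + 1L,
      span = pos[starts + config$block_span - 1L] - pos[starts] + 1L
    )
    positions[[ch]] <- tibble(chrom = ch, pos = pos[member], block_id = ids)
    next_id <- next_id + length(starts)
  }
  structure(
    list(blocks = bind_rows(blocks), positions = bind_rows(positions),
         config = config),
    class = "block_set"
  )
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %d blocks of %d callable bases on %d chromosome(s)\n",
              nrow(x$blocks), x$config$block_span,
              length(unique(x$blocks$chrom))))
  invisible(x)
}

#' Intersect two samples' callable intervals
#'
#' @param callable A per-sample callable table (`sample`, `chrom`, `start`,
#'   `end`) or a [callable_profile()].
#' @param sample_a,sample_b The two sample names.
#' @return A tibble of intervals callable in both samples.
#' @export
intersect_callable <- function(callable, sample_a, sample_b) {
  if (inherits(callable, "callable_profile")) callable <- callable$intervals
  ca <- callable[callable$sample == sample_a, ]
  cb <- callable[callable$sample == sample_b, ]
  purrr::map_dfr(intersect(unique(ca$chrom), unique(cb$chrom)), function(ch) {
    ia <- IRanges::reduce(IRanges::IRanges(ca$start[ca$chrom == ch] + 1L,
                                           ca$end[ca$chrom == ch]))
    ib <- IRanges::reduce(IRanges::IRanges(cb$start[cb$chrom == ch] + 1L,
                                           cb$end[cb$chrom == ch]))
    ov <- IRanges::intersect(ia, ib)
    if (length(ov) == 0) return(tibble())
    tibble(chrom = ch, start = IRanges::start(ov) - 1L, end = IRanges::end(ov))
  })
}

#' Tally the blockwise SFS over a block set
#'
#' Counts the four mutation types per block for one diploid pair, truncating
#' at `kmax` (counts above `kmax` fall into the per-type overflow bin).
#' Callable positions without a variant record are invariant. Blocks
#' containing any unusable site (missing genotype, or more than two alleles
#' within the pair) are discarded and reported in the attached discard log;
#' variants falling outside every callable block raise a warning and are
#' ignored.
#'
#' @param block_set A [cut_blocks()] result for the pair.
#' @param vcf A filtered `vcf_tbl` ([read_vcf_tbl()], [filter_variants()]).
#' @param sample_a,sample_b Sample names of the pair (A-species first).
#' @param kmax Per-type truncation.
#' @return A [bsfs_tally]; attribute `"discarded"` gives the number of
#'   discarded blocks.
#' @export
tally_blocks <- function(block_set, vcf, sample_a, sample_b,
                         kmax = c(2, 2, 2, 2)) {
  stopifnot(inherits(block_set, "block_set"), inherits(vcf, "vcf_tbl"))
  kmax <- as.integer(kmax)
  pos <- block_set$positions
  sites <- vcf$sites
  key <- paste(sites$chrom, sites$pos - 1L)       # VCF POS is 1-based
  hit <- match(key, paste(pos$chrom, pos$pos))
  outside <- is.na(hit)
  if (any(outside)) {
    warn(sprintf("%d variant(s) outside callable blocks were ignored",
                 sum(outside)))
  }
  use <- which(!outside)
  type <- classify_site(vcf$gt[use, sample_a], vcf$gt[use, sample_b])
  bid <- pos$block_id[hit[use]]

  nb <- nrow(block_set$blocks)
  counts <- matrix(0L, nb, 4L,
                   dimnames = list(NULL, c("hetA", "hetB", "hetAB", "fixed")))
  for (t in c("hetA", "hetB", "hetAB", "fixed")) {
    tb <- table(factor(bid[type == t], levels = block_set$blocks$block_id))
    counts[, t] <- as.integer(tb)
  }
  bad <- unique(bid[type == "unusable"])
  keep <- !(block_set$blocks$block_id %in% bad)
  tally <- tally_from_counts(as_tibble(counts)[keep, , drop = FALSE],
                             kmax = kmax,
                             block_span = block_set$config$block_span)
  attr(tally, "discarded") <- sum(!keep)
  tally
}
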