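#' Variant filtering rules
#'
#' Thresholds of the SNP filter applied ahead of block construction: SNPs
#' within `snp_gap` bases of an indel are removed (distance `<= snp_gap`,
#' matching bcftools SnpGap semantics), records with QUAL below `min_qual`
#' are removed, and individual genotypes whose read depth falls outside
#' `[min_depth, floor(max_depth_factor * mean coverage)]` are set to missing.
#' Multiallelic SNP sites are retained if they satisfy all other criteria;
#' indel records themselves never enter the filtered SNP set.
#'
#' @param snp_gap Bases around indels within which SNPs are dropped.
#' @param min_qual Minimum variant QUAL (records with `QUAL < min_qual` drop).
#' @param min_depth Minimum genotype read depth (inclusive).
#' @param max_depth_factor Maximum depth as a multiple of the sample's mean
#'   coverage (inclusive after flooring).
#' @return A `filter_rules` object.
#' @examples
#' filter_rules() # snp_gap 2, min_qual 10, min_depth 8, max 3 x mean
#' @export
filter_rules <- function(snp_gap = 2, min_qual = 10, min_depth = 8,
                         max_depth_factor = 3) {
  if (any(c(snp_gap, min_qual, min_depth) < 0) || max_depth_factor <= 0) {
    abort("all thresholds must be >= 0 and `max_depth_factor` > 0")
  }
  structure(list(snp_gap = snp_gap, min_qual = min_qual,
                 min_depth = min_depth, max_depth_factor = max_depth_factor),
            class = "filter_rules")
}

#' Per-sample coverage profile and callable intervals
#'
#' @param mean_coverage Named numeric vector of per-sample mean coverage.
#' @param intervals Optional tibble of per-sample callable intervals
#'   (`sample`, `chrom`, `start`, `end`; 0-based half-open). Intervals are
#'   sorted and merged per sample.
#' @return A `callable_profile` object.
#' @export
callable_profile <- function(mean_coverage, intervals = NULL) {
  stopifnot(is.numeric(mean_coverage), !is.null(names(mean_coverage)))
  if (!is.null(intervals)) {
    intervals <- as_tibble(intervals)
    stopifnot(all(c("sample", "chrom", "start", "end") %in% names(intervals)))
    if (any(intervals$start < 0)) abort("negative interval coordinates")
    intervals <- intervals |>
      group_by(.data$sample, .data$chrom) |>
      dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
      ungroup()
  }
  structure(list(mean_coverage = mean_coverage, intervals = intervals),
            class = "callable_profile")
}

# sort + merge half-open intervals; returns tibble(start, end)
merge_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Read a VCF into a tabular container
#'
#' Wraps `vcfR` and exposes the pieces the pipeline needs: a site table
#' (CHROM, POS, REF, ALT, QUAL), the genotype matrix and, when present, the
#' per-genotype depth matrix.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return A list of class `vcf_tbl` with elements `sites` (tibble), `gt`
#'   (character matrix sites x samples) and `dp` (numeric matrix or `NULL`).
#' @export
read_vcf_tbl <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  sites <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  gt <- if (nrow(v@gt) > 0) vcfR::extract.gt(v, "GT") else NULL
  dp <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp) && (length(dp) == 0 || all(is.na(dp)))) dp <- NULL
  structure(list(sites = sites, gt = gt, dp = dp), class = "vcf_tbl")
}

#' @export
print.vcf_tbl <- function(x, ...) {
  cat(sprintf("<vcf_tbl> %d records, %d samples\n", nrow(x$sites),
              if (is.null(x$gt)) 0L else ncol(x$gt)))
  invisible(x)
}

is_indel_record <- function(sites) {
  alt_len <- vapply(strsplit(sites$alt %||% "", ",", fixed = TRUE),
                    function(a) if (length(a)) max(nchar(a)) else 1L,
                    integer(1))
  nchar(sites$ref) > 1L | alt_len > 1L
}

#' Filter SNP calls ahead of block construction
#'
#' Applies [filter_rules()] to a [read_vcf_tbl()] container: removes indel
#' records (after using them to blank nearby SNPs), removes SNPs within
#' `snp_gap` bases of any indel's reference span, removes records with
#' `QUAL < min_qual`, and sets genotypes with out-of-bounds depth to missing.
#' Records without any depth annotation are dropped with a diagnostic.
#' The operation is idempotent.
#'
#' @param vcf A `vcf_tbl`.
#' @param rules A [filter_rules()].
#' @param profile A [callable_profile()] supplying per-sample mean coverage
#'   (required when the VCF carries depth).
#' @return A filtered `vcf_tbl`; the number of records and genotypes touched
#'   is attached as attribute `"log"`.
#' @export
filter_variants <- function(vcf, rules = filter_rules(), profile = NULL) {
  stopifnot(inherits(vcf, "vcf_tbl"), inherits(rules, "filter_rules"))
  sites <- vcf$sites
  indel <- is_indel_record(sites)
  log <- list()

  near_indel <- rep(FALSE, nrow(sites))
  if (any(indel)) {
    for (ch in unique(sites$chrom[indel])) {
      on_ch <- sites$chrom == ch
      spans <- IRanges::IRanges(
        sites$pos[on_ch & indel],
        sites$pos[on_ch & indel] + nchar(sites$ref[on_ch & indel]) - 1L
      )
      snp_ir <- IRanges::IRanges(sites$pos[on_ch], sites$pos[on_ch])
      # base-pair distance <= snp_gap means: overlapping, or separated by a
      # gap of at most snp_gap - 1 positions
      hit <- IRanges::countOverlaps(snp_ir, spans,
                                    maxgap = rules$snp_gap - 1L) > 0
      near_indel[on_ch] <- hit & !indel[on_ch]
    }
  }
  log$snps_near_indel <- sum(near_indel)

  low_qual <- is.na(sites$qual) | sites$qual < rules$min_qual
  log$low_qual <- sum(low_qual & !indel)

  keep <- !indel & !near_indel & !low_qual
  gt <- vcf$gt
  dp <- vcf$dp
  if (!is.null(dp)) {
    no_depth <- apply(dp, 1, function(r) all(is.na(r)))
    if (any(no_depth & keep)) {
      inform(sprintf("dropping %d record(s) without depth annotations",
                     sum(no_depth & keep)))
    }
    log$no_depth <- sum(no_depth & keep)
    keep <- keep & !no_depth
    if (is.null(profile)) {
      abort("depth present in VCF but no `callable_profile` given")
    }
    mc <- profile$mean_coverage[colnames(dp)]
    if (anyNA(mc)) abort("profile lacks mean coverage for some samples")
    upper <- floor(rules$max_depth_factor * mc)
    bad <- sweep(dp, 2, rules$min_depth, "<") |
      sweep(dp, 2, upper, ">") | is.na(dp)
    log$genotypes_masked <- sum(bad[keep, , drop = FALSE] &
                                  gt[keep, , drop = FALSE] != "./.",
                                na.rm = TRUE)
    gt[bad] <- "./."
  }

  out <- structure(
    list(sites = sites[keep, , drop = FALSE],
         gt = if (!is.null(gt)) gt[keep, , drop = FALSE] else NULL,
         dp = if (!is.null(dp)) dp[keep, , drop = FALSE] else NULL),
    class = "vcf_tbl"
  )
  attr(out, "log") <- log
  out
}

#' Subtract genic and repeat masks from callable intervals
#'
#' Returns the set difference of the callable intervals and the union of the
#' genic and repeat intervals, sorted and merged. Inputs are 0-based
#' half-open interval tables (`chrom`, `start`, `end`); a `sample` column in
#' the callable set is honoured (the subtraction is per sample). Unsorted
#' input is tolerated; negative coordinates are rejected.
#'
#' @param callable Callable intervals (tibble or [callable_profile()]).
#' @param genic,repeats Mask interval tables (either may be `NULL`).
#' @return A tibble of intergenic callable intervals.
#' @examples
#' intergenic_callable(
#'   tibble::tibble(chrom = "c", start = 0, end = 100),
#'   genic = tibble::tibble(chrom = "c", start = 40, end = 60)
#' )
#' @export
intergenic_callable <- function(callable, genic = NULL, repeats = NULL) {
  if (inherits(callable, "callable_profile")) callable <- callable$intervals
  callable <- as_tibble(callable)
  masks <- bind_rows(
    tibble(chrom = character(), start = integer(), end = integer()),
    if (!is.null(genic)) as_tibble(genic)[, c("chrom", "start", "end")],
    if (!is.null(repeats)) as_tibble(repeats)[, c("chrom", "start", "end")]
  )
  if (any(callable$start < 0) || (nrow(masks) && any(masks$start < 0))) {
    abort("negative interval coordinates are not allowed")
  }
  by_sample <- "sample" %in% names(callable)
  groups <- if (by_sample) split(callable, callable$sample) else list(callable)
  out <- purrr::imap_dfr(groups, function(cal, sm) {
    res <- purrr::map_dfr(unique(cal$chrom), function(ch) {
      ci <- cal[cal$chrom == ch, ]
      cr <- IRanges::reduce(IRanges::IRanges(ci$start + 1L, ci$end))
      mi <- masks[masks$chrom == ch, ]
      if (nrow(mi)) {
        mr <- IRanges::reduce(IRanges::IRanges(mi$start + 1L, mi$end))
        cr <- IRanges::setdiff(cr, mr)
      }
      if (length(cr) == 0) return(tibble())
      tibble(chrom = ch, start = IRanges::start(cr) - 1L,
             end = IRanges::end(cr))
    })
    if (by_sample && nrow(res)) res$sample <- sm
    res
  })
  arrange(out, dplyr::pick(dplyr::any_of(c("sample", "chrom", "start"))))
}

#' Read / write BED interval tables
#'
#' Minimal 3-column BED (0-based half-open), as used for callable-site and
#' mask files.
#'
#' @param path File path.
#' @param bed A tibble with `chrom`, `start`, `end`.
#' @return `read_bed()` returns a tibble; `write_bed()` returns `path`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", comment = "#")
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Extract gene spans from a GFF3 as a BED-like table
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to extract (default `"gene"`).
#' @return A tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @export
gff_genes <- function(path, feature = "gene") {
  g <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                       col_types = readr::cols(.default = "c"))
  g <- g[g$X3 == feature, ]
  tibble(chrom = g$X1, start = as.integer(g$X4) - 1L,
         end = as.integer(g$X5))
}
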