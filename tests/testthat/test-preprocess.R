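# builds a small VCF with indels, QUAL and DP fields on the fly
write_test_vcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t")
  )
  writeLines(c(header, records), path)
  path
}

rec <- function(pos, ref, alt, qual, gt1 = "0/1", dp1 = 15, gt2 = "0/0",
                dp2 = 15) {
  paste("chr1", pos, ".", ref, alt, qual, "PASS", ".", "GT:DP",
        paste0(gt1, ":", dp1), paste0(gt2, ":", dp2), sep = "\t")
}

test_profile <- function() {
  callable_profile(c(s1 = 10, s2 = 10))
}

test_that("SNPs within the snp-gap of an indel are removed, QUAL and depth bounds hold", {
  path <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    rec(100, "AT", "A", 50),              # indel record (excluded itself)
    rec(102, "C", "G", 50),               # distance 2 from indel span -> out
    rec(104, "C", "G", 50),               # distance 3 -> kept
    rec(300, "C", "G", 9.99),             # below QUAL 10 -> out
    rec(301, "C", "G", 10),               # QUAL exactly 10 -> kept
    rec(500, "C", "G", 50, "0/1", 7),     # depth 7 < 8 -> genotype missing
    rec(600, "C", "G", 50, "0/1", 31),    # depth 31 > 3*10 -> missing
    rec(700, "C", "G", 50, "0/1", 30),    # depth 30 = floor(3*10) -> kept
    rec(800, "C", "G,T", 50)              # multiallelic SNP retained
  ))
  v <- read_vcf_tbl(path)
  f <- filter_variants(v, filter_rules(), test_profile())
  expect_setequal(f$sites$pos, c(104, 301, 500, 600, 700, 800))
  expect_identical(unname(f$gt[f$sites$pos == 500, "s1"]), "./.")
  expect_identical(unname(f$gt[f$sites$pos == 600, "s1"]), "./.")
  expect_identical(unname(f$gt[f$sites$pos == 700, "s1"]), "0/1")
})

test_that("variant filtering is idempotent", {
  path <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    rec(100, "AT", "A", 50), rec(102, "C", "G", 50), rec(104, "C", "G", 50),
    rec(300, "C", "G", 5), rec(500, "C", "G", 50, "0/1", 7)
  ))
  v <- read_vcf_tbl(path)
  f1 <- filter_variants(v, filter_rules(), test_profile())
  f2 <- filter_variants(f1, filter_rules(), test_profile())
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$gt, f2$gt)
})

test_that("intergenic subtraction matches interval arithmetic and a brute-force oracle", {
  out <- intergenic_callable(
    tibble::tibble(chrom = "c", start = 0, end = 100),
    genic = tibble::tibble(chrom = "c", start = 40, end = 60)
  )
  expect_equal(out$start, c(0, 60))
  expect_equal(out$end, c(40, 100))

  # full masking empties the output
  empty <- intergenic_callable(
    tibble::tibble(chrom = "c", start = 10, end = 90),
    genic = tibble::tibble(chrom = "c", start = 0, end = 100)
  )
  expect_equal(nrow(empty), 0)

  # random masks on a 1 kb toy versus per-base membership
  local_seed(21, {
    for (rep in 1:5) {
      cal <- tibble::tibble(chrom = "c",
                            start = sort(sample(0:900, 5)) + c(0:4) * 0)
      cal$end <- cal$start + sample(10:80, 5, replace = TRUE)
      gen <- tibble::tibble(chrom = "c", start = sort(sample(0:950, 4)))
      gen$end <- gen$start + sample(5:60, 4, replace = TRUE)
      reps <- tibble::tibble(chrom = "c", start = sort(sample(0:950, 3)))
      reps$end <- reps$start + sample(5:60, 3, replace = TRUE)
      out <- intergenic_callable(cal, gen, reps)
      member <- function(bed) {
        x <- rep(FALSE, 1100)
        for (i in seq_len(nrow(bed))) {
          if (bed$end[i] > bed$start[i]) {
            x[(bed$start[i] + 1):bed$end[i]] <- TRUE
          }
        }
        x
      }
      expect_identical(member(out), member(cal) & !member(gen) & !member(reps))
      expect_lte(sum(out$end - out$start), sum(cal$end - cal$start))
    }
  })
})

test_that("negative coordinates are rejected, unsorted input tolerated", {
  expect_error(intergenic_callable(
    tibble::tibble(chrom = "c", start = -5, end = 10)
  ), "negative")
  out <- intergenic_callable(
    tibble::tibble(chrom = "c", start = c(50, 0), end = c(80, 20))
  )
  expect_equal(out$start, c(0, 50))
})

test_that("every retained SNP lies inside a callable interval of some sample", {
  cfg <- block_config()
  p <- demography_params(5e4, 5e4, 5e4, 2e5, mu = 1e-7)
  sim <- simulate_vcf_bed(p, cfg, 2, 2, chrom_lengths = c(chr1 = 2000),
                          seed = 9, dir = withr::local_tempdir())
  v <- read_vcf_tbl(sim$vcf)
  f <- filter_variants(v, filter_rules())
  bed <- read_bed(sim$bed)
  inside <- vapply(f$sites$pos, function(pos) {
    any(bed$start < pos & pos <= bed$end)
  }, logical(1))
  expect_true(all(inside))
})
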