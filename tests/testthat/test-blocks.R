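test_that("site classification covers the mutation-type taxonomy", {
  expect_identical(classify_site("0/1", "0/0"), "hetA")
  expect_identical(classify_site("0/0", "0/1"), "hetB")
  expect_identical(classify_site("0/1", "0/1"), "hetAB")
  expect_identical(classify_site("1/1", "0/0"), "fixed")
  expect_identical(classify_site("1/1", "1/1"), "invariant")
  expect_identical(classify_site("./.", "0/0"), "unusable")
  expect_identical(classify_site("0/1", "0/2"), "unusable")
  expect_identical(classify_site("1|0", "0|0"), "hetA") # phased input ok
})

test_that("swapping species labels transposes hetA and hetB", {
  ga <- c("0/1", "0/0", "1/1", "0/1", "1/1")
  gb <- c("0/0", "0/1", "0/0", "0/1", "1/1")
  fwd <- classify_site(ga, gb)
  rev <- classify_site(gb, ga)
  map <- c(hetA = "hetB", hetB = "hetA", hetAB = "hetAB", fixed = "fixed",
           invariant = "invariant", unusable = "unusable")
  expect_identical(unname(map[fwd]), rev)
})

test_that("greedy block cutting honours span limits", {
  cfg <- block_config()
  bs <- cut_blocks(tibble::tibble(chrom = "c", start = 0, end = 128), cfg)
  expect_equal(nrow(bs$blocks), 2)
  expect_equal(bs$blocks$span, c(64, 64))

  # 64 callable bases spread over 129 bases violate max_span
  pos <- local_seed(1, sort(c(0L, 128L, sample(1:127, 62))))
  sparse <- tibble::tibble(chrom = "c", start = pos, end = pos + 1L)
  expect_equal(nrow(cut_blocks(sparse, cfg)$blocks), 0)
})

test_that("block packing matches the brute-force left-anchored oracle on random masks", {
  oracle_pack <- function(pos, span, max_span) {
    starts <- integer()
    i <- 1
    while (i + span - 1 <= length(pos)) {
      if (pos[i + span - 1] - pos[i] + 1 <= max_span) {
        starts <- c(starts, i)
        i <- i + span
      } else {
        i <- i + 1
      }
    }
    starts
  }
  local_seed(31, {
    for (rep in 1:10) {
      pos <- sort(sample(0:999, 400))
      span <- 16
      bed <- tibble::tibble(chrom = "c", start = pos, end = pos + 1)
      bs <- cut_blocks(bed, block_config(block_span = span, max_span = 32,
                                         kmax = c(2, 2, 2, 2)))
      expect_identical(bs$blocks$start,
                       pos[oracle_pack(pos, span, 32)])
      # blocks never overlap and hold exactly span positions
      expect_true(all(table(bs$positions$block_id) == span))
      expect_false(any(duplicated(bs$positions$pos)))
    }
  })
})

test_that("tallies count blocks correctly and are invariant to record order", {
  cfg <- block_config()
  p <- demography_params(5e4, 5e4, 5e4, 2e5, mu = 1e-7)
  sim <- simulate_vcf_bed(p, cfg, 1, 1, chrom_lengths = c(chr1 = 4096),
                          seed = 13, dir = withr::local_tempdir())
  v <- read_vcf_tbl(sim$vcf)
  bs <- cut_blocks(read_bed(sim$bed), cfg)
  t1 <- tally_blocks(bs, v, "A1", "B1")
  expect_equal(sum(t1$n) + attr(t1, "discarded"), nrow(bs$blocks))

  # permute record order
  perm <- local_seed(3, sample(nrow(v$sites)))
  v2 <- structure(list(sites = v$sites[perm, ],
                       gt = v$gt[perm, , drop = FALSE], dp = NULL),
                  class = "vcf_tbl")
  t2 <- tally_blocks(bs, v2, "A1", "B1")
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("blocks with no variants are invariant; truncation and voiding apply", {
  bed <- tibble::tibble(chrom = "c", start = 0, end = 192) # 3 blocks
  bs <- cut_blocks(bed, block_config())
  gt <- function(a, b) list(a = a, b = b)
  # 3 hetA in block 1 (overflow), 1 unusable in block 2, block 3 clean
  sites <- tibble::tibble(chrom = "c", pos = c(5L, 10L, 15L, 70L, 130L),
                          ref = "A", alt = "T", qual = 50)
  gtm <- rbind(c("0/1", "0/0"), c("0/1", "0/0"), c("0/1", "0/0"),
               c("./.", "0/0"), c("1/1", "0/0"))
  colnames(gtm) <- c("sa", "sb")
  v <- structure(list(sites = sites, gt = gtm, dp = NULL), class = "vcf_tbl")
  tal <- tally_blocks(bs, v, "sa", "sb")
  expect_equal(attr(tal, "discarded"), 1)
  expect_equal(sum(tal$n), 2)
  expect_equal(tal$n[tal$hetA == 3 & tal$fixed == 0], 1)  # overflow bin
  expect_equal(tal$n[tal$hetA == 0 & tal$fixed == 1], 1)
})

test_that("variants outside callable blocks raise a warning and are ignored", {
  bs <- cut_blocks(tibble::tibble(chrom = "c", start = 0, end = 64),
                   block_config())
  sites <- tibble::tibble(chrom = "c", pos = c(10L, 500L), ref = "A",
                          alt = "T", qual = 50)
  gtm <- rbind(c("0/1", "0/0"), c("0/1", "0/0"))
  colnames(gtm) <- c("sa", "sb")
  v <- structure(list(sites = sites, gt = gtm, dp = NULL), class = "vcf_tbl")
  expect_warning(tal <- tally_blocks(bs, v, "sa", "sb"), "outside")
  expect_equal(sum(tal$n * tal$hetA), 1)
})

test_that("per-pair block totals scale with the number of pairs on identical masks", {
  # 7 x 6 interspecific pairs on the same mask: total blocks = 42 x per-pair
  bed <- tibble::tibble(chrom = "c", start = 0, end = 64 * 10)
  bs <- cut_blocks(bed, block_config())
  per_pair <- nrow(bs$blocks)
  total <- sum(vapply(1:42, function(i) nrow(bs$blocks), numeric(1)))
  expect_equal(total, 42 * per_pair)
})
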