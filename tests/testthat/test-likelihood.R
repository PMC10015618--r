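test_that("probability tables normalize and respect model nesting", {
  cfg <- block_config()
  div <- table1_div()
  expect_equal(sum(bsfs_probabilities(div, cfg)$prob), 1, tolerance = 1e-10)

  im0 <- demography_params(div$ne_a, div$ne_b, div$ne_anc, div$split_time,
                           me = 0, direction = "none", mu = div$mu)
  expect_identical(bsfs_probabilities(div, cfg)$prob,
                   bsfs_probabilities(im0, cfg)$prob)
})

test_that("swapping species labels and migration direction transposes hetA/hetB", {
  cfg <- block_config()
  p <- demography_params(2e5, 6e5, 9e5, 1.5e6, me = 2e-7,
                         direction = "into_A", mu = 2.9e-9)
  q <- demography_params(6e5, 2e5, 9e5, 1.5e6, me = 2e-7,
                         direction = "into_B", mu = 2.9e-9)
  tp <- bsfs_probabilities(p, cfg)
  tq <- bsfs_probabilities(q, cfg)
  swapped <- tq[order(tq$hetB, tq$hetA, tq$hetAB, tq$fixed), ]
  orig <- tp[order(tp$hetA, tp$hetB, tp$hetAB, tp$fixed), ]
  expect_equal(orig$prob, swapped$prob, tolerance = 1e-9)
})

test_that("probabilities are invariant to a joint rescaling of sizes, times and rates", {
  cfg <- block_config()
  p <- demography_params(2e5, 6e5, 9e5, 1.5e6, me = 2e-7,
                         direction = "into_A", mu = 2.9e-9)
  c_ <- 3.7
  q <- demography_params(2e5 * c_, 6e5 * c_, 9e5 * c_, 1.5e6 * c_,
                         me = 2e-7 / c_, direction = "into_A",
                         mu = 2.9e-9 / c_)
  expect_equal(bsfs_probabilities(p, cfg)$prob,
               bsfs_probabilities(q, cfg)$prob, tolerance = 1e-9)
})

test_that("deep-split isolated species reproduce single-population heterozygosity", {
  # tiny theta so truncation mass is negligible
  cfg <- block_config()
  mu <- 1e-10
  p <- demography_params(1e5, 3e5, 1e5, split_time = 1e9, mu = mu)
  tab <- bsfs_probabilities(p, cfg)
  e_hetA <- sum(tab$hetA * tab$prob) / cfg$block_span
  e_hetB <- sum(tab$hetB * tab$prob) / cfg$block_span
  expect_equal(e_hetA, 4 * 1e5 * mu, tolerance = 1e-3)
  expect_equal(e_hetB, 4 * 3e5 * mu, tolerance = 1e-3)
})

test_that("exact tables match the Monte-Carlo simulator within 3 SE per bin", {
  cfg <- block_config()
  n <- 2e5
  pts <- list(table1_im_bda(),
              demography_params(5e5, 2e5, 8e5, 3e6, me = 4e-7,
                                direction = "into_B"))
  for (i in seq_along(pts)) {
    tab <- bsfs_probabilities(pts[[i]], cfg)
    sim <- simulate_blocks(pts[[i]], cfg, n, seed = 40 + i)
    idx <- meflow:::bin_index(meflow:::truncate_counts(sim, cfg$kmax),
                              cfg$kmax)
    phat <- tabulate(idx, nbins = nrow(tab)) / n
    tol <- 3 * sqrt(tab$prob * (1 - tab$prob) / n) + 5 / n
    expect_true(all(abs(phat - tab$prob) <= tol))
  }
})

test_that("composite lnCL follows the multinomial identities", {
  cfg <- block_config()
  tab <- bsfs_probabilities(table1_div(), cfg)
  empty <- tally_from_counts(tibble::tibble(hetA = integer(), hetB = integer(),
                                            hetAB = integer(),
                                            fixed = integer()))
  expect_equal(composite_lnCL(empty, tab), 0)

  one <- tally_from_counts(tibble::tibble(hetA = 1L, hetB = 0L, hetAB = 0L,
                                          fixed = 1L))
  k <- which(tab$hetA == 1 & tab$hetB == 0 & tab$hetAB == 0 & tab$fixed == 1)
  expect_equal(composite_lnCL(one, tab), log(tab$prob[k]))

  # additivity over disjoint block sets
  p <- table1_div()
  x <- simulate_blocks(p, cfg, 500, seed = 1)
  y <- simulate_blocks(p, cfg, 500, seed = 2)
  lx <- composite_lnCL(tally_from_counts(x), tab)
  ly <- composite_lnCL(tally_from_counts(y), tab)
  lxy <- composite_lnCL(tally_from_counts(dplyr::bind_rows(x, y)), tab)
  expect_equal(lxy, lx + ly, tolerance = 1e-10)

  # mismatched truncation is rejected
  t2 <- tally_from_counts(x, kmax = c(1, 1, 1, 1))
  expect_error(composite_lnCL(t2, tab), "kmax")
})

test_that("migrants-per-generation conversion satisfies its identities", {
  expect_equal(signif(migrants_per_generation(0.171e6, 1.811e-7), 3), 0.124)
  expect_equal(migrants_per_generation(123456, 0), 0)
  me <- 3e-7
  expect_equal(migrants_per_generation(1 / (4 * me), me), 1)
})
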