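test_that("window cutting tiles chromosomes and drops remainders", {
  b <- tibble::tibble(chrom = "c", start = (0:89) * 64, end = (0:89) * 64 + 64)
  w <- suppressMessages(cut_windows(b, 30))
  expect_equal(nrow(attr(w, "windows")), 3)
  expect_equal(attr(w, "dropped"), 0)

  b2 <- b[1:29, ]
  expect_warning(w2 <- suppressMessages(cut_windows(b2, 30)), "no windows")
  expect_equal(nrow(attr(w2, "windows")), 0)

  # multi-chromosome brute-force re-partition
  local_seed(8, {
    nb <- c(c1 = 25, c2 = 61, c3 = 7)
    b3 <- dplyr::bind_rows(lapply(names(nb), function(ch) {
      tibble::tibble(chrom = ch, start = seq_len(nb[[ch]]) * 64,
                     end = seq_len(nb[[ch]]) * 64 + 64)
    }))
    w3 <- suppressWarnings(suppressMessages(cut_windows(b3, 10)))
    ww <- attr(w3, "windows")
    expect_equal(nrow(ww), sum(floor(nb / 10)))
    expect_equal(attr(w3, "dropped"), sum(nb %% 10))
    # every block in at most one window, windows never span chromosomes
    expect_true(all(table(w3$window_id) == 10))
    expect_equal(nrow(dplyr::distinct(ww, window_id, chrom)), nrow(ww))
  })
})

test_that("window block counts scale proportionally with pair number", {
  expect_equal(scale_window_block_count(30000, 42, 6), 4286L)
  expect_equal(scale_window_block_count(1234, 7, 7), 1234L)
  expect_equal(scale_window_block_count(30000, 42, 84), 60000L)
})

test_that("the grid scan recovers on-grid window truths and profiles are max-of-max", {
  cfg <- block_config()
  g <- make_grid(small_grid_spec())
  gt <- evaluate_grid(g, cfg)
  truth <- g[g$ne_a == 2e5 & g$ne_b == 9e5 & g$ne_anc == 1.1e6 &
               g$me == 1.75e-7, ]
  p <- demography_params(truth$ne_a, truth$ne_b, truth$ne_anc,
                         truth$split_time, me = truth$me,
                         direction = "into_A", mu = 2.9e-9)
  n_win <- 4
  sims <- simulate_blocks(p, cfg, 30000 * n_win, seed = 19)
  sims$window_id <- rep(seq_len(n_win), each = 30000)
  wt <- window_tallies(sims, cfg$kmax)
  res <- window_scan(wt, gt)
  expect_equal(nrow(res), n_win)
  expect_true(all(res$me == truth$me))
  expect_true(all(res$ne_a == truth$ne_a))
  # conditional profile max equals the unconditional MCL
  for (i in seq_len(n_win)) {
    expect_equal(max(res$profile[[i]]$lnCL), res$lnCL[i])
  }
  # identical windows give identical results
  sims2 <- sims[sims$window_id <= 2, ]
  sims2$window_id <- rep(1:2, each = 30000)
  sims2[sims2$window_id == 2, 1:7] <- sims2[sims2$window_id == 1, 1:7]
  res2 <- window_scan(window_tallies(sims2, cfg$kmax), gt)
  expect_equal(res2$lnCL[1], res2$lnCL[2])
  expect_equal(res2$me[1], res2$me[2])
})

test_that("barrier classification is strict and validates its inputs", {
  prof <- function(l0, lb) {
    tibble::tibble(me = c(0, 1.75e-7), lnCL = c(l0, lb))
  }
  res <- tibble::tibble(window_id = 1:2, me = 0,
                        profile = list(prof(-1000, -1001), prof(-1000, -1000)))
  out <- classify_barrier(res, 1.75e-7)
  expect_identical(out$barrier, c(TRUE, FALSE))
  expect_error(classify_barrier(res, 9.9e-7), "background")
})

test_that("windows simulated without migration are flagged as barriers more often", {
  cfg <- block_config()
  g <- make_grid(small_grid_spec())
  gt <- evaluate_grid(g, cfg)
  bg <- 1.75e-7
  mk_res <- function(me, dirn, seed, n_win = 6) {
    p <- demography_params(2e5, 9e5, 1.1e6, 2.202e6, me = me,
                           direction = dirn, mu = 2.9e-9)
    sims <- simulate_blocks(p, cfg, 5000 * n_win, seed = seed)
    sims$window_id <- rep(seq_len(n_win), each = 5000)
    classify_barrier(window_scan(window_tallies(sims, cfg$kmax), gt), bg)
  }
  barrier0 <- mk_res(0, "none", 101)
  barrier2 <- mk_res(2 * bg, "into_A", 102)
  expect_gt(mean(barrier0$barrier), mean(barrier2$barrier))
  expect_gt(mean(barrier0$barrier), 0.5)
})

test_that("chromosome summaries average me and handle rank statistics", {
  res <- tibble::tibble(
    window_id = 1:10,
    chrom = rep(c("c1", "c2", "c3", "c4", "c5"), each = 2),
    me = c(1, 3, 2, 2, 5, 7, 4, 4, 9, 11) * 1e-8,
    barrier = rep(c(TRUE, FALSE), 5)
  )
  lens <- c(c1 = 1e6, c2 = 2e6, c3 = 3e6, c4 = 4e6, c5 = 5e6)
  s <- summarize_chromosomes(res, lengths = lens)
  expect_equal(s$chromosomes$mean_me,
               c(2, 2, 6, 4, 10) * 1e-8)
  expect_equal(s$chromosomes$barrier_fraction, rep(0.5, 5))
  # hand-computed Spearman on (1,2,3,4,5) vs ranks of (2,2,6,4,10):
  # ranks (1.5, 1.5, 4, 3, 5) -> rho = 0.8720816 (cor of ranks with ties)
  expect_equal(s$spearman$rho,
               stats::cor(1:5, c(1.5, 1.5, 4, 3, 5)), tolerance = 1e-6)

  # perfectly monotone decreasing toy
  res2 <- res
  res2$me <- rev(sort(res$me))[order(rep(1:5, each = 2))]
  res2$me <- c(10, 10, 8, 8, 6, 6, 4, 4, 2, 2) * 1e-8
  s2 <- summarize_chromosomes(res2, lengths = lens)
  expect_equal(s2$spearman$rho, -1)

  # constant me: correlation undefined, reported as NA
  res3 <- res
  res3$me <- 2e-7
  s3 <- summarize_chromosomes(res3, lengths = lens)
  expect_true(is.na(s3$spearman$rho))
  expect_true(all(s3$chromosomes$mean_me == 2e-7))
})

test_that("windows are assigned to the aligned genome by majority overlap", {
  al <- tibble::tibble(
    qname = "q1", qlen = 1000L, qstart = c(0, 600), qend = c(600, 1000),
    strand = "+", tname = c("t1", "t2"), tlen = 1000L,
    tstart = 0, tend = 600, nmatch = 500, alen = c(600, 400), mapq = 60
  )
  w <- tibble::tibble(window_id = 1:2, chrom = "q1",
                      start = c(0, 500), end = c(500, 1000))
  a <- assign_windows_by_alignment(w, al)
  expect_equal(a$chromosome, c("t1", "t2"))
})
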