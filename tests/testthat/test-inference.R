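test_that("grids materialize as ordered Cartesian products", {
  gs <- small_grid_spec()
  g <- make_grid(gs)
  expect_equal(nrow(g), 3 * 2 * 2 * 4)
  # me varies fastest
  expect_equal(g$me[1:4], gs$me)
  expect_equal(nrow(make_grid(grid_spec(1e5, 1e5, 1e5, 0, 1e6))), 1)
  expect_equal(nrow(make_grid(grid_spec(
    c(1e5, 2e5), c(1e5, 2e5), c(1e5, 2e5), c(0, 1e-7), 1e6
  ))), 16)
  expect_error(grid_spec(c(2e5, 1e5), 1e5, 1e5, 0, 1e6), "increasing")
})

test_that("nearest grid value picks the closest, ties to the smaller", {
  v <- scan_me_grid()
  expect_equal(nearest_grid_value(v, 1.811e-7), 1.75e-7, tolerance = 1e-12)
  expect_equal(nearest_grid_value(v, v[7]), v[7])
  # exact midpoint resolves to the smaller value
  expect_equal(nearest_grid_value(c(1, 3, 5), 2), 1)
})

test_that("grid evaluation caches deterministically and nests at me = 0", {
  cfg <- block_config()
  gs <- grid_spec(c(2e5, 4e5), 6e5, 1e6, c(0, 2e-7), 1.5e6)
  g <- make_grid(gs)
  dir <- withr::local_tempdir()
  g1 <- evaluate_grid(g, cfg, cache_dir = dir)
  g2 <- evaluate_grid(g, cfg, cache_dir = dir)  # re-read from cache
  expect_equal(g1$log_prob, g2$log_prob)
  expect_equal(length(g1$failed), 0)

  # me = 0 columns equal DIV tables
  div <- demography_params(2e5, 6e5, 1e6, 1.5e6)
  tab <- bsfs_probabilities(div, cfg)
  i0 <- which(g$ne_a == 2e5 & g$me == 0)
  expect_equal(g1$log_prob[, i0], log(pmax(tab$prob, 1e-300)),
               tolerance = 1e-9)
})

test_that("grid argmax recovers an on-grid truth point", {
  cfg <- block_config()
  g <- make_grid(small_grid_spec())
  gt <- evaluate_grid(g, cfg)
  truth <- g[g$ne_a == 2e5 & g$ne_b == 9e5 & g$ne_anc == 1.1e6 &
               g$me == 1.75e-7, ]
  p <- demography_params(truth$ne_a, truth$ne_b, truth$ne_anc,
                         truth$split_time, me = truth$me,
                         direction = "into_A", mu = 2.9e-9)
  tal <- simulate_block_tallies(p, cfg, n_blocks = 1e5, seed = 17)
  v <- meflow:::tally_vector(tal)
  lnCL <- as.numeric(v %*% gt$log_prob)
  best <- g[which.max(lnCL), ]
  expect_equal(best$ne_a, truth$ne_a)
  expect_equal(best$ne_b, truth$ne_b)
  expect_equal(best$ne_anc, truth$ne_anc)
  expect_equal(best$me, truth$me)
})

test_that("DIV fits recover simulated truth and IM collapses onto nested DIV", {
  cfg <- block_config()
  div <- table1_div()
  tal <- simulate_block_tallies(div, cfg, n_blocks = 1e5, seed = 23)
  fd <- optimize_model(tal, "DIV", cfg, n_starts = 2, seed = 1)
  expect_true(is.finite(fd$lnCL))
  est <- fd$params
  for (nm in c("ne_a", "ne_b", "ne_anc", "split_time")) {
    expect_equal(est[[nm]], div[[nm]], tolerance = 0.2)
  }

  fi <- optimize_model(tal, "IM_into_B", cfg, n_starts = 2, seed = 1)
  expect_lt(fi$params$me, 2e-8)              # me pinned near the lower bound
  expect_gte(fi$lnCL, fd$lnCL - 0.05)        # nesting up to optimizer noise
  expect_lt(fi$lnCL - fd$lnCL, 5)            # no spurious improvement

  expect_s3_class(tidy(fd), "tbl_df")
  expect_equal(glance(fd)$model, "DIV")
})

test_that("the parametric bootstrap yields a reproducible non-negative null", {
  cfg <- block_config(recomb_rate = 8.5e-9)
  div <- table1_div()
  tal <- simulate_block_tallies(div, block_config(), n_blocks = 3e4, seed = 5)
  fd <- optimize_model(tal, "DIV", block_config(), n_starts = 1, seed = 2)
  boot <- parametric_bootstrap(fd, n_reps = 3, config = cfg,
                               n_blocks = 2e4, seed = 7, n_starts = 1)
  expect_equal(nrow(boot), 3)
  expect_true(all(boot$delta >= -0.05))
  boot2 <- parametric_bootstrap(fd, n_reps = 3, config = cfg,
                                n_blocks = 2e4, seed = 7, n_starts = 1)
  expect_equal(boot$delta, boot2$delta)
  # an observed improvement far above the null rejects the DIV history
  expect_equal(bootstrap_pvalue(boot, max(boot$delta) + 100), 1 / 4)
})
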