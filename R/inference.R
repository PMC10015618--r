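# fast composite-lnCL evaluator: pre-extracts the dense bin-count vector once
lnCL_evaluator <- function(tally, config) {
  nvec <- tally_vector(tally)
  occ <- which(nvec > 0)
  nocc <- nvec[occ]
  function(params) {
    tab <- bsfs_probabilities(params, config)
    sum(nocc * log(pmax(tab$prob[occ], 1e-300)))
  }
}

default_bounds <- function() {
  list(ne_a = c(1e4, 1e7), ne_b = c(1e4, 1e7), ne_anc = c(1e4, 1e7),
       split_time = c(1e4, 2e7), me = c(0, 1e-6))
}

# crude method-of-moments parameter guesses from a tally, used to place the
# first optimizer start: within-species heterozygosities give the Ne's,
# between-species diversity gives a split-time scale
moment_start <- function(tally, config, mu) {
  span <- attr(tally, "block_span") %||% config$block_span
  w <- tally$n / sum(tally$n)
  hA <- sum(w * (tally$hetA + tally$hetAB)) / span
  hB <- sum(w * (tally$hetB + tally$hetAB)) / span
  dxy <- sum(w * (0.5 * (tally$hetA + tally$hetB + tally$hetAB) +
                    tally$fixed)) / span
  ne_a <- hA / (4 * mu)
  ne_b <- hB / (4 * mu)
  ne_anc <- (ne_a + ne_b) / 2
  split_time <- dxy / (2 * mu) - 2 * ne_anc
  list(ne_a = ne_a, ne_b = ne_b, ne_anc = ne_anc,
       split_time = split_time, me = 2e-8)
}

#' Fit a DIV or IM model to a bSFS tally by maximum composite likelihood
#'
#' Bounded multi-start local optimization of the composite log-likelihood.
#' Sizes and the split time are searched on a log10 scale; `me` (IM models)
#' on a linear scale with a lower bound of exactly 0, so an IM fit can
#' collapse onto the nested DIV model. Start points are scattered uniformly
#' in the (transformed) box, the first start sitting at its centre.
#'
#' @param tally A [bsfs_tally].
#' @param model `"DIV"`, `"IM_into_A"` or `"IM_into_B"` (direction stated
#'   forwards in time; `into_A` receives migrants from B).
#' @param config A [block_config()] matching the tally.
#' @param mu Mutation rate per site per generation.
#' @param bounds Named list of `c(lower, upper)` per free parameter
#'   (`ne_a`, `ne_b`, `ne_anc`, `split_time`, `me`); defaults cover
#'   10^4..10^7 individuals/generations and me up to 1e-6.
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(split_time = 2.2e6)` for window scans).
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed controlling start placement.
#' @param control Passed to [stats::nlminb()] (default relative tolerance
#'   1e-8).
#' @return An `im_fit` object: list with the fitted [demography_params()]
#'   (`params`), `lnCL`, `model`, a per-start trace tibble (`starts`) and a
#'   `converged` flag. Supports [tidy()] and [glance()].
#' @export
optimize_model <- function(tally, model = c("DIV", "IM_into_A", "IM_into_B"),
                           config = block_config(), mu = 2.9e-9,
                           bounds = default_bounds(), fixed = list(),
                           n_starts = 5, seed = 1,
                           control = list(rel.tol = 1e-8)) {
  model <- match.arg(model)
  n_starts <- assert_count(n_starts, "n_starts")
  stopifnot(inherits(tally, "bsfs_tally"))
  direction <- switch(model, DIV = "none", IM_into_A = "into_A",
                      IM_into_B = "into_B")
  par_names <- c("ne_a", "ne_b", "ne_anc", "split_time",
                 if (model != "DIV") "me")
  free <- setdiff(par_names, names(fixed))
  if (length(free) == 0) abort("no free parameters to optimize")
  b <- bounds[free]
  if (any(vapply(b, is.null, logical(1)))) {
    abort("`bounds` must cover every free parameter")
  }
  is_log <- free != "me"
  lower <- vapply(b, `[`, numeric(1), 1)
  upper <- vapply(b, `[`, numeric(1), 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("bounds must be finite")
  }
  tl <- ifelse(is_log, log10(lower), lower * 1e7)
  tu <- ifelse(is_log, log10(upper), upper * 1e7)

  eval_lnCL <- lnCL_evaluator(tally, config)
  to_params <- function(x) {
    v <- ifelse(is_log, 10^x, x / 1e7)
    names(v) <- free
    full <- c(as.list(v), fixed)
    me <- full$me %||% 0
    demography_params(
      ne_a = full$ne_a, ne_b = full$ne_b, ne_anc = full$ne_anc,
      split_time = full$split_time, me = me,
      direction = if (me > 0) direction else "none", mu = mu
    )
  }
  objective <- function(x) -eval_lnCL(to_params(x))

  starts <- local_seed(seed, {
    s <- matrix(runif(n_starts * length(free), tl, tu),
                nrow = n_starts, byrow = TRUE)
    ms <- moment_start(tally, config, mu)
    m0 <- vapply(free, function(p) ms[[p]], numeric(1))
    m0 <- pmin(pmax(m0, lower * 1.001), upper * 0.999)
    s[1, ] <- ifelse(is_log, log10(m0), m0 * 1e7)
    if (n_starts >= 2) s[2, ] <- (tl + tu) / 2
    s
  })

  runs <- purrr::map(seq_len(n_starts), function(i) {
    res <- tryCatch(
      nlminb(starts[i, ], objective, lower = tl, upper = tu,
             control = control),
      error = function(e) list(par = starts[i, ], objective = Inf,
                               convergence = 1L, message = conditionMessage(e),
                               iterations = NA_integer_)
    )
    res
  })
  obj <- vapply(runs, function(r) r$objective, numeric(1))
  if (all(!is.finite(obj))) {
    abort("all optimizer starts failed", trace_data = runs)
  }
  best <- runs[[which.min(obj)]]
  params <- to_params(best$par)
  fit <- structure(list(
    model = model,
    params = params,
    lnCL = -best$objective,
    starts = tibble(
      start = seq_len(n_starts),
      lnCL = -obj,
      iterations = vapply(runs, function(r) {
        as.integer(r$iterations %||% NA_integer_)
      }, integer(1)),
      converged = vapply(runs, function(r) {
        identical(r$convergence, 0L)
      }, logical(1))
    ),
    converged = identical(best$convergence, 0L),
    fixed = fixed
  ), class = "im_fit")
  fit
}

#' @export
print.im_fit <- function(x, ...) {
  cat(sprintf("<im_fit> %s model, lnCL = %.3f%s\n", x$model, x$lnCL,
              if (x$converged) "" else " (not converged)"))
  p <- x$params
  cat(sprintf("  Ne_A = %.4g  Ne_B = %.4g  Ne_anc = %.4g  T = %.4g gen\n",
              p$ne_a, p$ne_b, p$ne_anc, p$split_time))
  if (x$model != "DIV") cat(sprintf("  me = %.4g\n", p$me))
  invisible(x)
}

#' Parameter grid for windowed likelihood scans
#'
#' @param ne_a,ne_b,ne_anc Strictly increasing value lists for the three
#'   effective sizes.
#' @param me Strictly increasing effective-migration values (may include 0).
#' @param split_time Single fixed split time (generations); window scans hold
#'   it at the genome-wide estimate.
#' @return A `grid_spec` object.
#' @examples
#' gs <- grid_spec(
#'   ne_a = seq(20e3, 720e3, length.out = 15),
#'   ne_b = seq(50e3, 2850e3, length.out = 15),
#'   ne_anc = seq(50e3, 2010e3, length.out = 15),
#'   me = seq(0, 6.65e-7, length.out = 20),
#'   split_time = 2.202e6
#' )
#' nrow(make_grid(gs)) # 67,500
#' @export
grid_spec <- function(ne_a, ne_b, ne_anc, me, split_time) {
  for (nm in c("ne_a", "ne_b", "ne_anc", "me")) {
    v <- get(nm)
    if (length(v) == 0 || is.unsorted(v, strictly = TRUE)) {
      abort(sprintf("`%s` must be non-empty and strictly increasing", nm))
    }
  }
  stopifnot(length(split_time) == 1, split_time >= 0)
  structure(list(ne_a = ne_a, ne_b = ne_b, ne_anc = ne_anc, me = me,
                 split_time = split_time), class = "grid_spec")
}

#' Materialize a grid specification as parameter points
#'
#' The Cartesian product in documented lexicographic order: `me` varies
#' fastest, then `ne_anc`, `ne_b`, `ne_a`.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with `point` (1..n), the four parameters and
#'   `split_time`.
#' @export
make_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- expand.grid(me = spec$me, ne_anc = spec$ne_anc, ne_b = spec$ne_b,
                   ne_a = spec$ne_a, KEEP.OUT.ATTRS = FALSE)
  tibble(point = seq_len(nrow(g)), ne_a = g$ne_a, ne_b = g$ne_b,
         ne_anc = g$ne_anc, me = g$me, split_time = spec$split_time)
}

#' Nearest grid value
#'
#' Returns the grid value minimizing the absolute distance to `x`; exact
#' midpoints between two grid values resolve to the smaller one.
#'
#' @param values Ordered numeric grid values.
#' @param x A number.
#' @return One element of `values`.
#' @examples
#' nearest_grid_value(seq(0, 6.65e-7, length.out = 20), 1.811e-7) # 1.75e-7
#' @export
nearest_grid_value <- function(values, x) {
  stopifnot(length(values) >= 1)
  values[order(abs(values - x), values)][1]
}

#' Evaluate bSFS probability tables over a parameter grid
#'
#' One exact probability table per grid point, optionally cached to disk as
#' TSV (one file per point, keyed by the point id) so interrupted runs can
#' resume; cached points are re-read rather than recomputed.
#'
#' @param grid A [make_grid()] tibble.
#' @param config A [block_config()].
#' @param mu Mutation rate per site per generation.
#' @param cache_dir Optional directory for the per-point TSV cache.
#' @return A `grid_tables` object: list with `grid` and `log_prob`, a
#'   (bins x points) matrix of log probabilities in canonical bin order.
#'   Per-point kernel failures are recorded in `failed` (their columns are
#'   `NA`) and the run continues.
#' @export
evaluate_grid <- function(grid, config = block_config(), mu = 2.9e-9,
                          cache_dir = NULL) {
  stopifnot(nrow(grid) >= 1)
  nbin <- prod(config$kmax + 2L)
  logp <- matrix(NA_real_, nbin, nrow(grid))
  failed <- integer()
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  }
  for (i in seq_len(nrow(grid))) {
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("point_%06d.tsv", grid$point[i]))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      logp[, i] <- readr::read_tsv(cache_file, col_types = "d")$log_prob
      next
    }
    tab <- tryCatch({
      params <- demography_params(
        ne_a = grid$ne_a[i], ne_b = grid$ne_b[i], ne_anc = grid$ne_anc[i],
        split_time = grid$split_time[i], me = grid$me[i],
        direction = if (grid$me[i] > 0) "into_A" else "none", mu = mu
      )
      bsfs_probabilities(params, config)
    }, error = function(e) {
      warn(sprintf("grid point %d failed: %s", grid$point[i],
                   conditionMessage(e)))
      NULL
    })
    if (is.null(tab)) {
      failed <- c(failed, grid$point[i])
      next
    }
    logp[, i] <- log(pmax(tab$prob, 1e-300))
    if (!is.null(cache_file)) {
      readr::write_tsv(tibble(log_prob = logp[, i]), cache_file)
    }
  }
  structure(list(grid = grid, log_prob = logp, failed = failed,
                 config = config, mu = mu),
            class = "grid_tables")
}

#' @export
print.grid_tables <- function(x, ...) {
  cat(sprintf("<grid_tables> %d points x %d bins (%d failed)\n",
              nrow(x$grid), nrow(x$log_prob), length(x$failed)))
  invisible(x)
}

#' Parametric bootstrap for the DIV vs IM model comparison
#'
#' Simulates replicate tallies under the fitted DIV history (linked blocks
#' when `config$recomb_rate > 0`, reproducing the recombination setting of
#' the bootstrap), refits both the DIV and IM models to each replicate and
#' records the improvement in fit `delta = lnCL(IM) - lnCL(DIV)`. The
#' resulting null distribution calibrates an observed delta:
#' `bootstrap_pvalue()` applies the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n)`.
#'
#' @param div_fit An `im_fit` with `model == "DIV"` (the null history).
#' @param n_reps Number of bootstrap replicates.
#' @param config A [block_config()]; set `recomb_rate` for linked blocks.
#' @param n_blocks,n_pairs Size of each simulated tally.
#' @param im_model Alternative model to refit (default `"IM_into_A"`).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param n_starts Optimizer starts per fit.
#' @return A `bootstrap_result`: tibble with `replicate`, `seed`,
#'   `lnCL_div`, `lnCL_im`, `delta`; failed replicates are dropped and
#'   counted in attribute `"failures"`.
#' @export
parametric_bootstrap <- function(div_fit, n_reps, config = block_config(),
                                 n_blocks = 1e4, n_pairs = 1,
                                 im_model = "IM_into_A", seed = 1,
                                 n_starts = 2) {
  stopifnot(inherits(div_fit, "im_fit"))
  n_reps <- assert_count(n_reps, "n_reps")
  res <- purrr::map(seq_len(n_reps), function(r) {
    rs <- derive_seed(seed, r)
    tryCatch({
      tal <- simulate_block_tallies(div_fit$params, config, n_blocks,
                                    n_pairs, seed = rs)
      fd <- optimize_model(tal, "DIV", config, mu = div_fit$params$mu,
                           n_starts = n_starts, seed = rs)
      fi <- optimize_model(tal, im_model, config, mu = div_fit$params$mu,
                           n_starts = n_starts, seed = rs)
      tibble(replicate = r, seed = rs, lnCL_div = fd$lnCL, lnCL_im = fi$lnCL,
             delta = fi$lnCL - fd$lnCL)
    }, error = function(e) {
      warn(sprintf("bootstrap replicate %d failed: %s", r,
                   conditionMessage(e)))
      NULL
    })
  })
  failures <- sum(vapply(res, is.null, logical(1)))
  out <- bind_rows(res)
  structure(out, failures = failures,
            class = c("bootstrap_result", class(out)))
}

#' @rdname parametric_bootstrap
#' @param boot A `bootstrap_result`.
#' @param observed Observed `lnCL(IM) - lnCL(DIV)` from the data.
#' @export
bootstrap_pvalue <- function(boot, observed) {
  (1 + sum(boot$delta >= observed)) / (1 + nrow(boot))
}
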