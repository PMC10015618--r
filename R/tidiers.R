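#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted demographic model
#'
#' @param x An `im_fit` from [optimize_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `fixed`).
#' @export
tidy.im_fit <- function(x, ...) {
  p <- x$params
  terms <- c("ne_a", "ne_b", "ne_anc", "split_time",
             if (x$model != "DIV") "me")
  tibble(
    term = terms,
    estimate = vapply(terms, function(t) p[[t]], numeric(1)),
    fixed = terms %in% names(x$fixed)
  )
}

#' @rdname tidy.im_fit
#' @return `glance()` returns a one-row tibble with `model`, `lnCL`,
#'   `converged`, `n_starts`.
#' @export
glance.im_fit <- function(x, ...) {
  tibble(model = x$model, lnCL = x$lnCL, converged = x$converged,
         n_starts = nrow(x$starts))
}

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-value and
#'   permutation bookkeeping.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         p_value = x$p_value, n_perm = x$n_perm, n_used = x$n_used,
         discarded = x$discarded, seed = x$seed)
}

#' Tidy a polarized rearrangement history
#'
#' @param x An `event_set` from [polarize_parsimony()].
#' @param ... Unused.
#' @return The per-branch event tibble.
#' @export
tidy.event_set <- function(x, ...) {
  select(x$events, "branch", "type", "operands")
}

#' @rdname tidy.event_set
#' @return `glance()` returns one row per branch with event counts plus the
#'   inferred ancestral chromosome number.
#' @export
glance.event_set <- function(x, ...) {
  mutate(x$counts, n_ancestral_chromosomes = x$n_ancestral_chromosomes)
}
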