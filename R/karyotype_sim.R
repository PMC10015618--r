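#' Describe a synthetic fission/fusion history on a 3-taxon tree
#'
#' A scenario starts from an ancestral karyotype of `n_ancestral_chroms`
#' chromosomes at the root of the ingroup pair (A, B) and applies an ordered
#' list of fission and fusion events along the branches leading to taxa A, B
#' and the outgroup O. The outgroup retains the root karyotype unless events
#' are placed on its branch.
#'
#' @param n_ancestral_chroms Chromosome count of the (A, B) ancestor.
#' @param events A data frame with columns `branch` (`"A"`, `"B"` or `"O"`),
#'   `type` (`"fission"` or `"fusion"`), `chrom1`, `chrom2` (second operand,
#'   fusions only) and `split_at` (marker index, fissions only: the first
#'   `split_at` markers form the left product). Events are applied in row
#'   order within each branch, and operand ids may reference chromosomes
#'   created by earlier events (fission products of `x` are `x.1`/`x.2`,
#'   a fusion of `x` and `y` is `x+y`).
#' @param markers_per_chrom Markers placed on each ancestral chromosome.
#' @return A `rearrangement_scenario` object.
#' @examples
#' rearrangement_scenario(4, tibble::tibble(
#'   branch = "A", type = "fusion", chrom1 = "anc_1", chrom2 = "anc_2",
#'   split_at = NA
#' ))
#' @export
rearrangement_scenario <- function(n_ancestral_chroms, events = NULL,
                                   markers_per_chrom = 10) {
  n_ancestral_chroms <- assert_count(n_ancestral_chroms, "n_ancestral_chroms")
  markers_per_chrom <- assert_count(markers_per_chrom, "markers_per_chrom")
  if (is.null(events)) {
    events <- tibble(branch = character(), type = character(),
                     chrom1 = character(), chrom2 = character(),
                     split_at = integer())
  }
  events <- as_tibble(events)
  if (!"chrom2" %in% names(events)) events$chrom2 <- NA_character_
  if (!"split_at" %in% names(events)) events$split_at <- NA_integer_
  stopifnot(all(c("branch", "type", "chrom1") %in% names(events)))
  if (!all(events$branch %in% c("A", "B", "O"))) {
    abort("event `branch` must be one of \"A\", \"B\", \"O\"")
  }
  if (!all(events$type %in% c("fission", "fusion"))) {
    abort("event `type` must be \"fission\" or \"fusion\"")
  }
  structure(
    list(n_ancestral_chroms = n_ancestral_chroms, events = events,
         markers_per_chrom = markers_per_chrom),
    class = "rearrangement_scenario"
  )
}

#' Apply a rearrangement scenario and emit per-taxon marker tables
#'
#' Replays the scenario's fissions and fusions along each branch and reports,
#' for every marker, the chromosome carrying it in each taxon. Chromosome ids
#' are strings namespaced by taxon (`"A:anc_1+anc_2"` and so on); marker order
#' within chromosomes is preserved (fissions cut the ordered marker list,
#' fusions concatenate).
#'
#' @param scenario A [rearrangement_scenario()].
#' @return A tibble with columns `marker_id`, `taxon`, `chromosome` (one row
#'   per marker per taxon) and a `position` column giving the marker's rank
#'   on its chromosome.
#' @examples
#' sc <- rearrangement_scenario(3)
#' simulate_rearrangement_history(sc) # identical partitions in all taxa
#' @export
simulate_rearrangement_history <- function(scenario) {
  stopifnot(inherits(scenario, "rearrangement_scenario"))
  root <- lapply(seq_len(scenario$n_ancestral_chroms), function(i) {
    paste0("m", i, "_", seq_len(scenario$markers_per_chrom))
  })
  names(root) <- paste0("anc_", seq_len(scenario$n_ancestral_chroms))

  apply_branch <- function(karyotype, branch) {
    ev <- dplyr::filter(scenario$events, .data$branch == !!branch)
    for (r in seq_len(nrow(ev))) {
      e <- ev[r, ]
      if (!e$chrom1 %in% names(karyotype)) {
        abort(sprintf("event %d on branch %s: chromosome \"%s\" does not exist",
                      r, branch, e$chrom1))
      }
      if (e$type == "fusion") {
        if (is.na(e$chrom2) || !e$chrom2 %in% names(karyotype)) {
          abort(sprintf("event %d on branch %s: fusion partner \"%s\" does not exist",
                        r, branch, e$chrom2))
        }
        if (e$chrom1 == e$chrom2) {
          abort("fusion operands must be two distinct chromosomes")
        }
        fused <- c(karyotype[[e$chrom1]], karyotype[[e$chrom2]])
        karyotype[[e$chrom1]] <- NULL
        karyotype[[e$chrom2]] <- NULL
        karyotype[[paste0(e$chrom1, "+", e$chrom2)]] <- fused
      } else {
        mk <- karyotype[[e$chrom1]]
        s <- e$split_at
        if (is.na(s) || s < 1 || s >= length(mk)) {
          abort(sprintf(
            "event %d on branch %s: fission of \"%s\" must leave two non-empty parts",
            r, branch, e$chrom1))
        }
        karyotype[[e$chrom1]] <- NULL
        karyotype[[paste0(e$chrom1, ".1")]] <- mk[seq_len(s)]
        karyotype[[paste0(e$chrom1, ".2")]] <- mk[-seq_len(s)]
      }
    }
    karyotype
  }

  purrr::map_dfr(c("A", "B", "O"), function(tx) {
    k <- apply_branch(root, tx)
    purrr::imap_dfr(k, function(markers, chrom) {
      tibble(marker_id = markers, taxon = tx,
             chromosome = paste0(tx, ":", chrom),
             position = seq_along(markers))
    })
  })
}

#' Draw a random identifiable rearrangement scenario
#'
#' Samples a random fission/fusion history on the `((A,B),O)` tree for
#' recovery experiments: per ingroup branch, a uniform number of events
#' (0..`max_events`), each a fission at a random marker boundary (with
#' probability `p_fission`) or a fusion of two random chromosomes.
#'
#' With `identifiable = TRUE` (the default) scenarios are rejection-sampled
#' so that the history leaves a recoverable trace: (i) no branch's event
#' list is reducible (its event count must equal the minimal fission+fusion
#' distance between the root and leaf partitions — redundant events such as
#' a fission later undone by a fusion are invisible to any method), and
#' (ii) no two root chromosomes become associated on a single chromosome in
#' both ingroup taxa while staying separate in the outgroup (such convergent
#' associations are attributed to the ancestor by parsimony, which is the
#' maximally parsimonious but historically wrong reading; they are
#' fundamentally unpolarizable from co-occurrence data).
#'
#' @param seed Integer seed.
#' @param n_chroms Root chromosome count.
#' @param markers_per_chrom Markers per root chromosome.
#' @param max_events Maximum events per ingroup branch.
#' @param p_fission Probability that an event is a fission.
#' @param identifiable Reject unidentifiable scenarios (see above).
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return A [rearrangement_scenario()] with the drawn events.
#' @export
random_rearrangement_scenario <- function(seed, n_chroms = 10,
                                          markers_per_chrom = 10,
                                          max_events = 6, p_fission = 0.4,
                                          identifiable = TRUE,
                                          max_tries = 100) {
  draw <- function() {
    evs <- list()
    for (br in c("A", "B")) {
      k <- as.list(rep(markers_per_chrom, n_chroms))
      names(k) <- paste0("anc_", seq_len(n_chroms))
      n_ev <- sample(0:max_events, 1)
      for (e in seq_len(n_ev)) {
        if (runif(1) < p_fission && any(unlist(k) >= 2)) {
          ch <- sample(names(k)[unlist(k) >= 2], 1)
          s <- sample(k[[ch]] - 1, 1)
          evs[[length(evs) + 1L]] <- tibble(branch = br, type = "fission",
                                            chrom1 = ch, chrom2 = NA,
                                            split_at = s)
          k[[paste0(ch, ".1")]] <- s
          k[[paste0(ch, ".2")]] <- k[[ch]] - s
          k[[ch]] <- NULL
        } else if (length(k) >= 2) {
          pr <- sample(names(k), 2)
          evs[[length(evs) + 1L]] <- tibble(branch = br, type = "fusion",
                                            chrom1 = pr[1], chrom2 = pr[2],
                                            split_at = NA)
          k[[paste0(pr[1], "+", pr[2])]] <- k[[pr[1]]] + k[[pr[2]]]
          k[[pr[1]]] <- NULL
          k[[pr[2]]] <- NULL
        }
      }
    }
    rearrangement_scenario(
      n_chroms,
      if (length(evs)) bind_rows(evs) else NULL,
      markers_per_chrom
    )
  }
  local_seed(seed, {
    for (try in seq_len(max_tries)) {
      sc <- draw()
      if (!identifiable || scenario_identifiable(sc)) return(sc)
    }
    abort("no identifiable scenario found; relax the event settings")
  })
}

# identifiability of a scenario from co-occurrence data (see
# random_rearrangement_scenario): branch-wise minimal event lists and no
# convergent root-chromosome associations shared by both ingroup taxa
scenario_identifiable <- function(scenario) {
  mk <- simulate_rearrangement_history(scenario)
  part <- function(tx) {
    m <- mk[mk$taxon == tx, ]
    unname(lapply(split(m$marker_id, m$chromosome), sort))
  }
  pa <- part("A")
  pb <- part("B")
  po <- part("O")
  for (br in c("A", "B")) {
    n_ev <- sum(scenario$events$branch == br)
    d <- partition_distance(po, if (br == "A") pa else pb)
    if (d != n_ev) return(FALSE)
  }
  root_of <- function(marker) sub("^m([0-9]+)_.*$", "\\1", marker)
  assoc <- function(P) {
    prs <- character()
    for (g in P) {
      r <- unique(root_of(g))
      if (length(r) >= 2) {
        cmb <- utils::combn(sort(r), 2)
        prs <- c(prs, paste(cmb[1, ], cmb[2, ]))
      }
    }
    unique(prs)
  }
  conv <- intersect(assoc(pa), assoc(pb))
  length(setdiff(conv, assoc(po))) == 0
}

#' Write / read a marker table as 3-column TSV
#'
#' @param markers A marker table (`marker_id`, `taxon`, `chromosome`).
#' @param path File path.
#' @return `write_marker_table()` returns `path` invisibly;
#'   `read_marker_table()` returns a tibble.
#' @export
write_marker_table <- function(markers, path) {
  readr::write_tsv(markers[, c("marker_id", "taxon", "chromosome")], path)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), taxon = readr::col_character(),
    chromosome = readr::col_character()
  ))
}
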