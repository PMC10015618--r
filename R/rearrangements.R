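#' Read a PAF whole-genome alignment
#'
#' Parses the 12 mandatory PAF columns (optional tags are ignored).
#' Malformed lines are skipped with a line-number diagnostic.
#'
#' @param path Path to a PAF file.
#' @return A tibble with `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`
#'   (coordinates 0-based half-open).
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 12
  num <- function(i) suppressWarnings(as.numeric(vapply(fields[ok], `[`, "", i)))
  out <- tibble(
    qname = vapply(fields[ok], `[`, "", 1), qlen = num(2),
    qstart = num(3), qend = num(4),
    strand = vapply(fields[ok], `[`, "", 5),
    tname = vapply(fields[ok], `[`, "", 6), tlen = num(7),
    tstart = num(8), tend = num(9),
    nmatch = num(10), alen = num(11), mapq = num(12)
  )
  bad_num <- is.na(out$qstart) | is.na(out$qend) | is.na(out$alen) |
    is.na(out$mapq)
  if (any(!ok) || any(bad_num)) {
    warn(sprintf("skipped malformed PAF line(s): %s",
                 paste(c(which(!ok), which(ok)[bad_num]), collapse = ", ")))
  }
  out[!bad_num, ]
}

#' Filter whole-genome alignments for synteny analysis
#'
#' Retains alignments strictly longer than `min_length` bases with mapping
#' quality at least `min_mapq`.
#'
#' @param paf A [read_paf()] tibble.
#' @param min_length Minimum alignment block length, exclusive (an alignment
#'   of exactly `min_length` is dropped).
#' @param min_mapq Minimum mapping quality, inclusive.
#' @return The filtered alignment tibble.
#' @export
filter_alignments <- function(paf, min_length = 50000, min_mapq = 60) {
  filter(as_tibble(paf), .data$alen > min_length, .data$mapq >= min_mapq)
}

#' Detect rearrangement points from filtered alignments
#'
#' Rearrangement points are (i) internal junctions: positions on a
#' chromosome where the alignments on either side connect to different
#' chromosomes of the other genome (placed at the midpoint of the
#' inter-alignment gap), and (ii) chromosome ends implicated in a fission or
#' fusion: ends of chromosomes that share an aligned partner chromosome with
#' another chromosome of the same genome (the end nearer the alignments to
#' the shared partner). Points are reported for both genomes; reciprocal
#' duplicates are removed.
#'
#' @param alignments A [filter_alignments()] tibble.
#' @param query_lengths,target_lengths Named vectors of chromosome lengths;
#'   defaults are taken from the PAF `qlen`/`tlen` columns.
#' @return A tibble with `genome` (`"query"`/`"target"`), `chromosome`,
#'   `position` and `kind` (`"internal_junction"`/`"chromosome_end"`).
#' @export
detect_rearrangement_points <- function(alignments, query_lengths = NULL,
                                        target_lengths = NULL) {
  al <- as_tibble(alignments)
  if (is.null(query_lengths)) {
    query_lengths <- setNames(al$qlen, al$qname)[!duplicated(al$qname)]
  }
  if (is.null(target_lengths)) {
    target_lengths <- setNames(al$tlen, al$tname)[!duplicated(al$tname)]
  }

  one_side <- function(a, lengths) {
    # a has columns chrom,start,end,partner,alen
    pts <- list()
    for (ch in unique(a$chrom)) {
      x <- arrange(a[a$chrom == ch, ], .data$start)
      if (nrow(x) >= 2) {
        brk <- which(x$partner[-nrow(x)] != x$partner[-1])
        for (i in brk) {
          pts[[length(pts) + 1L]] <- tibble(
            chromosome = ch,
            position = floor((x$end[i] + x$start[i + 1]) / 2),
            kind = "internal_junction"
          )
        }
      }
    }
    # chromosome ends: chromosomes sharing a partner with another chromosome
    pairs <- distinct(a, .data$chrom, .data$partner)
    shared <- pairs |>
      group_by(.data$partner) |>
      filter(n() > 1) |>
      ungroup()
    for (i in seq_len(nrow(shared))) {
      ch <- shared$chrom[i]
      x <- a[a$chrom == ch & a$partner == shared$partner[i], ]
      mid <- sum((x$start + x$end) / 2 * x$alen) / sum(x$alen)
      len <- unname(lengths[ch])
      pos <- if (!is.na(len) && mid > len / 2) len else 0
      pts[[length(pts) + 1L]] <- tibble(
        chromosome = ch, position = pos, kind = "chromosome_end"
      )
    }
    bind_rows(pts)
  }

  q <- one_side(tibble(chrom = al$qname, start = al$qstart, end = al$qend,
                       partner = al$tname, alen = al$alen), query_lengths)
  t <- one_side(tibble(chrom = al$tname, start = al$tstart, end = al$tend,
                       partner = al$qname, alen = al$alen), target_lengths)
  no_aln_q <- setdiff(names(query_lengths), al$qname)
  if (length(no_aln_q)) {
    inform(sprintf("query chromosome(s) without alignments: %s",
                   paste(no_aln_q, collapse = ", ")))
  }
  out <- bind_rows(
    if (nrow(q)) mutate(q, genome = "query"),
    if (nrow(t)) mutate(t, genome = "target")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(genome = character(), chromosome = character(),
                  position = numeric(), kind = character()))
  }
  distinct(select(out, "genome", "chromosome", "position", "kind"))
}

## ---- parsimony polarization ------------------------------------------------

# minimal fission+fusion count between two partitions of the same elements:
# per connected component of the group-intersection graph with p groups of P
# and q groups of Q the minimum is (p - 1) + (q - 1)
partition_distance <- function(P, Q) {
  p <- length(P)
  q <- length(Q)
  if (p == 0 && q == 0) return(0)
  parent <- seq_len(p + q)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      if (length(intersect(P[[i]], Q[[j]]))) {
        ri <- find(i)
        rj <- find(p + j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(p + q), find, integer(1))
  comp <- unique(roots)
  sum(vapply(comp, function(r) {
    np <- sum(roots[seq_len(p)] == r)
    nq <- sum(roots[p + seq_len(q)] == r)
    max(np - 1, 0) + max(nq - 1, 0)
  }, numeric(1)))
}

# all set partitions of 1..n as assignment vectors (restricted growth strings)
all_set_partitions <- function(n) {
  res <- list()
  rec <- function(assign, maxg) {
    k <- length(assign)
    if (k == n) {
      res[[length(res) + 1L]] <<- assign
      return(invisible())
    }
    for (g in seq_len(maxg + 1L)) rec(c(assign, g), max(maxg, g))
  }
  rec(integer(0), 0L)
  res
}

assignment_to_partition <- function(assign, atoms) {
  unname(lapply(split(atoms, assign), sort))
}

partition_key <- function(P) {
  paste(sort(vapply(P, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = ";")
}

# groups of `part` restricted to `atoms`
restrict_partition <- function(part, atoms) {
  out <- lapply(part, function(g) sort(intersect(g, atoms)))
  out[lengths(out) > 0]
}

#' Polarize fission/fusion rearrangements by parsimony
#'
#' Given marker tables for the ingroup taxa A and B and an outgroup O on the
#' tree `((A,B),O)`, collapses markers into maximal sets that co-occur on one
#' chromosome in every taxon, infers the partition of these marker sets on
#' the chromosomes of the (A, B) ancestor that minimizes the total number of
#' fissions and fusions on the A- and B-branches (ties broken in favour of
#' ancestral groupings present in the outgroup), and emits per-branch event
#' lists whose replay reproduces each leaf partition exactly (checked on
#' every run).
#'
#' The optimum decomposes over connected components of the marker-set
#' co-occurrence graph; components with up to `exact_limit` marker sets are
#' searched exhaustively, larger ones by outgroup-seeded merge/split
#' hill-climbing.
#'
#' @param markers A marker table (`marker_id`, `taxon`, `chromosome`), e.g.
#'   from [simulate_rearrangement_history()] or [read_marker_table()]. Only
#'   markers present in all three taxa are used.
#' @param tree The 3-taxon tree: an `ape` `phylo` or a newick string such as
#'   `"((A,B),O);"`. The two cherry tips are the ingroup.
#' @param exact_limit Largest component searched exhaustively.
#' @return An `event_set`: list with `ancestor` (tibble `group`, `marker_sets`
#'   list-column of atom ids), `events` (tibble `branch`, `type`, `operands`),
#'   `counts` (tibble `branch`, `fissions`, `fusions`),
#'   `n_ancestral_chromosomes`, and `atoms` (the marker-set table).
#' @export
polarize_parsimony <- function(markers, tree = "((A,B),O);",
                               exact_limit = 8) {
  markers <- as_tibble(markers)
  taxa <- parse_three_taxon_tree(tree)
  have <- markers |>
    filter(.data$taxon %in% unlist(taxa)) |>
    count(.data$marker_id) |>
    filter(n == 3) |>
    pull(.data$marker_id)
  if (length(have) == 0) abort("no markers shared by all three taxa")
  mk <- markers |>
    filter(.data$marker_id %in% have) |>
    select("marker_id", "taxon", "chromosome") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "chromosome")
  a_col <- taxa$ingroup[1]
  b_col <- taxa$ingroup[2]
  o_col <- taxa$outgroup

  atoms <- mk |>
    group_by(chrom_a = .data[[a_col]], chrom_b = .data[[b_col]],
             chrom_o = .data[[o_col]]) |>
    summarise(markers = list(.data$marker_id), .groups = "drop") |>
    mutate(atom = row_number(), n_markers = lengths(.data$markers))

  part_of <- function(col) {
    unname(lapply(split(atoms$atom, atoms[[col]]), sort))
  }
  PA <- part_of("chrom_a")
  PB <- part_of("chrom_b")
  PO <- part_of("chrom_o")

  # connected components of atom co-occurrence (any taxon)
  parent <- atoms$atom
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (P in list(PA, PB, PO)) {
    for (g in P) {
      for (i in seq_along(g)[-1]) {
        ri <- find(g[1])
        rj <- find(g[i])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp_id <- vapply(atoms$atom, find, integer(1))

  ancestor <- list()
  for (cid in unique(comp_id)) {
    comp_atoms <- atoms$atom[comp_id == cid]
    pa <- restrict_partition(PA, comp_atoms)
    pb <- restrict_partition(PB, comp_atoms)
    po <- restrict_partition(PO, comp_atoms)
    best <- search_component(comp_atoms, pa, pb, po, exact_limit)
    ancestor <- c(ancestor, best)
  }

  events <- list()
  counts <- list()
  for (br in c("A", "B")) {
    leaf <- if (br == "A") PA else PB
    ev <- events_between(ancestor, leaf, br)
    # hard postcondition: replay must reproduce the leaf partition
    replayed <- replay_events(ancestor, ev)
    if (!identical(partition_key(replayed), partition_key(leaf))) {
      abort(sprintf("internal error: event replay on branch %s does not reproduce the leaf partition", br))
    }
    events[[br]] <- ev
    counts[[br]] <- tibble(branch = br,
                           fissions = sum(ev$type == "fission"),
                           fusions = sum(ev$type == "fusion"))
  }

  structure(list(
    ancestor = tibble(
      group = seq_along(ancestor),
      marker_sets = ancestor,
      n_markers = vapply(ancestor, function(g) {
        sum(atoms$n_markers[match(g, atoms$atom)])
      }, numeric(1))
    ),
    events = bind_rows(events),
    counts = bind_rows(counts),
    n_ancestral_chromosomes = length(ancestor),
    atoms = atoms,
    taxa = taxa
  ), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> ancestor with %d chromosomes (%d marker sets)\n",
              x$n_ancestral_chromosomes, nrow(x$atoms)))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  branch %s: %d fission(s), %d fusion(s)\n",
                x$counts$branch[i], x$counts$fissions[i],
                x$counts$fusions[i]))
  }
  invisible(x)
}

parse_three_taxon_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo") || length(tree$tip.label) != 3) {
    abort("`tree` must be a rooted 3-taxon tree such as \"((A,B),O);\"")
  }
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tip_kids <- kids[kids <= 3]
  if (length(tip_kids) != 1) {
    abort("`tree` must have a single outgroup sister to the ingroup cherry")
  }
  outgroup <- tree$tip.label[tip_kids]
  ingroup <- setdiff(tree$tip.label, outgroup)
  list(ingroup = sort(ingroup), outgroup = outgroup)
}

# search one component for the ancestral partition minimizing
# d(anc, A) + d(anc, B), ties toward groupings present in the outgroup
search_component <- function(comp_atoms, pa, pb, po, exact_limit) {
  score <- function(anc) {
    d <- partition_distance(anc, pa) + partition_distance(anc, pb)
    ko <- vapply(po, function(g) paste(g, collapse = ","), character(1))
    not_in_o <- sum(!vapply(anc, function(g) {
      paste(g, collapse = ",") %in% ko
    }, logical(1)))
    c(d, not_in_o)
  }
  better <- function(s1, k1, s2, k2) {
    if (s1[1] != s2[1]) return(s1[1] < s2[1])
    if (s1[2] != s2[2]) return(s1[2] < s2[2])
    k1 < k2
  }
  n <- length(comp_atoms)
  if (n == 1) return(list(comp_atoms))

  if (n <= exact_limit) {
    best <- NULL
    best_s <- NULL
    best_k <- NULL
    for (assign in all_set_partitions(n)) {
      cand <- assignment_to_partition(assign, comp_atoms)
      s <- score(cand)
      k <- partition_key(cand)
      if (is.null(best) || better(s, k, best_s, best_k)) {
        best <- cand
        best_s <- s
        best_k <- k
      }
    }
    return(best)
  }

  # hill-climbing from the outgroup partition
  cur <- po
  cur_s <- score(cur)
  cur_k <- partition_key(cur)
  leaf_groups <- c(pa, pb, po)
  repeat {
    improved <- FALSE
    cand_list <- list()
    ng <- length(cur)
    if (ng >= 2) {
      for (i in seq_len(ng - 1)) {
        for (j in (i + 1):ng) {
          cand_list[[length(cand_list) + 1L]] <-
            c(cur[-c(i, j)], list(sort(c(cur[[i]], cur[[j]]))))
        }
      }
    }
    for (i in seq_len(ng)) {
      g <- cur[[i]]
      if (length(g) < 2) next
      for (lg in leaf_groups) {
        left <- intersect(g, lg)
        if (length(left) == 0 || length(left) == length(g)) next
        cand_list[[length(cand_list) + 1L]] <-
          c(cur[-i], list(sort(left), sort(setdiff(g, left))))
      }
    }
    for (cand in cand_list) {
      s <- score(cand)
      k <- partition_key(cand)
      if (better(s, k, cur_s, cur_k)) {
        cur <- cand
        cur_s <- s
        cur_k <- k
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  cur
}

# minimal event list (merge-then-split per bipartite component) turning
# partition `from` into partition `to`
events_between <- function(from, to, branch) {
  p <- length(from)
  q <- length(to)
  parent <- seq_len(p + q)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      if (length(intersect(from[[i]], to[[j]]))) {
        ri <- find(i)
        rj <- find(p + j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(p + q), find, integer(1))
  ev <- list()
  lab <- function(g) paste(g, collapse = "+")
  for (r in unique(roots)) {
    gi <- which(roots[seq_len(p)] == r)
    hj <- which(roots[p + seq_len(q)] == r)
    cur <- from[gi]
    # fusions: merge the ancestral groups of the component into one
    while (length(cur) > 1) {
      ev[[length(ev) + 1L]] <- tibble(
        branch = branch, type = "fusion",
        operands = paste(lab(cur[[1]]), lab(cur[[2]]), sep = " | "),
        detail = list(list(op1 = cur[[1]], op2 = cur[[2]]))
      )
      cur <- c(list(sort(c(cur[[1]], cur[[2]]))), cur[-(1:2)])
    }
    # fissions: split off the target groups one by one
    targets <- to[hj]
    whole <- cur[[1]]
    while (length(targets) > 1) {
      part <- targets[[1]]
      rest <- sort(setdiff(whole, part))
      ev[[length(ev) + 1L]] <- tibble(
        branch = branch, type = "fission",
        operands = paste(lab(whole), "->", lab(part), "/", lab(rest)),
        detail = list(list(op1 = whole, part = part))
      )
      whole <- rest
      targets <- targets[-1]
    }
  }
  if (length(ev) == 0) {
    return(tibble(branch = character(), type = character(),
                  operands = character(), detail = list()))
  }
  bind_rows(ev)
}

replay_events <- function(part, events) {
  keyify <- function(g) paste(sort(g), collapse = ",")
  for (i in seq_len(nrow(events))) {
    d <- events$detail[[i]]
    keys <- vapply(part, keyify, character(1))
    if (events$type[i] == "fusion") {
      i1 <- match(keyify(d$op1), keys)
      i2 <- match(keyify(d$op2), keys)
      if (is.na(i1) || is.na(i2)) abort("replay: fusion operand missing")
      merged <- sort(c(part[[i1]], part[[i2]]))
      part <- c(part[-c(i1, i2)], list(merged))
    } else {
      i1 <- match(keyify(d$op1), keys)
      if (is.na(i1)) abort("replay: fission operand missing")
      part <- c(part[-i1], list(sort(d$part)),
                list(sort(setdiff(d$op1, d$part))))
    }
  }
  part
}

#' Annotate windows with distance to the nearest rearrangement point
#'
#' The distance is the minimum gap between the window span and any point on
#' the same chromosome (0 if the point falls inside the window). Windows
#' closer than `radius` are labelled near; windows on chromosomes without
#' any rearrangement point get `NA` (not applicable).
#'
#' @param windows A window table with `chrom`, `start`, `end`.
#' @param points A [detect_rearrangement_points()] tibble (or any table with
#'   `chromosome` and `position`).
#' @param radius Near/far threshold in bases (near iff distance < radius).
#' @return `windows` with `distance_to_point` and logical `near_point`.
#' @export
annotate_window_distance <- function(windows, points, radius = 1e6) {
  windows <- as_tibble(windows)
  points <- as_tibble(points)
  windows$distance_to_point <- vapply(seq_len(nrow(windows)), function(i) {
    p <- points$position[points$chromosome == windows$chrom[i]]
    if (length(p) == 0) return(NA_real_)
    min(pmax(0, pmax(windows$start[i] - p, p - (windows$end[i] - 1))))
  }, numeric(1))
  windows$near_point <- windows$distance_to_point < radius
  windows
}
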