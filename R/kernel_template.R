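# Enumeration of the genealogical state space for the likelihood kernel.
#
# A block carries 2 + 2 sampled haplotypes (one diploid per species). Each
# ancestral lineage is summarised by how many A- and B-haplotypes it subtends;
# a mutation on a lineage produces one of the four unphased, unpolarised
# mutation types. Classes (na, nb):
#   (1,0) hetA   (0,1) hetB   (1,1) hetAB
#   (2,0) fixed  (0,2) fixed  (2,1) hetB   (1,2) hetA
# (2,2) is the MRCA: mutations above it are unobservable and end the process.
#
# Epoch 1 (present -> split): lineages live in demes A/B; coalescence within
# demes and unidirectional migration. Epoch 2 (beyond the split): one deme.
# The enumeration is model-independent; per-call rates are attached to the
# edge kinds:
#   1 coalescence in deme A   2 coalescence in deme B
#   3 migration A -> B        4 migration B -> A     5 coalescence (ancestral)

CLASS_NA <- c(1L, 0L, 1L, 2L, 0L, 2L, 1L)
CLASS_NB <- c(0L, 1L, 1L, 0L, 2L, 1L, 2L)
CLASS_TYPE <- c(1L, 2L, 3L, 4L, 4L, 2L, 1L)  # hetA, hetB, hetAB, fixed

kernel_template <- function() {
  if (!is.null(the$kernel_template)) {
    return(the$kernel_template)
  }

  merge_class <- function(i, j) {
    na <- CLASS_NA[i] + CLASS_NA[j]
    nb <- CLASS_NB[i] + CLASS_NB[j]
    if (na == 2L && nb == 2L) return(0L)  # MRCA
    which(CLASS_NA == na & CLASS_NB == nb)
  }

  ## ---- epoch 1: counts over (class, deme) --------------------------------
  cfg_key <- function(m) paste(m, collapse = ",")
  configs <- list()
  keys <- character()
  register <- function(m) {
    k <- cfg_key(m)
    hit <- match(k, keys)
    if (!is.na(hit)) return(hit)
    configs[[length(configs) + 1L]] <<- m
    keys[length(keys) + 1L] <<- k
    length(configs)
  }

  init <- matrix(0L, 7L, 2L)
  init[1L, 1L] <- 2L  # two A-haplotype singletons in deme A
  init[2L, 2L] <- 2L  # two B-haplotype singletons in deme B
  done <- matrix(0L, 7L, 2L)

  init_id <- register(init)
  done_id <- register(done)

  e_from <- integer()
  e_to <- integer()
  e_kind <- integer()
  e_mult <- numeric()

  queue <- init_id
  seen <- init_id
  while (length(queue)) {
    ci <- queue[[1L]]
    queue <- queue[-1L]
    m <- configs[[ci]]
    if (sum(m) <= 1L) next
    for (d in 1:2) {
      present <- which(m[, d] > 0L)
      for (ii in seq_along(present)) {
        for (jj in ii:length(present)) {
          i <- present[ii]
          j <- present[jj]
          if (i == j) {
            if (m[i, d] < 2L) next
            mult <- m[i, d] * (m[i, d] - 1) / 2
          } else {
            mult <- m[i, d] * m[j, d]
          }
          nm <- m
          nm[i, d] <- nm[i, d] - 1L
          nm[j, d] <- nm[j, d] - 1L
          mc <- merge_class(i, j)
          if (mc > 0L) nm[mc, d] <- nm[mc, d] + 1L
          ti <- register(nm)
          e_from <- c(e_from, ci); e_to <- c(e_to, ti)
          e_kind <- c(e_kind, d); e_mult <- c(e_mult, mult)
          if (!(ti %in% seen)) { seen <- c(seen, ti); queue <- c(queue, ti) }
        }
      }
    }
    for (d in 1:2) {
      present <- which(m[, d] > 0L)
      for (i in present) {
        nm <- m
        nm[i, d] <- nm[i, d] - 1L
        nm[i, 3L - d] <- nm[i, 3L - d] + 1L
        ti <- register(nm)
        e_from <- c(e_from, ci); e_to <- c(e_to, ti)
        e_kind <- c(e_kind, 2L + d); e_mult <- c(e_mult, m[i, d])
        if (!(ti %in% seen)) { seen <- c(seen, ti); queue <- c(queue, ti) }
      }
    }
  }

  n1 <- length(configs)
  mut1 <- matrix(0L, n1, 4L)
  for (c in seq_len(n1)) {
    lin <- rowSums(configs[[c]])
    for (t in 1:4) mut1[c, t] <- sum(lin[CLASS_TYPE == t])
  }

  ## ---- epoch 2: counts over class only -----------------------------------
  configs2 <- list()
  keys2 <- character()
  register2 <- function(v) {
    k <- paste(v, collapse = ",")
    hit <- match(k, keys2)
    if (!is.na(hit)) return(hit)
    configs2[[length(configs2) + 1L]] <<- v
    keys2[length(keys2) + 1L] <<- k
    length(configs2)
  }

  # seed with every deme-collapsed epoch-1 configuration
  for (c in seq_len(n1)) register2(rowSums(configs[[c]]))
  f_from <- integer(); f_to <- integer(); f_mult <- numeric()
  qi <- 1L
  while (qi <= length(configs2)) {
    v <- configs2[[qi]]
    ci <- qi
    qi <- qi + 1L
    if (sum(v) <= 1L) next
    present <- which(v > 0L)
    for (ii in seq_along(present)) {
      for (jj in ii:length(present)) {
        i <- present[ii]
        j <- present[jj]
        if (i == j) {
          if (v[i] < 2L) next
          mult <- v[i] * (v[i] - 1) / 2
        } else {
          mult <- v[i] * v[j]
        }
        nv <- v
        nv[i] <- nv[i] - 1L
        nv[j] <- nv[j] - 1L
        mc <- merge_class(i, j)
        if (mc > 0L) nv[mc] <- nv[mc] + 1L
        ti <- register2(nv)
        f_from <- c(f_from, ci); f_to <- c(f_to, ti); f_mult <- c(f_mult, mult)
      }
    }
  }

  # topological order: decreasing lineage count (coalescence only moves down)
  n2 <- length(configs2)
  ord <- order(-vapply(configs2, sum, numeric(1)))
  rank2 <- integer(n2)
  rank2[ord] <- seq_len(n2)
  configs2 <- configs2[ord]
  f_from <- rank2[f_from]
  f_to <- rank2[f_to]
  mut2 <- matrix(0L, n2, 4L)
  for (c in seq_len(n2)) {
    for (t in 1:4) mut2[c, t] <- sum(configs2[[c]][CLASS_TYPE == t])
  }
  abs2 <- which(vapply(configs2, sum, numeric(1)) == 0)

  map12 <- integer(n1)
  for (c in seq_len(n1)) {
    k <- paste(rowSums(configs[[c]]), collapse = ",")
    map12[c] <- which(vapply(configs2, function(v) {
      paste(v, collapse = ",") == k
    }, logical(1)))
  }

  the$kernel_template <- list(
    n1 = n1, init1 = init_id,
    e1_from = e_from, e1_to = e_to, e1_kind = e_kind, e1_mult = e_mult,
    mut1 = mut1, map12 = map12,
    n2 = n2, e2_from = f_from, e2_to = f_to, e2_mult = f_mult,
    mut2 = mut2, abs2 = abs2
  )
  the$kernel_template
}
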