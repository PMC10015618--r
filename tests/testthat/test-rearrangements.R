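make_paf_line <- function(qname, qlen, qs, qe, tname, tlen, ts, te,
                          alen = qe - qs, mapq = 60) {
  paste(qname, qlen, qs, qe, "+", tname, tlen, ts, te, alen, alen, mapq,
        sep = "\t")
}

test_that("PAF parsing skips malformed lines and filtering applies strict thresholds", {
  path <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    make_paf_line("q1", 2e5, 0, 60000, "t1", 2e5, 0, 60000),
    make_paf_line("q1", 2e5, 60000, 120000, "t1", 2e5, 60000, 120000,
                  alen = 50000),                      # exactly 50 kb -> out
    make_paf_line("q2", 2e5, 0, 80000, "t2", 2e5, 0, 80000, mapq = 59),
    "garbage line without fields",
    make_paf_line("q2", 2e5, 80000, 200000, "t2", 2e5, 80000, 200000)
  ), path)
  expect_warning(paf <- read_paf(path), "malformed")
  expect_equal(nrow(paf), 4)
  kept <- filter_alignments(paf)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$alen > 50000 & kept$mapq >= 60))
})

test_that("rearrangement points appear at junctions and implicated ends only", {
  # q1 maps left half to t1, right half to t2 -> one internal junction;
  # t1/t2 each share no partner with other targets, but q-side fusion means
  # t1 and t2 both pair only with q1 (no shared partners on target side)
  al <- tibble::tibble(
    qname = "q1", qlen = 2e5, qstart = c(0, 1.2e5), qend = c(0.8e5, 2e5),
    strand = "+", tname = c("t1", "t2"), tlen = 1e5,
    tstart = 0, tend = 1e5, nmatch = 8e4, alen = c(8e4, 8e4), mapq = 60
  )
  pts <- detect_rearrangement_points(al)
  junc <- pts[pts$kind == "internal_junction", ]
  expect_equal(nrow(junc), 1)
  expect_equal(junc$chromosome, "q1")
  expect_equal(junc$position, 1e5)

  # one-to-one pair: no points at all
  one <- tibble::tibble(
    qname = "q1", qlen = 1e5, qstart = 0, qend = 1e5, strand = "+",
    tname = "t1", tlen = 1e5, tstart = 0, tend = 1e5, nmatch = 9e4,
    alen = 1e5, mapq = 60
  )
  expect_equal(nrow(detect_rearrangement_points(one)), 0)

  # fission seen from the target side: t1 split across q1/q2 implicates
  # chromosome ends of q1 and q2
  fis <- tibble::tibble(
    qname = c("q1", "q2"), qlen = 1e5, qstart = c(2e4, 0), qend = c(1e5, 8e4),
    strand = "+", tname = "t1", tlen = 2e5, tstart = c(0, 1e5),
    tend = c(8e4, 1.8e5), nmatch = 7e4, alen = 8e4, mapq = 60
  )
  pts2 <- detect_rearrangement_points(fis,
                                      query_lengths = c(q1 = 1e5, q2 = 1e5),
                                      target_lengths = c(t1 = 2e5))
  ends_q <- pts2[pts2$genome == "query" & pts2$kind == "chromosome_end", ]
  expect_setequal(ends_q$chromosome, c("q1", "q2"))
})

test_that("planted junctions are detected within gap resolution", {
  # synthetic genome pair: query chromosome assembled from three target
  # pieces with known junctions at 1e5 and 1.7e5
  local_seed(12, {
    al <- tibble::tibble(
      qname = "q1", qlen = 3e5,
      qstart = c(0, 1.02e5, 1.72e5), qend = c(0.98e5, 1.68e5, 3e5),
      strand = "+", tname = c("t1", "t2", "t3"), tlen = 1e5,
      tstart = 0, tend = 9e4, nmatch = 6e4,
      alen = c(9.8e4, 6.6e4, 1.28e5), mapq = 60
    )
    pts <- detect_rearrangement_points(al)
    junc <- sort(pts$position[pts$kind == "internal_junction" &
                                pts$genome == "query"])
    expect_equal(length(junc), 2)
    expect_lt(abs(junc[1] - 1e5), 2e3 + 1)
    expect_lt(abs(junc[2] - 1.7e5), 2e3 + 1)
  })
})

test_that("parsimony handles the trivial and single-event cases", {
  mk0 <- simulate_rearrangement_history(rearrangement_scenario(5))
  es0 <- polarize_parsimony(mk0)
  expect_equal(nrow(es0$events), 0)
  expect_equal(es0$n_ancestral_chromosomes, 5)

  sc1 <- rearrangement_scenario(5, tibble::tibble(
    branch = "A", type = "fusion", chrom1 = "anc_1", chrom2 = "anc_2",
    split_at = NA
  ))
  es1 <- polarize_parsimony(simulate_rearrangement_history(sc1))
  expect_equal(es1$counts$fusions[es1$counts$branch == "A"], 1)
  expect_equal(sum(es1$counts$fissions), 0)
  expect_equal(sum(es1$counts$fusions[es1$counts$branch == "B"]), 0)
})

test_that("the published 16-chromosome history is recovered exactly", {
  sc <- published_history_scenario()
  mk <- simulate_rearrangement_history(sc)
  # leaf karyotypes: 16 + 2 - 5 = 13 and 16 - 2 = 14
  expect_equal(length(unique(mk$chromosome[mk$taxon == "A"])), 13)
  expect_equal(length(unique(mk$chromosome[mk$taxon == "B"])), 14)
  es <- polarize_parsimony(mk)
  expect_equal(es$n_ancestral_chromosomes, 16)
  cc <- es$counts
  expect_equal(cc$fissions[cc$branch == "A"], 2)
  expect_equal(cc$fusions[cc$branch == "A"], 5)
  expect_equal(cc$fissions[cc$branch == "B"], 0)
  expect_equal(cc$fusions[cc$branch == "B"], 2)
})

test_that("event replay and count parity hold across random scenarios", {
  # replay is asserted inside polarize_parsimony on every run; here we check
  # the chromosome-count parity leaf = root + fissions - fusions explicitly
  for (s in 1:10) {
    sc <- random_rearrangement_scenario(200 + s)
    mk <- simulate_rearrangement_history(sc)
    es <- polarize_parsimony(mk)
    for (br in c("A", "B")) {
      n_leaf <- length(unique(mk$chromosome[mk$taxon == br]))
      cc <- es$counts
      expect_equal(
        n_leaf,
        es$n_ancestral_chromosomes +
          cc$fissions[cc$branch == br] - cc$fusions[cc$branch == br]
      )
    }
  }
})

test_that("windows are annotated with distances to rearrangement points", {
  w <- tibble::tibble(chrom = c("c1", "c1", "c2"),
                      start = c(0, 2.5e6, 0), end = c(1e6, 3.5e6, 1e6))
  pts <- tibble::tibble(chromosome = "c1", position = 5e5,
                        kind = "internal_junction")
  out <- annotate_window_distance(w, pts, radius = 1e6)
  expect_equal(out$distance_to_point, c(0, 2e6, NA))
  expect_identical(out$near_point, c(TRUE, FALSE, NA))

  # brute-force all-pairs oracle on a toy set
  local_seed(44, {
    w2 <- tibble::tibble(chrom = "c", start = (0:49) * 1e5)
    w2$end <- w2$start + 1e5
    pts2 <- tibble::tibble(chromosome = "c",
                           position = sort(sample(0:5e6, 4)),
                           kind = "internal_junction")
    out2 <- annotate_window_distance(w2, pts2, radius = 7e5)
    brute <- vapply(seq_len(50), function(i) {
      min(vapply(pts2$position, function(p) {
        if (p >= w2$start[i] && p < w2$end[i]) 0
        else min(abs(p - w2$start[i]), abs(p - (w2$end[i] - 1)))
      }, numeric(1)))
    }, numeric(1))
    expect_equal(out2$distance_to_point, brute)
  })
})
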