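# shared fixtures: the published maximum-composite-likelihood parameter
# points (Ne in individuals, times in generations, one-year generations)

table1_im_bda <- function(mu = 2.9e-9) {
  demography_params(
    ne_a = 0.171e6, ne_b = 0.880e6, ne_anc = 1.116e6,
    split_time = 2.202e6, me = 1.811e-7, direction = "into_A", mu = mu
  )
}

table1_div <- function(mu = 2.9e-9) {
  demography_params(
    ne_a = 0.252e6, ne_b = 0.683e6, ne_anc = 1.433e6,
    split_time = 1.183e6, mu = mu
  )
}

# the me grid of the windowed scan: 20 evenly spaced values on [0, 6.65e-7]
scan_me_grid <- function() seq(0, 6.65e-7, length.out = 20)

# a small but representative scan grid (keeps kernel evaluations cheap)
small_grid_spec <- function(split_time = 2.202e6) {
  grid_spec(
    ne_a = c(1e5, 2e5, 4e5),
    ne_b = c(4e5, 9e5),
    ne_anc = c(6e5, 1.1e6),
    me = c(0, 8.75e-8, 1.75e-7, 3.5e-7),
    split_time = split_time
  )
}

# scenario encoding the inferred Brenthis rearrangement history: a
# 16-chromosome ancestor, 2 fissions + 5 fusions on the A branch, 2 fusions
# on the B branch, with two small ancestral chromosomes fused independently
# to different partners in either species
published_history_scenario <- function(markers_per_chrom = 10) {
  ev <- tibble::tribble(
    ~branch, ~type, ~chrom1, ~chrom2, ~split_at,
    "A", "fission", "anc_1", NA, 5L,
    "A", "fission", "anc_2", NA, 5L,
    "A", "fusion", "anc_1.1", "anc_3", NA,
    "A", "fusion", "anc_1.2", "anc_4", NA,
    "A", "fusion", "anc_2.1", "anc_5", NA,
    "A", "fusion", "anc_15", "anc_6", NA,
    "A", "fusion", "anc_16", "anc_7", NA,
    "B", "fusion", "anc_15", "anc_8", NA,
    "B", "fusion", "anc_16", "anc_9", NA
  )
  rearrangement_scenario(16, ev, markers_per_chrom)
}

true_event_counts <- function(scenario) {
  ev <- scenario$events
  tibble::tibble(
    branch = c("A", "B"),
    fissions = c(sum(ev$branch == "A" & ev$type == "fission"),
                 sum(ev$branch == "B" & ev$type == "fission")),
    fusions = c(sum(ev$branch == "A" & ev$type == "fusion"),
                sum(ev$branch == "B" & ev$type == "fusion"))
  )
}

# simulated window table for the permutation tests: `n_win` windows on each
# of `n_chrom` chromosomes, gamma-distributed me, optionally scaled down on
# the rearranged chromosomes / near planted points
sim_window_table <- function(seed, n_chrom = 14, n_win = 15,
                             n_rearranged = 6, effect = 1) {
  local_seed(seed, {
    chroms <- sprintf("chr%02d", seq_len(n_chrom))
    rear <- chroms[seq_len(n_rearranged)]
    tibble::tibble(
      chromosome = rep(chroms, each = n_win),
      start = rep(seq_len(n_win) - 1, n_chrom) * 1e5,
      me = stats::rgamma(n_chrom * n_win, shape = 1.2, rate = 1) * 1.8e-7 *
        ifelse(rep(chroms, each = n_win) %in% rear, effect, 1),
      rearranged = rep(chroms, each = n_win) %in% rear
    )
  })
}

local_seed <- meflow:::local_seed
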