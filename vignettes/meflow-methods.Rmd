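---
title: "Methods: blockwise-SFS inference of effective migration and rearrangement barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blockwise-SFS inference of effective migration and rearrangement barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question and the data summary

When two species still exchange genes, the *effective* migration rate
`me` — the per-generation probability that a lineage migrates, net of
selection against introgressed material — varies along the genome: regions
harbouring barriers to gene flow show locally reduced `me`. `meflow`
estimates genome-wide and window-wise `me` from the blockwise site
frequency spectrum (bSFS) of two diploid genomes, one per species, and
intersects the resulting map with chromosome fission/fusion rearrangements
to ask whether rearranged chromosomes are barriers.

The data summary is deliberately small: short blocks of fixed callable
content (64 callable bases by default, allowed to stretch over at most 128
genomic bases to step across non-callable gaps) are tallied by their joint
counts of four unphased, unpolarised mutation types for a sampled pair of
diploids — `hetA`, `hetB`, `hetAB`, `fixed`. Counts above `kmax = 2` per
type are pooled into marginal overflow bins, so a block is one of
`4^4 = 256` outcomes. Unlike the per-site SFS, the bSFS preserves linkage
within blocks, which is what lends it power to separate migration from
ancestral polymorphism.

# The demographic model

Two extant populations A (recipient candidate) and B of diploid effective
sizes `ne_a`, `ne_b` split from an ancestor of size `ne_anc` at time
`split_time` generations before present. Under the IM histories a constant
effective migration rate `me` acts after the split in one direction only,
stated forwards in time: `into_A` means gene flow from B into A. The DIV
(strict divergence) history is the nested `me = 0` case. Mutations follow
an infinite-sites model at rate `mu` per site per generation
(default `2.9e-9`, a butterfly de novo estimate; generation time defaults
to one year so split times in generations read as years).

**Backwards-time convention.** Forwards migration donor -> recipient is
realised backwards in time as recipient-lineage movement into the donor
deme at rate `me` per lineage per generation. With `direction = "into_A"`,
lineages sampled in A jump into the B deme when traced backwards; B
lineages never migrate, which is why within-B diversity follows the plain
two-epoch formula `2 mu (2 Ne_B + e^(-T / (2 Ne_B)) (2 Ne_anc - 2 Ne_B))`
— a closed form the test suite uses as an oracle.

Assumptions worth stating: panmixia within each species (real data show
mild intraspecific structure, which perturbs this only weakly for
long-term interspecific inference), a single constant `me` per window, no
migration in the ancestral epoch, free recombination between blocks and
none within them, and neutrality of the intergenic sequence analysed.

# The likelihood kernel

The probability of each block outcome is computed exactly (no Monte
Carlo). The state of a block's genealogy is the multiset of ancestral
lineages, each labelled by the subset of the 2+2 sampled haplotypes it
subtends and, before the split, by its deme. A mutation on a lineage
produces a type determined by that subset (singleton of A -> `hetA`,
one-from-each pair -> `hetAB`, both-of-A -> `fixed`, triples -> het of the
minority species; mutations above the MRCA are unobservable and excluded).
The chain is augmented with the four count coordinates truncated at
`kmax + 1`, the overflow level, which saturates (further mutations of a
saturated type are no longer events), so the table sums to exactly one
over the 256 bins including overflow.

Numerically, epoch 1 (present to split) is solved by uniformization of the
augmented generator up to the scaled split time; epoch 2 collapses the
demes and, because both coalescence and count increments are monotone,
absorption probabilities at the MRCA follow from a single forward sweep
over the resulting DAG. Internally everything is scaled to coalescent
units of `2 ne_a` generations with `theta/2 = 2 ne_a mu * block_span` per
lineage; the scaling is invisible in the returned probabilities (a test
asserts exact invariance under joint rescaling of sizes, times, `mu` and
`me`). Uniformization details: the rate bound is taken over configurations
reachable under the given migration direction; the Poisson series is
truncated at relative mass `1e-13` and renormalised; intervals with rate x
time above 400 are split. Probabilities below `1e-300` are clamped before
logs. A failed kernel evaluation aborts with the offending parameter
point; it never returns silent `NaN`s.

The kernel's only accuracy authority is the independent Monte-Carlo
simulator: the acceptance suite checks every bin of the exact table
against a `10^6`-genealogy simulation at five parameter points spanning
DIV and both IM directions, within three binomial standard errors plus a
`5/n` floor that covers Poisson discreteness in near-empty bins.

# Composite likelihood, fitting, grids and the bootstrap

Blocks are treated as independent, `lnCL = sum_k n_k log p_k`. Model fits
use bounded multi-start local optimization (`nlminb`, a quasi-Newton
method on function values only) on log10-transformed sizes and split time
and a linear `me` with a hard lower bound at zero so the IM fit can
collapse onto the nested DIV optimum. The first start is a
method-of-moments guess (heterozygosities give the `Ne`s, interspecific
diversity the time scale), the second the centre of the box, further
starts uniform in the box; the spread of per-start optima is reported in
the fit object. Convergence is judged by `nlminb` at relative tolerance
`1e-8`, i.e. well below 0.01 lnCL units at realistic tally sizes.

Window scans avoid per-window optimization: a probability table is
computed once per point of a parameter grid (the canonical scan grid is
15 `ne_a` x 15 `ne_b` x 15 `ne_anc` x 20 `me` values = 67,500 points,
evenly spaced over their published ranges, with the split time fixed to
the genome-wide estimate — linear spacing is our reading of ranges given
as endpoints-plus-counts, and it reproduces both the printed nearest-grid
value `1.75e-7` and the printed mode `3.5e-8`). Each window of 30,000
consecutive blocks (proportionally fewer when fewer diploid pairs enter,
e.g. `round(30000 * 6/42) = 4286` for a male-only Z analysis) gets the
argmax point and a conditional profile of the maximal lnCL at each `me`
value; ties break toward smaller `me`, then smaller `ne_a`, so barrier
calls are conservative. A window is a *barrier window* iff
`lnCL(me = 0) > lnCL(me_bg)` strictly, where `me_bg` is the grid value
nearest the genome-wide estimate; equality is not a barrier. Windows tile
chromosomes disjointly (the non-overlapping reading of "consecutive
blocks"); sliding windows are not implemented.

The parametric bootstrap simulates replicate tallies under the fitted DIV
history, refits DIV and IM to each, and uses the null distribution of
`delta lnCL = lnCL(IM) - lnCL(DIV)` to calibrate the observed improvement
(add-one p-value). Replicates can be simulated with linked blocks (below)
to mirror a realistic recombination setting, `8.5e-9` per base per
generation.

# The simulator

The block simulator is a labelled-lineage Gillespie implementation of the
same two-epoch structured coalescent, written independently of the kernel
(direct simulation in natural units versus matrix analysis in scaled
units), which is what makes it a legitimate oracle. It reports raw,
untruncated type counts plus pairwise difference counts for one haplotype
pair of each kind, so expected heterozygosities and dxy can be read off
directly.

Two linkage modes exist. The default simulates every block as an
independent genealogy — the correct setting for validating the likelihood,
which itself assumes independent blocks. The linked mode (any
`recomb_rate > 0`) approximates the sequential coalescent by a renewal
process: the genealogy persists between adjacent blocks and is refreshed
by an independent draw with probability
`1 - exp(-r * block_span * E[L])`, with `E[L]` the expected total branch
length estimated from a 256-genealogy pilot. Using the expectation rather
than the realized length keeps refreshes independent of the current tree,
so the marginal distribution of every block is exactly the unlinked
coalescent and only the correlation structure is approximate (roughly
exponential decay, no within-block recombination, no gradual topology
change). This is sufficient for the bootstrap, whose statistics depend on
marginals; it does not emulate fine-scale linkage disequilibrium.

The VCF/BED emitter generalises the simulator to arbitrarily many diploids
per species (plain R, event-driven), tiles chromosomes into 64-base
segments with one independent genealogy each, gives every mutation its own
site (biallelic records), masks genotype calls independently at a given
missingness rate, and writes VCF v4.2 (1-based) plus a 0-based half-open
callable BED. A round-trip test asserts that tallies built by the
preprocessing and block modules from the emitted files equal an in-memory
tally of the same simulated haplotypes.

What the generator does not emulate: read-level errors and depth
variation (the depth filters are exercised with hand-built fixtures),
selection and true barrier loci (`me` is the effective summary being
tested downstream), intraspecific structure, and realistic repeat/gene
annotation geometry.

# Preprocessing and block construction

Filtering follows fixed rules with the boundary conventions pinned down
and tested: SNPs within 2 bases of an indel's reference span are removed
(base-pair distance `<= snp_gap`, matching SnpGap-style semantics);
records with `QUAL < 10` are removed (`QUAL = 10` survives); genotype
depths outside `[8, floor(3 * sample mean coverage)]` become missing
(rounding of the upper bound is not stated anywhere authoritative; floor
is our choice); multiallelic SNP sites pass preprocessing; indel records
never enter the SNP set. Filtering is idempotent. Callable masks are kept
per sample; the pairwise intersection happens at block construction.

Blocks are cut per pair by greedy left-anchored packing: collect the next
64 callable bases from the leftmost unused one; emit iff the genomic span
is at most 128, else restart one callable base later. The algorithm is
deterministic and locked by a brute-force oracle test on random masks.
At tallying, a site with a missing genotype or more than two alleles
within the sampled pair is *unusable* and voids its whole block (counted
in a discard log) — the conservative convention, since partially observed
blocks would bias the joint counts; absence of a variant record inside the
callable span is an invariant site.

# Rearrangements and parsimony

Alignments longer than 50 kb (strict) with mapping quality at least 60
define the synteny map. Internal junctions are called between adjacent
alignments of a chromosome that connect to different chromosomes of the
other genome, placed at the midpoint of the inter-alignment gap (the data
define junctions topologically; the midpoint is a convention, so planted
junction tests assert recovery only to gap resolution). Chromosome ends
are implicated when two chromosomes of one genome share an aligned
partner; the end nearer the shared alignments is reported. Translocations
are not forced into fission/fusion calls.

Polarization collapses markers into maximal sets co-occurring on one
chromosome in all three taxa, then finds the partition of these sets at
the (A,B) ancestor minimizing the total fission + fusion count on the two
ingroup branches, breaking ties toward groupings present in the outgroup
and then lexicographically (determinism). The minimal event count between
two partitions decomposes over connected components of their
group-intersection graph as `(p - 1) + (q - 1)`; within a minimal
scenario, the fission/fusion split is forced (`q - 1` fissions, `p - 1`
fusions), which is what makes per-branch counts well defined. The search
likewise decomposes over components of the marker-set co-occurrence
graph: components of up to 8 sets are searched exhaustively over all set
partitions (Bell(8) = 4140), larger ones by outgroup-seeded merge/split
hill-climbing (split moves follow leaf-group boundaries). Every returned
event list is replayed against the leaf partitions as a hard
postcondition.

Identifiability deserves honesty: a parsimony polarizer cannot recover
events that leave no trace (a fission later undone by a fusion) nor
convergent associations (the same two ancestral chromosomes fused
independently on both branches — parsimony will, correctly by its own
criterion, place that fusion in the ancestor). The recovery experiment
therefore draws random scenarios rejection-sampled to be identifiable in
exactly this sense — branch event lists minimal, no shared ingroup
associations absent from the outgroup — and demands 95% exact per-branch
count recovery over 100 seeds; the excluded histories are the documented
identifiability caveat, not a defect of the search. Note that fusing the
same ancestral chromosome to *different* partners in the two species (the
interesting pattern in the motivating system) is identifiable, and the
corresponding fixture is tested exactly.

# Diversity and the permutation framework

Heterozygosity is heterozygous sites over jointly callable sites; pairwise
dxy between two diploids is the mean per-site allele-frequency difference
`pA (1 - pB) + pB (1 - pA)`; species-level dxy averages the interspecific
pairs. FST is Hudson-style `1 - Hw / Hb` with `Hw` the mean individual
heterozygosity averaged over the two species and `Hb` the mean
interspecific dxy — the upstream script that produced the published
values is not recoverable, so the estimator is isolated behind one
function and documented here.

Both permutation tests use the one-tailed add-one estimator
`p = (1 + #{null >= observed}) / (1 + n_used)` (the number of permutations
behind the label test is not published; 10,000 is the default,
configurable). The label-switching test relabels whole chromosomes,
always drawing the published number of rearranged chromosomes (six),
and contrasts mean window `me` (and barrier fraction) between groups. The
adjacent-window test redraws the published number of rearrangement points
(nine) uniformly from the rearranged-chromosome window sequence, samples
the matched number of adjacent windows around each (centred; rolling over
across rearranged chromosomes concatenated in name order and treated
circularly — the roll-over order is open in the source description, so it
is fixed and documented here), discards permutations that sample any
window twice, and contrasts sampled versus remaining windows. The
observed statistic is computed through the same sum expressions as the
null draws so that exact ties (e.g. constant `me`) compare as equalities.
Type-I error of both tests is checked on 500 seeded null datasets, and
planted-effect power checks reach the published significance thresholds
(`p < 0.005` label switching, `p < 0.0005` adjacent windows).

# Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which each check is statistically sharp:
Monte-Carlo oracle, `10^6` genealogies per parameter point; parameter
recovery, 20 replicates of `10^5` blocks fitted with two optimizer starts
(moment start plus box centre — the full five-start default is for real
analyses where the moment start may be poor); model-expectation targets,
`1.5-2 x 10^5` blocks; bootstrap demonstration, replicates of
`2 x 10^4` blocks; permutation type-I, 500 datasets at 399 permutations
(exact discreteness: 20/400 = 0.05); power checks at `10^4` and `10^5`
permutations; parsimony recovery, 100 scenarios on 10 x 10-marker
karyotypes.

# Known limitations

- Two populations, one epoch of migration, constant rates; no secondary
  contact or pulse models, although the bSFS may carry information about
  them.
- Composite likelihood ignores linkage between blocks; lnCL differences
  are calibrated only through the parametric bootstrap, never through
  chi-square asymptotics.
- The linked-blocks simulator approximates the sequential coalescent by a
  marginal-preserving renewal process.
- The windowed scan estimates are grid-discretized; means of window `me`
  inherit the grid resolution (half the `me` spacing, `1.75e-8`, at
  worst).
- Parsimony polarization is blind to convergent identical rearrangements
  and reports translocation-like patterns as unexplained adjacencies.
- `classify_site` and the tally treat more-than-biallelic pairs as
  unusable rather than modelling them.
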