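---
title: "Models and methods behind evopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

evopop re-implements, as a tested and reusable toolkit, the computational
core of whole-population time-series sequencing analysis for long-term
laboratory evolution experiments in budding yeast: calling mutations and
their fixation (including loss of heterozygosity in diploids) from
allele-depth tables, detecting copy-number variants with a windowed-depth
HMM, quantifying parallelism and contingency against simulation-based
nulls, and estimating competitive fitness and mutation rates. Every input
the pipeline consumes can be generated synthetically with planted ground
truth, which is how the package validates itself.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions made where the
underlying procedures left genuine freedom. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The synthetic-data generator

`simulate_wf_population()` runs a discrete-generation Wright–Fisher
simulation structured by *lineages*: every new mutation founds a lineage
that inherits its parent's mutations, so mutations are perfectly linked
within a lineage and rise or crash together in cohorts — the clonal
interference regime these experiments live in. Reproduction is
multinomial with fitness weights; lineage fitness is multiplicative over
mutations. In diploids, mutations arise heterozygous with fitness
$1 + hs$ and convert to homozygosity ($1 + s$) at `loh_rate` per carrier
per generation — an instantaneous whole-lineage het-to-hom conversion,
matching the mitotic-recombination interpretation of loss of
heterozygosity. Recorded allele frequencies weight heterozygotes by 1/2.

Default configuration (all overridable via `sim_config()`):

* `population_size = 1e4`, `generations_total = 1e4`: the scale of the
  experiment's effective population sizes and duration.
* `sequencing_timepoints`: six generations, the first at 70 (the first
  weekly archive at ten generations per day) and the rest evenly spaced
  to the end — a placeholder schedule, fully configurable, since any
  real experiment has its own archive calendar.
* `beneficial_rate = 1e-5` per genome per generation with exponential
  effects of mean `0.03`; `neutral_rate = 4e-3`, the order of the
  per-genome point-mutation rate measured for *S. cerevisiae*. These are
  field-typical values chosen once, not fitted.
* `dominance = 0.5`, `loh_rate = 1e-4` per heterozygous mutation per
  generation.
* Sequencing: depth is Poisson(`coverage_mean`) per variant per
  timepoint (the simplest overdispersion-free depth model, adequate for
  threshold testing) and alternate reads are binomial in the true
  frequency (`sample_allele_counts()`).

Validation runs use scaled-down populations (N = 1000, 600 generations,
elevated `beneficial_rate = 2e-4` and `effect_mean = 0.08` so that sweeps
complete within the shortened run) — stated here as the package's chosen
validation sizes; the statistical structure is unchanged.

What the generator deliberately does **not** emulate: real chromosome
lengths or sequence content, codon structure, alignment and mapping
artifacts (the main source of false variants in real data), overdispersed
coverage, index hopping, or cross-contamination. Passing tests therefore
demonstrate the *logic* of the filters and callers and their behaviour
under sampling noise, not robustness to upstream artifacts.

The generator also produces planted depth tracks (`plant_cnv_track()`,
Gaussian noise with variance proportional to copy-number state, matching
the HMM's emission model), Luria–Delbrück colony counts
(`simulate_luria_delbruck()`), Bernoulli gene-hit matrices
(`simulate_hit_matrix()`), and cytometry competition series
(`simulate_fitness_assay()`).

A note on the Luria–Delbrück simulator: mutation times are uniform on the
log-growth of the culture, so a mutant clone's final size $U$ has survival
function $1/u$ and integer counts have $P(s) = 1/(s(s+1))$ per event. This
is exactly the clone-size law assumed by the Ma–Sandri–Sarkar recursion,
so simulated counts match `msr_pmf()` class by class — a property the test
suite checks by Monte Carlo. A discrete-doubling scheme (clone sizes
restricted to powers of two) was considered and rejected because it
provably disagrees with the recursion at count 2 ($me^{-m}/4$ versus
$me^{-m}/6$ at small $m$).

## Mutation calling

Inputs are long-format allele-count tables: one row per (population,
variant, timepoint) with reference and alternate read counts, as produced
upstream from per-sample VCF allele depths (`read_vcf_allele_depths()`
splits multi-allelic records into biallelic rows).

**Filtering** (`filter_population_variants()`): a variant is kept for a
population iff it has ≥ 5 alternate reads summed over timepoints, and
either (1) that sum exceeds 90% of the alternate reads across *all*
populations and all timepoints (the variant is essentially private, so
not a recurrent pipeline artifact), or (2) at least two timepoints have
≥ 5 alternate reads *and* the sum exceeds 90% of the all-population
alternate total at the first sequenced timepoint only. Criterion 2 compares the focal population's all-timepoint total against
the first-timepoint cross-population total; it is the lenient path that
tolerates nucleotide-level parallelism between populations while still
rejecting artifacts that recur across populations at every timepoint.

**Linkage grouping** (`group_linked_variants()`): variant pairs on the
same chromosome within 25 bp are merged when no timepoint's 2×2 Fisher
exact test on (alt, ref) counts rejects at p < 0.01, and groups are the
transitive closure of merged pairs (an equivalence class, so chains
A–B–C merge when both pair tests pass). Two-sided tests are used — the conservative default, since linkage
makes no directional prediction about which variant's counts run
higher. Member counts are summed per
timepoint before frequencies are computed.

**Calling** (`call_timeline()`): with frequency $f_t$ = alt/(alt+ref)
(0/0 treated as missing, never as zero) and coverage floor 5×:
*present* means $f_t \ge 0.1$ at ≥ 5×; *fixed* means $f_t \ge \theta$ at
≥ 5× and no later ≥ 5× timepoint drops below $\theta$, with
$\theta = 0.9$ for haploids and $0.4$ for diploids (heterozygous
fixation); once fixed, always fixed, regardless of later coverage.
Diploid *loss of heterozygosity* applies the same rule at $\theta = 0.9$,
so LOH implies fixation by construction. Effect annotations collapse to
one type by decreasing putative effect: indel, nonsense, missense,
synonymous, noncoding.

Coordinates: variant positions are 1-based (VCF convention); exclusion
masks are half-open `[start, end)` *in the position's own coordinate
system*, so a call at `pos == end` is retained. `read_bed_mask()`
converts 0-based BED intervals into this convention so that exactly the
BED-covered bases are masked.

dN/dS (`compute_dnds()`) counts missense plus nonsense fixations as
nonsynonymous and scales by the genome-wide opportunity ratio; indels and
noncoding changes do not enter either side, and a zero synonymous count
flags the ratio undefined rather than dividing.

## The CNV depth HMM

Depth is averaged in non-overlapping 500-bp windows; each sample is
divided by its genome-wide median window depth (*relative depth*), then
by the per-window mean relative depth of first-timepoint samples of the
same strain (*standardized depth*), so copy number ancestral to the
experiment maps to 1. Windows below 0.25 first-timepoint relative depth
are masked.

The HMM is deliberately untrained: states {0, 0.5, 1, 1.5, 2, 3, 4},
Gaussian emissions with mean equal to the state and variance equal to the
sample's standardized-depth variance multiplied by the state (0.5 for
state 0, since depth noise does not vanish at zero copies), initial
probabilities 0.94 on state 1 and 0.01 elsewhere, transitions $10^{-4}$
off-diagonal. Decoding is Viterbi — tract detection wants a single
consistent path — run per chromosome, with masked windows skipped so the
path bridges them. Emission log-densities are floored at
$\log(10^{-300})$ and the variance at $10^{-6}$ to keep noiseless or
exact-zero inputs finite. The decoder is validated against an independent
branch-and-bound exhaustive search over all state paths
(`exhaustive_best_path()`) on tracks up to 12 windows.

Per-timepoint non-1 tracts become CNV calls via `merge_and_filter()`:
tracts merge across timepoints when they share a chromosome and state and
overlap by at least one window — the weakest overlap notion consistent
with "the same region"; records with different states are kept separate
so a 2x and a 3x event over the same span stay distinguishable. The merged call's boundaries are the *median* start and
end of the contributing tracts rather than their union: with three or
more timepoints a single timepoint's one-window wobble would otherwise
widen the merged span and spoil boundary accuracy. Calls must appear at
≥ 2 timepoints, span ≥ 4 windows (2 kb), and avoid the telomere mask
(default: the terminal 20 windows, 10 kb, of each chromosome end;
configurable, since what counts as telomeric is assembly-dependent) and the high-copy
tandem-array mask when one is supplied.

## Parallelism

A *hit* is a nonsynonymous mutation fixed by the final timepoint. Gene
multiplicity is $m_i = n_i / (L_i/\bar L)$: hits divided by the gene's
nonsynonymous target size relative to the genome mean. (Dividing — not multiplying — by relative target size is what makes a
gene hit purely in proportion to its mutational opportunity come out
with multiplicity equal to its expected hit count; the statistic is a
parallelism measure only in this form.) The null redistributes each
population's observed hit count across all genes multinomially with
probabilities proportional to target size (1000 replicates by default),
yielding envelopes for the survival curves of multiplicity and of
populations-hit; the codon-level null re-draws each hit's position
uniformly within its own gene (10 replicates). Multi-hit genes are those
hit in ≥ 6 *distinct* populations — double hits within a population do
not count twice.

## Contingency

**Enrichment.** Within a population set, the probability that gene $i$ is
hit in population $g$ is $1 - (1 - \tilde N_i/M)^{M_g}$ with $\tilde N_i$
the pseudocounted (+0.1) number of populations carrying a fixed hit in
gene $i$ and $M$, $M_g$ the total and per-population gene-hit counts
(within-population double hits ignored). Four models estimate these
probabilities on different partitions: pooled, by strain, by environment,
by strain×environment. Per gene, the log-likelihood ratios of the three
structured models against the pooled model are compared with their
empirical null distributions from datasets simulated under the pooled
model, with all parameters re-estimated per simulated dataset; p-values
use the $(r+1)/(n+1)$ convention and Benjamini–Hochberg correction is
applied *jointly* across genes and the three comparisons (the more
conservative of the two readings). Among significant models the smallest
AIC, $2k - 2\log L$ with $k$ = 1, 3, 3, 9 partition cells, decides the
label (S, E, or SxE). Degenerate metadata (fewer than two strains or two
environments) is rejected rather than silently collapsing the models.
Numerical guards: the pseudocount can push $\tilde N_i$ above $M$ in tiny
partitions, so the base probability is clamped to [0, 1], and Bernoulli
probabilities are clamped away from 0 and 1 before taking logs.

**Mutual information.** Within each strain×environment combination with
$N_e$ populations and $M$ gene hits, the marginal hit probability is the
pseudocount-padded mean of indicators,
$P(h_i|e) = (n_i + N_e\varepsilon) / (N_e(1+\varepsilon))$ with
$\varepsilon = 1/M$ by default. The joint distribution of a gene pair is
defined from co-occurrence counts padded the same way, with the entire
pad placed on the (1,1) cell — the unique placement whose row and column
sums reproduce the padded marginals, so the joint is a proper
distribution and MI (base 2) is non-negative. Pairs are zeroed in any
combination where either gene has no hits, and summed across the nine
combinations. `mi_null_test()` draws null datasets gene-independently
from the estimated marginals and reports upper-tail $(r+1)/(n+1)$
p-values for MI$_{tot}$ and MI$_{max}$; `mi_pseudocount_sweep()` repeats
the test for $\varepsilon M$ between 0.1 and 2.

*Known limitation, measured by the acceptance suite:* this plug-in
bootstrap is **anti-conservative** in the regime the analysis targets.
When data are generated with genes truly independent (9 combinations of
12/12/6 populations, gene hit probabilities 0.08–0.4), the p-value for
MI$_{tot}$ has mean ≈ 0.17 rather than 0.5 and fails a
Kolmogorov–Smirnov uniformity check decisively. The mechanism is the
interaction of the zero rule with re-estimation: the observed dataset
always counts a pair in combinations where both genes happen to be hit,
while null datasets regenerate hit status from the estimated marginals
and are zeroed more often for low-probability genes. Calibration is
approached only when every gene is hit in essentially every combination.
Small p-values from this test should therefore be interpreted
cautiously; a conditional (margin-preserving permutation) null would be
calibrated, but it answers a different question and is not the procedure
implemented here.

**Dispersion.** For one population set, each gene's hits are compared to
multinomial redistribution weighted by per-population hit totals: for
every observed hit count the simulated distribution of distinct
populations hit is built (10,000 draws per count), and *excess
probability* is observed minus simulated cell probability. *Missed
opportunities* — hits landing in populations already hit in the same
gene, i.e. hits minus distinct populations hit, summed over genes — gets
a one-sided p-value for the over-dispersion direction (fewer missed
opportunities than the null). The statistic is defined here as hits minus distinct populations hit,
summed over genes — the simplest count of repeat landings.

## Fitness assays

The corrected reference frequency is $x = x_{obs}/(1-f)$, capped at 1,
where $f$ is the nonfluorescent fraction of the reference estimated from
reference-only control wells; the cap makes control wells consistent. The
correction divides by $1-f$, which exactly inverts the binomial thinning
of reference counts by non-fluorescence. Fitness is the ordinary-least-squares slope of
$\ln((1-x)/x)$ against cumulative generations, after excluding
timepoints with $x < 0.05$ or $x > 0.95$; at least two usable timepoints
are required, otherwise the estimate is flagged missing rather than
extrapolated. Fitness is reported *per generation*, which makes environments with
different daily dilutions (and hence different generations per day)
directly comparable. Batch correction subtracts the mean fitness of
unlabeled-reference wells in the same assay batch. Ancestral fitness is
the median first-timepoint fitness among populations with no
nonsynonymous mutations detected at that timepoint, with an explicit
fallback value for strain/environment combinations where none qualify.

## Fluctuation assays

`msr_pmf()` implements the Luria–Delbrück probability recursion
($p_0 = e^{-m}$, $p_n = (m/n)\sum_{j<n} p_j/(n-j+1)$); mass beyond
`n_max` is pooled into a tail class so the distribution sums to one.
`msr_mle()` maximizes the resulting multinomial likelihood over $m$ by
one-dimensional bounded search (`optimize`), with the all-zero boundary
handled exactly ($\hat m = 0$); the likelihood's unimodality on
simulated data is checked by grid scan in the tests. Counts above
`n_max = 150` are pooled because large colony counts are unreliable to
resolve on a plate (counts above ~50 are already approximate); no
plating-efficiency or post-plating-growth correction is applied. The
mutation rate is $\hat m / N_t$ per cell per generation; confidence
intervals and fold-change intervals resample cultures with replacement.

## Problem sizes used by the validation suites

The test suite and `scripts/acceptance.R` use: 50 synthetic haploid
populations (N = 1000, 600 generations, 40× coverage, 6 timepoints) for
calling sensitivity and specificity; 60 planted CNV segments (4–20
windows, noise sd 0.15, 3 timepoints) plus 200 randomized ≤ 12-window
instances for oracle equivalence and a 10,000-window pure-noise track for
specificity; 100 replicate fluctuation experiments of 88 cultures at
m = 2 and 10⁵-culture Monte-Carlo pmf checks; 100 null datasets
(n_null = 2000) for enrichment type-I calibration and 10 planted-effect
replicates for power; 200 null datasets (n_null = 1000) for MI
calibration at the 90-population design; 3000-gene multinomial data for
dispersion calibration; 200 simulated assays at 20,000 events for
fitness bias. Seeds are fixed in the tests and derived from `--seed` in
the acceptance script.
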