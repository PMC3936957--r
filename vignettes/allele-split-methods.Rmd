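---
title: "Allele-split association mapping of recombination hotspots: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-split association mapping of recombination hotspots: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhosplit)
```

## The question and the statistic

Meiotic recombination hotspots vary in intensity between individuals, and
part of that variation is cis-encoded: a SNP allele that preserves a
hotspot-stimulating DNA motif (the canonical example being the PRDM9-bound
core heptamer CCTCCCT) should be associated with a hotter hotspot than the
allele that disrupts it. Direct sperm-typing measurements of this effect
exist for a handful of loci; `rhosplit` screens for it genome-scale from
ordinary phased population haplotype panels.

For a candidate SNP $A$ near a hotspot $H$, the panel is split into the two
allele-defined subpopulations. Each subpopulation's historical
recombination landscape is estimated as a per-interval population
recombination rate profile $\rho(x)$ (in units of $4N_e r$ per kb), each
profile is summarized as a hotspot *strength*, and the statistic is the
normalized difference

$$\Delta\rho = \frac{\rho_0 - \rho_1}{\rho_0 + \rho_1} \in [-1, 1],$$

defined as 0 when both strengths are 0. Its null distribution is obtained
by permutation: haplotypes are repeatedly re-split at random into
pseudo-populations of the observed sizes $(n_0, n_1)$, the statistic is
recomputed with the identical estimator configuration, and the two-sided
p-value is the add-one estimator $(1 + \#\{|\Delta\rho_\text{null}| \ge
|\Delta\rho_\text{obs}|\})/(B + 1)$, which can never be exactly zero and is
conservative under the null. Because the permutation scheme preserves the
subpopulation sizes and reuses the same estimator seed, the test is exact
(distribution-free) under haplotype exchangeability for any choice of
estimator — estimator quality affects power, not validity; the strength
section below discusses what relatedness among haplotypes does to
exchangeability and how the default statistic neutralizes it. A one-sided alternative (`alternative = "greater"`) is
available for the directional motif-disruption question; the default is
two-sided because a screen has no a-priori direction.

Ties in the permutation count are handled by the $\ge$ comparison,
applied at a resolution of $10^{-9}$ so that splits with equal true
statistics count as ties regardless of floating-point noise;
`split_test(method = "exhaustive")` enumerates all distinct splits for
small panels (complementary splits are collapsed for the two-sided
statistic, where they are equivalent).

### What "strength" means, and why the default is relative

Three strength measures are available. `"integral"` is the raw
$\rho$–distance integral over the hotspot interval (a dimensionless
$4N_e r$ total, the measure [hotspot_strength()] reports for profiles);
`"peak"` is the maximum interval rate inside it. The default,
`"relative"`, is the hotspot's *share* of the subpopulation's total
integrated map length. The reason is empirical and important. An allele
split is a split along the panel's genealogy at that site: the two allele
classes are more internally related than random halves of the panel, and
in low-recombination regions — the benchmark simulations have essentially
one shared tree across the whole 200 kb window — that relatedness shifts
the *level* of the whole estimated rate profile in each subpanel.
Measured on null simulations (no causal SNP anywhere), the raw-integral
statistic rejected at roughly 25% at nominal $\alpha = 0.05$ across every
estimator configuration tried, while the relative statistic is calibrated
(the level shift cancels in the ratio and the permutation comparison sees
only the hotspot-specific concentration of rate). Both alternative
measures remain one argument away for panels where absolute intensities
are of interest. For the same reason the tested SNP's own column is
excluded from every estimation — within the observed split it is
monomorphic and carries nothing, and keeping it only in the permuted
splits would bias the null.

## The recombination-profile estimator

Allele-split screens of this kind have historically delegated rate
estimation to LDhat's `rhomap` (reversible-jump MCMC) as an external
black box. `rhosplit` instead ships a
deterministic, self-contained estimator built on the
product-of-approximate-conditionals (PAC) composite likelihood of the
haplotype copying model: haplotype $k$ in an ordering is an imperfect
mosaic copy of the $k-1$ haplotypes before it; the copying template
switches across interval $j$ with probability $1 - \exp(-\rho_j d_j / k)$
($d_j$ the interval length in kb) and each copied site mismatches with
probability $\theta / (2(k + \theta))$, with $\theta$ the Watterson-style
per-site mutation parameter $1/\sum_{i<n} 1/i$ by default. The first
haplotype contributes a constant. Because the PAC likelihood depends on the
haplotype ordering, the objective averages the log-likelihood over
`n_orderings` random orderings (seeded, hence reproducible bit-for-bit).

Rates are maximized per interval on a log-spaced grid
($10^{-2}$–$10^{2}$ per kb, 25 points by default — spanning the 10–100
fold dynamic range of human hotspots) under a smoothness penalty
$\lambda \sum_j (\Delta \log \rho_j)^2$ with $\lambda = 1$ by default.
The search is initialized at the best constant-rate fit (found on a
thinned version of the same grid): a panel carrying no recombination
signal then stays at its flat optimum instead of inheriting an arbitrary
anchor value. Each coordinate-ascent sweep refreshes a forward–backward decomposition of
the likelihood (the per-interval profile likelihood is an $O(1)$ function
of the interval's switch probability given stored forward/backward
vectors), updates every interval on the grid with the freshest neighbour
values in the penalty, and stops when nothing moves, the objective gain
falls below `tol`, or `max_sweeps` is reached. Ties on the grid resolve to
the smaller rate. The forward algorithm and sweep machinery are compiled
(Rcpp); the exact forward recursion is cross-checked in the test suite
against brute-force enumeration of all copy paths on small panels.

Monomorphic sites carry no copying information and the split SNP itself is
always monomorphic within each subpanel, so such sites are dropped before
estimation and the profile is re-expanded to the original coordinates, the
dropped intervals inheriting the rate of the informative interval spanning
them. Sites with missing calls are likewise dropped (with a warning):
the copying likelihood assumes complete phased data, and there is no
principled single imputation at this panel size. Panels with
fewer than two segregating sites are an error. Estimation is defined for
any $n \ge 2$ — permutation enumeration on 6-haplotype panels estimates on
3-haplotype subpanels.

At the profile level, [hotspot_strength()] reports the rate–distance
integral over an interval (additive over partitions, linear under profile
rescaling, and robust to how the estimate distributes rate among adjacent
intervals within the hotspot); the split statistic's strength measures
build on it as described above.
`detect_hotspots()` automates interval choice as runs of intervals at
$\ge$ 5-fold the median rate; the scan API also accepts a user interval,
mirroring the manual boundary choice interactive implementations offer.

## The benchmark simulator

`sim_config()`/`simulate_benchmark()` generate all test data: a
forward-time diploid Wright–Fisher population (no mutation, non-overlapping
generations, random mating with distinct parents) over a 200 kb window of
biallelic SNPs, with at most one crossover per transmitted gamete. The
crossover probability per meiosis is 0.001 (one crossover per 200 Mb
scaled to 200 kb) when the hot allele of the causal SNP at 100 kb is
absent and 0.01 when it is present; the crossover position is drawn from
a Normal centered at the 100 kb hotspot (sd = half the hotspot width),
truncated to the window.

What "present" means is the single most consequential modelling choice in
the benchmark, and the package settles it empirically. Under the default
`penetrance = "cis"`, the rate is keyed to the causal allele of the
*donor* haplotype — the one contributing the causal-site side of the
gamete — so a transmitted chromosome's crossover history carries the full
10-fold hot/cold contrast, as a cis-acting motif implies. Under the
parent-genotype readings (`"dominant"`, `"additive"`, both selectable)
the contrast between *extant alleles* collapses: at hot-allele frequency
$p$ a cold-allele gamete still recombines at
$p\,p_\text{hot} + (1-p)\,p_\text{bg}$ because most parents carry the hot
allele, so with the allele descending from 0.99 the historical contrast
is near 1 for most of the trajectory. Measured on desk-scale benchmarks,
dominant penetrance leaves the causal SNP statistically indistinguishable
from other sites (it attains the minimum p in ~3/10 datasets and is
significant no more often than bystanders), which cannot reproduce an
allele-split screen's intended behaviour — so the cis reading is the
default and the genotype readings are retained as controls.

The hot allele starts at frequency 0.99 and must end near 0.50. Neutral
drift essentially never makes that traverse in the configured number of
generations, and a constant selection coefficient sized to the logit path
loses the rare cold allele to drift in most runs (10 copies at $2N = 1000$).
The default mechanism is therefore a logit-proportional controller: each
generation applies genic selection against the hot allele with coefficient
$s_t = \kappa\,(\mathrm{logit}\,p_t - \mathrm{logit}\,0.5)$, gain $\kappa =
10/\text{generations}$, capped at $|s_t| \le 0.5$ — a stand-in for the
self-erosion of hotspots by biased gene conversion together with whatever
countervailing forces kept the allele segregating. Rejection conditioning
on the final frequency ($0.50 \pm 0.05$) remains the guarantee; with the
controller it accepts most runs, and each accepted run records its seed and
attempt count. Constant-coefficient and pure-drift modes stay selectable.

Initial standing variation is site-independent with uniform(0.1, 0.9)
frequencies — linkage equilibrium, from which drift then builds LD. Two
consequences for interpretation: the estimator sees an elevated apparent
background rate (an LE start is indistinguishable from an infinitely
recombining past), and the LD signal of the hotspot accumulates only over
the simulated generations. Passing benchmarks on these data therefore
demonstrates the pipeline's mechanics and calibration, not performance on
real human panels, whose LD reflects far deeper genealogies, variable
marker density and ascertainment.

Two presets are used throughout. `"table1"` is the full benchmark scale:
5000 diploids, 3000 generations, 200 SNPs, 10 subsets of 90 individuals
(180 haplotypes). `"desk"` is the scaled twin used by the test suite and
the acceptance script — 500 diploids, 300 generations, 40 SNPs, 10 subsets
of 45 individuals (90 haplotypes) — chosen once so that a full scan of a
panel costs seconds rather than hours while keeping ~20 MAF-qualifying
candidate SNPs per panel. The test and acceptance runs use estimator
settings reduced the same way (2 orderings, 2 sweeps for scans; a minimal
1-ordering configuration for the type-I calibration, where only
exchangeability matters); the package defaults (10 orderings, 3 sweeps)
are used where only a handful of profile estimates is needed, e.g. the
hotspot-localization checks.

## The motif stage

`find_motif_occurrences_with_snp()` locates exact motif occurrences that
contain exactly one known SNP, on either strand, recording which allele
preserves and which disrupts the motif (windows holding two or more SNPs
are excluded and counted; they are vanishingly rare for 7-mer motifs in
real SNP data).
`classify_motif_allele()` labels a hotspot–SNP pair *positive* when the
preserving allele has the larger estimated strength; exact ties are
*negative* — a tie carries no evidence for stimulation.

`oops_em()` re-implements the one-occurrence-per-sequence (OOPS) EM motif
model: every record carries exactly one site of width $w$ at an unknown
position (and strand, by default), other positions following a 0-order
background estimated from the records. Starting points are seeded from
observed subsequences (a pool of 4 per requested restart, screened by two
EM iterations, the best run to convergence), mirroring the data-driven
starts of the established EM motif finders. PWM updates add a Dirichlet
pseudocount of 0.1 per base; the monotone quantity is therefore the
penalized (MAP) objective, recorded per iteration in `objective_trace` and
asserted non-decreasing in the tests. `discover_motifs()` ranks motifs by
a BIC-penalized log-likelihood ratio, $2\,\mathrm{LLR} - 3w\log n$,
searches widths 10–20, drops motifs with fewer than 10 confident sites
(posterior > 0.5), and masks each reported motif's confident sites with
background-sampled bases before the next rank. E-values are deliberately
not reproduced; only the ranking order matters here.

A known limitation, deliberately not engineered away: under OOPS every
sequence must contribute a site, so when a planted motif occupies only
about half the corpus the maximum-likelihood PWM blends motif instances
with forced background sites (and, when two similar motifs share a corpus,
blends the motifs themselves — the benchmark pair are ~50% identical once
strand flips are allowed). The PWM's consensus probabilities then saturate
near the motif's corpus fraction plus background, even though the model's
confident sites still localize the planted instances almost perfectly. The
package tests assert exactly these two facets: site-level localization on
mixed corpora, and high-consensus PWM recovery (match $\ge 0.8$) on
corpora where one motif dominates. The guided benchmark is accordingly run
as two separate recovery experiments, one per planted motif, each over the
full screen output, with each corpus built from the top significant SNP
(p < 0.05, ties broken by effect size) of every dataset — which keeps
causal windows dominant exactly as intended by guiding motif finding with
the screen.

The simulated guided-discovery benchmark (`benchmark_motif_corpus()`)
extends each selected SNP to a 101-base random-DNA window and plants the
benchmark 13-mers `ACTATCGATCTAG` / `ATGATGTAATGGT` across the windows
whose SNP is the causal one, centered on the SNP; when the causal SNP is
not selected (a false negative of the screen), nothing is planted — false
negatives propagate exactly as they would in practice. The negative
control selects the same number of SNPs per dataset at random, so causal
windows are rare and the finder has (correctly) almost nothing to find.

## Numerical and interface conventions

* Site indices are 1-based and windows closed intervals, as R users
  expect; file headers use the dialect's own count conventions.
* Panel positions are stored in kb (the locs file's native unit) and
  exposed in bp by default; locs files are written with `%.15g` so
  write–read–write cycles are byte-identical.
* Every stochastic routine takes an explicit integer seed, derives any
  sub-seeds deterministically from it, and restores the caller's RNG
  state, so results are reproducible end-to-end from one master seed and
  independent of session state.
* The scan keeps `n_perm` modest by default (200); with the add-one
  estimator the attainable p-value floor is $1/(B+1)$, so screening at
  $\alpha = 0.05$ needs $B \ge 39$; the desk-scale runs use $B = 49$
  (floor 0.02) and the type-I calibration $B = 99$.
* No multiple-testing correction is applied by default (the screen is
  exploratory, and correcting a screen that feeds a downstream
motif-discovery stage would trade recall for little gain); a
  Benjamini–Hochberg adjustment is one `p.adjust()` call away on the tidy
  scan table.

## Known limitations

* **Association is not causality, even in simulation.** In benchmark
  panels that carry the causal hotspot, many SNPs *other* than the causal
  one show genuine association: with near-zero background recombination
  the window shares one genealogy, and any allele split that partitions
  the recombinant lineages unevenly yields a real hotspot-concentration
  difference between its subpopulations. This is not LD tagging of the
  causal SNP (the affected sites are often nearly uncorrelated with it,
  $|r| < 0.4$) and it disappears on no-hotspot panels, so it is signal,
  not miscalibration. Consequently the causal SNP attains the smallest
  p-value in only a minority of desk-scale datasets, and significant-SNP
  counts per dataset run well above the nominal false-positive budget.
  The screen localizes *hotspot-associated variation*; pinpointing the
  causal variant requires the motif stage or denser information.
* **OOPS purity ceiling.** Under the one-occurrence-per-sequence model
  every record contributes a site, so PWM consensus probabilities saturate
  near the motif's corpus fraction; high-consensus recovery needs corpora
  where one motif dominates (the guided benchmark is therefore run once
  per planted motif), while mixed corpora are still localized correctly at
  the site level.
* **Scope of the simulations.** The generator's linkage-equilibrium start,
  single-crossover meioses and absence of mutation or gene conversion mean
  that passing benchmarks demonstrate mechanics and calibration, not
  performance on real panels.

## Problem sizes used by the checks

The bundled acceptance script (`scripts/acceptance.R`) regenerates
everything from a single `--seed`: 10 conditioned desk-scale populations
scanned over 4 panels each (49 permutations per SNP), 200 null panels for
type-I calibration (99 permutations), 20 flat-crossover simulations, two
guided motif corpora of ~15–20 windows plus a random-SNP control, $10^5$
single meioses for the crossover laws, and 100 random write–read
round-trips. These sizes are the package's desk-scale study conditions;
the `"table1"` preset reproduces the full-scale configuration for cluster
runs via the `sim` CLI subcommand.
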