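---
title: "Models and methods behind meadowpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meadowpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meadowpop)
```

`meadowpop` re-implements, as one coherent and tested package, the
computational chain used in range-wide population-genomic studies of
eelgrass (*Zostera marina*): SNP quality control, clonemate and selfing
exclusion, pangenome presence/absence classification, diversity and
differentiation statistics, chloroplast haplotype networks, and
molecular-clock dating. This vignette records the models, the assumptions
they rest on, the tunable parameters, and the design choices that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic-data generator

All testing rests on a built-in structured coalescent. Populations carry
piecewise-constant diploid effective sizes $N_e$; looking back in time,
lineage pairs within a population of size $N$ coalesce at rate
$k(k-1)/(4N)$; at a split time the derived population's lineages join the
ancestral one; an admixture pulse at time $t$ with fraction $f$ moves each
lineage of the target to the source with probability $f$ (the backward
image of a single-generation migrant pulse — enough to make Patterson's D
respond, without continuous migration). Loci are independent and
non-recombining; mutations follow the infinite-sites model, implemented on
a finite grid by sampling distinct positions within each locus. Diploids
pair two haploid lineages drawn from the same population (random mating).

Two closed-form expectations anchor the engine and are asserted in the
tests at Monte-Carlo precision (3 standard errors over 10,000 and 2,000
loci respectively):

- within a population, $E[\pi] = 4 N_e \mu$ per site;
- between two populations split $T$ generations ago with ancestral size
  $N_e$, $E[d_{xy}] = 2\mu(T + 2N_e)$ per site.

What the generator emulates: multi-population diploid genotype matrices
with realistic call-level fields (GQ, DP, AD), clonemate duplicates with
independent genotyping errors, selfed offspring under exact Mendelian
segregation, records engineered to fail each QC filter in exact numbers,
chloroplast read pileups with artifact positions, and gene
presence/absence with separated frequency classes. What it does not
emulate: read-level errors and mapping artifacts (beyond the summary
metrics), recombination within loci, linked selection, overlapping
generations, and spatial structure within meadows. A green test therefore
establishes that the algorithms implement their definitions and recover
parameters under the stated model — not that any particular field data set
satisfies that model.

Generator defaults are the study conditions they emulate: the sample
ledger fixture uses 190 samples of which 17 are clonemate duplicates, 10
are selfed offspring and 10 carry missing rates above 15 %; the
chloroplast fixture uses the 143,968 bp quadripartite plastome, 174
variable positions and 11 + 12 artifact positions. Where the source
material states no value (e.g. the nuclear per-generation mutation rate,
which the original dating obtained from an external calibration rather
than a rate), the recovery experiments inject a conventional plant-scale
rate of $10^{-8}$ per site per generation and re-use the same value in
estimation; the tests exercise recovery, not the rate itself. Simulated
median coverage for the plastome (500×) reflects the high organelle copy
number in leaf tissue.

## SNP quality control

The cascade mirrors standard joint-genotyping practice:

1. remove SNPs within 20 bp (inclusive, $|\Delta| \le 20$) of an indel or
   other non-SNP record;
2. site-level hard filters — MQ < 40, FS > 60, QD < 10, |MQRankSum| > 2.5,
   |ReadPosRankSum| > 2.5, SOR > 3, DP > 2 × mean site depth. All
   inequalities are strict: a site exactly at a threshold passes. A
   missing annotation passes its criterion (rank sums are undefined at
   sites without heterozygotes, and the upstream caller leaves them
   absent);
3. call-level masking — GQ < 30 or DP < 10, plus homozygotes whose allele
   depths carry one or more reads of the other allele;
4. biallelic selection; optional intersection with core-gene regions;
   annotation subsetting (synonymous sites for neutral sets, optionally
   with no missing data); greedy 3 kb thinning; sample exclusion above a
   15 % missing rate.

The depth ceiling is computed from the data (2 × mean input DP), never
hard-coded, because any printed absolute value is dataset-specific.
Thinning is greedy left-to-right per chromosome — keep the first site,
then every site at least 3,000 bp beyond the last kept one — stated
explicitly because "no two sites within 3 kb" underdetermines the scan
rule; the output is verified to have no same-chromosome spacing below the
minimum. Coordinates follow VCF (1-based) internally with a single
conversion routine to 0-based half-open BED.

## Clonemates and selfing

For samples $a, b$ the package uses the Jaccard index of heterozygous site
sets restricted to sites called in both:
$\mathrm{sh}(a,b) = |H_a \cap H_b| / |H_a \cup H_b|$. Ramets of one genet
differ only by genotyping error, so $\mathrm{sh} \approx 1$; two outbred
individuals share heterozygosity only through allele-frequency chance
($\mathrm{sh} \approx 0.1$–$0.3$ at typical diversity); a selfed offspring
retains each parental heterozygous site with probability 1/2, giving
$\mathrm{sh} \approx 1/2$ against its parent but a het-subset fraction of
1. Detection uses:

- clones: $\mathrm{sh} \ge 0.9$ (default) and overall genotype identity
  $\ge 1 -$ allowance (0.01), single-linkage groups, one representative
  (highest call rate) retained. The exact statistic behind the original
  study's clone calls is in an external reference the paper does not
  restate; this Jaccard form is a documented stand-in with the same
  behaviour on the extremes that matter.
- selfing: ordered pair (P, D) flagged when ≥ 99 % of D's heterozygous
  sites are heterozygous in P, the het-count ratio lies in the central
  99 % binomial interval around 1/2, and the pair is not clonemates; the
  sample with fewer heterozygous sites is the descendant.
- the exclusion ledger assigns one primary reason per sample with priority
  selfing > clonality > missingness (configurable); this makes compound
  cases well-defined and the ledger arithmetic exact.

## Pangenome presence/absence

A gene is present in a sample if a single alignment exceeds 60 % identity
and 60 % transcript coverage, or if all its hits lie on at most three
scaffolds and jointly exceed 85 % summed (non-overlapping) coverage at
85 % coverage-weighted identity. The aggregated reading of the
multi-scaffold rule is the package's explicit choice where the prose was
ambiguous; with identical per-hit values on four scaffolds the rule is
inapplicable and the gene absent, which keeps presence monotone in
identity and coverage. Samples with 17,500 or fewer present genes are
dropped (strictly-greater retention) before per-gene frequencies are
computed, optionally on one representative per clone group. Classification
into cloud/shell/core replaces a discriminant analysis with deterministic
1-D Lloyd k-means initialised at the 0.1/0.5/0.9 frequency quantiles: on a
single frequency axis the discriminant reduces to threshold clustering
anyway, and determinism makes exact recovery testable. Fewer than three
distinct frequencies trigger a threshold fallback (< 0.2 cloud, < 0.9
shell, else core) with a warning.

## Population-genetic statistics

Nucleotide diversity uses the unbiased per-site form
$\pi_i = 2 c_0 c_1 / (n(n-1))$ and averages over the SNPs of a chromosome
(per-SNP mode, matching analyses run on fixed no-missing SNP sets); a
`seq_length` argument gives per-bp values instead. $H_{obs}$ is the
heterozygous fraction of an individual's called genotypes.

$F_{ST}$ is Weir & Cockerham's θ, aggregated ratio-of-sums across sites,
with significance from bootstrap resampling across **loci** (chromosomes):
SNPs within a locus share a genealogy, and resampling them as if
independent demonstrably understates the sampling variance (the null
panmixia test failed with site-level resampling and passes with
locus-level resampling). The p-value is the fraction of bootstrap θ ≤ 0.

Patterson's D uses the frequency form over polarized sites,
$D = \sum[(1-p_1)p_2p_3(1-p_O) - p_1(1-p_2)p_3(1-p_O)] /
\sum[(1-p_1)p_2p_3(1-p_O) + p_1(1-p_2)p_3(1-p_O)]$, with a polymorphic
outgroup entering through $p_O$. The standard error is a delete-one block
jackknife over contiguous blocks that break only at locus boundaries, and
the two-sided p-value references Student's t with (blocks − 1) degrees of
freedom rather than the normal: the SE itself is estimated from ~20
blocks, and in 400-replicate null calibrations the normal reference
rejected at ~0.07 while the t reference sits at ~0.055 for a nominal
0.05. The heatmap summary reports, for every ordered (P2, P3), the trio
minimizing p over candidate P1 populations (ties break on larger |Z|).

## Chloroplast haplotypes and networks

A position is variable in a sample when its variant-read fraction strictly
exceeds 0.5 and its coverage strictly exceeds 0.3 × that sample's median;
the variable set is the union over samples. Microsatellite-adjacent,
hairpin-inversion and rRNA positions are supplied as mask intervals (the
original artifacts were identified by inspection; no automatic detection
is attempted), and overlapping masks attribute a removal to the first mask
in priority order. Haplotypes collapse identical strings over retained
positions; missing states are an error rather than imputed, appropriate
for high-coverage organelle data. Parsimony-informative selection keeps
columns with at least two states each in at least two sequences.

The median-joining network is a deterministic variant of the Bandelt
construction: iterate (a) the ε-relaxed minimum spanning network (an edge
survives when its Hamming distance is within ε of the pair's minimax path
distance), (b) for triplets joined by at least two network edges, propose
the column-majority median (three-way column ties resolve to the
lexicographically smallest member) and accept, in lexicographic order, the
first median that strictly shortens the minimum spanning tree length, and
(c) finally prune unobserved vertices of degree ≤ 2 whose removal does not
lengthen the tree. Total tree length strictly decreases with each accepted
median, so the construction terminates; every observed haplotype remains a
vertex; for ε = 0 the final length never exceeds the observed-only MST.
On the three-haplotype benchmark the construction finds exactly the
Steiner point that exhaustive enumeration identifies.

## Clock dating

Chloroplast step dating uses $t = k / (2\mu L)$ years for $k$ mutation
steps over $L$ sites at per-year rate $\mu$ (both lineages accumulate
mutations). The package ships the plastome constants (quadripartite
lengths summing to 143,968 bp, 9,818 bp rRNA excluded) and the synonymous
plastome rate $2\times10^{-9}$/site/year as `eelgrass_plastome()` and
`eelgrass_calibrations()`. The effective site count behind any particular
published figure is not always printed, so the worked examples use
hand-checkable inputs.

Generation-to-year conversion is a product, with the convention of a
3-year mean generation time; `find_ne_minima` reports strict local minima
of log $N_e$ older than 1,000 generations (recent sequentially-Markovian
estimates are unreliable) and is invariant to monotone rescaling.

Calibration priors are lognormal with the real-space mean and log-space
standard deviation convention of multispecies-coalescent calibration files
(meanlog = log(mean) − sd²/2); this is the documented interpretation of
"mean/s.d." pairs like (11.154, 0.07) and is switchable by constructing
the prior directly.

Full Bayesian multispecies-coalescent dating is deliberately not
re-implemented. Instead, dated-phylogeny node ages are exercised as
parameter-recovery targets through the net-divergence estimator:
$d_a = d_{xy} - (\pi_A + \pi_B)/2$, $T = d_a / (2\mu_{yr})$. This tests
the simulator and the dating arithmetic jointly — the quantity the
pipeline contributes — not the Bayesian machinery. Negative $d_a$ (drift
noise at very recent splits) clamps to zero with a warning. Across the
node ages used in the acceptance suite (~352 to ~18.8 kya; 500 × 5 kb
loci, 2,000 for the shallowest node; $N_e$ = 10,000; 10 diploids per
population) the mean over five seeds lands within a few percent of truth.

## Pipeline and reproducibility

`run_pipeline` executes synthesize/ingest → QC → clonality → PAV →
statistics → chloroplast → dating from one configuration. Each stage is
cached under a content hash of its parameters and a stage-namespaced seed
derived from the global seed, so identical configurations reproduce the
JSON run report byte for byte and single-stage re-runs do not shift other
stages' draws. Exit codes of the CLI wrapper: 0 ok, 1 user error, 2
internal error.

## Known limitations

- The coalescent engine has no recombination within loci; linked-selection
  and haplotype-structure statistics are out of scope.
- The clonality statistic is a stand-in for an external reference the
  source prose does not restate; its clone/outbred/selfed separation is
  validated only under the generator's error model (exact at error rates
  up to ~10⁻³ in the tests).
- Median-joining is exponential in the worst case; the implementation is
  intended for organelle-scale haplotype sets (tens of haplotypes).
- The net-divergence dater assumes equal ancestral and daughter $N_e$ and
  no post-split gene flow; with gene flow it underestimates, and at very
  shallow splits its variance is dominated by ancestral-diversity noise
  (hence the larger locus count for the shallowest acceptance node).
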