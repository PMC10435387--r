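# meadowpop

Population genomics for clonal marine plants — an integrated, tested R
implementation of the computational pipeline behind range-wide eelgrass
(*Zostera marina*) resequencing studies. Seagrass meadows mix clonal
(rhizome) spread, occasional selfing and sexual reproduction, which breaks
the assumptions of most population-genetic toolchains: duplicate genets and
selfed offspring must be found and removed before any diversity,
differentiation or dating analysis is meaningful. `meadowpop` packages the
whole chain, from raw jointly-genotyped SNPs to a dated population history,
with a built-in coalescent simulator so every stage is exercised against
known truth without any external data.

## What it does

| Stage | Functions | Method |
| --- | --- | --- |
| Synthetic data | `simulate_coalescent`, `inject_clones_and_selfs`, `corrupt_for_qc`, `simulate_cp_pileup`, `simulate_pav` | structured Hudson coalescent (splits, pulses, piecewise N_e), infinite-sites mutation, truth-labelled perturbations |
| SNP QC | `qc_cascade` and its stages (`mask_near_variants`, `apply_hard_filters`, `mask_genotypes`, `select_biallelic`, `intersect_regions`, `subset_by_annotation`, `thin_by_distance`, `sample_missing_filter`) | GATK-style hard-filter cascade: MQ < 40, FS > 60, QD < 10, &#124;MQRankSum&#124; > 2.5, &#124;ReadPosRankSum&#124; > 2.5, SOR > 3, DP > 2×mean; GQ < 30 / DP < 10 call masking; 20 bp indel windows; 3 kb thinning |
| Clonality | `shared_het`, `detect_clones`, `detect_selfing`, `build_exclusion_ledger` | Jaccard index of heterozygous site sets; Mendelian het-ratio test for selfed parent–descendant pairs |
| Pangenome | `call_presence`, `build_pav`, `classify_genes` | >60 % identity/coverage single-hit rule, >85 % aggregated rule on ≤ 3 scaffolds; deterministic 1-D k-means into cloud/shell/core |
| Statistics | `nucleotide_diversity`, `individual_heterozygosity`, `pairwise_fst`, `patterson_d`, `d_heatmap_summarize` | π = 2c₀c₁/(n(n−1)) per SNP; Weir–Cockerham θ (ratio of sums, bootstrap over loci); ABBA–BABA D with block jackknife |
| Chloroplast | `call_cp_variants`, `apply_masks`, `collapse_haplotypes`, `parsimony_informative`, `median_joining_network`, `count_mutation_steps` | >50 % variant reads and >30 % of median coverage; artifact masks; Bandelt-style median-joining with deterministic tie-breaking |
| Dating | `cp_clock_time`, `generations_to_years`, `find_ne_minima`, `net_divergence_split_time`, `build_calibration` | t = k/(2μL); net divergence d_a = d_xy − (π_A+π_B)/2, T = d_a/(2μ) |
| Orchestration | `run_pipeline`, `validate_config`, CLI at `inst/scripts/meadowpop-cli.R` | content-hash stage caching, namespaced seeds, byte-reproducible reports |

## Worked example

Simulate two populations that diverged 5,000 generations ago, inject two
clonemate duplicates and two selfed offspring, then detect and exclude them
and re-estimate the split time:

```r
library(meadowpop)

model <- two_pop_model(split_gens = 5000, ne = 10000, mutation_rate = 1e-7,
                       n_loci = 200, locus_length = 1000)
d <- simulate_coalescent(model, c(A = 10, B = 10), seed = 1)
d <- inject_clones_and_selfs(d, n_clonemate_copies = 2, n_selfed = 2,
                             genotyping_error_rate = 0, seed = 2)
g <- d$genotypes

ledger <- build_exclusion_ledger(g$samples, detect_selfing(g),
                                 detect_clones(g),
                                 sample_missing_filter(g)$excluded)
ledger
#> relatedness_report: 24 input, 20 retained (clone: 2, selfing: 2)

keep <- gt_subset_samples(g, g$samples %in% ledger$retained)
est <- net_divergence_split_time(
  keep, grep("^A", keep$samples, value = TRUE),
  grep("^B", keep$samples, value = TRUE),
  clock_params(mu_per_generation = 1e-7, generation_time = 3),
  total_length = 200 * 1000)
round(est$split_time_generations)
#> [1] 5213
```

The ledger shows all four injected problem samples excluded for the right
reasons (24 → 20), and the net-divergence estimator recovers the true
5,000-generation split within ~4 % on this small simulation.

An end-to-end demo (synthesis → QC → clonality → PAV → statistics →
chloroplast network → dating, with caching and a JSON report):

```r
report <- run_pipeline(default_pipeline_config(outdir = "demo_run", seed = 1))
```

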