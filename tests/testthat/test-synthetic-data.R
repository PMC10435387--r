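# Coalescent simulator, clone/selfing injection, QC corruption.

test_that("zero mutation rate yields zero variant sites", {
  m <- demographic_model("A", ne = 1000, mutation_rate = 0, n_loci = 10,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 3), seed = 1)
  expect_identical(nrow(d$genotypes$sites), 0L)
})

test_that("identical seeds give identical datasets, different seeds differ", {
  m <- demographic_model("A", ne = 5000, mutation_rate = 1e-7, n_loci = 30,
                         locus_length = 1000)
  d1 <- simulate_coalescent(m, c(A = 4), seed = 42)
  d2 <- simulate_coalescent(m, c(A = 4), seed = 42)
  d3 <- simulate_coalescent(m, c(A = 4), seed = 43)
  expect_identical(d1, d2)
  expect_false(identical(d1$genotypes$sites, d3$genotypes$sites))
})

test_that("simulated tables satisfy the container invariants", {
  m <- demographic_model("A", ne = 5000, mutation_rate = 1e-7, n_loci = 40,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 6), seed = 5)
  g <- d$genotypes
  expect_silent(validate_genotype_table(g))
  expect_true(all(g$ad_ref + g$ad_alt <= g$dp))
  expect_true(all(g$sites$ann %in% c("synonymous", "nonsynonymous",
                                     "noncoding")))
  expect_true(all(tapply(g$sites$pos, g$sites$chrom,
                         function(p) all(diff(p) > 0))))
  # truth labels: one population per sample, clone groups disjoint
  expect_identical(anyDuplicated(d$truth$sample), 0L)
  expect_false(anyNA(d$truth$population))
})

test_that("mean pairwise diversity matches E[pi] = 4 Ne mu within 3 SE", {
  ne <- 10000; mu <- 1e-8
  m <- demographic_model("A", ne = ne, mutation_rate = mu, n_loci = 10000,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 2), seed = 7)
  pl <- per_locus_pi(d, 1000)
  se <- stats::sd(pl) / sqrt(length(pl))
  expect_lt(abs(mean(pl) - 4 * ne * mu), 3 * se)
})

test_that("two-population divergence matches 2 mu (T + 2 Ne) within 3 SE", {
  ne <- 10000; mu <- 1e-8; split_t <- 20000
  m <- two_pop_model(split_t, ne = ne, mutation_rate = mu, n_loci = 2000,
                     locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 1, B = 1), seed = 3)
  g <- d$genotypes
  pa <- gt_dosage(gt_subset_samples(g, "A01")) / 2
  pb <- gt_dosage(gt_subset_samples(g, "B01")) / 2
  dxy_site <- pa * (1 - pb) + pb * (1 - pa)
  sums <- tapply(dxy_site, g$sites$chrom, sum)
  per_loc <- rep(0, 2000)
  names(per_loc) <- sprintf("locus%04d", 1:2000)
  per_loc[names(sums)] <- sums
  per_loc <- per_loc / 1000
  se <- stats::sd(per_loc) / sqrt(2000)
  expect_lt(abs(mean(per_loc) - 2 * mu * (split_t + 2 * ne)), 3 * se)
})

test_that("inconsistent split topologies are rejected", {
  expect_error(demographic_model(c("A", "B"), splits = NULL),
               "no splits")
  expect_error(demographic_model(
    c("A", "B", "C"),
    splits = data.frame(derived = c("A", "C"), ancestral = c("B", "A"),
                        time = c(100, 200))),
    "already merged")
  expect_error(demographic_model(
    c("A", "B"),
    splits = data.frame(derived = "A", ancestral = "B", time = -5)),
    "strictly positive")
  expect_error(demographic_model(
    c("A", "B"),
    splits = data.frame(derived = "A", ancestral = "B", time = 10),
    pulses = data.frame(source = "A", target = "B", time = 5,
                        fraction = 1.2)),
    "strictly in")
})

test_that("error-free clonemate copies are exact and selfed offspring obey Mendel", {
  m <- demographic_model("P", ne = 10000, mutation_rate = 1e-7, n_loci = 50,
                         locus_length = 1000)
  d0 <- simulate_coalescent(m, c(P = 10), seed = 2)
  d <- inject_clones_and_selfs(d0, n_clonemate_copies = 2, n_selfed = 3,
                               genotyping_error_rate = 0, seed = 9)
  g <- d$genotypes
  expect_identical(unname(g$ga[, "P01_clone"]), unname(g$ga[, "P01"]))
  expect_identical(unname(g$gb[, "P01_clone"]), unname(g$gb[, "P01"]))
  for (p in c("P03", "P04", "P05")) {
    o <- paste0(p, "_self")
    ph <- g$ga[, p] != g$gb[, p]
    oh <- g$ga[, o] != g$gb[, o]
    expect_true(all(ph[oh]))            # offspring het only where parent het
    hom <- !ph
    expect_identical(g$ga[hom, o], g$ga[hom, p])  # hom sites inherited
  }
  # truth bookkeeping: clone groups disjoint, selfed_from recorded
  cg <- d$truth$clone_group[!is.na(d$truth$clone_group)]
  expect_identical(sort(unique(table(cg))), 2L)   # source + one copy
  expect_setequal(d$truth$selfed_from[!is.na(d$truth$selfed_from)],
                  c("P03", "P04", "P05"))
  expect_error(inject_clones_and_selfs(d0, 1, 0, genotyping_error_rate = 2),
               "\\[0, 1\\]")
})

test_that("selfed het ratio concentrates at 1/2 (binomial expectation)", {
  set.seed(31)
  n_sites <- 400
  parent_a <- rep(0L, n_sites)
  parent_b <- rep(1L, n_sites)   # fully heterozygous parent
  n_rep <- 1000
  ga <- matrix(parent_a, n_sites, n_rep)
  gb <- matrix(parent_b, n_sites, n_rep)
  gt <- make_gt(ga, gb)
  d <- inject_clones_and_selfs(make_dataset(gt), 0, n_rep,
                               genotyping_error_rate = 0, seed = 77)
  g <- d$genotypes
  off <- g$samples[endsWith(g$samples, "_self")]
  ratios <- vapply(off, function(o)
    mean(g$ga[, o] != g$gb[, o]), numeric(1))
  se <- stats::sd(ratios) / sqrt(n_rep)
  expect_lt(abs(mean(ratios) - 0.5), 3 * se)
})

test_that("corruption with all counts zero is the identity", {
  m <- demographic_model("A", ne = 5000, mutation_rate = 1e-7, n_loci = 20,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 4), seed = 6)
  d2 <- corrupt_for_qc(d, corruption_spec(), seed = 1)
  expect_identical(d$genotypes, d2$genotypes)
})

test_that("corruption counts are exact, per filter and per sample", {
  m <- demographic_model("A", ne = 10000, mutation_rate = 1e-7, n_loci = 80,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 20), seed = 8)
  spec <- corruption_spec(n_mq = 4, n_fs = 3, n_qd = 2, n_mqranksum = 2,
                          n_readposranksum = 2, n_sor = 2, n_dp = 2,
                          n_indel_adjacent = 3, n_multiallelic = 3,
                          n_low_gq = 2, n_low_dp = 2, n_conflicting_ad = 2,
                          n_high_missing_samples = 5, missing_rate = 0.25)
  dc <- corrupt_for_qc(d, spec, seed = 4)
  tags <- table(dc$genotypes$sites$qc_tag)
  expect_identical(as.integer(tags[c("mq", "fs", "qd", "mqranksum",
                                     "readposranksum", "sor", "dp",
                                     "indel_adjacent", "indel_record",
                                     "multiallelic")]),
                   c(4L, 3L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  miss_rate <- colMeans(gt_missing(dc$genotypes))
  expect_identical(sum(miss_rate > 0.15), 5L)
  expect_setequal(dc$genotypes$samples[miss_rate > 0.15],
                  dc$high_missing_samples)
  expect_identical(nrow(dc$corrupt_calls), 6L)
})
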