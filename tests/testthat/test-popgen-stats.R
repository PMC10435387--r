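# Diversity, F_ST and Patterson's D against enumeration and brute-force
# oracles, plus null-calibration properties.

test_that("per-site diversity matches pair enumeration", {
  # one site, two diploids both 0/1: alleles {0,1,0,1} -> 4/6
  ga <- matrix(0L, 1, 2); gb <- matrix(1L, 1, 2)
  gt <- make_gt(ga, gb)
  expect_equal(unname(nucleotide_diversity(gt)), 4 / 6)
  expect_equal(oracle_pi_site(c(0, 1, 0, 1)), 4 / 6)
  # monomorphic sites give zero
  gt0 <- make_gt(matrix(0L, 5, 3), matrix(0L, 5, 3))
  expect_equal(unname(nucleotide_diversity(gt0)), 0)
  # random instances <= 10 alleles equal the enumeration oracle
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    ga <- matrix(rbinom(3 * k, 1, 0.4), 3, k)
    gb <- matrix(rbinom(3 * k, 1, 0.4), 3, k)
    gt <- make_gt(ga, gb)
    got <- unname(nucleotide_diversity(gt))
    want <- mean(vapply(1:3, function(s)
      oracle_pi_site(c(ga[s, ], gb[s, ])), numeric(1)))
    expect_equal(got, want)
  }
  # sample-order invariance
  ga <- matrix(rbinom(40, 1, 0.5), 10, 4)
  gb <- matrix(rbinom(40, 1, 0.5), 10, 4)
  gt <- make_gt(ga, gb)
  expect_equal(nucleotide_diversity(gt),
               nucleotide_diversity(gt_subset_samples(gt, 4:1)))
  # missing calls are an error
  gtm <- make_gt(ga, gb)
  gtm$ga[1, 1] <- NA_integer_; gtm$gb[1, 1] <- NA_integer_
  expect_error(nucleotide_diversity(gtm), "missing")
})

test_that("simulated panmictic diversity matches 4 Ne mu via nucleotide_diversity", {
  ne <- 10000; mu <- 5e-8
  m <- demographic_model("A", ne = ne, mutation_rate = mu, n_loci = 2000,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 5), seed = 77)
  pi_loc <- nucleotide_diversity(d$genotypes, seq_length = 1000)
  # loci with zero variants are absent from the table; add them as zeros
  full <- rep(0, 2000)
  full[match(names(pi_loc), sprintf("locus%04d", 1:2000))] <- pi_loc
  se <- stats::sd(full) / sqrt(2000)
  expect_lt(abs(mean(full) - 4 * ne * mu), 3 * se)
})

test_that("individual heterozygosity is the het fraction of called sites", {
  ga <- matrix(0L, 10, 1)
  gb <- matrix(c(rep(1L, 3), rep(0L, 7)), 10, 1)
  gt <- make_gt(ga, gb)
  expect_equal(individual_heterozygosity(gt, 1), 0.3)
  # missing calls leave the denominator
  gt$ga[10, 1] <- NA_integer_; gt$gb[10, 1] <- NA_integer_
  expect_equal(individual_heterozygosity(gt, "s01"), 3 / 9)
  gt0 <- make_gt(matrix(0L, 4, 1), matrix(0L, 4, 1))
  expect_equal(individual_heterozygosity(gt0, 1), 0)
  gt0$ga[] <- NA_integer_; gt0$gb[] <- NA_integer_
  expect_error(individual_heterozygosity(gt0, 1), "no called")
})

test_that("H_obs matches the HWE expectation on simulated data", {
  m <- demographic_model("A", ne = 10000, mutation_rate = 1e-7,
                         n_loci = 400, locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 30), seed = 55)
  g <- d$genotypes
  hobs <- vapply(g$samples, function(s) individual_heterozygosity(g, s),
                 numeric(1))
  p <- rowMeans(gt_dosage(g)) / 2
  expected <- mean(2 * p * (1 - p)) * nrow(g$sites) / nrow(g$sites)
  se <- stats::sd(hobs) / sqrt(length(hobs))
  expect_lt(abs(mean(hobs) - expected), 3 * se + 0.01 * expected)
})

test_that("F_ST is 1 under complete fixation and errors on single-individual pops", {
  ga <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  gt <- make_gt(ga, ga)
  r <- pairwise_fst(gt, c("s01", "s02"), c("s03", "s04"), n_boot = 50)
  expect_equal(r$theta, 1)
  expect_error(pairwise_fst(gt, "s01", c("s03", "s04")), "at least 2")
})

test_that("F_ST equals the brute-force variance-component oracle to 1e-12", {
  # small worked instance: 2 pops x 3 diploids x 2 loci, explicit genotypes
  dos_a <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L))
  dos_b <- rbind(c(2L, 2L, 1L), c(0L, 0L, 1L))
  ga <- cbind(pmax(dos_a - 1L, 0L), pmax(dos_b - 1L, 0L))
  gb <- cbind(pmin(dos_a, 1L), pmin(dos_b, 1L))
  gt <- make_gt(ga, gb)
  r <- pairwise_fst(gt, c("s01", "s02", "s03"), c("s04", "s05", "s06"),
                    n_boot = 10)
  expect_equal(r$theta, oracle_wc_theta(dos_a, dos_b), tolerance = 1e-12)
  # randomized instances, including missing calls
  set.seed(13)
  for (rep in 1:15) {
    n_sites <- sample(3:8, 1)
    da <- matrix(sample(0:2, n_sites * 4, TRUE), n_sites)
    db <- matrix(sample(0:2, n_sites * 4, TRUE), n_sites)
    da[sample(length(da), 2)] <- NA
    keep <- rowSums(!is.na(da)) >= 2 & rowSums(!is.na(db)) >= 2 &
      (rowSums(da, na.rm = TRUE) + rowSums(db, na.rm = TRUE)) > 0
    ga <- cbind(pmax(da - 1L, 0L), pmax(db - 1L, 0L))
    gb <- cbind(pmin(da, 1L), pmin(db, 1L))
    gt <- make_gt(ga, gb)
    th <- tryCatch(pairwise_fst(gt, paste0("s0", 1:4), paste0("s0", 5:8),
                                n_boot = 5)$theta, error = function(e) NULL)
    if (is.null(th)) next
    expect_equal(th, oracle_wc_theta(da, db), tolerance = 1e-12)
  }
})

test_that("F_ST is near zero with p > 0.05 under panmixia", {
  m <- demographic_model("P", ne = 10000, mutation_rate = 2e-7,
                         n_loci = 150, locus_length = 1000)
  ok <- 0; reps <- 20
  for (i in seq_len(reps)) {
    d <- simulate_coalescent(m, c(P = 12), seed = 100 + i)
    g <- d$genotypes
    r <- pairwise_fst(g, g$samples[1:6], g$samples[7:12], n_boot = 200,
                      seed = i)
    if (abs(r$theta) < 0.05 && r$p_value > 0.05) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("Patterson's D reproduces hand-counted ABBA/BABA patterns", {
  # haploid toy: 3 ABBA sites, 1 BABA site -> D = (3 - 1)/(3 + 1) = 0.5
  p1 <- c(0, 0, 0, 1)
  p2 <- c(1, 1, 1, 0)
  p3 <- c(1, 1, 1, 1)
  pO <- c(0, 0, 0, 0)
  r <- patterson_d(p1, p2, p3, pO, blocks = 2)
  expect_equal(r$d, 0.5)
  expect_equal(r$abba, 3)
  expect_equal(r$baba, 1)
  # swapping P1 and P2 negates D exactly
  r2 <- patterson_d(p2, p1, p3, pO, blocks = 2)
  expect_equal(r2$d, -0.5)
  expect_error(patterson_d(0, 0, 0, 0), "undefined")
})

test_that("D antisymmetry holds on simulated frequencies", {
  set.seed(3)
  p1 <- runif(500); p2 <- runif(500); p3 <- runif(500); pO <- rbinom(500, 1, 0.1)
  a <- patterson_d(p1, p2, p3, pO)
  b <- patterson_d(p2, p1, p3, pO)
  expect_equal(a$d, -b$d)
  expect_equal(a$se, b$se)
})

test_that("admixture pulses drive D positive (power increases with fraction)", {
  base <- function(f) {
    pulses <- if (f > 0)
      data.frame(source = "p3", target = "p2", time = 500, fraction = f)
    else NULL
    demographic_model(
      populations = c("p1", "p2", "p3", "o"), ne = 10000,
      splits = data.frame(derived = c("p1", "p3", "o"),
                          ancestral = c("p2", "p2", "p2"),
                          time = c(2000, 6000, 20000)),
      pulses = pulses, mutation_rate = 1e-7, n_loci = 120,
      locus_length = 1000)
  }
  pm <- data.frame(sample = paste0(rep(c("p1", "p2", "p3", "o"), each = 2),
                                   "0", 1:2),
                   population = rep(c("p1", "p2", "p3", "o"), each = 2))
  dvals <- vapply(c(0, 0.05, 0.2), function(f) {
    mean(vapply(1:6, function(s) {
      d <- simulate_coalescent(base(f), c(p1 = 2, p2 = 2, p3 = 2, o = 2),
                               seed = 7000 + s)
      patterson_d_trio(d$genotypes, pm, "p1", "p2", "p3", "o")$d
    }, numeric(1)))
  }, numeric(1))
  expect_true(dvals[2] > dvals[1])
  expect_true(dvals[3] > dvals[2])
  expect_gt(dvals[3], 0.02)
})

test_that("the heatmap cell takes the most significant P1", {
  res <- data.frame(P1 = c("x", "y", "x"), P2 = c("a", "a", "a"),
                    P3 = c("b", "b", "c"),
                    d = c(0.10, 0.30, 0.2), z = c(1.0, 3.5, 1.1),
                    p_value = c(0.20, 0.001, 0.25))
  out <- d_heatmap_summarize(res)
  cell <- out[out$P2 == "a" & out$P3 == "b", ]
  expect_equal(cell$d, 0.30)      # the p = 0.001 trio wins
  expect_identical(cell$P1, "y")
  cell2 <- out[out$P2 == "a" & out$P3 == "c", ]
  expect_equal(cell2$d, 0.2)      # single candidate: cell equals that trio
})
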