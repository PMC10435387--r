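# Chloroplast pipeline: calling rules, masking, haplotype collapsing,
# parsimony-informative selection, median-joining networks.

# minimal hand-built pileup: one sample, explicit counts
tiny_pileup <- function(counts, ref) list(ref = ref, samples = list(S1 = counts))

test_that("variant calling uses strict > 0.5 fraction and > 0.3 x median coverage", {
  ref <- rep("A", 7)
  counts <- matrix(0L, 7, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[, "A"] <- 200L                    # median coverage 200
  counts[1, ] <- c(100L, 100L, 0L, 0L)     # fraction exactly 0.50: not variable
  counts[2, ] <- c(98L, 102L, 0L, 0L)      # 0.51: variable
  counts[3, ] <- c(49L, 51L, 0L, 0L)       # cov 100 = 0.5 x median, frac 0.51: variable
  counts[4, ] <- c(29L, 31L, 0L, 0L)       # cov 60 = 0.3 x median, not strictly above
  res <- call_cp_variants(tiny_pileup(counts, ref))
  expect_identical(res$positions, c(2L, 3L))
  zero <- matrix(0L, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(call_cp_variants(tiny_pileup(zero, rep("A", 3))),
               "zero-coverage")
})

test_that("generator pileups are called and masked to exact counts", {
  sim <- simulate_cp_pileup(6, genome_length = 8000, n_variable = 60,
                            n_microsat_artifacts = 5,
                            n_hairpin_artifacts = 4,
                            median_coverage = 120, seed = 41)
  called <- call_cp_variants(sim$pileup)
  expect_setequal(called$positions, sim$truth$variable_pos)
  masked <- apply_masks(called$positions, sim$masks)
  expect_setequal(masked$positions, sim$truth$genuine_pos)
  expect_identical(as.integer(masked$counts["microsatellite"]), 5L)
  expect_identical(as.integer(masked$counts["hairpin"]), 4L)
  # dropping a true variant's coverage below 0.3 x median removes it
  p <- sim$truth$genuine_pos[1]
  id <- names(sim$pileup$samples)
  for (s in id) {
    row <- sim$pileup$samples[[s]][p, ]
    sim$pileup$samples[[s]][p, ] <- as.integer(round(row * 0.2 * 120 / sum(row)))
  }
  called2 <- call_cp_variants(sim$pileup)
  expect_false(p %in% called2$positions)
})

test_that("mask application is attributed by priority and empty masks are a no-op", {
  pos <- c(10L, 20L, 30L)
  expect_identical(apply_masks(pos, NULL)$positions, pos)
  masks <- data.frame(start = c(9, 9, 19), end = c(10, 10, 20),
                      name = c("microsatellite", "hairpin", "hairpin"))
  res <- apply_masks(pos, masks)
  expect_identical(res$positions, 30L)
  # overlapping masks: position 10 counted once, for the first mask in
  # priority order (microsatellite before hairpin)
  expect_identical(res$removed$mask[res$removed$pos == 10L],
                   "microsatellite")
})

test_that("haplotype collapsing counts identical strings and rejects missing states", {
  seqs <- c(a = "ACGT", b = "ACGT", c = "AGGT", d = "ACGT", e = "AGGA",
            f = "AGGA", g = "AGGA", h = "ACGT", i = "AGGT", j = "AGGA")
  res <- collapse_haplotypes(seqs)
  expect_identical(nrow(res$table), 3L)
  expect_identical(sort(res$table$count), c(2L, 4L, 4L))
  # permutation invariance
  res2 <- collapse_haplotypes(seqs[sample(names(seqs))])
  expect_identical(res2$table, res$table)
  # all identical -> one haplotype
  expect_identical(nrow(collapse_haplotypes(c(x = "AAAA", y = "AAAA"))$table),
                   1L)
  expect_error(collapse_haplotypes(c(x = "ACNT", y = "ACGT")),
               "missing state in sample x at position 3")
  # restriction to positions + per-population counts
  pm <- data.frame(sample = names(seqs),
                   population = rep(c("P", "Q"), 5))
  res3 <- collapse_haplotypes(seqs, positions = c(2L, 4L), pop_map = pm)
  expect_identical(sum(res3$pop_counts), 10L)
})

test_that("parsimony-informative selection drops singletons and invariant columns", {
  seqs <- c("AAG", "AAG", "AAG", "AAG", "AAG",
            "GAG", "GAT", "GAT", "GCT", "GAT")
  # col 1: A x5 / G x5 -> informative; col 2: C singleton -> no;
  # col 3: G x6 / T x4 -> informative
  expect_identical(parsimony_informative(seqs), c(1L, 3L))
  expect_identical(parsimony_informative(c("AG", "AG", "AT")), integer(0))
})

test_that("median-joining reproduces the exhaustively verified Steiner example", {
  # 000 / 110 / 101 as DNA-free binary strings
  obs <- c(h1 = "000", h2 = "110", h3 = "101")
  oracle <- oracle_steiner_3bit(unname(obs))
  expect_identical(oracle$base, 4)
  expect_identical(oracle$best, 3)
  expect_identical(oracle$points, "100")
  net <- median_joining_network(obs, epsilon = 0)
  med <- net$vertices$sequence[!net$vertices$observed]
  expect_identical(med, "100")
  expect_equal(net$mst_length, 3)
  # two haplotypes: one edge at the Hamming distance
  n2 <- median_joining_network(c(a = "AAAA", b = "ATTA"))
  expect_identical(nrow(n2$edges), 1L)
  expect_identical(n2$edges$weight, 2L)
  expect_error(median_joining_network(c(a = "AA", b = "AAA")),
               "equal length")
})

test_that("every observed haplotype is a vertex and the network is connected", {
  set.seed(61)
  for (rep in 1:100) {
    k <- sample(3:7, 1)
    L <- sample(5:9, 1)
    obs <- unique(vapply(seq_len(k), function(i)
      paste(sample(c("A", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    if (length(obs) < 2) next
    names(obs) <- paste0("H", seq_along(obs))
    eps <- sample(0:1, 1)
    net <- median_joining_network(obs, epsilon = eps)
    expect_true(all(obs %in% net$vertices$sequence))
    expect_true(igraph::is_connected(net$graph))
    expect_true(all(net$edges$weight >= 1))
    if (eps == 0) {
      # total spanning length never exceeds the observed-only MST
      d <- meadowpop:::hamming_matrix(unname(obs))
      expect_lte(net$mst_length, meadowpop:::mst_length(d))
    }
  }
})

test_that("mutation steps report Hamming and network path distances", {
  obs <- c(a = "AAAAAA", b = "AAAATT", c = "TTAAAA", d = "TTAATT")
  net <- median_joining_network(obs, epsilon = 0)
  same <- count_mutation_steps(net, "a", "a")
  expect_identical(same$hamming, 0L)
  expect_equal(same$path, 0)
  r <- count_mutation_steps(net, c("a", "b"), c("c", "d"))
  expect_identical(r$hamming, 2L)
  expect_gte(r$path, r$hamming)
  # toy clades at Hamming 4
  r2 <- count_mutation_steps(net, "a", "d")
  expect_identical(r2$hamming, 4L)
  expect_gte(r2$path, 4)
})
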