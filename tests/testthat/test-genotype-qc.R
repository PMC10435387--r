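# SNP filter cascade: boundary semantics, coordinate conventions, thinning,
# idempotence and exact agreement with corruption truth tags.

test_that("SNPs within 20 bp of an indel are removed, inclusive boundary", {
  ga <- matrix(0L, 4, 2); gb <- matrix(1L, 4, 2)
  gt <- make_gt(ga, gb, pos = c(1000L, 1020L, 2000L, 2021L),
                type = c("snp", "indel", "snp", "indel"))
  out <- mask_near_variants(gt, 20L)
  expect_identical(out$sites$pos, 2000L)   # 1000 removed (|d|=20), 2000 kept (|d|=21)
  # no indels: unchanged
  gt2 <- make_gt(ga, gb, pos = c(1000L, 1020L, 2000L, 2021L))
  expect_identical(mask_near_variants(gt2, 20L), gt2)
  # window 0: only shared positions on the same chromosome
  gt3 <- make_gt(ga, gb, chrom = c("c1", "c2", "c1", "c1"),
                 pos = c(1000L, 1000L, 2000L, 3000L),
                 type = c("snp", "indel", "snp", "indel"))
  out3 <- mask_near_variants(gt3, 0L)
  expect_identical(out3$sites$pos, c(1000L, 2000L))
  unsorted <- make_gt(ga, gb, pos = c(2L, 5L, 8L, 9L),
                      type = c("snp", "indel", "snp", "snp"))
  unsorted$sites$pos <- c(5L, 2L, 8L, 9L)
  expect_error(mask_near_variants(unsorted, 20L), "sorted")
})

test_that("hard filters use strict inequalities and let NA metrics pass", {
  ga <- matrix(0L, 6, 2); gb <- matrix(1L, 6, 2)
  gt <- make_gt(ga, gb,
                MQ = c(39.9, 40.0, 50, 50, 50, 50),
                FS = c(1, 60.0, 60.1, 1, 1, 1),
                QD = c(25, 10.0, 25, 9.9, 25, 25),
                SOR = c(1, 3.0, 1, 1, 3.1, 1),
                MQRankSum = c(0, 2.5, 0, 0, 0, NA),
                ReadPosRankSum = c(0, -2.5, 0, 0, 0, 2.6))
  res <- apply_hard_filters(gt, filter_config())
  # site 1: MQ 39.9 < 40 -> removed; site 2: every metric exactly at its
  # threshold -> retained; sites 3-5 each breach one; site 6 has NA MQRankSum
  # (passes) but ReadPosRankSum 2.6 (fails)
  expect_identical(res$table$sites$pos, gt$sites$pos[2])
  expect_identical(res$report$input, 6L)
  expect_identical(res$report$removed, 5L)
  gt$sites$MQ <- as.character(gt$sites$MQ)
  expect_error(apply_hard_filters(gt), "non-numeric")
})

test_that("DP ceiling is 2 x mean site DP of the input", {
  ga <- matrix(0L, 5, 2); gb <- matrix(1L, 5, 2)
  gt <- make_gt(ga, gb)
  gt$sites$DP <- c(100, 100, 100, 100, 250)   # mean 130, ceiling 260: keep all
  expect_identical(nrow(apply_hard_filters(gt)$table$sites), 5L)
  gt$sites$DP <- c(100, 100, 100, 100, 900)   # mean 240, ceiling 480: drop 900
  expect_identical(nrow(apply_hard_filters(gt)$table$sites), 4L)
})

test_that("genotype masking follows GQ, DP and conflicting-AD rules", {
  ga <- matrix(c(0L, 0L, 0L, 0L), 4, 1)
  gb <- matrix(c(1L, 1L, 0L, 1L), 4, 1)
  gt <- make_gt(ga, gb)
  gt$gq[1, 1] <- 29L                      # GQ 29 -> missing
  gt$dp[2, 1] <- 9L                       # DP 9 -> missing
  gt$ad_alt[3, 1] <- 1L                   # hom-ref with alt read -> missing
  gt$ad_ref[3, 1] <- gt$dp[3, 1] - 1L
  gt$gq[4, 1] <- 30L; gt$dp[4, 1] <- 10L  # boundary het with AD (5,5): kept
  gt$ad_ref[4, 1] <- 5L; gt$ad_alt[4, 1] <- 5L
  out <- mask_genotypes(gt, filter_config())
  expect_identical(is.na(out$ga[, 1]), c(TRUE, TRUE, TRUE, FALSE))
  # hom-alt with a reference read is masked too
  gt2 <- make_gt(matrix(1L, 1, 1), matrix(1L, 1, 1))
  gt2$ad_ref[1, 1] <- 1L; gt2$ad_alt[1, 1] <- gt2$dp[1, 1] - 1L
  expect_true(is.na(mask_genotypes(gt2)$ga[1, 1]))
})

test_that("biallelic selection drops multiallelic and non-SNP records", {
  ga <- matrix(0L, 3, 2); gb <- matrix(1L, 3, 2)
  gt <- make_gt(ga, gb)
  gt$sites$alt[2] <- "T,G"
  gt$sites$type[3] <- "indel"
  out <- select_biallelic(gt)
  expect_identical(out$sites$pos, gt$sites$pos[1])
  gt2 <- make_gt(ga, gb)
  expect_identical(select_biallelic(gt2), gt2)
})

test_that("region intersection maps 1-based sites onto 0-based half-open BED", {
  ga <- matrix(0L, 1, 2); gb <- matrix(1L, 1, 2)
  gt <- make_gt(ga, gb, pos = 100L)
  r1 <- data.frame(chrom = "chr1", start = 99, end = 100)   # covers pos 100
  r2 <- data.frame(chrom = "chr1", start = 100, end = 101)  # covers pos 101
  expect_identical(nrow(intersect_regions(gt, r1)$sites), 1L)
  expect_identical(nrow(intersect_regions(gt, r2)$sites), 0L)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  expect_identical(nrow(intersect_regions(gt, empty)$sites), 0L)
  whole <- data.frame(chrom = "chr1", start = 0, end = 1e9)
  expect_identical(intersect_regions(gt, whole)$sites, gt$sites)
  expect_error(intersect_regions(gt, data.frame(chrom = "chr1", start = 10,
                                                end = 5)), "malformed")
})

test_that("annotation subsetting honours class and the no-missing option", {
  ga <- matrix(0L, 6, 2); gb <- matrix(1L, 6, 2)
  gt <- make_gt(ga, gb, ann = c("synonymous", "synonymous", "nonsynonymous",
                                "noncoding", "synonymous", "nonsynonymous"))
  expect_identical(nrow(subset_by_annotation(gt, "synonymous")$sites), 3L)
  expect_identical(nrow(subset_by_annotation(gt, "noncoding")$sites), 1L)
  expect_error(subset_by_annotation(gt, "intergenic"), "unknown")
  gt$ga[1, 1] <- NA_integer_; gt$gb[1, 1] <- NA_integer_
  expect_identical(nrow(subset_by_annotation(gt, "synonymous",
                                             drop_missing = TRUE)$sites), 2L)
  # complete table: drop_missing is a no-op
  gt2 <- make_gt(ga, gb, ann = "synonymous")
  expect_identical(subset_by_annotation(gt2, "synonymous",
                                        drop_missing = TRUE),
                   subset_by_annotation(gt2, "synonymous"))
})

test_that("thinning keeps the greedy left-to-right set", {
  ga <- matrix(0L, 4, 2); gb <- matrix(1L, 4, 2)
  gt <- make_gt(ga, gb, pos = c(100L, 2900L, 3200L, 7000L))
  out <- thin_by_distance(gt, 3000L)
  expect_identical(out$sites$pos, c(100L, 3200L, 7000L))
  one <- make_gt(matrix(0L, 1, 2), matrix(1L, 1, 2))
  expect_identical(thin_by_distance(one, 3000L)$sites, one$sites)
  expect_identical(thin_by_distance(gt, 1L)$sites, gt$sites)
})

test_that("thinned output never has same-chromosome spacing under the minimum", {
  m <- demographic_model("A", ne = 10000, mutation_rate = 5e-7, n_loci = 10,
                         locus_length = 20000)
  d <- simulate_coalescent(m, c(A = 4), seed = 14)
  out <- thin_by_distance(d$genotypes, 3000L)
  gaps <- unlist(tapply(out$sites$pos, out$sites$chrom, diff))
  expect_true(all(gaps >= 3000))
})

test_that("sample missing-rate filter excludes strictly above the cutoff", {
  ga <- matrix(0L, 10, 3); gb <- matrix(1L, 10, 3)
  gt <- make_gt(ga, gb)
  gt$ga[1:2, 2] <- NA_integer_; gt$gb[1:2, 2] <- NA_integer_   # 20%
  res <- sample_missing_filter(gt, 0.15)
  expect_identical(res$excluded, "s02")
  expect_identical(sample_missing_filter(make_gt(ga, gb), 0.15)$excluded,
                   character(0))
  gt$ga[1, 3] <- NA_integer_; gt$gb[1, 3] <- NA_integer_
  expect_setequal(sample_missing_filter(gt, 0)$excluded, c("s02", "s03"))
})

test_that("the cascade is idempotent, monotone and reconciles its report", {
  m <- demographic_model("A", ne = 10000, mutation_rate = 1e-7, n_loci = 60,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 10), seed = 21)
  d <- corrupt_for_qc(d, corruption_spec(
    n_mq = 5, n_fs = 3, n_sor = 2, n_indel_adjacent = 2, n_multiallelic = 3,
    n_low_gq = 3, n_high_missing_samples = 2, missing_rate = 0.3), seed = 22)
  r1 <- qc_cascade(d$genotypes, filter_config(), filter_samples = TRUE)
  r2 <- qc_cascade(r1$table, filter_config(), filter_samples = TRUE)
  expect_identical(r2$table$sites, r1$table$sites)
  expect_identical(r2$table$samples, r1$table$samples)
  expect_true(all(r1$report$input == r1$report$removed + r1$report$retained))
  key <- function(t) paste(t$sites$chrom, t$sites$pos)
  expect_true(all(key(r1$table) %in% key(d$genotypes)))
})

test_that("cascade removal matches the corruption truth tags exactly", {
  m <- demographic_model("A", ne = 10000, mutation_rate = 1e-7, n_loci = 60,
                         locus_length = 1000)
  d <- simulate_coalescent(m, c(A = 10), seed = 33)
  d <- corrupt_for_qc(d, corruption_spec(
    n_mq = 4, n_fs = 3, n_qd = 2, n_mqranksum = 2, n_readposranksum = 2,
    n_sor = 2, n_dp = 2, n_indel_adjacent = 3, n_multiallelic = 3),
    seed = 34)
  g <- d$genotypes
  out <- qc_cascade(g, filter_config())
  key <- function(s) paste(s$chrom, s$pos)
  removed <- setdiff(key(g$sites), key(out$table$sites))
  tagged <- key(g$sites[!is.na(g$sites$qc_tag), ])
  # precision = recall = 1: the removed set is exactly the tagged set
  expect_setequal(removed, tagged)
})
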