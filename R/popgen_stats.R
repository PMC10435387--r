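# Diversity, differentiation and admixture statistics: nucleotide diversity,
# individual observed heterozygosity, Weir & Cockerham (1984) theta with
# bootstrap significance, and Patterson's D with delete-one block-jackknife
# significance plus the max-over-P1 trio heatmap summary.

#' Per-chromosome nucleotide diversity of a population
#'
#' For each biallelic SNP with allele counts (c0, c1), n = c0 + c1 alleles,
#' the unbiased per-site diversity is pi_i = 2 c0 c1 / (n (n - 1)); the
#' chromosome value is the mean of pi_i over included SNPs (per-SNP mode) or
#' their sum divided by `seq_length` (per-bp mode).
#'
#' @param table a `genotype_table` with complete calls for the chosen
#'   samples (a missing call is an error: diversity uses a no-missing set).
#' @param samples sample ids (e.g. one population); default all.
#' @param seq_length optional per-chromosome sequence length; when given,
#'   values are per bp instead of per SNP.
#' @return named numeric vector of per-chromosome diversity.
#' @export
nucleotide_diversity <- function(table, samples = NULL, seq_length = NULL) {
  if (!is.null(samples)) table <- gt_subset_samples(table, samples)
  if (any(gt_missing(table)))
    stop("missing genotype calls: diversity requires a complete site set")
  d <- gt_dosage(table)
  n <- 2L * ncol(d)
  c1 <- rowSums(d)
  pi_i <- 2 * c1 * (n - c1) / (n * (n - 1))
  chrom <- table$sites$chrom
  if (is.null(seq_length)) {
    vapply(split(pi_i, chrom), mean, numeric(1))
  } else {
    sums <- vapply(split(pi_i, chrom), sum, numeric(1))
    sums / seq_length
  }
}

#' Observed heterozygosity of one individual
#'
#' (number of heterozygous sites) / (number of sites with a genotype call).
#'
#' @param table a `genotype_table`.
#' @param sample sample id or column index.
#' @return a fraction in \[0, 1\].
#' @export
individual_heterozygosity <- function(table, sample) {
  if (is.character(sample)) sample <- match(sample, table$samples)
  called <- !is.na(table$ga[, sample]) & !is.na(table$gb[, sample])
  if (!sum(called)) stop("no called sites for sample")
  sum(table$ga[called, sample] != table$gb[called, sample]) / sum(called)
}

# Weir & Cockerham (1984) per-site variance components a (among populations),
# b (among individuals within populations), c (within individuals), for r
# populations scored at one biallelic site. Inputs per population: n_i
# (individuals with calls), p_i (alt-allele frequency), h_i (observed het
# fraction). Returns c(a, b, c).
wc_site_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# per-site components for a pair of sample index vectors; drops sites where
# either population has < 2 called individuals or no variation overall.
# Returns the component matrix plus each retained site's chromosome (the
# bootstrap resampling unit).
wc_components_table <- function(table, idx_a, idx_b) {
  d <- gt_dosage(table)
  da <- d[, idx_a, drop = FALSE]
  db <- d[, idx_b, drop = FALSE]
  na_i <- rowSums(!is.na(da))
  nb_i <- rowSums(!is.na(db))
  pa <- rowMeans(da, na.rm = TRUE) / 2
  pb <- rowMeans(db, na.rm = TRUE) / 2
  ha <- rowMeans(da == 1L, na.rm = TRUE)
  hb <- rowMeans(db == 1L, na.rm = TRUE)
  ok <- na_i >= 2 & nb_i >= 2
  comp <- t(vapply(which(ok), function(i)
    wc_site_components(c(na_i[i], nb_i[i]), c(pa[i], pb[i]),
                       c(ha[i], hb[i])), numeric(3)))
  list(comp = comp, chrom = table$sites$chrom[ok])
}

#' Pairwise Weir-Cockerham F_ST with bootstrap significance
#'
#' Theta is the ratio-of-sums estimator sum(a) / sum(a + b + c) over sites;
#' the p-value is the fraction of `n_boot` bootstrap replicates with
#' theta <= 0 (one-sided test of differentiation). Bootstrap resampling is
#' across loci (chromosomes), not individual SNPs: sites on one locus share
#' a genealogy, and resampling them independently understates the sampling
#' variance.
#'
#' @param table a `genotype_table`.
#' @param pop_a,pop_b character vectors of sample ids (>= 2 each).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list with `theta`, `p_value`, `n_sites`, `n_loci`, `n_boot`.
#' @export
pairwise_fst <- function(table, pop_a, pop_b, n_boot = 1000L, seed = 1L) {
  if (length(pop_a) < 2 || length(pop_b) < 2)
    stop("each population needs at least 2 individuals")
  idx_a <- match(pop_a, table$samples)
  idx_b <- match(pop_b, table$samples)
  if (anyNA(c(idx_a, idx_b))) stop("unknown sample id")
  wc <- wc_components_table(table, idx_a, idx_b)
  ok <- stats::complete.cases(wc$comp)
  comp <- wc$comp[ok, , drop = FALSE]
  chrom <- wc$chrom[ok]
  if (!nrow(comp)) stop("no usable sites")
  theta <- sum(comp[, 1]) / sum(rowSums(comp))
  # per-locus component sums are sufficient for the bootstrap
  a_l <- rowsum(comp[, 1], chrom)
  abc_l <- rowsum(rowSums(comp), chrom)
  set.seed(as.integer(seed))
  L <- nrow(a_l)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(L, L, replace = TRUE)
    sum(a_l[i]) / sum(abc_l[i])
  }, numeric(1))
  list(theta = theta, p_value = mean(boot <= 0), n_sites = nrow(comp),
       n_loci = L, n_boot = as.integer(n_boot))
}

#' All-pairs F_ST matrix
#'
#' @param table a `genotype_table`.
#' @param pop_map data.frame with columns `sample`, `population`.
#' @param n_boot,seed passed to \link{pairwise_fst}.
#' @return list with symmetric matrices `theta` and `p_value`.
#' @export
fst_matrix <- function(table, pop_map, n_boot = 1000L, seed = 1L) {
  pops <- unique(pop_map$population)
  k <- length(pops)
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- pairwise_fst(table,
                      pop_map$sample[pop_map$population == pops[i]],
                      pop_map$sample[pop_map$population == pops[j]],
                      n_boot = n_boot, seed = seed)
    th[i, j] <- th[j, i] <- r$theta
    pv[i, j] <- pv[j, i] <- r$p_value
  }
  list(theta = th, p_value = pv)
}

#' Patterson's D from per-site allele frequencies
#'
#' D = sum\[(1-p1) p2 p3 (1-pO) - p1 (1-p2) p3 (1-pO)\] /
#' sum\[(1-p1) p2 p3 (1-pO) + p1 (1-p2) p3 (1-pO)\], the ABBA-BABA site
#' asymmetry polarized by the outgroup frequency pO. The standard error comes
#' from a delete-one jackknife over `blocks` contiguous equal-count site
#' blocks; Z = D / SE and p is the two-sided normal tail.
#'
#' @param p1,p2,p3,pO numeric vectors of derived/alt allele frequencies per
#'   site (pO may be polymorphic).
#' @param blocks number of jackknife blocks (default 20).
#' @param chrom optional per-site chromosome/locus labels (sites in input
#'   order); when given, block boundaries fall only between chromosomes so
#'   linked sites are never split across blocks.
#' @return a `trio_d_result`: list with `d`, `se`, `z`, `p_value`,
#'   `n_blocks`, `n_sites`, `abba`, `baba`.
#' @export
patterson_d <- function(p1, p2, p3, pO, blocks = 20L, chrom = NULL) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(pO))
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  num <- abba - baba
  den <- abba + baba
  if (sum(den) == 0) stop("undefined D: no informative sites (denominator 0)")
  d <- sum(num) / sum(den)
  m <- length(p1)
  blocks <- max(2L, min(as.integer(blocks), m))
  if (is.null(chrom)) {
    bl <- cut(seq_len(m), blocks, labels = FALSE)
  } else {
    stopifnot(length(chrom) == m)
    target <- m / blocks
    rl <- rle(as.character(chrom))
    bl_of_chrom <- integer(length(rl$lengths))
    acc <- 0L; b <- 1L
    for (i in seq_along(rl$lengths)) {
      if (acc >= target && b < blocks) { b <- b + 1L; acc <- 0L }
      bl_of_chrom[i] <- b
      acc <- acc + rl$lengths[i]
    }
    bl <- rep.int(bl_of_chrom, rl$lengths)
  }
  num_b <- vapply(split(num, bl), sum, numeric(1))
  den_b <- vapply(split(den, bl), sum, numeric(1))
  keep <- (sum(den) - den_b) > 0 & den_b > 0
  d_j <- (sum(num) - num_b[keep]) / (sum(den) - den_b[keep])
  nb <- sum(keep)
  se <- sqrt((nb - 1) / nb * sum((d_j - mean(d_j))^2))
  z <- if (se > 0) d / se else NA_real_
  # the SE rests on nb blocks, so reference t with nb - 1 df rather than the
  # normal: with 20 blocks the normal tail is visibly anticonservative
  p <- if (is.na(z)) NA_real_ else 2 * stats::pt(-abs(z), df = nb - 1)
  structure(list(d = d, se = se, z = z, p_value = p, n_blocks = nb,
                 n_sites = m, abba = sum(abba), baba = sum(baba)),
            class = "trio_d_result")
}

#' @export
print.trio_d_result <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (SE %.4f, Z = %.2f, p = %.3g, %d sites)\n",
              x$d, x$se, x$z, x$p_value, x$n_sites))
  invisible(x)
}

# population alt-allele frequency per site from a genotype table
pop_freq <- function(table, samples) {
  d <- gt_dosage(gt_subset_samples(table, samples))
  rowMeans(d, na.rm = TRUE) / 2
}

#' Patterson's D for a population trio from a genotype table
#'
#' @param table a `genotype_table`.
#' @param pop_map data.frame with `sample`, `population`.
#' @param p1,p2,p3,outgroup population names.
#' @param blocks jackknife blocks.
#' @return a `trio_d_result` with the trio recorded in `$trio`.
#' @export
patterson_d_trio <- function(table, pop_map, p1, p2, p3, outgroup,
                             blocks = 20L) {
  f <- function(p) pop_freq(table, pop_map$sample[pop_map$population == p])
  q1 <- f(p1); q2 <- f(p2); q3 <- f(p3); qo <- f(outgroup)
  ok <- !is.na(q1) & !is.na(q2) & !is.na(q3) & !is.na(qo)
  res <- patterson_d(q1[ok], q2[ok], q3[ok], qo[ok], blocks = blocks,
                     chrom = table$sites$chrom[ok])
  res$trio <- c(P1 = p1, P2 = p2, P3 = p3, O = outgroup)
  res
}

#' Summarize trio D results into the (P2, P3) heatmap
#'
#' For each ordered (P2, P3) pair, reports the D, Z and p of the trio that
#' minimizes the p-value over all populations placed at P1 (the "most
#' significant D" cell); ties break on larger |Z| then first occurrence.
#'
#' @param results data.frame with columns `P1`, `P2`, `P3`, `d`, `z`,
#'   `p_value` (one row per computed trio).
#' @return data.frame with one row per (P2, P3) and the chosen `P1`.
#' @export
d_heatmap_summarize <- function(results) {
  need <- c("P1", "P2", "P3", "d", "z", "p_value")
  if (!all(need %in% names(results))) stop("results must have ", paste(need, collapse = ", "))
  key <- paste(results$P2, results$P3, sep = "\r")
  picked <- lapply(split(seq_len(nrow(results)), key), function(i) {
    r <- results[i, , drop = FALSE]
    ord <- order(r$p_value, -abs(r$z))
    r[ord[1], , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(out$P2, out$P3), , drop = FALSE]
}
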