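# Shared fixture builders and independent oracles. The oracles deliberately
# use different algorithms (scalar enumeration, exhaustive search) from the
# package's vectorised implementations.

# Build a genotype_table from explicit allele matrices, filling in passing
# INFO metrics and consistent call-level fields.
make_gt <- function(ga, gb, chrom = NULL, pos = NULL, samples = NULL,
                    ann = "synonymous", type = "snp", MQ = 50, FS = 1,
                    QD = 25, MQRankSum = 0, ReadPosRankSum = 0, SOR = 1,
                    gq = 99L, dp = 40L) {
  ga <- as.matrix(ga); gb <- as.matrix(gb)
  n <- nrow(ga); k <- ncol(ga)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(k))
  storage.mode(ga) <- "integer"; storage.mode(gb) <- "integer"
  sites <- data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep("A", n), alt = rep("T", n), type = rep_len(type, n),
    MQ = rep_len(MQ, n), FS = rep_len(FS, n), QD = rep_len(QD, n),
    MQRankSum = rep_len(MQRankSum, n),
    ReadPosRankSum = rep_len(ReadPosRankSum, n),
    SOR = rep_len(SOR, n), DP = rep(40 * k, n),
    ann = rep_len(ann, n), qc_tag = NA_character_,
    stringsAsFactors = FALSE)
  dpm <- matrix(as.integer(dp), n, k)
  gqm <- matrix(as.integer(gq), n, k)
  ad_alt <- matrix(0L, n, k)
  het <- !is.na(ga) & ga != gb
  homalt <- !is.na(ga) & ga == gb & ga > 0L
  ad_alt[het] <- dpm[het] %/% 2L
  ad_alt[homalt] <- dpm[homalt]
  genotype_table(sites, ga, gb, gqm, dpm, dpm - ad_alt, ad_alt, samples)
}

# Wrap a genotype_table as a minimal simulated_dataset (for the injection
# and corruption operations).
make_dataset <- function(gt, population = "P") {
  structure(list(
    genotypes = gt,
    truth = data.frame(sample = gt$samples,
                       population = rep_len(population,
                                            length(gt$samples)),
                       clone_group = NA_character_,
                       selfed_from = NA_character_,
                       stringsAsFactors = FALSE),
    true_tree_times = numeric(0), seed = 0L, model = NULL),
    class = "simulated_dataset")
}

# Oracle: per-site diversity by enumerating every allele pair.
oracle_pi_site <- function(alleles) {
  n <- length(alleles)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + (alleles[i] != alleles[j])
    cnt <- cnt + 1
  }
  tot / cnt
}

# Oracle: Weir & Cockerham (1984) theta, written scalar per allele (summing
# components over both alleles of each biallelic site) with explicit loops.
oracle_wc_theta <- function(geno_a, geno_b) {
  num <- 0; den <- 0
  r <- 2
  for (s in seq_len(nrow(geno_a))) {
    xa <- geno_a[s, ]; xb <- geno_b[s, ]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) next
    for (allele in c(1, 0)) {
      dose <- function(x) if (allele == 1) x else 2 - x
      n1 <- length(xa); n2 <- length(xb)
      p1 <- sum(dose(xa)) / (2 * n1)
      p2 <- sum(dose(xb)) / (2 * n2)
      h1 <- sum(xa == 1) / n1   # het calls are het for either allele
      h2 <- sum(xb == 1) / n2
      nbar <- (n1 + n2) / 2
      nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
        s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# Oracle: best single Steiner point for a set of binary strings, by
# exhaustive enumeration over the full hypercube; returns the minimum
# achievable spanning-tree length and the optimal added points.
oracle_steiner_3bit <- function(seqs) {
  L <- nchar(seqs[1])
  all_pts <- apply(expand.grid(rep(list(c("0", "1")), L)), 1, paste,
                   collapse = "")
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  mstlen <- function(ss) {
    n <- length(ss)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- ham(ss[i], ss[j])
    g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                             mode = "undirected")
    sum(igraph::E(igraph::mst(g))$weight)
  }
  base <- mstlen(seqs)
  best <- base; best_pts <- character()
  for (p in setdiff(all_pts, seqs)) {
    v <- mstlen(c(seqs, p))
    if (v < best) { best <- v; best_pts <- p }
    else if (v == best && best < base) best_pts <- c(best_pts, p)
  }
  list(base = base, best = best, points = best_pts)
}

# Quick per-locus pairwise diversity (per site) from a simulated dataset.
per_locus_pi <- function(dataset, locus_length) {
  g <- dataset$genotypes
  hap <- cbind(g$ga, g$gb)
  n <- ncol(hap)
  dac <- rowSums(hap)
  pi_site <- 2 * dac * (n - dac) / (n * (n - 1))
  sums <- tapply(pi_site, g$sites$chrom, sum)
  n_loci <- dataset$model$n_loci
  out <- rep(0, n_loci)
  names(out) <- sprintf("locus%04d", seq_len(n_loci))
  out[names(sums)] <- sums
  out / locus_length
}
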