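# Fixture generators for the organelle and pangenome stages: chloroplast
# read pileups with artifact positions, and gene presence/absence alignment
# summaries engineered so the presence rules reproduce a known truth matrix.

#' Simulate chloroplast per-position read pileups
#'
#' Emulates BWA-style pileups of a circular plastome across samples carrying
#' a small number of haplotype groups. `n_variable` positions satisfy the
#' calling rules (variant-read fraction > 0.5 in carrier samples, coverage
#' > 0.3 x median); of these, `n_microsat_artifacts` + `n_hairpin_artifacts`
#' are artifacts shared by all samples and listed in the returned masks, the
#' rest are genuine haplotype-defining substitutions.
#'
#' @param n_samples number of samples.
#' @param genome_length plastome length in bp (default 143968, the eelgrass
#'   quadripartite total).
#' @param n_variable total positions engineered to pass the calling rules.
#' @param n_microsat_artifacts,n_hairpin_artifacts artifact position counts.
#' @param median_coverage target per-position coverage (Poisson mean).
#' @param n_haplogroups number of true haplotype groups among samples.
#' @param error_rate per-read probability of a miscalled base at
#'   non-variant positions.
#' @param seed integer seed.
#' @return list of class `cp_pileup_sim`: `pileup` (a `cp_pileup`: `ref`
#'   bases and per-sample count matrices), `masks` (0-based half-open
#'   data.frame start, end, name), `truth` (variable/artifact positions,
#'   carrier groups, per-sample group, true haplotypes over genuine
#'   positions).
#' @export
simulate_cp_pileup <- function(n_samples, genome_length = 143968L,
                               n_variable = 174L,
                               n_microsat_artifacts = 11L,
                               n_hairpin_artifacts = 12L,
                               median_coverage = 500L, n_haplogroups = 3L,
                               error_rate = 0.01, seed = 1L) {
  n_art <- n_microsat_artifacts + n_hairpin_artifacts
  if (n_variable < n_art)
    stop("n_variable must be >= total artifact count")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, genome_length, replace = TRUE)
  pos_all <- sort(sample.int(genome_length, n_variable))
  art_idx <- sort(sample.int(n_variable, n_art))
  art_pos <- pos_all[art_idx]
  genuine_pos <- pos_all[-art_idx]
  ms_pos <- art_pos[seq_len(n_microsat_artifacts)]
  hp_pos <- setdiff(art_pos, ms_pos)
  group <- rep_len(seq_len(n_haplogroups), n_samples)
  names(group) <- sprintf("S%02d", seq_len(n_samples))
  # each genuine position: derived in a random nonempty proper subset of
  # groups (so some sample differs from some other)
  derived_base <- vapply(ref[c(genuine_pos, art_pos)], function(r)
    sample(setdiff(bases, r), 1L), character(1), USE.NAMES = FALSE)
  names(derived_base) <- as.character(c(genuine_pos, art_pos))
  carrier <- lapply(genuine_pos, function(p) {
    k <- sample.int(n_haplogroups - 1L, 1L)
    sort(sample.int(n_haplogroups, k))
  })
  names(carrier) <- as.character(genuine_pos)
  samples <- list()
  for (id in names(group)) {
    cov <- stats::rpois(genome_length, median_coverage)
    cov[cov < 1] <- 1L
    err <- stats::rbinom(genome_length, cov, error_rate)
    counts <- matrix(0L, genome_length, 4L,
                     dimnames = list(NULL, bases))
    ref_i <- match(ref, bases)
    counts[cbind(seq_len(genome_length), ref_i)] <- cov - err
    err_base <- sample.int(4L, genome_length, replace = TRUE)
    clash <- err_base == ref_i
    err_base[clash] <- (err_base[clash] %% 4L) + 1L
    counts[cbind(seq_len(genome_length), err_base)] <-
      counts[cbind(seq_len(genome_length), err_base)] + err
    # variant positions carried by this sample: genuine ones of its group
    mine <- genuine_pos[vapply(carrier, function(g) group[[id]] %in% g,
                               logical(1))]
    vpos <- c(mine, art_pos)   # artifacts appear variant in every sample
    cov_v <- pmax(cov[vpos], as.integer(ceiling(0.4 * median_coverage)))
    vb <- match(derived_base[as.character(vpos)], bases)
    vcount <- as.integer(ceiling(0.9 * cov_v))
    counts[vpos, ] <- 0L
    counts[cbind(vpos, vb)] <- vcount
    counts[cbind(vpos, ref_i[vpos])] <- cov_v - vcount
    samples[[id]] <- counts
  }
  masks <- rbind(
    if (length(ms_pos)) data.frame(start = ms_pos - 1L, end = ms_pos,
                                   name = "microsatellite"),
    if (length(hp_pos)) data.frame(start = hp_pos - 1L, end = hp_pos,
                                   name = "hairpin"))
  hap <- vapply(names(group), function(id) {
    ch <- ref[genuine_pos]
    mine <- vapply(carrier, function(g) group[[id]] %in% g, logical(1))
    ch[mine] <- derived_base[as.character(genuine_pos)][mine]
    paste(ch, collapse = "")
  }, character(1))
  list(pileup = list(ref = ref, samples = samples),
       masks = masks,
       truth = list(variable_pos = pos_all, genuine_pos = genuine_pos,
                    microsat_pos = ms_pos, hairpin_pos = hp_pos,
                    group = group, carrier = carrier,
                    derived_base = derived_base, haplotypes = hap),
       seed = as.integer(seed))
}

#' Simulate pangenome alignment summaries with a known truth PAV matrix
#'
#' Genes are split into cloud / shell / core classes by `class_fractions`;
#' each gene gets a target observation frequency drawn from well-separated
#' class bands (cloud 0.01-0.10, shell 0.40-0.60, core 0.94-1.00) and is
#' made present in exactly `round(freq x n_samples)` samples. Present calls
#' emit either a single strong hit (identity and coverage > 0.6; rule a) or,
#' with probability `split_fraction`, three ~0.3-coverage hits at ~0.9
#' identity on three scaffolds (rule b); absent calls emit nothing or a weak
#' hit. Optionally the last `low_quality_samples` samples are degraded so
#' their present-gene count falls below `qc_threshold`.
#'
#' @param n_genes number of genes.
#' @param class_fractions numeric of length 3, cloud/shell/core fractions
#'   summing to 1.
#' @param n_samples number of (good) samples.
#' @param seed integer seed.
#' @param split_fraction fraction of present calls emitted as rule-b
#'   multi-scaffold hits.
#' @param low_quality_samples number of additional degraded samples.
#' @param qc_threshold present-gene count the degraded samples must not
#'   exceed (default 17500).
#' @return list of class `pav_sim`: `hits` (data.frame gene, sample,
#'   scaffold, identity, coverage), `truth` (presence matrix over good
#'   samples, class, frequency), `samples`, `low_quality`.
#' @export
simulate_pav <- function(n_genes, class_fractions = c(cloud = 0.15,
                                                      shell = 0.10,
                                                      core = 0.75),
                         n_samples, seed = 1L, split_fraction = 0.1,
                         low_quality_samples = 0L, qc_threshold = 17500L) {
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class fractions must sum to 1")
  set.seed(as.integer(seed))
  n_cloud <- round(n_genes * class_fractions[[1]])
  n_shell <- round(n_genes * class_fractions[[2]])
  n_core <- n_genes - n_cloud - n_shell
  cls <- rep(c("cloud", "shell", "core"), c(n_cloud, n_shell, n_core))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  freq <- numeric(n_genes)
  freq[cls == "cloud"] <- stats::runif(n_cloud, 0.01, 0.10)
  freq[cls == "shell"] <- stats::runif(n_shell, 0.40, 0.60)
  freq[cls == "core"] <- stats::runif(n_core, 0.94, 1.00)
  good <- sprintf("G%03d", seq_len(n_samples))
  lowq <- if (low_quality_samples > 0)
    sprintf("LQ%02d", seq_len(low_quality_samples)) else character()
  presence <- matrix(FALSE, n_genes, n_samples,
                     dimnames = list(genes, good))
  for (i in seq_len(n_genes)) {
    k <- round(freq[i] * n_samples)
    if (cls[i] != "cloud") k <- max(k, 1L)
    if (k > 0) presence[i, sample.int(n_samples, k)] <- TRUE
  }
  emit <- function(gene, sample, present) {
    if (present) {
      if (stats::runif(1) < split_fraction) {
        data.frame(gene = gene, sample = sample,
                   scaffold = paste0("sc", 1:3),
                   identity = stats::runif(3, 0.90, 0.99),
                   coverage = stats::runif(3, 0.29, 0.32))
      } else {
        data.frame(gene = gene, sample = sample, scaffold = "sc1",
                   identity = stats::runif(1, 0.90, 0.99),
                   coverage = stats::runif(1, 0.90, 0.99))
      }
    } else if (stats::runif(1) < 0.5) {
      data.frame(gene = gene, sample = sample, scaffold = "sc1",
                 identity = stats::runif(1, 0.20, 0.50),
                 coverage = stats::runif(1, 0.20, 0.50))
    } else NULL
  }
  rows <- vector("list", n_genes * (n_samples + low_quality_samples))
  ri <- 0L
  for (i in seq_len(n_genes)) for (j in seq_len(n_samples)) {
    h <- emit(genes[i], good[j], presence[i, j])
    if (!is.null(h)) { ri <- ri + 1L; rows[[ri]] <- h }
  }
  # degraded samples: present in only qc_threshold - 100 genes
  for (s in lowq) {
    n_present <- max(0L, min(n_genes, qc_threshold - 100L))
    pres_idx <- sample.int(n_genes, n_present)
    flag <- logical(n_genes)
    flag[pres_idx] <- TRUE
    for (i in seq_len(n_genes)) {
      h <- emit(genes[i], s, flag[i])
      if (!is.null(h)) { ri <- ri + 1L; rows[[ri]] <- h }
    }
  }
  hits <- do.call(rbind, rows[seq_len(ri)])
  rownames(hits) <- NULL
  list(hits = hits,
       truth = list(presence = presence,
                    class = stats::setNames(cls, genes),
                    frequency = stats::setNames(rowMeans(presence), genes)),
       samples = c(good, lowq), low_quality = lowq,
       seed = as.integer(seed))
}
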