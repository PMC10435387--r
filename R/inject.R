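# Truth-labelled perturbations of simulated datasets: clonemate copies,
# selfed offspring, and records engineered to fail each QC filter.

# Regenerate call-level GQ/DP/AD consistent with a genotype column.
fresh_call_fields <- function(ga, gb) {
  n <- length(ga)
  dp <- 10L + stats::rpois(n, 30)
  gq <- pmin(99L, 30L + stats::rpois(n, 60))
  ad_alt <- integer(n)
  het <- !is.na(ga) & ga != gb
  ad_alt[het] <- stats::rbinom(sum(het), dp[het], 0.5)
  homalt <- !is.na(ga) & ga == gb & ga > 0L
  ad_alt[homalt] <- dp[homalt]
  list(gq = gq, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt)
}

add_samples <- function(gt, ga_new, gb_new, ids) {
  fields <- lapply(seq_along(ids), function(j)
    fresh_call_fields(ga_new[, j], gb_new[, j]))
  bindm <- function(old, new) {
    m <- cbind(old, new)
    colnames(m) <- c(gt$samples, ids)
    m
  }
  structure(list(
    sites = gt$sites,
    ga = bindm(gt$ga, ga_new), gb = bindm(gt$gb, gb_new),
    gq = bindm(gt$gq, do.call(cbind, lapply(fields, `[[`, "gq"))),
    dp = bindm(gt$dp, do.call(cbind, lapply(fields, `[[`, "dp"))),
    ad_ref = bindm(gt$ad_ref, do.call(cbind, lapply(fields, `[[`, "ad_ref"))),
    ad_alt = bindm(gt$ad_alt, do.call(cbind, lapply(fields, `[[`, "ad_alt"))),
    samples = c(gt$samples, ids)), class = "genotype_table")
}

#' Inject clonemate copies and selfed offspring
#'
#' Appends to a simulated dataset (i) clonemate copies — duplicates of a
#' source genotype with independent per-call genotyping errors at the stated
#' rate — and (ii) selfed offspring drawn from one parent by Mendelian
#' segregation: each parental heterozygous site stays heterozygous with
#' probability 1/2 and otherwise becomes a random homozygote; homozygous
#' parental sites are inherited unchanged. Truth labels (`clone_group`,
#' `selfed_from`) are updated; source samples are chosen deterministically
#' from the front of the sample list, clone sources first, then distinct
#' selfing parents.
#'
#' @param data a `simulated_dataset`.
#' @param n_clonemate_copies number of clonemate duplicates to add (one copy
#'   per distinct source sample).
#' @param n_selfed number of selfed offspring to add (one per distinct
#'   parent, parents disjoint from clone sources).
#' @param genotyping_error_rate per-call probability that a clonemate call is
#'   replaced by a different genotype, in \[0, 1\].
#' @param seed integer seed.
#' @return the augmented `simulated_dataset`.
#' @export
inject_clones_and_selfs <- function(data, n_clonemate_copies, n_selfed,
                                    genotyping_error_rate = 0, seed = 1) {
  if (genotyping_error_rate < 0 || genotyping_error_rate > 1)
    stop("genotyping_error_rate must lie in [0, 1]")
  gt <- data$genotypes
  n0 <- length(gt$samples)
  if (n_clonemate_copies + n_selfed > n0)
    stop("not enough source samples")
  set.seed(as.integer(seed))
  truth <- data$truth

  clone_src <- gt$samples[seq_len(n_clonemate_copies)]
  self_src <- gt$samples[n_clonemate_copies + seq_len(n_selfed)]
  n_sites <- nrow(gt$sites)

  new_ga <- NULL; new_gb <- NULL; ids <- character()
  if (n_clonemate_copies > 0) {
    src_idx <- match(clone_src, gt$samples)
    ca <- gt$ga[, src_idx, drop = FALSE]
    cb <- gt$gb[, src_idx, drop = FALSE]
    if (genotyping_error_rate > 0 && n_sites > 0) {
      err <- matrix(stats::runif(n_sites * n_clonemate_copies) <
                      genotyping_error_rate, n_sites)
      err[is.na(ca)] <- FALSE
      if (any(err)) {
        # replace with a uniformly chosen different genotype class
        cur <- ca[err] + cb[err]          # dosage 0/1/2
        shift <- sample.int(2L, sum(err), replace = TRUE)  # +1 or +2 mod 3
        newd <- (cur + shift) %% 3L
        ca[err] <- as.integer(newd >= 1L)
        cb[err] <- as.integer(newd == 2L)
      }
    }
    ids_c <- paste0(clone_src, "_clone")
    new_ga <- ca; new_gb <- cb; ids <- ids_c
    grp <- paste0("cg_", clone_src)
    truth$clone_group[match(clone_src, truth$sample)] <- grp
    truth <- rbind(truth, data.frame(
      sample = ids_c, population = truth$population[match(clone_src, truth$sample)],
      clone_group = grp, selfed_from = NA_character_))
  }
  if (n_selfed > 0) {
    src_idx <- match(self_src, gt$samples)
    sa <- gt$ga[, src_idx, drop = FALSE]
    sb <- gt$gb[, src_idx, drop = FALSE]
    oa <- sa; ob <- sb
    het <- !is.na(sa) & sa != sb
    if (any(het)) {
      u <- stats::runif(sum(het))
      stay_het <- u < 0.5
      hom_alt <- !stay_het & u < 0.75   # else hom ref
      hi <- which(het)
      amax <- pmax(sa[hi], sb[hi])      # the alt allele of the het call
      oa[hi] <- ifelse(stay_het, 0L, ifelse(hom_alt, amax, 0L))
      ob[hi] <- ifelse(stay_het, amax, ifelse(hom_alt, amax, 0L))
    }
    ids_s <- paste0(self_src, "_self")
    new_ga <- if (is.null(new_ga)) oa else cbind(new_ga, oa)
    new_gb <- if (is.null(new_gb)) ob else cbind(new_gb, ob)
    ids <- c(ids, ids_s)
    truth <- rbind(truth, data.frame(
      sample = ids_s, population = truth$population[match(self_src, truth$sample)],
      clone_group = NA_character_, selfed_from = self_src))
  }
  if (length(ids)) data$genotypes <- add_samples(gt, new_ga, new_gb, ids)
  data$truth <- truth
  data
}

#' Corruption specification for `corrupt_for_qc`
#'
#' Exact per-filter corruption counts. Every count is a number of sites (or,
#' for the genotype-level filters, a number of single calls on distinct
#' sites; for `n_high_missing_samples`, a number of samples). Defaults are
#' all zero.
#'
#' @param n_mq,n_fs,n_qd,n_mqranksum,n_readposranksum,n_sor,n_dp sites whose
#'   INFO metric is set to a hard-filter-failing value.
#' @param n_indel_adjacent SNP sites that get a new indel record placed
#'   within the indel window (both the SNP and the indel are tagged).
#' @param n_multiallelic sites given a second alternate allele.
#' @param n_low_gq,n_low_dp,n_conflicting_ad single calls set to fail the
#'   genotype-level masks (GQ < 30, DP < 10, homozygote with conflicting AD).
#' @param n_high_missing_samples samples whose missing rate is raised to
#'   `missing_rate`.
#' @param missing_rate target missing-call rate for those samples (> 0.15 to
#'   trip the default sample filter).
#' @param indel_offset distance (bp) between a tagged SNP and its injected
#'   indel; must be within the QC indel window to be effective.
#' @return a list of class `corruption_spec`.
#' @export
corruption_spec <- function(n_mq = 0, n_fs = 0, n_qd = 0, n_mqranksum = 0,
                            n_readposranksum = 0, n_sor = 0, n_dp = 0,
                            n_indel_adjacent = 0, n_multiallelic = 0,
                            n_low_gq = 0, n_low_dp = 0, n_conflicting_ad = 0,
                            n_high_missing_samples = 0, missing_rate = 0.25,
                            indel_offset = 5L) {
  spec <- list(n_mq = n_mq, n_fs = n_fs, n_qd = n_qd,
               n_mqranksum = n_mqranksum,
               n_readposranksum = n_readposranksum, n_sor = n_sor,
               n_dp = n_dp, n_indel_adjacent = n_indel_adjacent,
               n_multiallelic = n_multiallelic, n_low_gq = n_low_gq,
               n_low_dp = n_low_dp, n_conflicting_ad = n_conflicting_ad,
               n_high_missing_samples = n_high_missing_samples,
               missing_rate = missing_rate,
               indel_offset = as.integer(indel_offset))
  if (any(unlist(spec[1:13]) < 0)) stop("corruption counts must be >= 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  class(spec) <- "corruption_spec"
  spec
}

#' Corrupt a simulated dataset so that exact counts fail each QC filter
#'
#' Each corrupted site receives a `qc_tag` naming the filter it must fail;
#' tagged site sets are disjoint across filters so downstream removal counts
#' are exact, not expected. Genotype-level corruptions (low GQ, low DP,
#' conflicting AD) touch one call on each tagged site and are recorded in
#' `data$corrupt_calls`. High-missing samples are chosen among samples not
#' already involved in clone groups or selfing and recorded in
#' `data$high_missing_samples`.
#'
#' @param data a `simulated_dataset`.
#' @param spec a \link{corruption_spec}.
#' @param seed integer seed.
#' @return the corrupted `simulated_dataset`.
#' @export
corrupt_for_qc <- function(data, spec, seed = 1) {
  if (!inherits(spec, "corruption_spec")) spec <- do.call(corruption_spec, spec)
  set.seed(as.integer(seed))
  gt <- data$genotypes
  s <- gt$sites
  n_sites <- nrow(s)
  site_counts <- c(mq = spec$n_mq, fs = spec$n_fs, qd = spec$n_qd,
                   mqranksum = spec$n_mqranksum,
                   readposranksum = spec$n_readposranksum, sor = spec$n_sor,
                   dp = spec$n_dp, indel_adjacent = spec$n_indel_adjacent,
                   multiallelic = spec$n_multiallelic,
                   low_gq = spec$n_low_gq, low_dp = spec$n_low_dp,
                   conflicting_ad = spec$n_conflicting_ad)
  n_needed <- sum(site_counts)
  if (n_needed > n_sites)
    stop("not enough sites to corrupt: need ", n_needed, ", have ", n_sites)
  # Indel-adjacent corruption must not bleed onto neighbouring SNPs: the
  # injected indel masks everything within the QC window, so eligible sites
  # need an empty neighbourhood of indel_offset + 20 bp on both sides.
  idx_indel <- integer()
  if (spec$n_indel_adjacent > 0) {
    guard <- spec$indel_offset + 21L
    iso <- vapply(seq_len(n_sites), function(i) {
      same <- s$chrom == s$chrom[i]
      d <- abs(s$pos[same] - s$pos[i])
      sum(d < guard) == 1L   # itself only
    }, logical(1))
    cand <- which(iso)
    if (length(cand) < spec$n_indel_adjacent)
      stop("not enough isolated sites for indel-adjacent corruption")
    idx_indel <- sample(cand, spec$n_indel_adjacent)
    s$qc_tag[idx_indel] <- "indel_adjacent"
  }
  pool <- setdiff(seq_len(n_sites), idx_indel)
  n_rest <- n_needed - spec$n_indel_adjacent
  pick <- if (n_rest > 0) sample(pool, n_rest) else integer()
  take <- function(tag) {
    k <- site_counts[[tag]]
    if (k == 0) return(integer())
    out <- pick[seq_len(k)]
    pick <<- pick[-seq_len(k)]
    s$qc_tag[out] <<- tag
    out
  }
  # NB: take() mutates s via <<-, so it must never appear inside a complex
  # assignment to s (the [<- form snapshots s before the index evaluates).
  idx <- take("mq"); s$MQ[idx] <- 20
  idx <- take("fs"); s$FS[idx] <- 100
  idx <- take("qd"); s$QD[idx] <- 5
  idx <- take("mqranksum")
  s$MQRankSum[idx] <- sample(c(-3, 3), spec$n_mqranksum, replace = TRUE)
  idx <- take("readposranksum")
  s$ReadPosRankSum[idx] <- sample(c(-3, 3), spec$n_readposranksum,
                                  replace = TRUE)
  idx <- take("sor"); s$SOR[idx] <- 5
  idx <- take("dp"); s$DP[idx] <- 50 * max(mean(s$DP), 1)
  site_counts[["indel_adjacent"]] <- 0  # handled above
  idx_multi <- take("multiallelic")
  if (length(idx_multi)) {
    other <- vapply(seq_along(idx_multi), function(i) {
      row <- idx_multi[i]
      sample(setdiff(c("A", "C", "G", "T"), c(s$ref[row], s$alt[row])), 1L)
    }, character(1))
    s$alt[idx_multi] <- paste(s$alt[idx_multi], other, sep = ",")
  }
  corrupt_calls <- data.frame(site = integer(), sample = character(),
                              kind = character())
  one_call <- function(idx, kind, fun) {
    for (row in idx) {
      j <- sample.int(length(gt$samples), 1L)
      fun(row, j)
      corrupt_calls <<- rbind(corrupt_calls, data.frame(
        site = row, sample = gt$samples[j], kind = kind))
    }
  }
  one_call(take("low_gq"), "low_gq", function(row, j) gt$gq[row, j] <<- 10L)
  one_call(take("low_dp"), "low_dp", function(row, j) {
    gt$dp[row, j] <<- 5L
    gt$ad_ref[row, j] <<- min(gt$ad_ref[row, j], 5L)
    gt$ad_alt[row, j] <<- 5L - gt$ad_ref[row, j]
  })
  one_call(take("conflicting_ad"), "conflicting_ad", function(row, j) {
    # force a homozygote whose AD carries reads of the other allele
    gt$ga[row, j] <<- 0L; gt$gb[row, j] <<- 0L
    gt$ad_alt[row, j] <<- 2L
    gt$ad_ref[row, j] <<- gt$dp[row, j] - 2L
  })

  # insert indel records next to the tagged SNPs
  if (length(idx_indel)) {
    newrows <- s[idx_indel, , drop = FALSE]
    newrows$pos <- newrows$pos + spec$indel_offset
    newrows$type <- "indel"
    newrows$alt <- paste0(newrows$ref, "A")
    newrows$qc_tag <- "indel_record"
    k <- nrow(newrows)  # isolation guard above precludes position collisions
    if (k) {
      pad <- function(m, fill) {
        add <- matrix(fill, k, ncol(m))
        colnames(add) <- colnames(m)
        rbind(m, add)
      }
      gt$ga <- pad(gt$ga, 0L); gt$gb <- pad(gt$gb, 0L)
      gt$gq <- pad(gt$gq, 99L); gt$dp <- pad(gt$dp, 40L)
      gt$ad_ref <- pad(gt$ad_ref, 40L); gt$ad_alt <- pad(gt$ad_alt, 0L)
      s <- rbind(s, newrows)
      ord <- order(s$chrom, s$pos)
      gt$ga <- gt$ga[ord, , drop = FALSE]; gt$gb <- gt$gb[ord, , drop = FALSE]
      gt$gq <- gt$gq[ord, , drop = FALSE]; gt$dp <- gt$dp[ord, , drop = FALSE]
      gt$ad_ref <- gt$ad_ref[ord, , drop = FALSE]
      gt$ad_alt <- gt$ad_alt[ord, , drop = FALSE]
      # remap recorded call-level corruption rows
      if (nrow(corrupt_calls))
        corrupt_calls$site <- match(corrupt_calls$site, ord)
      s <- s[ord, , drop = FALSE]
      rownames(s) <- NULL
    }
  }
  gt$sites <- s

  high_missing <- character()
  if (spec$n_high_missing_samples > 0) {
    involved <- unique(c(
      data$truth$sample[!is.na(data$truth$clone_group)],
      data$truth$sample[!is.na(data$truth$selfed_from)],
      stats::na.omit(data$truth$selfed_from)))
    free <- setdiff(gt$samples, involved)
    if (length(free) < spec$n_high_missing_samples)
      stop("not enough uninvolved samples for high-missing corruption")
    high_missing <- free[seq_len(spec$n_high_missing_samples)]
    n_miss <- ceiling(spec$missing_rate * nrow(gt$sites))
    for (id in high_missing) {
      j <- match(id, gt$samples)
      rows <- sample.int(nrow(gt$sites), n_miss)
      gt$ga[rows, j] <- NA_integer_
      gt$gb[rows, j] <- NA_integer_
    }
  }
  data$genotypes <- gt
  data$corrupt_calls <- corrupt_calls
  data$high_missing_samples <- high_missing
  validate_genotype_table(gt)
  data
}
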