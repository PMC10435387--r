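# Post-calling SNP filter cascade: indel-proximity masking, INFO hard
# filters, genotype-level masking, biallelic selection, region intersection,
# annotation subsetting, distance thinning and sample missing-rate filtering.

#' Filter configuration for the QC cascade
#'
#' Thresholds follow the hard-filter conventions of joint short-read variant
#' calling. All hard filters use strict inequalities: a value exactly at a
#' threshold passes. A missing INFO metric passes its criterion (rank-sum
#' annotations are undefined at sites without heterozygotes).
#'
#' @param indel_window bp; SNPs within this distance (inclusive) of an indel
#'   or other non-SNP variant are removed.
#' @param mq_min,fs_max,qd_min,rank_sum_abs_max,sor_max site-level INFO
#'   thresholds (MQ, FS, QD, |MQRankSum| and |ReadPosRankSum|, SOR).
#' @param dp_multiplier site DP ceiling as a multiple of the dataset mean DP.
#' @param gq_min,dp_min genotype-level minima; calls below either are set
#'   missing.
#' @param thin_distance bp; minimum spacing for \link{thin_by_distance}.
#' @param sample_missing_max maximum tolerated per-sample missing-call rate.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(indel_window = 20L, mq_min = 40.0, fs_max = 60.0,
                          qd_min = 10.0, rank_sum_abs_max = 2.5,
                          sor_max = 3.0, dp_multiplier = 2.0, gq_min = 30L,
                          dp_min = 10L, thin_distance = 3000L,
                          sample_missing_max = 0.15) {
  cfg <- list(indel_window = indel_window, mq_min = mq_min, fs_max = fs_max,
              qd_min = qd_min, rank_sum_abs_max = rank_sum_abs_max,
              sor_max = sor_max, dp_multiplier = dp_multiplier,
              gq_min = gq_min, dp_min = dp_min,
              thin_distance = as.integer(thin_distance),
              sample_missing_max = sample_missing_max)
  if (any(!is.finite(unlist(cfg)))) stop("all thresholds must be finite")
  if (cfg$thin_distance <= 0) stop("thin_distance must be positive")
  class(cfg) <- "filter_config"
  cfg
}

check_sorted <- function(table) {
  s <- table$sites
  if (nrow(s) > 1) {
    ok <- tapply(s$pos, s$chrom, function(p) all(diff(p) > 0))
    if (!all(unlist(ok))) stop("genotype table must be position-sorted")
  }
  invisible(TRUE)
}

#' Remove SNPs near indels and other non-SNP variants
#'
#' A SNP is removed iff some indel/non-SNP record on the same chromosome lies
#' within `window` bp (inclusive, |delta| <= window). The non-SNP records
#' themselves are also dropped: everything downstream operates on SNPs only.
#'
#' @param table a `genotype_table`, position-sorted.
#' @param window bp distance, inclusive.
#' @return the filtered `genotype_table`.
#' @export
mask_near_variants <- function(table, window = 20L) {
  check_sorted(table)
  s <- table$sites
  is_snp <- s$type == "snp"
  if (all(is_snp)) return(table)
  keep <- is_snp
  for (ch in unique(s$chrom[!is_snp])) {
    on_ch <- s$chrom == ch
    bad_pos <- s$pos[on_ch & !is_snp]
    snp_i <- which(on_ch & is_snp)
    if (!length(snp_i)) next
    near <- vapply(s$pos[snp_i],
                   function(p) any(abs(p - bad_pos) <= window), logical(1))
    keep[snp_i[near]] <- FALSE
  }
  gt_subset_sites(table, keep)
}

#' Apply the site-level hard-filter cascade
#'
#' A site is removed iff MQ < mq_min OR FS > fs_max OR QD < qd_min OR
#' |MQRankSum| > rank_sum_abs_max OR |ReadPosRankSum| > rank_sum_abs_max OR
#' SOR > sor_max OR DP > dp_multiplier x mean site DP of the input. All
#' inequalities are strict, so boundary-equal values pass; a missing (NA)
#' metric passes that criterion.
#'
#' @param table a `genotype_table`.
#' @param config a \link{filter_config}.
#' @return list with `table` (retained sites) and `report` (a
#'   \link{filter_report} with per-criterion and total counts).
#' @export
apply_hard_filters <- function(table, config = filter_config()) {
  s <- table$sites
  metrics <- c("MQ", "FS", "QD", "MQRankSum", "ReadPosRankSum", "SOR", "DP")
  for (m in metrics)
    if (!is.numeric(s[[m]]))
      stop("non-numeric INFO metric ", m)
  dp_ceiling <- config$dp_multiplier * mean(s$DP, na.rm = TRUE)
  fails <- function(x, bad) !is.na(x) & bad
  f <- cbind(
    mq = fails(s$MQ, s$MQ < config$mq_min),
    fs = fails(s$FS, s$FS > config$fs_max),
    qd = fails(s$QD, s$QD < config$qd_min),
    mqranksum = fails(s$MQRankSum, abs(s$MQRankSum) > config$rank_sum_abs_max),
    readposranksum = fails(s$ReadPosRankSum,
                           abs(s$ReadPosRankSum) > config$rank_sum_abs_max),
    sor = fails(s$SOR, s$SOR > config$sor_max),
    dp = fails(s$DP, s$DP > dp_ceiling))
  remove <- if (nrow(s)) rowSums(f) > 0 else logical(0)
  report <- filter_report("hard_filters", nrow(s), sum(remove),
                          details = c(colSums(f),
                                      dp_ceiling = dp_ceiling))
  list(table = gt_subset_sites(table, !remove), report = report)
}

#' Mask individual genotype calls
#'
#' A call is set to missing iff GQ < gq_min OR DP < dp_min OR it is a
#' homozygous-reference call with >= 1 read supporting the alternate allele
#' OR a homozygous-alternate call with >= 1 read supporting the reference.
#'
#' @param table a `genotype_table`.
#' @param config a \link{filter_config}.
#' @return the `genotype_table` with masked calls set to NA.
#' @export
mask_genotypes <- function(table, config = filter_config()) {
  called <- !is.na(table$ga)
  homref <- called & table$ga == 0L & table$gb == 0L
  homalt <- called & table$ga > 0L & table$ga == table$gb
  bad <- called & (table$gq < config$gq_min | table$dp < config$dp_min |
                     (homref & table$ad_alt >= 1L) |
                     (homalt & table$ad_ref >= 1L))
  table$ga[bad] <- NA_integer_
  table$gb[bad] <- NA_integer_
  table
}

#' Keep only biallelic SNPs
#'
#' Retains sites with exactly one reference and one alternate allele and SNP
#' type.
#'
#' @param table a `genotype_table`.
#' @return the filtered `genotype_table`.
#' @export
select_biallelic <- function(table) {
  s <- table$sites
  keep <- s$type == "snp" & !grepl(",", s$alt, fixed = TRUE) &
    nchar(s$ref) == 1L & nchar(s$alt) == 1L
  gt_subset_sites(table, keep)
}

#' Map a 1-based position into 0-based half-open intervals
#'
#' The single coordinate-convention conversion point: a 1-based position
#' `pos` lies inside a BED interval \[start, end) iff `pos - 1` is in
#' \[start, end).
#'
#' @param pos integer vector of 1-based positions.
#' @param start,end interval bounds, 0-based half-open.
#' @return logical vector.
#' @export
pos_in_interval <- function(pos, start, end) (pos - 1L) >= start & (pos - 1L) < end

#' Intersect sites with BED-style regions
#'
#' @param table a `genotype_table`.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   or a `GRanges` (converted; GRanges is 1-based closed).
#' @return the `genotype_table` restricted to sites inside any region.
#' @export
intersect_regions <- function(table, regions) {
  if (inherits(regions, "GRanges")) {
    regions <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions)),
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions))
  }
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have chrom, start, end")
  if (any(regions$end < regions$start) || any(regions$start < 0))
    stop("malformed interval")
  s <- table$sites
  keep <- logical(nrow(s))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    on_ch <- which(s$chrom == ch)
    if (!length(on_ch)) next
    inside <- rep(FALSE, length(on_ch))
    for (i in seq_len(nrow(r)))
      inside <- inside | pos_in_interval(s$pos[on_ch], r$start[i], r$end[i])
    keep[on_ch] <- inside
  }
  gt_subset_sites(table, keep)
}

#' Subset sites by annotation class
#'
#' @param table a `genotype_table`.
#' @param class one of `"synonymous"`, `"nonsynonymous"`, `"noncoding"`.
#' @param drop_missing if TRUE, additionally drop sites with any missing call
#'   (the "no missing data" subset used for diversity).
#' @return the filtered `genotype_table`.
#' @export
subset_by_annotation <- function(table, class, drop_missing = FALSE) {
  if (!class %in% c("synonymous", "nonsynonymous", "noncoding"))
    stop("unknown annotation class: ", class)
  keep <- table$sites$ann == class
  if (drop_missing) keep <- keep & rowSums(gt_missing(table)) == 0L
  gt_subset_sites(table, keep)
}

#' Thin sites to a minimum pairwise distance
#'
#' Greedy left-to-right scan per chromosome: the first site is kept; each
#' subsequent site is kept iff its distance to the last kept site is at least
#' `min_distance`. Output spacing is therefore >= `min_distance` everywhere.
#'
#' @param table a `genotype_table`, position-sorted.
#' @param min_distance bp.
#' @return the thinned `genotype_table`.
#' @export
thin_by_distance <- function(table, min_distance = 3000L) {
  check_sorted(table)
  s <- table$sites
  keep <- logical(nrow(s))
  for (ch in unique(s$chrom)) {
    i <- which(s$chrom == ch)
    last <- -Inf
    for (k in i) {
      if (s$pos[k] - last >= min_distance) {
        keep[k] <- TRUE
        last <- s$pos[k]
      }
    }
  }
  gt_subset_sites(table, keep)
}

#' Exclude samples with high missing-call rates
#'
#' @param table a `genotype_table`.
#' @param max_rate samples with missing fraction strictly above this are
#'   excluded.
#' @return list with `table` (retained samples), `excluded` (sample ids) and
#'   `rates` (named per-sample missing rates).
#' @export
sample_missing_filter <- function(table, max_rate = 0.15) {
  rates <- colMeans(gt_missing(table))
  names(rates) <- table$samples
  excl <- table$samples[rates > max_rate]
  list(table = gt_subset_samples(table, !(table$samples %in% excl)),
       excluded = excl, rates = rates)
}

#' Per-stage filter report
#'
#' @param stage stage name.
#' @param input,removed site (or sample) counts entering and removed.
#' @param details optional named numeric vector of per-criterion counts.
#' @return a one-row data.frame of class `filter_report`.
#' @export
filter_report <- function(stage, input, removed, details = NULL) {
  r <- data.frame(stage = stage, input = input, removed = removed,
                  retained = input - removed, stringsAsFactors = FALSE)
  attr(r, "details") <- details
  class(r) <- c("filter_report", class(r))
  r
}

#' Run the full SNP QC cascade
#'
#' Stages in calling order: indel-proximity masking, INFO hard filters,
#' genotype-call masking, biallelic selection, optional core-region
#' intersection (producing the high-quality SNP set), optional sample
#' missing-rate exclusion. Counts reconcile exactly at every stage
#' (input = removed + retained).
#'
#' @param table a `genotype_table`.
#' @param config a \link{filter_config}.
#' @param regions optional BED-style regions (core genes) to intersect.
#' @param filter_samples if TRUE, apply \link{sample_missing_filter} last.
#' @return list with `table`, `report` (stacked \link{filter_report} rows),
#'   `excluded_samples` and `missing_rates`.
#' @export
qc_cascade <- function(table, config = filter_config(), regions = NULL,
                       filter_samples = FALSE) {
  rows <- list()
  n0 <- nrow(table$sites)
  t1 <- mask_near_variants(table, config$indel_window)
  rows$indel <- filter_report("indel_proximity", n0, n0 - nrow(t1$sites))
  hf <- apply_hard_filters(t1, config)
  rows$hard <- hf$report
  t2 <- mask_genotypes(hf$table, config)
  rows$geno <- filter_report("genotype_mask", nrow(t2$sites), 0)
  t3 <- select_biallelic(t2)
  rows$biall <- filter_report("biallelic", nrow(t2$sites),
                              nrow(t2$sites) - nrow(t3$sites))
  t4 <- t3
  if (!is.null(regions)) {
    t4 <- intersect_regions(t3, regions)
    rows$core <- filter_report("core_regions", nrow(t3$sites),
                               nrow(t3$sites) - nrow(t4$sites))
  }
  excluded <- character(); rates <- numeric()
  if (filter_samples) {
    sm <- sample_missing_filter(t4, config$sample_missing_max)
    t4 <- sm$table
    excluded <- sm$excluded
    rates <- sm$rates
    rows$samp <- filter_report("sample_missing", length(rates),
                               length(excluded))
  }
  report <- do.call(rbind, lapply(rows, function(r) {
    class(r) <- "data.frame"; r
  }))
  rownames(report) <- NULL
  list(table = t4, report = report, excluded_samples = excluded,
       missing_rates = rates)
}
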