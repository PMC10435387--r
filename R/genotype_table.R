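#' Genotype table container
#'
#' A `genotype_table` holds an ordered site table (one row per variant record)
#' together with per-call diploid genotype matrices and call-level quality
#' fields, mirroring what a jointly genotyped multi-sample VCF carries.
#'
#' @details
#' Components:
#' \describe{
#'   \item{sites}{data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'     `alt` (comma-separated for multiallelic records), `type`
#'     (`"snp"`/`"indel"`), the INFO metrics `MQ`, `FS`, `QD`, `MQRankSum`,
#'     `ReadPosRankSum`, `SOR`, `DP`, an annotation class `ann`
#'     (`synonymous`/`nonsynonymous`/`noncoding`) and a truth tag `qc_tag`
#'     (NA for clean records) naming the filter a corrupted record must fail.}
#'   \item{ga, gb}{integer allele matrices (site x sample); 0 = ref, k = k-th
#'     alt; both NA for a missing call.}
#'   \item{gq, dp, ad_ref, ad_alt}{integer call-level matrices.}
#'   \item{samples}{character vector of sample ids (column order).}
#' }
#' Positions are strictly increasing within a chromosome and AD components
#' never exceed the call DP.
#'
#' @param sites site data.frame as described above.
#' @param ga,gb integer allele matrices.
#' @param gq,dp,ad_ref,ad_alt call-level integer matrices.
#' @param samples character vector of sample ids.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, ga, gb, gq, dp, ad_ref, ad_alt, samples) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "ref", "alt", "type", "MQ", "FS", "QD",
            "MQRankSum", "ReadPosRankSum", "SOR", "DP", "ann", "qc_tag")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(sites)
  for (m in list(ga, gb, gq, dp, ad_ref, ad_alt)) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != length(samples))
      stop("call matrices must be n_sites x n_samples")
  }
  obj <- structure(
    list(sites = sites, ga = ga, gb = gb, gq = gq, dp = dp,
         ad_ref = ad_ref, ad_alt = ad_alt, samples = as.character(samples)),
    class = "genotype_table")
  validate_genotype_table(obj)
  obj
}

#' Validate genotype_table invariants
#'
#' Checks strictly increasing positions within chromosome, AD sums bounded by
#' call DP, and known annotation classes.
#'
#' @param x a `genotype_table`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_genotype_table <- function(x) {
  s <- x$sites
  if (nrow(s) > 1) {
    ok <- tapply(s$pos, s$chrom, function(p) all(diff(p) > 0))
    if (!all(unlist(ok)))
      stop("positions must be strictly increasing within each chromosome")
  }
  called <- !is.na(x$ga)
  adsum <- x$ad_ref + x$ad_alt
  bad <- called & !is.na(adsum) & !is.na(x$dp) & (adsum > x$dp)
  if (any(bad)) stop("AD components exceed call DP at ", sum(bad), " calls")
  if (!all(s$ann %in% c("synonymous", "nonsynonymous", "noncoding")))
    stop("unknown annotation class")
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples on %d chromosomes\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype table by site index
#' @param x a `genotype_table`.
#' @param keep logical or integer site index.
#' @return a `genotype_table` with the retained rows.
#' @export
gt_subset_sites <- function(x, keep) {
  structure(list(
    sites = x$sites[keep, , drop = FALSE],
    ga = x$ga[keep, , drop = FALSE], gb = x$gb[keep, , drop = FALSE],
    gq = x$gq[keep, , drop = FALSE], dp = x$dp[keep, , drop = FALSE],
    ad_ref = x$ad_ref[keep, , drop = FALSE],
    ad_alt = x$ad_alt[keep, , drop = FALSE],
    samples = x$samples), class = "genotype_table")
}

#' Subset a genotype table by sample
#' @param x a `genotype_table`.
#' @param keep sample ids, logical mask, or integer index.
#' @return a `genotype_table` with the retained columns.
#' @export
gt_subset_samples <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$samples)
  structure(list(
    sites = x$sites,
    ga = x$ga[, keep, drop = FALSE], gb = x$gb[, keep, drop = FALSE],
    gq = x$gq[, keep, drop = FALSE], dp = x$dp[, keep, drop = FALSE],
    ad_ref = x$ad_ref[, keep, drop = FALSE],
    ad_alt = x$ad_alt[, keep, drop = FALSE],
    samples = x$samples[keep]), class = "genotype_table")
}

#' Missing-call indicator matrix
#' @param x a `genotype_table`.
#' @return logical site x sample matrix, TRUE where the call is missing.
#' @export
gt_missing <- function(x) is.na(x$ga) | is.na(x$gb)

#' Heterozygous-call indicator matrix
#' @param x a `genotype_table`.
#' @return logical site x sample matrix; NA where the call is missing.
#' @export
gt_het <- function(x) x$ga != x$gb

#' Alternate-allele dosage matrix (biallelic sites)
#' @param x a `genotype_table`.
#' @return integer site x sample matrix of 0/1/2 dosages; NA where missing.
#' @export
gt_dosage <- function(x) (x$ga > 0L) + (x$gb > 0L)
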