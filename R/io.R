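# File-format bridges: VCF v4.2 (write by formatting, read via
# VariantAnnotation), BED via rtracklayer, FASTA via Biostrings, and the
# plain-TSV side formats (pileups, population maps, reports).

vcf_info_defs <- c(
  "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
  "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand phred p\">",
  "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
  "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
  "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
  "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
  "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
  "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation class\">")

#' Write a genotype table as VCF v4.2
#'
#' Emits GT:GQ:DP:AD FORMAT fields and the MQ, FS, QD, MQRankSum,
#' ReadPosRankSum, SOR, DP INFO metrics plus an ANN key carrying the
#' annotation class (so \link{read_vcf_genotypes} round-trips it).
#'
#' @param table a `genotype_table`.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  s <- table$sites
  n <- nrow(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=meadowpop",
    vcf_info_defs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")), con)
  if (n == 0) return(invisible(path))
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g",
                                                       digits = 6))
  info <- sprintf(
    "MQ=%s;FS=%s;QD=%s;MQRankSum=%s;ReadPosRankSum=%s;SOR=%s;DP=%s;ANN=%s",
    fmt_num(s$MQ), fmt_num(s$FS), fmt_num(s$QD), fmt_num(s$MQRankSum),
    fmt_num(s$ReadPosRankSum), fmt_num(s$SOR), fmt_num(round(s$DP)), s$ann)
  gtm <- matrix("./.:.:.:.", n, length(table$samples))
  called <- !is.na(table$ga)
  gtm[called] <- sprintf("%d/%d:%d:%d:%d,%d",
                         pmin(table$ga[called], table$gb[called]),
                         pmax(table$ga[called], table$gb[called]),
                         table$gq[called], table$dp[called],
                         table$ad_ref[called], table$ad_alt[called])
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info,
                "GT:GQ:DP:AD",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a genotype table
#'
#' Uses Bioconductor VariantAnnotation for parsing; GT, GQ, DP and AD are
#' required FORMAT fields, the seven hard-filter INFO metrics are read when
#' present (NA otherwise).
#'
#' @param path VCF file path.
#' @return a \link{genotype_table}.
#' @export
read_vcf_genotypes <- function(path) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  getm <- function(key) {
    if (key %in% names(info)) as.numeric(info[[key]]) else
      rep(NA_real_, length(rr))
  }
  alt_l <- VariantAnnotation::alt(v)
  alt <- vapply(seq_along(alt_l), function(i)
    paste(as.character(alt_l[[i]]), collapse = ","), character(1))
  ref <- as.character(VariantAnnotation::ref(v))
  type <- ifelse(nchar(ref) == 1 &
                   !grepl(",", alt, fixed = TRUE) & nchar(alt) == 1,
                 "snp", "indel")
  ann <- if ("ANN" %in% names(info)) as.character(info$ANN) else
    rep("noncoding", length(rr))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref, alt = alt, type = type,
    MQ = getm("MQ"), FS = getm("FS"), QD = getm("QD"),
    MQRankSum = getm("MQRankSum"), ReadPosRankSum = getm("ReadPosRankSum"),
    SOR = getm("SOR"), DP = getm("DP"), ann = ann,
    qc_tag = NA_character_, stringsAsFactors = FALSE)
  g <- VariantAnnotation::geno(v)
  gt <- g$GT
  samples <- colnames(gt)
  parse_allele <- function(k) {
    a <- sub("^(\\d+|\\.)[/|](\\d+|\\.)$", paste0("\\", k), gt)
    a[!grepl("^\\d+$", a)] <- NA
    matrix(as.integer(a), nrow(gt))
  }
  ga <- parse_allele(1)
  gb <- parse_allele(2)
  toint <- function(m) {
    m[is.na(m)] <- NA
    storage.mode(m) <- "integer"
    unname(m)
  }
  gq <- toint(g$GQ); dp <- toint(g$DP)
  ad <- g$AD
  ad_ref <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ad_alt <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) {
    col <- ad[, j]
    ad_ref[, j] <- vapply(col, function(x)
      if (length(x) >= 1) as.integer(x[1]) else NA_integer_, integer(1))
    ad_alt[, j] <- vapply(col, function(x)
      if (length(x) >= 2) as.integer(x[2]) else NA_integer_, integer(1))
  }
  miss <- is.na(ga)
  gq[miss] <- NA_integer_; dp[miss] <- NA_integer_
  ad_ref[miss] <- NA_integer_; ad_alt[miss] <- NA_integer_
  colnames(ga) <- colnames(gb) <- samples
  genotype_table(sites, ga, gb, gq, dp, ad_ref, ad_alt, samples)
}

#' Write BED intervals (0-based half-open)
#' @param regions data.frame with `chrom`, `start`, `end`, optional `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  if (!is.null(regions$name)) gr$name <- regions$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED intervals into a 0-based half-open data.frame
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write named sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write chloroplast pileups as per-sample TSVs
#'
#' One file per sample named `<prefix><sample>.tsv` with 1-based `pos`,
#' `cov` and A/C/G/T counts, plus `<prefix>reference.fa`.
#'
#' @param pileup a `cp_pileup` (`ref` + `samples`).
#' @param dir output directory (created).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_pileup_tsv <- function(pileup, dir, prefix = "cp_") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (id in names(pileup$samples)) {
    counts <- pileup$samples[[id]]
    df <- data.frame(pos = seq_len(nrow(counts)), cov = rowSums(counts),
                     A = counts[, "A"], C = counts[, "C"],
                     G = counts[, "G"], T = counts[, "T"])
    p <- file.path(dir, paste0(prefix, id, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  fa <- file.path(dir, paste0(prefix, "reference.fa"))
  write_fasta(c(reference = paste(pileup$ref, collapse = "")), fa)
  invisible(c(paths, fa))
}

#' Read chloroplast pileups written by \link{write_pileup_tsv}
#' @param dir directory holding the TSVs and reference FASTA.
#' @param prefix file-name prefix used at write time.
#' @return a `cp_pileup` list (`ref`, `samples`).
#' @export
read_pileup_tsv <- function(dir, prefix = "cp_") {
  fa <- file.path(dir, paste0(prefix, "reference.fa"))
  ref <- strsplit(read_fasta(fa)[[1]], "")[[1]]
  files <- list.files(dir, pattern = paste0("^", prefix, ".*\\.tsv$"),
                      full.names = TRUE)
  samples <- list()
  for (f in files) {
    id <- sub(paste0("^", prefix), "", sub("\\.tsv$", "", basename(f)))
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            check.names = FALSE)
    m <- as.matrix(df[, c("A", "C", "G", "T")])
    storage.mode(m) <- "integer"
    colnames(m) <- c("A", "C", "G", "T")
    samples[[id]] <- m
  }
  list(ref = ref, samples = samples)
}

#' Read a sample-to-population map TSV
#' @param path TSV with columns `sample`, `population`.
#' @return data.frame.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(df)))
    stop("population map needs columns sample, population")
  df
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
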