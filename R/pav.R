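# Pangenome presence/absence: presence calling from alignment summaries,
# sample QC, and cloud/shell/core classification of gene frequencies.

#' Call gene presence from alignment hits
#'
#' A gene is present in a sample iff (a) some single hit has identity > 0.60
#' AND coverage > 0.60, or (b) all hits fall on three or fewer scaffolds and
#' their summed (non-overlapping) coverage is > 0.85 with a coverage-weighted
#' identity > 0.85. Monotone: improving any hit's identity or coverage never
#' flips a present call to absent.
#'
#' @param hits data.frame with columns `scaffold`, `identity`, `coverage`
#'   for one (gene, sample); may have zero rows.
#' @param single_identity,single_coverage rule (a) thresholds.
#' @param multi_identity,multi_coverage rule (b) thresholds.
#' @param max_scaffolds rule (b) scaffold cap.
#' @return logical scalar.
#' @export
call_presence <- function(hits, single_identity = 0.60,
                          single_coverage = 0.60, multi_identity = 0.85,
                          multi_coverage = 0.85, max_scaffolds = 3L) {
  if (is.null(hits) || nrow(hits) == 0) return(FALSE)
  if (any(hits$identity > single_identity & hits$coverage > single_coverage))
    return(TRUE)
  if (length(unique(hits$scaffold)) <= max_scaffolds) {
    cov <- sum(hits$coverage)
    wid <- sum(hits$identity * hits$coverage) / cov
    if (cov > multi_coverage && wid > multi_identity) return(TRUE)
  }
  FALSE
}

#' Build a presence/absence matrix from an alignment-summary table
#'
#' @param hits data.frame with columns `gene`, `sample`, `scaffold`,
#'   `identity`, `coverage` (one row per hit).
#' @param genes,samples optional universes (genes/samples with no hits at
#'   all still get rows/columns of FALSE).
#' @param ... thresholds passed to \link{call_presence}.
#' @return logical genes x samples matrix.
#' @export
presence_matrix <- function(hits, genes = NULL, samples = NULL, ...) {
  if (is.null(genes)) genes <- sort(unique(hits$gene))
  if (is.null(samples)) samples <- sort(unique(hits$sample))
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(hits)) {
    key <- paste(hits$gene, hits$sample, sep = "\r")
    for (grp in split(seq_len(nrow(hits)), key)) {
      g <- hits$gene[grp[1]]; s <- hits$sample[grp[1]]
      m[g, s] <- call_presence(hits[grp, , drop = FALSE], ...)
    }
  }
  m
}

#' Exclude low-quality samples from a PAV matrix
#'
#' Samples with strictly more than `min_genes` present genes are kept;
#' a sample at exactly `min_genes` is excluded ("greater than" is strict).
#' Applied before frequencies are computed.
#'
#' @param presence logical genes x samples matrix.
#' @param min_genes threshold (default 17500).
#' @return list with `presence` (retained columns), `excluded` (sample ids)
#'   and `gene_counts` (named per-sample present-gene counts).
#' @export
qc_samples <- function(presence, min_genes = 17500L) {
  counts <- colSums(presence)
  keep <- counts > min_genes
  list(presence = presence[, keep, drop = FALSE],
       excluded = colnames(presence)[!keep], gene_counts = counts)
}

#' Classify gene frequencies into cloud / shell / core
#'
#' Deterministic 1-D three-cluster partition: Lloyd k-means initialised at
#' the 0.1 / 0.5 / 0.9 frequency quantiles; clusters are labelled cloud <
#' shell < core by ascending centroid. With fewer than three distinct
#' frequencies the clustering is degenerate and a fixed threshold fallback
#' is used (< 0.2 cloud, < 0.9 shell, else core) with a warning.
#'
#' @param frequencies per-gene observation frequencies in \[0, 1\].
#' @return list with `class` (factor cloud/shell/core, named as
#'   `frequencies`), `centroids` (ascending) and `method`.
#' @export
classify_genes <- function(frequencies) {
  if (any(frequencies < 0 | frequencies > 1))
    stop("frequencies must lie in [0, 1]")
  lv <- c("cloud", "shell", "core")
  if (length(unique(frequencies)) < 3) {
    warning("fewer than 3 distinct frequencies: using threshold fallback")
    cls <- ifelse(frequencies < 0.2, "cloud",
                  ifelse(frequencies < 0.9, "shell", "core"))
    return(list(class = stats::setNames(factor(cls, levels = lv),
                                        names(frequencies)),
                centroids = NULL, method = "threshold_fallback"))
  }
  centers <- stats::quantile(frequencies, c(0.1, 0.5, 0.9), names = FALSE)
  # Lloyd iterations on 1-D data with fixed initialisation: deterministic
  for (it in seq_len(100)) {
    assign <- max.col(-abs(outer(frequencies, centers, "-")),
                      ties.method = "first")
    new_centers <- vapply(1:3, function(k) {
      x <- frequencies[assign == k]
      if (length(x)) mean(x) else centers[k]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  ord <- order(centers)
  lab <- integer(3)
  lab[ord] <- 1:3
  cls <- factor(lv[lab[assign]], levels = lv)
  list(class = stats::setNames(cls, names(frequencies)),
       centroids = sort(centers), method = "kmeans_1d")
}

#' Build a classified PAV matrix from alignment summaries
#'
#' Calls presence, optionally restricts to one representative per clone
#' group, applies sample QC, computes per-gene frequencies over retained
#' samples and classifies genes.
#'
#' @param hits alignment-summary data.frame (see \link{presence_matrix}).
#' @param min_genes sample-QC threshold.
#' @param clone_representatives optional sample ids to keep (one per genet)
#'   before any other step.
#' @param ... thresholds for \link{call_presence}.
#' @return a `pav_matrix`: list with `presence`, `frequency`, `class`,
#'   `excluded_samples`, `gene_counts`, `centroids`.
#' @export
build_pav <- function(hits, min_genes = 17500L,
                      clone_representatives = NULL, ...) {
  m <- presence_matrix(hits, ...)
  if (!is.null(clone_representatives))
    m <- m[, colnames(m) %in% clone_representatives, drop = FALSE]
  qc <- qc_samples(m, min_genes)
  freq <- rowMeans(qc$presence)
  cl <- classify_genes(freq)
  structure(list(presence = qc$presence, frequency = freq,
                 class = cl$class, excluded_samples = qc$excluded,
                 gene_counts = qc$gene_counts, centroids = cl$centroids),
            class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("pav_matrix: %d genes x %d samples (%s)\n",
              nrow(x$presence), ncol(x$presence),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
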