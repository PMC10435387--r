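# Clonemate and selfed-offspring detection from shared heterozygosity.
# Ramets of one genet share (up to genotyping error) all heterozygous sites;
# a first-generation selfed offspring is heterozygous at ~half of its
# parent's heterozygous sites and (error-free) at no others.

# site x sample helper matrices restricted to pairwise-called sites are
# assembled once via crossprod for all-pairs statistics.
pair_het_counts <- function(table) {
  called <- !gt_missing(table)
  het <- gt_het(table) & called
  het[is.na(het)] <- FALSE
  storage.mode(het) <- "double"
  storage.mode(called) <- "double"
  both_called <- crossprod(called)                    # sites called in both
  both_het <- crossprod(het)                          # het in both (and called)
  het_and_called <- crossprod(het, called)            # het in i, called in j
  list(both_called = both_called, both_het = both_het,
       het_and_called = het_and_called)
}

#' Shared heterozygosity between two samples
#'
#' Restricted to sites called in both samples, returns
#' |sites heterozygous in both| / |sites heterozygous in either| — a Jaccard
#' index of heterozygous site sets. Symmetric, in \[0, 1\].
#'
#' @param a,b sample ids or column indices.
#' @param table a `genotype_table`.
#' @param min_sites minimum number of sites called in both (error below).
#' @return a fraction in \[0, 1\].
#' @export
shared_het <- function(a, b, table, min_sites = 100L) {
  if (is.character(a)) a <- match(a, table$samples)
  if (is.character(b)) b <- match(b, table$samples)
  ca <- !is.na(table$ga[, a]) & !is.na(table$gb[, a])
  cb <- !is.na(table$ga[, b]) & !is.na(table$gb[, b])
  both <- ca & cb
  if (sum(both) < min_sites)
    stop("insufficient overlap: only ", sum(both), " sites called in both")
  ha <- both & table$ga[, a] != table$gb[, a]
  hb <- both & table$ga[, b] != table$gb[, b]
  either <- sum(ha | hb)
  if (either == 0) return(0)
  sum(ha & hb) / either
}

#' Detect clonemate groups
#'
#' Computes all pairwise shared-heterozygosity values and overall genotype
#' identities; pairs with shared_het >= `clone_threshold` AND identity >=
#' 1 - `error_rate_allowance` are linked; groups are the single-linkage
#' connected components. Within each group the sample with the highest call
#' rate is the retained representative.
#'
#' @param table a `genotype_table`.
#' @param clone_threshold shared-heterozygosity cutoff (default 0.9).
#' @param error_rate_allowance tolerated per-call genotype discordance.
#' @param min_sites minimum pairwise overlap for a comparison to count.
#' @return list with `groups` (list of sample-id vectors), `representative`
#'   (named by group), `excluded` (non-representative clonemates) and
#'   `pairwise` (data.frame of linked pairs).
#' @export
detect_clones <- function(table, clone_threshold = 0.9,
                          error_rate_allowance = 0.01, min_sites = 100L) {
  n <- length(table$samples)
  pc <- pair_het_counts(table)
  either <- pc$het_and_called + t(pc$het_and_called) - pc$both_het
  sh <- ifelse(either > 0, pc$both_het / either, 0)
  # overall genotype identity on pairwise-called sites
  d <- gt_dosage(table)
  idm <- matrix(0, n, n)
  same <- matrix(0, n, n)
  dd <- d; dd[is.na(dd)] <- -9L
  called <- !gt_missing(table)
  storage.mode(called) <- "double"
  for (g in 0:2) {
    m <- dd == g
    storage.mode(m) <- "double"
    same <- same + crossprod(m)
  }
  idm <- ifelse(pc$both_called > 0, same / pc$both_called, 0)
  link <- sh >= clone_threshold & idm >= 1 - error_rate_allowance &
    pc$both_called >= min_sites
  diag(link) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(link, mode = "undirected")
  comp <- igraph::components(gr)
  groups <- split(table$samples, comp$membership)
  groups <- groups[lengths(groups) > 1]
  call_rate <- colMeans(called)
  names(call_rate) <- table$samples
  rep_of <- vapply(groups, function(g) g[which.max(call_rate[g])],
                   character(1))
  pairs <- which(link & upper.tri(link), arr.ind = TRUE)
  list(groups = unname(groups), representative = unname(rep_of),
       excluded = setdiff(unlist(groups), rep_of),
       pairwise = data.frame(a = table$samples[pairs[, 1]],
                             b = table$samples[pairs[, 2]],
                             shared_het = sh[pairs],
                             identity = idm[pairs]))
}

#' Detect parent-descendant pairs under selfing
#'
#' Flags the ordered pair (P, D) when, over sites called in both,
#' (i) the fraction of D's heterozygous sites that are also heterozygous in P
#' is >= `het_subset_min`, (ii) the ratio |het(D)| / |het(P)| lies within the
#' central 99% binomial interval around 1/2, and (iii) the pair is not a
#' clonemate pair. The sample with fewer heterozygous sites is the
#' descendant.
#'
#' @param table a `genotype_table`.
#' @param het_subset_min condition (i) cutoff (default 0.99).
#' @param clone_threshold shared-het level above which a pair is treated as
#'   clonemates, not parent-offspring.
#' @param min_sites minimum pairwise-called overlap.
#' @return data.frame with `parent`, `descendant`, `het_subset_fraction`,
#'   `het_ratio`, `n_het_parent`, `n_het_descendant`.
#' @export
detect_selfing <- function(table, het_subset_min = 0.99,
                           clone_threshold = 0.9, min_sites = 100L) {
  pc <- pair_het_counts(table)
  n <- length(table$samples)
  either <- pc$het_and_called + t(pc$het_and_called) - pc$both_het
  sh <- ifelse(either > 0, pc$both_het / either, 0)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (pc$both_called[i, j] < min_sites) next
    # candidate: i = parent, j = descendant
    n_het_d <- pc$het_and_called[j, i]   # het in j among sites called in both
    n_het_p <- pc$het_and_called[i, j]
    if (n_het_d == 0 || n_het_p == 0) next
    if (n_het_d > n_het_p) next          # descendant has fewer het sites
    frac <- pc$both_het[i, j] / n_het_d
    if (frac < het_subset_min) next
    if (sh[i, j] >= clone_threshold) next
    lo <- stats::qbinom(0.005, n_het_p, 0.5) / n_het_p
    hi <- stats::qbinom(0.995, n_het_p, 0.5) / n_het_p
    ratio <- n_het_d / n_het_p
    if (ratio < lo || ratio > hi) next
    out[[length(out) + 1L]] <- data.frame(
      parent = table$samples[i], descendant = table$samples[j],
      het_subset_fraction = frac, het_ratio = ratio,
      n_het_parent = n_het_p, n_het_descendant = n_het_d)
  }
  if (!length(out))
    return(data.frame(parent = character(), descendant = character(),
                      het_subset_fraction = numeric(), het_ratio = numeric(),
                      n_het_parent = integer(), n_het_descendant = integer()))
  do.call(rbind, out)
}

#' Build the sample-exclusion ledger
#'
#' Combines selfing descendants, non-representative clonemates and
#' high-missing samples into one ledger with a single primary reason per
#' excluded sample, by priority selfing > clone > missing (configurable via
#' the order of `priority`).
#'
#' @param samples all sample ids entering the analysis.
#' @param selfing result of \link{detect_selfing} (its `descendant` column is
#'   excluded) or a character vector of sample ids.
#' @param clones result of \link{detect_clones} (its `excluded` component) or
#'   a character vector of sample ids.
#' @param missing_excluded character vector of high-missing sample ids.
#' @param priority order in which reasons claim a sample.
#' @return a `relatedness_report`: list with `ledger` (sample, reason),
#'   `retained`, `n_input`, `n_retained`.
#' @export
build_exclusion_ledger <- function(samples, selfing, clones,
                                   missing_excluded,
                                   priority = c("selfing", "clone",
                                                "missing")) {
  if (is.data.frame(selfing)) selfing <- unique(selfing$descendant)
  if (is.list(clones) && !is.null(clones$excluded)) clones <- clones$excluded
  sets <- list(selfing = selfing, clone = clones,
               missing = missing_excluded)
  unknown <- setdiff(unlist(sets), samples)
  if (length(unknown))
    stop("excluded ids not among input samples: ",
         paste(unknown, collapse = ", "))
  reason <- stats::setNames(rep(NA_character_, length(samples)), samples)
  for (p in priority) {
    ids <- intersect(sets[[p]], samples)
    free <- ids[is.na(reason[ids])]
    reason[free] <- p
  }
  ledger <- data.frame(sample = samples, reason = unname(reason[samples]),
                       stringsAsFactors = FALSE)
  retained <- samples[is.na(reason)]
  structure(list(ledger = ledger, retained = retained,
                 n_input = length(samples), n_retained = length(retained)),
            class = "relatedness_report")
}

#' @export
print.relatedness_report <- function(x, ...) {
  tab <- table(x$ledger$reason)
  cat(sprintf("relatedness_report: %d input, %d retained (%s)\n",
              x$n_input, x$n_retained,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
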