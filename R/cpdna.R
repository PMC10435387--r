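# Chloroplast haplotype analysis: pileup-based variable-position calling,
# artifact masking, haplotype collapsing, parsimony-informative selection,
# median-joining networks and mutation-step counting.

#' Eelgrass plastome structure constants
#'
#' Quadripartite architecture of the Zostera marina chloroplast genome: two
#' identical inverted repeats of 24,127 bp, a large single-copy region of
#' 83,312 bp and a small single-copy region of 12,402 bp (143,968 bp total),
#' with 9,818 bp of 23S/16S rRNA excluded from variant calling.
#'
#' @return list with `inverted_repeat`, `large_single_copy`,
#'   `small_single_copy`, `total`, `rrna_excluded`.
#' @export
eelgrass_plastome <- function() {
  list(inverted_repeat = 24127L, large_single_copy = 83312L,
       small_single_copy = 12402L, total = 143968L,
       rrna_excluded = 9818L)
}

#' Call chloroplast variable positions from per-sample pileups
#'
#' A position is variable for a sample iff its variant-read (non-reference)
#' fraction is strictly > 0.5 AND its total coverage is strictly > 0.3 x the
#' sample's median coverage (median over non-excluded positions). The
#' variable-position set is the union over samples.
#'
#' @param pileup a `cp_pileup` (see \link{simulate_cp_pileup}): list with
#'   `ref` (character vector of reference bases), and `samples`, a named list
#'   of integer count matrices (positions x A,C,G,T).
#' @param exclude optional integer positions excluded from the median
#'   computation (e.g. rRNA regions).
#' @return list with `positions` (sorted union), `per_sample` (named list of
#'   positions variable in each sample) and `median_coverage` (named).
#' @export
call_cp_variants <- function(pileup, exclude = NULL) {
  base_cols <- c("A", "C", "G", "T")
  ref_idx <- match(pileup$ref, base_cols)
  g <- length(pileup$ref)
  med <- numeric(0)
  per_sample <- list()
  for (id in names(pileup$samples)) {
    counts <- pileup$samples[[id]]
    cov <- rowSums(counts)
    use <- if (is.null(exclude)) cov else cov[-exclude]
    if (all(use == 0)) stop("zero-coverage genome for sample ", id)
    m <- stats::median(use)
    med[id] <- m
    refn <- counts[cbind(seq_len(g), ref_idx)]
    varf <- ifelse(cov > 0, (cov - refn) / cov, 0)
    hit <- which(varf > 0.5 & cov > 0.3 * m)
    if (!is.null(exclude)) hit <- setdiff(hit, exclude)
    per_sample[[id]] <- hit
  }
  list(positions = sort(unique(unlist(per_sample))),
       per_sample = per_sample, median_coverage = med)
}

#' Remove masked positions from a called variable-position set
#'
#' Masks are 0-based half-open intervals with a `name` (e.g. `rrna`,
#' `microsatellite`, `hairpin`). A position inside several masks is removed
#' once and attributed to the first matching mask in `priority` order.
#'
#' @param positions integer vector of 1-based positions.
#' @param masks data.frame with `start`, `end`, `name` (and optionally
#'   `chrom`, ignored: the plastome is a single molecule).
#' @param priority order in which masks claim a position; mask names not
#'   listed are appended in first-appearance order.
#' @return list with `positions` (retained), `removed` (data.frame pos,
#'   mask) and `counts` (removals per mask).
#' @export
apply_masks <- function(positions, masks,
                        priority = c("rrna", "microsatellite", "hairpin")) {
  if (is.null(masks) || nrow(masks) == 0)
    return(list(positions = positions,
                removed = data.frame(pos = integer(), mask = character()),
                counts = integer(0)))
  nm <- unique(c(intersect(priority, masks$name),
                 setdiff(masks$name, priority)))
  assigned <- stats::setNames(rep(NA_character_, length(positions)),
                              positions)
  for (mk in nm) {
    r <- masks[masks$name == mk, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      inside <- pos_in_interval(positions, r$start[i], r$end[i])
      assigned[inside & is.na(assigned)] <- mk
    }
  }
  removed <- data.frame(pos = positions[!is.na(assigned)],
                        mask = assigned[!is.na(assigned)])
  rownames(removed) <- NULL
  list(positions = positions[is.na(assigned)], removed = removed,
       counts = table(factor(removed$mask, levels = nm)))
}

#' Collapse sequences into haplotypes
#'
#' Identical strings (optionally first restricted to `positions`) collapse
#' into one haplotype. Missing states (anything outside A/C/G/T) are an
#' error naming the sample and offending position.
#'
#' @param sequences named character vector of equal-length sequences.
#' @param positions optional 1-based positions to restrict to.
#' @param pop_map optional data.frame `sample`, `population` for
#'   per-population counts.
#' @return list with `table` (haplotype, sequence, count), `assignment`
#'   (sample -> haplotype), `pop_counts` (matrix, if pop_map given).
#' @export
collapse_haplotypes <- function(sequences, positions = NULL, pop_map = NULL) {
  if (is.null(names(sequences))) stop("sequences must be named by sample")
  if (length(unique(nchar(sequences))) != 1)
    stop("sequences must have equal length")
  if (!is.null(positions)) {
    sequences <- vapply(sequences, function(s)
      paste(strsplit(s, "")[[1]][positions], collapse = ""),
      character(1))
  }
  for (id in names(sequences)) {
    ch <- strsplit(sequences[[id]], "")[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "T"))
    if (length(bad))
      stop("missing state in sample ", id, " at position ", bad[1])
  }
  uniq <- sort(unique(sequences))
  hid <- paste0("H", seq_along(uniq))
  assignment <- stats::setNames(hid[match(sequences, uniq)],
                                names(sequences))
  tab <- data.frame(haplotype = hid, sequence = uniq,
                    count = as.integer(table(factor(sequences,
                                                    levels = uniq))),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, assignment = assignment)
  if (!is.null(pop_map)) {
    pops <- unique(pop_map$population)
    m <- matrix(0L, nrow(tab), length(pops),
                dimnames = list(hid, pops))
    for (s in names(sequences)) {
      p <- pop_map$population[match(s, pop_map$sample)]
      if (!is.na(p)) m[assignment[[s]], p] <- m[assignment[[s]], p] + 1L
    }
    out$pop_counts <- m
  }
  out
}

#' Select parsimony-informative columns
#'
#' Retains alignment columns with at least two states each occurring in at
#' least two sequences (no singletons, no invariant columns).
#'
#' @param sequences character vector of equal-length strings.
#' @return integer vector of retained (1-based) column indices.
#' @export
parsimony_informative <- function(sequences) {
  if (length(unique(nchar(sequences))) != 1)
    stop("sequences must have equal length")
  m <- do.call(rbind, strsplit(sequences, ""))
  which(vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    sum(tab >= 2) >= 2
  }, logical(1)))
}

# --- median-joining machinery -------------------------------------------

hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# Minimum-spanning-tree length under Prim (unique value even when the tree
# is not); used as the objective the median additions must shorten.
mst_length <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  tot <- 0
  for (k in seq_len(n - 1)) {
    i <- which(!in_tree)[which.min(best[!in_tree])]
    tot <- tot + best[i]
    in_tree[i] <- TRUE
    best <- pmin(best, d[i, ])
  }
  tot
}

# Bottleneck (minimax path) distances: the connection thresholds lambda of
# the epsilon-relaxed minimum spanning network.
bottleneck_matrix <- function(d) {
  n <- nrow(d)
  b <- d
  # Floyd-Warshall on the minimax semiring
  for (k in seq_len(n)) {
    bk <- b[, k]
    for (i in seq_len(n)) {
      cand <- pmax(bk[i], bk)
      upd <- cand < b[i, ]
      b[i, upd] <- cand[upd]
    }
  }
  b
}

msn_edges <- function(d, epsilon) {
  lam <- bottleneck_matrix(d)
  keep <- d <= lam + epsilon & upper.tri(d)
  idx <- which(keep, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], weight = d[keep])
}

triplet_median <- function(chs, order_idx) {
  # column-majority consensus of three character vectors; a 3-way tie takes
  # the state of the lexicographically smallest member (order_idx[1])
  vapply(seq_along(chs[[1]]), function(p) {
    s <- c(chs[[1]][p], chs[[2]][p], chs[[3]][p])
    tab <- sort(table(s), decreasing = TRUE)
    if (tab[1] >= 2) names(tab)[1] else chs[[order_idx[1]]][p]
  }, character(1))
}

#' Median-joining haplotype network
#'
#' Deterministic construction: iterate (a) build the epsilon-relaxed minimum
#' spanning network (edges whose Hamming distance is within `epsilon` of the
#' pair's connection threshold, i.e. its minimax path distance), (b) over
#' triplets with at least two network edges among them, propose the
#' column-majority consensus (median) vector — 3-way column ties resolve to
#' the lexicographically smallest member — and add, in lexicographic order,
#' the first median that strictly shortens the minimum-spanning-tree length;
#' (c) on convergence prune unobserved degree-<=2 vertices whose removal
#' does not lengthen the tree. Every observed haplotype is a vertex and the
#' network is connected.
#'
#' @param haplotypes character vector of distinct equal-length sequences
#'   (names become vertex labels; unnamed get H1, H2, ...).
#' @param epsilon spanning-network relaxation, usually 0 or 1.
#' @return a `haplotype_network`: list with `graph` (igraph, edge attribute
#'   `weight` = mutation steps), `vertices` (data.frame name, sequence,
#'   observed), `edges`, `epsilon`, `mst_length`.
#' @export
median_joining_network <- function(haplotypes, epsilon = 0L) {
  if (length(haplotypes) < 2) stop("need at least 2 haplotypes")
  if (length(unique(nchar(haplotypes))) != 1)
    stop("haplotypes must have equal length")
  haplotypes <- haplotypes[!duplicated(unname(haplotypes))]
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("H", seq_along(haplotypes))
  seqs <- unname(haplotypes)
  observed <- rep(TRUE, length(seqs))
  n_med <- 0L
  repeat {
    d <- hamming_matrix(seqs)
    cur_len <- mst_length(d)
    ed <- msn_edges(d, epsilon)
    adj <- matrix(FALSE, length(seqs), length(seqs))
    adj[cbind(ed$i, ed$j)] <- TRUE
    adj <- adj | t(adj)
    cands <- character(0)
    cand_src <- list()
    n <- length(seqs)
    if (n >= 3) {
      chs <- strsplit(seqs, "")
      for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2) next
        trip <- c(i, j, k)
        ord <- trip[order(seqs[trip])]
        med <- paste(triplet_median(chs[ord], seq_along(ord)), collapse = "")
        if (med %in% seqs || med %in% cands) next
        cands <- c(cands, med)
      }
    }
    if (!length(cands)) break
    cands <- sort(cands)
    added <- FALSE
    for (m in cands) {
      dm <- vapply(strsplit(c(m), "")[[1]], identity, character(1))
      new_d <- rbind(cbind(d, 0L), 0L)
      hm <- vapply(seqs, function(s)
        sum(strsplit(s, "")[[1]] != dm), integer(1))
      new_d[n + 1L, seq_len(n)] <- hm
      new_d[seq_len(n), n + 1L] <- hm
      if (mst_length(new_d) < cur_len) {
        seqs <- c(seqs, m)
        observed <- c(observed, FALSE)
        n_med <- n_med + 1L
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  # prune obsolete medians
  repeat {
    d <- hamming_matrix(seqs)
    cur_len <- mst_length(d)
    ed <- msn_edges(d, epsilon)
    deg <- tabulate(c(ed$i, ed$j), length(seqs))
    drop <- NA_integer_
    for (i in order(seqs)) {
      if (observed[i] || deg[i] > 2) next
      if (mst_length(d[-i, -i, drop = FALSE]) <= cur_len) { drop <- i; break }
    }
    if (is.na(drop)) break
    seqs <- seqs[-drop]
    observed <- observed[-drop]
  }
  d <- hamming_matrix(seqs)
  ed <- msn_edges(d, epsilon)
  labels <- character(length(seqs))
  labels[observed] <- names(haplotypes)[match(seqs[observed], haplotypes)]
  labels[!observed] <- paste0("mv", seq_len(sum(!observed)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = labels[ed$i], to = labels[ed$j], weight = ed$weight),
    directed = FALSE,
    vertices = data.frame(name = labels, sequence = seqs,
                          observed = observed))
  structure(list(graph = g,
                 vertices = data.frame(name = labels, sequence = seqs,
                                       observed = observed),
                 edges = data.frame(from = labels[ed$i], to = labels[ed$j],
                                    weight = ed$weight),
                 epsilon = epsilon, mst_length = mst_length(d)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype_network: %d observed + %d median vertices, %d edges (eps %d)\n",
    sum(x$vertices$observed), sum(!x$vertices$observed), nrow(x$edges),
    x$epsilon))
  invisible(x)
}

#' Mutation steps separating two haplotype groups
#'
#' Reports both the minimum Hamming distance between members of the two
#' groups and the minimum network path weight (which is always >= the
#' Hamming distance).
#'
#' @param network a `haplotype_network`.
#' @param group_a,group_b vertex names or haplotype sequences.
#' @return list with `hamming` and `path`.
#' @export
count_mutation_steps <- function(network, group_a, group_b) {
  v <- network$vertices
  resolve <- function(g) {
    i <- match(g, v$name)
    i[is.na(i)] <- match(g[is.na(i)], v$sequence)
    if (anyNA(i)) stop("unknown haplotype in group")
    i
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  if (!length(ia) || !length(ib)) stop("groups must be non-empty")
  ham <- min(hamming_matrix(v$sequence)[ia, ib, drop = FALSE])
  pd <- igraph::distances(network$graph, v = v$name[ia], to = v$name[ib],
                          weights = igraph::E(network$graph)$weight)
  list(hamming = ham, path = min(pd))
}
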