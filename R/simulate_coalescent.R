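# Structured-coalescent simulator: Hudson-style event-driven coalescent with
# piecewise-constant sizes, population splits and admixture pulses; loci are
# independent and non-recombining; mutations follow the infinite-sites model
# on a finite position grid (distinct positions per locus).

# Simulate one locus genealogy. Returns parent/time vectors plus, for every
# internal node, its two children, so descendant leaf sets can be rebuilt.
sim_locus_tree <- function(n_leaves_per_pop, epochs, events) {
  npop <- length(epochs)
  n_leaves <- sum(n_leaves_per_pop)
  n_nodes_max <- 2L * n_leaves - 1L
  parent <- integer(n_nodes_max)
  ntime <- numeric(n_nodes_max)
  child1 <- integer(n_nodes_max)
  child2 <- integer(n_nodes_max)
  active <- seq_len(n_leaves)
  apop <- rep.int(seq_len(npop), n_leaves_per_pop)
  nxt <- n_leaves + 1L
  t <- 0
  ev_i <- 1L
  n_ev <- nrow(events)
  ep_time <- lapply(epochs, `[[`, "time")
  ep_ne <- lapply(epochs, `[[`, "ne")
  while (length(active) > 1L) {
    k <- tabulate(apop, npop)
    ne_t <- vapply(seq_len(npop), function(j)
      ep_ne[[j]][findInterval(t, ep_time[[j]])], numeric(1))
    rates <- k * (k - 1) / (4 * ne_t)
    tot <- sum(rates)
    t_ev <- if (ev_i <= n_ev) events$time[ev_i] else Inf
    if (tot > 0) {
      dt <- stats::rexp(1L, tot)
      if (t + dt < t_ev) {
        t <- t + dt
        j <- if (npop == 1L) 1L else
          sample.int(npop, 1L, prob = rates / tot)
        idx <- which(apop == j)
        pick <- if (length(idx) == 2L) idx else
          idx[sample.int(length(idx), 2L)]
        node <- nxt; nxt <- nxt + 1L
        a <- active[pick[1L]]; b <- active[pick[2L]]
        parent[a] <- node; parent[b] <- node
        child1[node] <- a; child2[node] <- b
        ntime[node] <- t
        active <- c(active[-pick], node)
        apop <- c(apop[-pick], j)
        next
      }
    }
    if (is.infinite(t_ev))
      stop("lineages in disconnected populations cannot coalesce")
    t <- t_ev
    if (events$type[ev_i] == "split") {
      apop[apop == events$a[ev_i]] <- events$b[ev_i]
    } else if (events$type[ev_i] == "pulse") {
      mv <- apop == events$a[ev_i] &
        stats::runif(length(apop)) < events$fraction[ev_i]
      apop[mv] <- events$b[ev_i]
    } # "epoch": rate change only
    ev_i <- ev_i + 1L
  }
  list(parent = parent, time = ntime, child1 = child1, child2 = child2,
       n_leaves = n_leaves)
}

# Leaf sets below every node, in node-id order (children are always created
# before their parent, so a single forward pass suffices).
tree_leaf_sets <- function(tree) {
  n_nodes <- 2L * tree$n_leaves - 1L
  desc <- vector("list", n_nodes)
  for (i in seq_len(tree$n_leaves)) desc[[i]] <- i
  if (n_nodes > tree$n_leaves)
    for (i in (tree$n_leaves + 1L):n_nodes)
      desc[[i]] <- c(desc[[tree$child1[i]]], desc[[tree$child2[i]]])
  desc
}

# Drop infinite-sites mutations on a genealogy; returns a 0/1 haplotype
# matrix (mutations x leaves) and sorted distinct positions.
sim_locus_mutations <- function(tree, mu, locus_length) {
  n_nodes <- 2L * tree$n_leaves - 1L
  nonroot <- seq_len(n_nodes - 1L)
  blen <- tree$time[tree$parent[nonroot]] - tree$time[nonroot]
  tot <- sum(blen)
  n_mut <- stats::rpois(1L, mu * locus_length * tot)
  n_mut <- min(n_mut, locus_length)
  if (n_mut == 0L)
    return(list(pos = integer(), hap = matrix(0L, 0L, tree$n_leaves)))
  branch <- nonroot[sample.int(n_nodes - 1L, n_mut, replace = TRUE,
                               prob = blen)]
  pos <- sort(sample.int(locus_length, n_mut))
  desc <- tree_leaf_sets(tree)
  hap <- matrix(0L, n_mut, tree$n_leaves)
  for (m in seq_len(n_mut)) hap[m, desc[[branch[m]]]] <- 1L
  list(pos = pos, hap = hap)
}

# Compile the model's demographic events into the simulator's internal form.
compile_events <- function(model) {
  pops <- names(model$populations)
  ev <- data.frame(time = numeric(), type = character(), a = integer(),
                   b = integer(), fraction = numeric())
  if (nrow(model$splits))
    ev <- rbind(ev, data.frame(
      time = model$splits$time, type = "split",
      a = match(model$splits$derived, pops),
      b = match(model$splits$ancestral, pops), fraction = NA_real_))
  if (nrow(model$pulses))
    ev <- rbind(ev, data.frame(
      time = model$pulses$time, type = "pulse",
      a = match(model$pulses$target, pops),
      b = match(model$pulses$source, pops),
      fraction = model$pulses$fraction))
  for (j in seq_along(model$populations)) {
    tt <- model$populations[[j]]$time
    tt <- tt[tt > 0]
    if (length(tt))
      ev <- rbind(ev, data.frame(time = tt, type = "epoch", a = j, b = j,
                                 fraction = NA_real_))
  }
  ord <- order(ev$time, match(ev$type, c("pulse", "epoch", "split")))
  ev[ord, , drop = FALSE]
}

#' Simulate a multi-population diploid SNP dataset under the coalescent
#'
#' Event-driven structured coalescent without recombination within loci;
#' loci are independent; infinite-sites mutations (distinct positions within a
#' locus). Diploid individuals pair two haploid lineages sampled from the same
#' population (random mating). Every variant record carries passing INFO
#' metrics and call-level GQ/DP/AD consistent with its genotype, so the QC
#' cascade leaves clean simulations untouched until `corrupt_for_qc` is used.
#'
#' @param model a `demographic_model`.
#' @param n_samples_per_pop named integer vector of diploids per population
#'   (names must match the model), or a single integer recycled to all
#'   populations.
#' @param seed integer seed; identical seeds give identical outputs.
#' @param ann_probs probabilities for the `synonymous`, `nonsynonymous`,
#'   `noncoding` annotation classes assigned per site.
#' @return a `simulated_dataset`: list with `genotypes` (a
#'   \link{genotype_table}; chromosomes are named `locus0001`, ...), `truth`
#'   (per-sample data.frame of population, clone group, selfing parent),
#'   `true_tree_times` (named split times, generations), `seed`, `model`.
#' @examples
#' d <- simulate_coalescent(two_pop_model(5000, n_loci = 5), c(A = 2, B = 2), seed = 1)
#' dim(d$genotypes)
#' @export
simulate_coalescent <- function(model, n_samples_per_pop, seed,
                                ann_probs = c(synonymous = 0.25,
                                              nonsynonymous = 0.35,
                                              noncoding = 0.40)) {
  validate_demographic_model(model)
  pops <- names(model$populations)
  if (length(n_samples_per_pop) == 1L && is.null(names(n_samples_per_pop)))
    n_samples_per_pop <- stats::setNames(rep(n_samples_per_pop, length(pops)),
                                         pops)
  if (!setequal(names(n_samples_per_pop), pops))
    stop("n_samples_per_pop names must match model populations")
  n_dip <- as.integer(n_samples_per_pop[pops])
  if (any(n_dip < 1L)) stop("need at least one diploid per population")
  set.seed(as.integer(seed))
  events <- compile_events(model)
  epochs <- model$populations
  n_hap_per_pop <- 2L * n_dip
  samples <- unlist(lapply(seq_along(pops), function(j)
    sprintf("%s%02d", pops[j], seq_len(n_dip[j]))))
  sample_pop <- rep.int(pops, n_dip)

  pos_l <- vector("list", model$n_loci)
  hap_l <- vector("list", model$n_loci)
  for (l in seq_len(model$n_loci)) {
    tree <- sim_locus_tree(n_hap_per_pop, epochs, events)
    mut <- sim_locus_mutations(tree, model$mutation_rate, model$locus_length)
    pos_l[[l]] <- mut$pos
    hap_l[[l]] <- mut$hap
  }
  n_per_locus <- lengths(pos_l)
  n_sites <- sum(n_per_locus)
  hap <- do.call(rbind, hap_l)
  chrom <- rep(sprintf("locus%04d", seq_len(model$n_loci)), n_per_locus)
  pos <- unlist(pos_l)

  odd <- seq_len(sum(n_dip)) * 2L - 1L
  ga <- hap[, odd, drop = FALSE]
  gb <- hap[, odd + 1L, drop = FALSE]
  colnames(ga) <- colnames(gb) <- samples

  bases <- c("A", "C", "G", "T")
  ref <- if (n_sites) sample(bases, n_sites, replace = TRUE) else character()
  alt <- if (n_sites) vapply(ref, function(r)
    sample(setdiff(bases, r), 1L), character(1), USE.NAMES = FALSE)
    else character()

  n_calls <- n_sites * sum(n_dip)
  dp <- matrix(10L + stats::rpois(n_calls, 30), n_sites, sum(n_dip))
  gq <- matrix(pmin(99L, 30L + stats::rpois(n_calls, 60)), n_sites,
               sum(n_dip))
  het <- ga != gb
  ad_alt <- matrix(0L, n_sites, sum(n_dip))
  ad_alt[het] <- stats::rbinom(sum(het), dp[het], 0.5)
  homalt <- !het & ga > 0L
  ad_alt[homalt] <- dp[homalt]
  ad_ref <- dp - ad_alt

  sites <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    type = rep("snp", n_sites),
    MQ = stats::runif(n_sites, 50, 60), FS = stats::runif(n_sites, 0, 5),
    QD = stats::runif(n_sites, 20, 35),
    MQRankSum = stats::runif(n_sites, -1, 1),
    ReadPosRankSum = stats::runif(n_sites, -1, 1),
    SOR = stats::runif(n_sites, 0.5, 1.5),
    DP = as.numeric(rowSums(dp)),
    ann = if (n_sites) sample(names(ann_probs), n_sites, replace = TRUE,
                              prob = ann_probs) else character(),
    qc_tag = rep(NA_character_, n_sites), stringsAsFactors = FALSE)

  gt <- genotype_table(sites, ga, gb, gq, dp, ad_ref, ad_alt, samples)
  truth <- data.frame(sample = samples, population = sample_pop,
                      clone_group = NA_character_,
                      selfed_from = NA_character_, stringsAsFactors = FALSE)
  structure(list(genotypes = gt, truth = truth,
                 true_tree_times = stats::setNames(model$splits$time,
                                                   model$splits$derived),
                 seed = as.integer(seed), model = model),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d samples, %d variant sites (seed %d)\n",
              length(x$genotypes$samples), nrow(x$genotypes$sites), x$seed))
  invisible(x)
}
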