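#' Demographic model for the coalescent simulator
#'
#' Describes a population tree with (piecewise-constant) diploid effective
#' sizes, split times in generations before present, optional single-generation
#' admixture pulses, a per-site per-generation mutation rate, a generation
#' time in years, and the locus layout.
#'
#' @param populations either a character vector of population names (all sizes
#'   taken from `ne`) or a named list mapping population name to a diploid
#'   size: a single number for a constant size, or a data.frame with columns
#'   `time` (start of the epoch, generations before present, first row must be
#'   0) and `ne` for piecewise-constant histories.
#' @param ne default constant diploid effective size used when `populations`
#'   is a character vector.
#' @param splits data.frame with columns `derived`, `ancestral`, `time`
#'   (generations): looking back in time, lineages of `derived` join
#'   `ancestral` at `time`. May be empty/NULL for a single population.
#' @param pulses optional data.frame with columns `source`, `target`, `time`,
#'   `fraction`: forward in time, a fraction of `target` is replaced by
#'   migrants from `source` at `time` (backwards, target lineages jump to
#'   source with that probability).
#' @param mutation_rate per-site per-generation mutation rate (>= 0).
#' @param generation_time years per generation (> 0).
#' @param n_loci number of independent non-recombining loci.
#' @param locus_length locus length in bp.
#' @return an object of class `demographic_model`.
#' @examples
#' two_pop_model(split_gens = 5000)
#' @export
demographic_model <- function(populations, ne = 10000, splits = NULL,
                              pulses = NULL, mutation_rate = 1e-8,
                              generation_time = 3, n_loci = 100,
                              locus_length = 5000) {
  if (is.character(populations)) {
    populations <- stats::setNames(as.list(rep(ne, length(populations))),
                                   populations)
  }
  pop_names <- names(populations)
  if (is.null(pop_names) || any(pop_names == "") || anyDuplicated(pop_names))
    stop("populations must be uniquely named")
  populations <- lapply(populations, function(p) {
    if (is.data.frame(p)) {
      if (!all(c("time", "ne") %in% names(p))) stop("epoch table needs time, ne")
      p <- p[order(p$time), , drop = FALSE]
      if (p$time[1] != 0) stop("first epoch must start at time 0")
      if (any(p$ne <= 0)) stop("effective sizes must be positive")
      p
    } else {
      if (length(p) != 1 || p <= 0) stop("effective sizes must be positive scalars")
      data.frame(time = 0, ne = as.numeric(p))
    }
  })
  if (is.null(splits)) splits <- data.frame(derived = character(),
                                            ancestral = character(),
                                            time = numeric())
  if (is.null(pulses)) pulses <- data.frame(source = character(),
                                            target = character(),
                                            time = numeric(),
                                            fraction = numeric())
  if (mutation_rate < 0) stop("mutation_rate must be >= 0")
  if (generation_time <= 0) stop("generation_time must be positive")
  if (n_loci < 1 || locus_length < 1) stop("invalid locus_spec")
  if (nrow(pulses) && (any(pulses$fraction <= 0) || any(pulses$fraction >= 1)))
    stop("admixture fractions must lie strictly in (0, 1)")
  model <- structure(list(populations = populations, splits = splits,
                          pulses = pulses, mutation_rate = mutation_rate,
                          generation_time = generation_time,
                          n_loci = as.integer(n_loci),
                          locus_length = as.integer(locus_length)),
                     class = "demographic_model")
  validate_demographic_model(model)
  model
}

#' Validate a demographic model
#'
#' Checks split times are strictly positive and topologically consistent
#' (every population merges at most once, into a population that has not yet
#' merged away; after all splits exactly one root population remains when
#' more than one population is declared).
#'
#' @param model a `demographic_model`.
#' @return the model, invisibly; errors describe the violation.
#' @export
validate_demographic_model <- function(model) {
  pops <- names(model$populations)
  sp <- model$splits
  if (nrow(sp)) {
    if (any(sp$time <= 0)) stop("split times must be strictly positive")
    if (!all(c(sp$derived, sp$ancestral) %in% pops))
      stop("split references unknown population")
    sp <- sp[order(sp$time), , drop = FALSE]
    gone <- character()
    merged_at <- stats::setNames(rep(Inf, length(pops)), pops)
    for (i in seq_len(nrow(sp))) {
      d <- sp$derived[i]; a <- sp$ancestral[i]; t <- sp$time[i]
      if (d == a) stop("a population cannot merge into itself")
      if (d %in% gone) stop("population '", d, "' merges twice")
      if (t >= merged_at[a])
        stop("split into '", a, "' at time ", t,
             " but '", a, "' has already merged (child must precede parent)")
      gone <- c(gone, d)
      merged_at[d] <- t
    }
    if (length(pops) - length(gone) != 1)
      stop("splits must leave exactly one root population")
  } else if (length(pops) > 1) {
    stop("multiple populations but no splits: lineages could never coalesce")
  }
  if (nrow(model$pulses)) {
    pu <- model$pulses
    if (!all(c(pu$source, pu$target) %in% pops))
      stop("pulse references unknown population")
    if (any(pu$time <= 0)) stop("pulse times must be strictly positive")
  }
  invisible(model)
}

#' Two-population isolation model helper
#'
#' Convenience constructor for the split-time recovery experiments: two
#' populations of constant equal size that diverged `split_gens` generations
#' ago, no migration.
#'
#' @param split_gens divergence time in generations.
#' @param ne diploid effective size of each population and of the ancestor.
#' @param mutation_rate per-site per-generation mutation rate.
#' @param generation_time years per generation.
#' @param n_loci,locus_length locus layout.
#' @return a `demographic_model` with populations `A`, `B`, root `B`.
#' @export
two_pop_model <- function(split_gens, ne = 10000, mutation_rate = 1e-8,
                          generation_time = 3, n_loci = 500,
                          locus_length = 5000) {
  demographic_model(
    populations = c("A", "B"), ne = ne,
    splits = data.frame(derived = "A", ancestral = "B", time = split_gens),
    mutation_rate = mutation_rate, generation_time = generation_time,
    n_loci = n_loci, locus_length = locus_length)
}

#' Eelgrass range-expansion demography configuration
#'
#' Node ages (kya) of the dated population phylogeny used as ground truth for
#' split-time recovery: the first trans-Pacific dispersal founding the
#' southern East-Pacific lineage (~352 kya), the second trans-Pacific
#' dispersal seeding Alaska (~270 kya), the colonization of the Atlantic
#' (~243 kya), the founding of the Mediterranean clade (~43.8 kya) and the
#' Northwest/Northeast Atlantic divergence (~18.8 kya), with a mean
#' generation time of 3 years.
#'
#' @return list with `node_times_kya` (named numeric), `generation_time`
#'   (years) and `node_times_generations` (named numeric).
#' @export
eelgrass_demography_config <- function() {
  kya <- c(trans_pacific_1 = 352, trans_pacific_2 = 270, atlantic = 243,
           mediterranean = 43.8, atlantic_w_e = 18.8)
  g <- 3
  list(node_times_kya = kya, generation_time = g,
       node_times_generations = kya * 1000 / g)
}
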