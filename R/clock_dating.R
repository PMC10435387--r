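# Molecular-clock arithmetic: chloroplast mutation-step dating, generation
# to year conversion, effective-population-size minima, lognormal
# calibration bookkeeping, and the net-divergence split-time estimator used
# for simulation-based parameter recovery.

#' Clock parameters
#'
#' @param mu_per_year per-site per-year mutation rate; either give this or
#'   `mu_per_generation` together with `generation_time`.
#' @param n_sites number of sites L the distance was measured over.
#' @param mu_per_generation per-site per-generation rate.
#' @param generation_time years per generation.
#' @return list of class `clock_params` with `mu_per_year`, `n_sites`,
#'   `generation_time`.
#' @export
clock_params <- function(mu_per_year = NULL, n_sites = NULL,
                         mu_per_generation = NULL, generation_time = 3) {
  if (is.null(mu_per_year)) {
    if (is.null(mu_per_generation))
      stop("give mu_per_year or mu_per_generation")
    mu_per_year <- mu_per_generation / generation_time
  }
  if (mu_per_year <= 0) stop("mutation rate must be positive")
  if (generation_time <= 0) stop("generation_time must be positive")
  structure(list(mu_per_year = mu_per_year, n_sites = n_sites,
                 generation_time = generation_time),
            class = "clock_params")
}

#' Chloroplast mutation-step divergence time
#'
#' t = k / (2 mu L) years for k mutation steps over L sites at per-year rate
#' mu (the factor 2 counts accumulation along both diverging lineages).
#' With the eelgrass synonymous plastome rate of 2e-9 per site per year,
#' ~30 steps over the analysed plastome correspond to a few hundred kyr.
#'
#' @param k mutation steps (>= 0).
#' @param params a \link{clock_params} with `n_sites` set.
#' @return divergence time in years.
#' @export
cp_clock_time <- function(k, params) {
  if (k < 0) stop("k must be >= 0")
  if (is.null(params$n_sites) || params$n_sites <= 0)
    stop("clock_params$n_sites must be positive")
  k / (2 * params$mu_per_year * params$n_sites)
}

#' Convert generations to years
#'
#' @param g_count number of generations.
#' @param gen_time years per generation.
#' @return years (the product).
#' @export
generations_to_years <- function(g_count, gen_time) {
  if (gen_time <= 0 || g_count < 0) stop("inputs must be positive")
  g_count * gen_time
}

#' Local minima of an effective-population-size trajectory
#'
#' Finds strict local minima of log N_e over trajectory steps older than
#' `ignore_recent` generations (recent sequentially-Markovian-coalescent
#' estimates are unreliable). Endpoints are not minima; the result is
#' invariant to monotone rescaling of N_e.
#'
#' @param traj data.frame with columns `generations` (strictly increasing)
#'   and `ne` (> 0).
#' @param ignore_recent generations; steps at or under this age are ignored.
#' @return data.frame with `generations` and `ne` of each minimum (possibly
#'   zero rows).
#' @export
find_ne_minima <- function(traj, ignore_recent = 1000) {
  if (!all(c("generations", "ne") %in% names(traj)))
    stop("traj needs generations, ne")
  if (nrow(traj) < 3) stop("need at least 3 trajectory steps")
  if (any(diff(traj$generations) <= 0)) stop("times must be strictly increasing")
  if (any(traj$ne <= 0)) stop("ne must be positive")
  keep <- traj$generations > ignore_recent
  tr <- traj[keep, , drop = FALSE]
  n <- nrow(tr)
  if (n < 3) return(tr[0, c("generations", "ne")])
  x <- log(tr$ne)
  i <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  out <- tr[i, c("generations", "ne")]
  rownames(out) <- NULL
  out
}

#' Lognormal calibration prior
#'
#' `mean` is interpreted as the real-space mean and `sd` as the log-space
#' standard deviation (the convention of multispecies-coalescent calibration
#' files), so meanlog = log(mean) - sd^2 / 2.
#'
#' @param mean real-space mean (e.g. mya).
#' @param sd log-space standard deviation.
#' @return a `calibration_prior`: list with `mean`, `sd`, `meanlog`,
#'   `density(x)` and `quantile(p)` functions.
#' @export
build_calibration <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("mean and sd must be positive")
  meanlog <- log(mean) - sd^2 / 2
  structure(list(
    mean = mean, sd = sd, meanlog = meanlog,
    density = function(x) stats::dlnorm(x, meanlog, sd),
    quantile = function(p) stats::qlnorm(p, meanlog, sd)),
    class = "calibration_prior")
}

#' Eelgrass calibration constants
#'
#' The two multispecies-coalescent calibration priors used for the dated
#' species tree: the Zostera marina - Z. japonica divergence (lognormal,
#' real-space mean 11.154 mya, log-sd 0.07; derived upstream from a
#' whole-genome-duplication clock) and the within-species crown age
#' (lognormal, mean 0.3564 mya, log-sd 0.1), plus the synonymous plastome
#' clock rate 2e-9 per site per year.
#'
#' @return named list of `calibration_prior` objects and `cp_mu_per_year`.
#' @export
eelgrass_calibrations <- function() {
  list(species_split = build_calibration(11.154, 0.07),
       marina_crown = build_calibration(0.3564, 0.1),
       cp_mu_per_year = 2e-9)
}

#' Net-divergence split-time estimator
#'
#' For two populations genotyped over a known total sequence length,
#' d_a = d_xy - (pi_A + pi_B) / 2 removes the ancestral-diversity component
#' from the raw between-population divergence, and T = d_a / (2 mu_year)
#' estimates the split time in years. Negative d_a (drift noise around zero)
#' returns 0 with a warning.
#'
#' @param table a `genotype_table` holding both populations.
#' @param samples_a,samples_b sample ids of the two populations.
#' @param params a \link{clock_params}.
#' @param total_length total surveyed sequence length in bp (monomorphic
#'   sites included), e.g. n_loci x locus_length for simulated data.
#' @return list with `split_time_years`, `split_time_generations`, `d_xy`,
#'   `pi_a`, `pi_b`, `d_a` (all per site).
#' @export
net_divergence_split_time <- function(table, samples_a, samples_b, params,
                                      total_length) {
  ia <- match(samples_a, table$samples)
  ib <- match(samples_b, table$samples)
  if (anyNA(c(ia, ib))) stop("unknown sample id")
  d <- gt_dosage(table)
  da <- d[, ia, drop = FALSE]
  db <- d[, ib, drop = FALSE]
  na <- 2 * rowSums(!is.na(da))
  nb <- 2 * rowSums(!is.na(db))
  ca <- rowSums(da, na.rm = TRUE)
  cb <- rowSums(db, na.rm = TRUE)
  pa <- ca / na
  pb <- cb / nb
  dxy <- sum(pa * (1 - pb) + pb * (1 - pa)) / total_length
  pia <- sum(2 * ca * (na - ca) / (na * (na - 1))) / total_length
  pib <- sum(2 * cb * (nb - cb) / (nb * (nb - 1))) / total_length
  da_net <- dxy - (pia + pib) / 2
  if (da_net < 0) {
    warning("negative net divergence (drift noise); returning 0")
    da_net <- 0
  }
  t_years <- da_net / (2 * params$mu_per_year)
  list(split_time_years = t_years,
       split_time_generations = t_years / params$generation_time,
       d_xy = dxy, pi_a = pia, pi_b = pib, d_a = da_net)
}

#' Split-time recovery experiment
#'
#' Simulates a two-population isolation model at a known split time and
#' re-estimates the split with \link{net_divergence_split_time}, averaging
#' over seeds. This exercises the simulator and the dating arithmetic
#' jointly.
#'
#' @param split_gens true split time in generations.
#' @param n_loci,locus_length locus layout (default 500 x 5 kb).
#' @param ne diploid size (default 10000).
#' @param n_per_pop diploids sampled per population (default 10).
#' @param mu per-site per-generation mutation rate (default 1e-8).
#' @param generation_time years per generation (default 3).
#' @param seeds integer vector of simulation seeds (>= 5 recommended).
#' @return list with `mean_years`, `mean_kya`, `per_seed_years`,
#'   `true_years`, `relative_error`.
#' @export
recover_split_time <- function(split_gens, n_loci = 500L,
                               locus_length = 5000L, ne = 10000,
                               n_per_pop = 10L, mu = 1e-8,
                               generation_time = 3, seeds = 1:5) {
  model <- two_pop_model(split_gens, ne = ne, mutation_rate = mu,
                         generation_time = generation_time,
                         n_loci = n_loci, locus_length = locus_length)
  params <- clock_params(mu_per_generation = mu,
                         generation_time = generation_time)
  est <- vapply(seeds, function(s) {
    d <- simulate_coalescent(model, c(A = n_per_pop, B = n_per_pop),
                             seed = s)
    g <- d$genotypes
    a <- g$samples[startsWith(g$samples, "A")]
    b <- g$samples[startsWith(g$samples, "B")]
    net_divergence_split_time(g, a, b, params,
                              total_length = as.numeric(n_loci) *
                                locus_length)$split_time_years
  }, numeric(1))
  true_years <- split_gens * generation_time
  m <- mean(est)
  list(mean_years = m, mean_kya = m / 1000, per_seed_years = est,
       true_years = true_years,
       relative_error = abs(m - true_years) / true_years)
}
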