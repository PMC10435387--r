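# End-to-end orchestration: a single configuration drives synthesis (or
# ingestion), QC, clonality, PAV, statistics, chloroplast haplotypes and
# dating, with per-stage caching keyed by a content hash of parameters +
# seed so re-runs are reproducible and resumable.

pipeline_stages <- c("simulate", "qc", "clones", "pav", "stats", "cpdna",
                     "dating")

#' Default pipeline configuration
#'
#' Synthetic-mode demo configuration: a two-population model with clone,
#' selfing and missing-rate injection mirroring a range-wide resequencing
#' design, plus small PAV and chloroplast blocks.
#'
#' @param outdir output directory.
#' @param seed global seed; each stage derives a namespaced seed from it.
#' @param stages stages to run, in dependency order.
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function(outdir = tempfile("meadowpop_run_"),
                                    seed = 1L,
                                    stages = pipeline_stages) {
  list(
    seed = as.integer(seed), outdir = outdir, stages = stages,
    synthetic = list(
      ne = 10000, split_gens = 5000, mutation_rate = 1e-7,
      generation_time = 3, n_loci = 60, locus_length = 1000,
      n_per_pop = 12, n_clonemate_copies = 2, n_selfed = 2,
      genotyping_error_rate = 0, n_high_missing_samples = 2,
      missing_rate = 0.25),
    qc = list(),          # filter_config() overrides
    clones = list(clone_threshold = 0.9, error_rate_allowance = 0.01),
    pav = list(n_genes = 300, n_samples = 12, min_genes = 150,
               class_fractions = c(cloud = 0.2, shell = 0.2, core = 0.6)),
    stats = list(n_boot = 200),
    cpdna = list(n_samples = 6, genome_length = 20000, n_variable = 30,
                 n_microsat_artifacts = 3, n_hairpin_artifacts = 2,
                 median_coverage = 200, epsilon = 0),
    dating = list(mu_per_generation = NULL))   # NULL: reuse synthetic rate
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns structured diagnostics rather than
#' stopping, so callers (and the CLI) can report all problems at once.
#'
#' @param config a configuration list (see
#'   \link{default_pipeline_config}).
#' @return data.frame with columns `level` ("fatal"/"warning") and
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(config) {
  d <- list()
  bad <- function(msg) d[[length(d) + 1L]] <<- data.frame(level = "fatal",
                                                          message = msg)
  warn <- function(msg) d[[length(d) + 1L]] <<- data.frame(level = "warning",
                                                           message = msg)
  if (is.null(config$seed) || !is.finite(config$seed)) bad("seed missing")
  if (is.null(config$outdir)) bad("outdir missing")
  unknown <- setdiff(config$stages, pipeline_stages)
  if (length(unknown)) bad(paste("unknown stages:",
                                 paste(unknown, collapse = ", ")))
  has_synth <- !is.null(config$synthetic)
  has_real <- !is.null(config$vcf)
  if (has_synth && has_real)
    bad("exactly one of {synthetic block, real inputs} may be active")
  if (!has_synth && !has_real && length(config$stages))
    bad("neither synthetic block nor real inputs configured")
  if (!is.null(config$qc$thin_distance) && config$qc$thin_distance <= 0)
    bad("thin_distance must be positive")
  if ("stats" %in% config$stages && isTRUE(config$stats$d_statistics) &&
      is.null(config$stats$outgroup))
    bad("D-statistics enabled without an outgroup")
  if ("cpdna" %in% config$stages && has_real && is.null(config$cp_masks))
    bad("cpdna stage on real inputs requires mask intervals")
  if (has_synth && !is.null(config$synthetic$n_per_pop) &&
      config$synthetic$n_per_pop < 2)
    warn("fewer than 2 diploids per population limits the statistics stage")
  if (!length(d)) return(data.frame(level = character(),
                                    message = character()))
  out <- do.call(rbind, d)
  rownames(out) <- NULL
  out
}

# content hash of an R object (via serialization to a temp file)
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stage_seed <- function(config, stage) {
  (config$seed + 1009L * match(stage, pipeline_stages)) %% .Machine$integer.max
}

# run one cached stage: if the manifest hash matches, reload the cached RDS
run_stage <- function(name, config, params, fun) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(config$outdir, paste0(name, ".hash"))
  cache <- file.path(config$outdir, paste0(name, ".cache.rds"))
  h <- content_hash(list(params = params, seed = stage_seed(config, name)))
  if (file.exists(manifest) && file.exists(cache) &&
      identical(readLines(manifest, warn = FALSE)[1], h)) {
    return(list(value = readRDS(cache), cached = TRUE, hash = h))
  }
  value <- fun(stage_seed(config, name))
  saveRDS(value, cache, version = 2)
  writeLines(h, manifest)
  list(value = value, cached = FALSE, hash = h)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in dependency order
#' (simulate/ingest, QC, clonality, PAV, statistics, chloroplast, dating),
#' writing per-stage TSV outputs plus a JSON run report under
#' `config$outdir`. Stages are cached by a content hash of their parameters
#' and namespaced seed: re-running with an identical configuration reuses
#' cached outputs and reproduces the report byte for byte.
#'
#' @param config configuration list; see \link{default_pipeline_config} and
#'   \link{validate_config}.
#' @return a `run_report` list (also written as `run_report.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  diag <- validate_config(config)
  if (any(diag$level == "fatal"))
    stop("invalid configuration:\n  ",
         paste(diag$message[diag$level == "fatal"], collapse = "\n  "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(),
                 package_version = as.character(utils::packageVersion("meadowpop")))
  dataset <- NULL
  qc_out <- NULL

  if ("simulate" %in% config$stages) {
    sy <- config$synthetic
    st <- run_stage("simulate", config, sy, function(seed) {
      model <- two_pop_model(sy$split_gens, ne = sy$ne,
                             mutation_rate = sy$mutation_rate,
                             generation_time = sy$generation_time,
                             n_loci = sy$n_loci,
                             locus_length = sy$locus_length)
      d <- simulate_coalescent(model, c(A = sy$n_per_pop, B = sy$n_per_pop),
                               seed = seed)
      d <- inject_clones_and_selfs(d, sy$n_clonemate_copies, sy$n_selfed,
                                   sy$genotyping_error_rate, seed = seed + 1)
      corrupt_for_qc(d, corruption_spec(
        n_high_missing_samples = sy$n_high_missing_samples,
        missing_rate = sy$missing_rate), seed = seed + 2)
    })
    dataset <- st$value
    write_vcf(dataset$genotypes, file.path(config$outdir, "simulated.vcf"))
    write_tsv(dataset$truth, file.path(config$outdir, "truth.tsv"))
    report$stages$simulate <- list(
      hash = st$hash,
      n_samples = length(dataset$genotypes$samples),
      n_sites = nrow(dataset$genotypes$sites))
  } else if (!is.null(config$vcf)) {
    dataset <- list(genotypes = read_vcf_genotypes(config$vcf),
                    truth = NULL)
  }

  if ("qc" %in% config$stages) {
    cfg <- do.call(filter_config, config$qc)
    st <- run_stage("qc", config, list(config$qc, dataset$genotypes$sites),
                    function(seed) qc_cascade(dataset$genotypes, cfg))
    qc_out <- st$value
    write_tsv(qc_out$report, file.path(config$outdir, "qc_report.tsv"))
    report$stages$qc <- list(hash = st$hash,
                             retained_sites = nrow(qc_out$table$sites))
  }
  tab <- if (!is.null(qc_out)) qc_out$table else dataset$genotypes

  if ("clones" %in% config$stages) {
    cl <- config$clones
    st <- run_stage("clones", config, list(cl, dim(tab)), function(seed) {
      clones <- detect_clones(tab, clone_threshold = cl$clone_threshold,
                              error_rate_allowance = cl$error_rate_allowance)
      selfs <- detect_selfing(tab)
      sm <- sample_missing_filter(tab)
      list(clones = clones, selfs = selfs, missing = sm$excluded,
           ledger = build_exclusion_ledger(tab$samples, selfs, clones,
                                           sm$excluded))
    })
    ledger <- st$value$ledger
    write_tsv(ledger$ledger, file.path(config$outdir, "exclusion_ledger.tsv"))
    report$stages$clones <- list(hash = st$hash,
                                 n_input = ledger$n_input,
                                 n_retained = ledger$n_retained)
    tab <- gt_subset_samples(tab, tab$samples %in% ledger$retained)
  }

  if ("pav" %in% config$stages) {
    pv <- config$pav
    st <- run_stage("pav", config, pv, function(seed) {
      sim <- simulate_pav(pv$n_genes, pv$class_fractions, pv$n_samples,
                          seed = seed, qc_threshold = pv$min_genes)
      pav <- build_pav(sim$hits, min_genes = pv$min_genes)
      list(sim = sim, pav = pav)
    })
    pav <- st$value$pav
    write_tsv(data.frame(gene = names(pav$frequency),
                         frequency = pav$frequency,
                         class = as.character(pav$class)),
              file.path(config$outdir, "gene_classes.tsv"))
    report$stages$pav <- list(hash = st$hash,
                              class_counts = as.list(table(pav$class)))
  }

  if ("stats" %in% config$stages) {
    stc <- config$stats
    pop_map <- data.frame(sample = tab$samples,
                          population = sub("[0-9_].*$", "", tab$samples))
    st <- run_stage("stats", config, list(stc, dim(tab)), function(seed) {
      pops <- unique(pop_map$population)
      hobs <- vapply(tab$samples, function(s)
        individual_heterozygosity(tab, s), numeric(1))
      complete <- gt_subset_sites(tab, rowSums(gt_missing(tab)) == 0)
      divers <- lapply(stats::setNames(pops, pops), function(p)
        nucleotide_diversity(complete,
                             pop_map$sample[pop_map$population == p]))
      fst <- if (length(pops) >= 2)
        fst_matrix(complete, pop_map, n_boot = stc$n_boot, seed = seed)
      else NULL
      list(hobs = hobs, diversity = divers, fst = fst)
    })
    v <- st$value
    write_tsv(data.frame(sample = names(v$hobs), h_obs = v$hobs),
              file.path(config$outdir, "heterozygosity.tsv"))
    if (!is.null(v$fst))
      utils::write.table(v$fst$theta,
                         file.path(config$outdir, "fst_matrix.tsv"),
                         sep = "\t", quote = FALSE)
    report$stages$stats <- list(
      hash = st$hash,
      mean_hobs = mean(v$hobs),
      fst = if (!is.null(v$fst)) v$fst$theta[1, 2] else NA_real_)
  }

  if ("cpdna" %in% config$stages) {
    cp <- config$cpdna
    st <- run_stage("cpdna", config, cp, function(seed) {
      sim <- simulate_cp_pileup(cp$n_samples,
                                genome_length = cp$genome_length,
                                n_variable = cp$n_variable,
                                n_microsat_artifacts = cp$n_microsat_artifacts,
                                n_hairpin_artifacts = cp$n_hairpin_artifacts,
                                median_coverage = cp$median_coverage,
                                seed = seed)
      called <- call_cp_variants(sim$pileup)
      masked <- apply_masks(called$positions, sim$masks)
      # sample sequences at the retained positions, from the pileup consensus
      seqs <- vapply(names(sim$pileup$samples), function(id) {
        counts <- sim$pileup$samples[[id]][masked$positions, , drop = FALSE]
        paste(c("A", "C", "G", "T")[max.col(counts, ties.method = "first")],
              collapse = "")
      }, character(1))
      haps <- collapse_haplotypes(seqs)
      net <- if (nrow(haps$table) >= 2)
        median_joining_network(stats::setNames(haps$table$sequence,
                                               haps$table$haplotype),
                               epsilon = cp$epsilon)
      else NULL
      list(called = called, masked = masked, haps = haps, net = net)
    })
    v <- st$value
    write_tsv(v$haps$table, file.path(config$outdir, "cp_haplotypes.tsv"))
    report$stages$cpdna <- list(hash = st$hash,
                                n_called = length(v$called$positions),
                                n_retained = length(v$masked$positions),
                                n_haplotypes = nrow(v$haps$table))
  }

  if ("dating" %in% config$stages) {
    sy <- config$synthetic
    mu <- if (!is.null(config$dating$mu_per_generation))
      config$dating$mu_per_generation else sy$mutation_rate
    st <- run_stage("dating", config, list(mu, dim(tab)), function(seed) {
      params <- clock_params(mu_per_generation = mu,
                             generation_time = sy$generation_time)
      a <- tab$samples[startsWith(tab$samples, "A")]
      b <- tab$samples[startsWith(tab$samples, "B")]
      net_divergence_split_time(tab, a, b, params,
                                total_length = as.numeric(sy$n_loci) *
                                  sy$locus_length)
    })
    v <- st$value
    write_tsv(data.frame(quantity = c("split_time_years",
                                      "split_time_generations", "d_a"),
                         value = c(v$split_time_years,
                                   v$split_time_generations, v$d_a)),
              file.path(config$outdir, "dating.tsv"))
    report$stages$dating <- list(hash = st$hash,
                                 split_time_years = v$split_time_years)
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d): stages %s\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
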