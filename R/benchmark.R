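#' Simulate one replicate and scan it
#'
#' Generates a structured genotype panel, simulates a phenotype replicate
#' under the given reaction-norm condition, and runs the genome scan under
#' one or more random-effect schemes.
#'
#' @param condition Reaction-norm condition (see [simulation_spec()]).
#' @param m,I Panel size: genotypes and markers.
#' @param schemes Character vector of random-effect schemes to scan under.
#' @param seed RNG seed for the replicate (genotypes, phenotype and scan).
#' @param trial_layout Trials per environment (default c(A = 2, B = 2)).
#' @param tests Tests to run (default all five).
#' @param fdr_level,n_pcs,fdr_method Passed to [run_scan()].
#' @param Fst,n_subpops Passed to [generate_genotypes()].
#' @param geno Optional pre-generated `GenotypeMatrix` (skips generation).
#' @param ... Further arguments to [run_scan()] (e.g. `wald`).
#' @return List with `sim` (the `SimulatedPhenotype`) and `scans` (named
#'   list of `AssociationResult`, one per scheme).
#' @export
simulate_and_scan <- function(condition, m = 96, I = 500,
                              schemes = "G+GE+GT", seed = NULL,
                              trial_layout = c(A = 2, B = 2),
                              tests = c("add", "ammi_all", "gge_all",
                                        "ammi_int", "gge_int"),
                              fdr_level = 0.05, n_pcs = 2,
                              fdr_method = "storey",
                              Fst = 0.1, n_subpops = 2, geno = NULL, ...) {
  if (is.null(geno))
    geno <- generate_genotypes(m, I, n_subpops = n_subpops, Fst = Fst,
                               seed = seed)
  design <- complete_design(geno, trial_layout)
  spec <- simulation_spec(condition, trial_layout = trial_layout,
                          seed = if (is.null(seed)) NULL else seed + 1L)
  sim <- simulate_phenotype(geno, design, spec)
  ph <- sim_phenotype_table(sim)
  scans <- lapply(schemes, function(s)
    run_scan(geno, ph, scheme = s, tests = tests, fdr_level = fdr_level,
             n_pcs = n_pcs, fdr_method = fdr_method, ...))
  names(scans) <- schemes
  list(sim = sim, scans = scans)
}

#' Replicated simulation benchmark over conditions, designs and schemes
#'
#' Reproduces the simulation-study grid at a configurable scale: for each
#' reaction-norm condition and replicate, a fresh structured panel and
#' calibrated phenotype are generated and scanned under every requested
#' random-effect scheme; each scan is scored against the truth QTLs
#' (recall/precision/F at the FDR threshold, AUC, genomic inflation).
#' Per-replicate seeds are drawn deterministically from the master seed, so
#' the full grid is reproducible and parallelisation-safe.
#'
#' @param conditions Conditions to simulate (default all four).
#' @param schemes Random-effect schemes (default "G+GE+GT").
#' @param n_reps Replicates per condition (default 20).
#' @param m,I Panel size per replicate (default 96 genotypes, 500 markers).
#' @param trial_layout Trials per environment.
#' @param tests Tests to score.
#' @param fdr_level FDR level (default 0.05).
#' @param seed Master seed.
#' @param fdr_method Passed to [run_scan()].
#' @return List with `summary` (mean metrics per condition x scheme x test)
#'   and `per_replicate` (every replicate's metrics).
#' @export
run_benchmark <- function(conditions = c("persistence", "divergence",
                                         "convergence", "crossover"),
                          schemes = "G+GE+GT", n_reps = 20,
                          m = 96, I = 500,
                          trial_layout = c(A = 2, B = 2),
                          tests = c("add", "ammi_all", "gge_all",
                                    "ammi_int", "gge_int"),
                          fdr_level = 0.05, seed = 1,
                          fdr_method = "storey") {
  if (3 >= I) stop("infeasible scale: markers must exceed the QTL count")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^30, length(conditions) * n_reps),
                      nrow = n_reps,
                      dimnames = list(NULL, conditions))
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(n_reps)) {
      rs <- simulate_and_scan(cond, m = m, I = I, schemes = schemes,
                              seed = rep_seeds[r, cond],
                              trial_layout = trial_layout, tests = tests,
                              fdr_level = fdr_level,
                              fdr_method = fdr_method)
      for (s in schemes) {
        ev <- evaluate_scan(rs$scans[[s]], rs$sim$truth)
        ev$condition <- cond
        ev$scheme <- s
        ev$replicate <- r
        rows[[length(rows) + 1]] <- ev
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  summary <- stats::aggregate(
    per_rep[, c("recall", "precision", "f_measure", "auc", "lambda_gc")],
    by = per_rep[, c("condition", "scheme", "test")],
    FUN = function(v) mean(v, na.rm = TRUE))
  list(summary = summary, per_replicate = per_rep)
}

#' Write a reproducibility manifest
#'
#' Records the configuration and seed of a run as JSON so that identical
#' config plus seed reproduces identical result tables.
#'
#' @param config Named list of run parameters (must include `seed`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  stopifnot("seed" %in% names(config))
  config$package_version <- as.character(utils::packageVersion("qxescan"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
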