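#' Build observation-level incidence structures for a multi-trial experiment
#'
#' From a validated phenotype table, constructs the incidence matrices that
#' every mixed model in the package shares: the trial design matrix `T_mat`
#' (one column per trial, carrying the per-trial population means), the
#' genotype incidence `Z_G`, the environment incidence `Z_E`, the trial
#' incidence `Z_T` (identical to `T_mat`), and the per-environment indicator
#' vectors `pi_l`. Trials are nested in environments: each trial maps to
#' exactly one environment.
#'
#' @param pheno A `PhenotypeTable` (see [as_phenotype_table()]).
#' @param genotype_ids Optional character vector fixing the genotype order
#'   (e.g. `colnames(geno$dosages)`); defaults to order of appearance.
#'   Phenotyped genotypes absent from this vector are an error.
#' @return An `ExperimentDesign`: list with `T_mat`, `Z_G`, `Z_E`, `Z_T`,
#'   `pi` (list of n-vectors, one per environment), `L`, `TR`, `n`,
#'   `genotype_ids`, `trial_ids`, `environment_ids`, `trial_env` (environment
#'   of each trial), and `y` (observation vector in design row order).
#' @export
build_design <- function(pheno, genotype_ids = NULL) {
  pheno <- as_phenotype_table(pheno)
  n <- nrow(pheno)
  if (is.null(genotype_ids)) genotype_ids <- unique(pheno$genotype_id)
  missing_g <- setdiff(pheno$genotype_id, genotype_ids)
  if (length(missing_g))
    stop("phenotyped genotype(s) absent from the genotype panel: ",
         paste(utils::head(missing_g, 3), collapse = ", "))
  trial_ids <- unique(pheno$trial_id)
  env_of_trial <- vapply(trial_ids, function(tr)
    unique(pheno$environment_id[pheno$trial_id == tr]), character(1))
  environment_ids <- unique(env_of_trial)
  TR <- length(trial_ids)
  L <- length(environment_ids)

  incidence <- function(fac, levels) {
    Z <- matrix(0, n, length(levels), dimnames = list(NULL, levels))
    Z[cbind(seq_len(n), match(fac, levels))] <- 1
    Z
  }
  Z_G <- incidence(pheno$genotype_id, genotype_ids)
  Z_T <- incidence(pheno$trial_id, trial_ids)
  Z_E <- incidence(pheno$environment_id, environment_ids)
  pi <- lapply(environment_ids, function(e)
    as.numeric(pheno$environment_id == e))
  names(pi) <- environment_ids

  d <- list(T_mat = Z_T, Z_G = Z_G, Z_E = Z_E, Z_T = Z_T, pi = pi,
            L = L, TR = TR, n = n,
            genotype_ids = genotype_ids, trial_ids = trial_ids,
            environment_ids = environment_ids, trial_env = env_of_trial,
            y = pheno$value)
  class(d) <- "ExperimentDesign"
  d
}

#' @export
print.ExperimentDesign <- function(x, ...) {
  cat("ExperimentDesign:", x$n, "observations,", length(x$genotype_ids),
      "genotypes,", x$TR, "trials in", x$L, "environments\n")
  invisible(x)
}

#' Fixed-effect design for one marker under a QTL parameterisation
#'
#' Builds the marker-derived regressor columns for the three fixed QTL-effect
#' parameterisations:
#' \describe{
#'   \item{additive_main}{one column `x` (no QxE assumed), q = 1;}
#'   \item{ammi}{`x` plus one per-environment deviation column
#'     \eqn{\pi_l \circ x} (main and interaction separated), q = L + 1 —
#'     rank-deficient by construction since the main column equals the sum of
#'     the environment columns;}
#'   \item{gge}{one column \eqn{\pi_l \circ x} per environment scoring main
#'     and interaction together, q = L.}
#' }
#'
#' @param x_obs Marker dosage per observation (length n; typically
#'   `design$Z_G %*% dosage_row`).
#' @param design_kind One of "additive_main", "ammi", "gge".
#' @param design An `ExperimentDesign`.
#' @return A `FixedQtlDesign`: list with `columns` (n x q), `labels`
#'   (environment tag or "main"), `design_kind`, `q`, and `rank_deficient`.
#' @export
build_qtl_design <- function(x_obs, design_kind, design) {
  x_obs <- as.numeric(x_obs)
  stopifnot(length(x_obs) == design$n)
  kinds <- c("additive_main", "ammi", "gge")
  if (!design_kind %in% kinds)
    stop("unknown design_kind '", design_kind, "'; must be one of ",
         paste(kinds, collapse = ", "))
  env_cols <- vapply(design$pi, function(p) p * x_obs,
                     numeric(design$n))
  if (design_kind == "additive_main") {
    cols <- matrix(x_obs, ncol = 1)
    labels <- "main"
  } else if (design_kind == "gge") {
    cols <- env_cols
    labels <- design$environment_ids
  } else {
    cols <- cbind(x_obs, env_cols)
    labels <- c("main", design$environment_ids)
  }
  colnames(cols) <- labels
  out <- list(columns = cols, labels = labels, design_kind = design_kind,
              q = ncol(cols), rank_deficient = design_kind == "ammi")
  class(out) <- "FixedQtlDesign"
  out
}

#' Base (marker-free) fixed-effect design
#'
#' Trial means plus population-structure covariates. The trial-mean term is
#' always a full set of trial indicators with no global intercept, avoiding
#' collinearity with the trial columns.
#'
#' @param design An `ExperimentDesign`.
#' @param S Optional n x c structure-covariate matrix.
#' @return n x (TR + c) numeric matrix.
#' @export
base_fixed_design <- function(design, S = NULL) {
  X <- design$T_mat
  if (!is.null(S)) X <- cbind(X, S)
  X
}
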