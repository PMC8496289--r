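#' Generate structured synthetic genotypes
#'
#' Balding-Nichols-style diploid dosages: each marker draws an ancestral
#' allele frequency uniformly in \[0.1, 0.9\], each subpopulation perturbs it
#' with a Beta draw of divergence Fst, and genotypes are binomial(2) in
#' their subpopulation frequency. A synthetic genetic map (uniform positions
#' in centimorgan over `n_chrom` chromosomes) is attached. Markers failing
#' the MAF filter are regenerated until exactly `I` markers remain, so the
#' returned panel always has the requested dimensions.
#'
#' @param m Number of genotypes.
#' @param I Number of markers after QC.
#' @param n_subpops Number of subpopulations (default 2).
#' @param Fst Divergence between subpopulations, in \[0, 1). 0 gives an
#'   unstructured panel.
#' @param n_chrom Chromosomes in the synthetic map (default 12).
#' @param chrom_length_cM Map length per chromosome (default 100).
#' @param maf_threshold MAF filter (default 0.05).
#' @param seed Optional RNG seed.
#' @return A `GenotypeMatrix` with a `subpop` attribute (subpopulation of
#'   each genotype).
#' @export
generate_genotypes <- function(m, I, n_subpops = 2, Fst = 0.1,
                               n_chrom = 12, chrom_length_cM = 100,
                               maf_threshold = 0.05, seed = NULL) {
  if (m < 2 || I < 1 || n_subpops < 1) stop("degenerate panel parameters")
  if (Fst < 0 || Fst >= 1) stop("Fst must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  subpop <- rep(seq_len(n_subpops), length.out = m)
  dos <- matrix(NA_real_, 0, m)
  while (nrow(dos) < I) {
    batch <- max(I - nrow(dos), 50)
    p_anc <- stats::runif(batch, 0.1, 0.9)
    p_sub <- matrix(p_anc, batch, n_subpops)
    if (Fst > 0) {
      a <- p_anc * (1 - Fst) / Fst
      b <- (1 - p_anc) * (1 - Fst) / Fst
      for (s in seq_len(n_subpops))
        p_sub[, s] <- stats::rbeta(batch, a, b)
    }
    new <- matrix(stats::rbinom(batch * m, 2, p_sub[, subpop]), batch, m)
    p <- rowMeans(new) / 2
    keep <- pmin(p, 1 - p) > maf_threshold
    dos <- rbind(dos, new[keep, , drop = FALSE])
  }
  dos <- dos[seq_len(I), , drop = FALSE]
  chrom <- sort(sample(seq_len(n_chrom), I, replace = TRUE))
  pos <- stats::runif(I, 0, chrom_length_cM)
  o <- order(chrom, pos)
  dos <- dos[o, , drop = FALSE]
  colnames(dos) <- sprintf("g%03d", seq_len(m))
  g <- new_genotype_matrix(dos, sprintf("snp%05d", seq_len(I)),
                           as.character(chrom[o]), pos[o],
                           maf_threshold = 0)   # already filtered
  attr(g, "subpop") <- subpop
  g
}

#' Simulation specification for one reaction-norm condition
#'
#' Encodes the four canonical QxE patterns of a biallelic QTL across two
#' environments: persistence (equal effects), divergence (attenuated in one
#' environment), convergence (absent in one environment), crossover
#' (opposite signs). Default per-environment effect multipliers are
#' persistence (1, 1), divergence (0.5, 1), convergence (0, 1), crossover
#' (-1, 1).
#'
#' @param condition One of "persistence", "divergence", "convergence",
#'   "crossover".
#' @param n_qtl Number of simulated major QTLs (default 3).
#' @param effect_by_env Named per-environment effect multipliers; defaults
#'   chosen by `condition`.
#' @param weights Relative weights (w_G, w_GE, w_GT) of the background
#'   random effects (default 1:1:1).
#' @param pve_qtl_target Variance fraction each QTL should explain after
#'   calibration (default 0.1).
#' @param h2_target Broad-sense heritability target over all environments
#'   and trials (default 0.5).
#' @param trial_layout Named integer vector: trials per environment
#'   (default c(A = 2, B = 2)).
#' @param seed Optional RNG seed.
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(condition = c("persistence", "divergence",
                                          "convergence", "crossover"),
                            n_qtl = 3, effect_by_env = NULL,
                            weights = c(G = 1, GE = 1, GT = 1),
                            pve_qtl_target = 0.1, h2_target = 0.5,
                            trial_layout = c(A = 2, B = 2), seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(effect_by_env)) {
    base <- switch(condition,
                   persistence = c(1, 1), divergence = c(0.5, 1),
                   convergence = c(0, 1), crossover = c(-1, 1))
    effect_by_env <- stats::setNames(
      rep(base, length.out = length(trial_layout)), names(trial_layout))
  }
  if (!(pve_qtl_target > 0 && pve_qtl_target < 1 &&
        h2_target > 0 && h2_target < 1))
    stop("pve_qtl_target and h2_target must lie in (0, 1)")
  if (n_qtl * pve_qtl_target >= h2_target)
    stop("infeasible targets: n_qtl * pve_qtl_target must be < h2_target")
  spec <- list(condition = condition, n_qtl = n_qtl,
               effect_by_env = effect_by_env, weights = weights,
               pve_qtl_target = pve_qtl_target, h2_target = h2_target,
               trial_layout = trial_layout, seed = seed)
  class(spec) <- "SimulationSpec"
  spec
}

#' Complete multi-trial design for a genotype panel
#'
#' Builds the `ExperimentDesign` of a balanced experiment in which every
#' genotype is observed once in every trial, with trials nested in
#' environments according to `trial_layout`.
#'
#' @param geno A `GenotypeMatrix`.
#' @param trial_layout Named integer vector of trials per environment.
#' @return An `ExperimentDesign` (phenotype values initialised to 0).
#' @export
complete_design <- function(geno, trial_layout = c(A = 2, B = 2)) {
  gids <- colnames(geno$dosages)
  envs <- rep(names(trial_layout), trial_layout)
  trials <- paste0(envs, "_t", unlist(lapply(trial_layout, seq_len)))
  ph <- expand.grid(genotype_id = gids, trial_id = trials,
                    stringsAsFactors = FALSE)
  ph$environment_id <- envs[match(ph$trial_id, trials)]
  ph$value <- 0
  build_design(as_phenotype_table(ph), gids)
}

#' Calibrate the background and residual scale factors
#'
#' Finds the scalars (omega, phi) dividing the background genetic effects
#' and the residuals so that, on the drawn sample, each major QTL explains
#' `pve_qtl_target` of the phenotypic variance and the total genetic
#' fraction equals `h2_target`. Nested one-dimensional root finding: for a
#' candidate omega, phi is solved so the realized heritability hits its
#' target; omega is then solved so the mean per-QTL variance fraction hits
#' its target. When the background components carry no variance (all
#' weights zero), omega is irrelevant and only phi is calibrated.
#'
#' @param components List with `qtl_parts` (n x n_qtl matrix of per-QTL
#'   phenotype contributions), `u` (summed weighted background effects),
#'   `eps` (unit residual draws).
#' @param targets List or vector with `pve_qtl` and `h2`.
#' @param tol Tolerance on the realized fractions (default 1e-6).
#' @return List with `omega`, `phi`, and the realized `pve` (per QTL) and
#'   `h2` at the solution.
#' @export
calibrate_scalars <- function(components, targets, tol = 1e-6) {
  qtl <- as.matrix(components$qtl_parts)
  u <- components$u
  eps <- components$eps
  pve_t <- targets$pve_qtl
  h2_t <- targets$h2
  if (ncol(qtl) * pve_t >= h2_t)
    stop("infeasible targets: n_qtl * pve_qtl >= h2")
  q_tot <- rowSums(qtl)

  realized <- function(omega, phi) {
    gen <- q_tot + u / omega
    y <- gen + eps / phi
    vy <- stats::var(y)
    list(pve = apply(qtl, 2, stats::var) / vy,
         h2 = stats::var(gen) / vy, y = y, gen = gen)
  }
  phi_for <- function(omega) {
    gen <- q_tot + u / omega
    f <- function(lphi) {
      y <- gen + eps / exp(lphi)
      stats::var(gen) / stats::var(y) - h2_t
    }
    lo <- -15; hi <- 15
    if (f(lo) > 0 || f(hi) < 0)
      stop("calibration failed to bracket phi (h2 target ", h2_t,
           " unattainable with these draws)")
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }

  no_background <- stats::var(u) < .Machine$double.eps * stats::var(q_tot)
  if (no_background) {
    omega <- 1                     # no background: omega is irrelevant
    phi <- phi_for(omega)
  } else {
    g <- function(lomega)
      mean(realized(exp(lomega), phi_for(exp(lomega)))$pve) - pve_t
    lo <- -10; hi <- 10
    if (g(hi) < 0 || g(lo) > 0)
      stop("calibration failed to bracket omega (pve target ", pve_t,
           " unattainable; mean achievable at weakest background: ",
           round(g(hi) + pve_t, 4), ")")
    omega <- exp(stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
    phi <- phi_for(omega)
  }
  r <- realized(omega, phi)
  if (abs(r$h2 - h2_t) > tol ||
      (!no_background && abs(mean(r$pve) - pve_t) > tol))
    stop("calibration did not reach tolerance ", tol)
  list(omega = omega, phi = phi, pve = r$pve, h2 = r$h2)
}

#' Simulate phenotypes under a QxE reaction-norm condition
#'
#' Draws a phenotype vector
#' \deqn{y = Q_a q_{tr} + (u_G w_G + u_{GE} w_{GE} + u_{GT} w_{GT})/\omega
#'       + \epsilon/\varphi}
#' on the given design. `n_qtl` QTL markers are sampled from the panel
#' (MAF >= `min_qtl_maf`, pairwise separated by at least `min_spacing_cM` on
#' the map); their dosage columns are centred and scaled to unit variance at
#' the genotype level so every QTL realises the same pooled variance
#' fraction after calibration. Per-trial QTL effects `q_tr` equal the
#' condition's per-environment multiplier, identical for trials sharing an
#' environment. Background effects are drawn from the G, GxE and GxT
#' covariances of the panel's own GRM; omega and phi are calibrated on the
#' drawn sample by [calibrate_scalars()].
#'
#' @param geno A `GenotypeMatrix`.
#' @param design An `ExperimentDesign` (e.g. from [complete_design()]).
#' @param spec A `SimulationSpec`.
#' @param min_qtl_maf Minimum MAF of candidate QTL markers (default 0.2).
#' @param min_spacing_cM Minimum map distance between chosen QTLs on the
#'   same chromosome (default 5).
#' @return A `SimulatedPhenotype`: list with `values`, `truth` (QTL ids,
#'   indices, per-trial effects), `realized_pve` (pooled, per QTL),
#'   `realized_pve_per_trial` (QTL x trial), `realized_h2`, `omega`, `phi`,
#'   `components` (the stored draws), `design`, `spec`.
#' @export
simulate_phenotype <- function(geno, design, spec, min_qtl_maf = 0.2,
                               min_spacing_cM = 5) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  m <- ncol(geno$dosages)
  n <- design$n
  maf <- pmin(geno$allele_freq, 1 - geno$allele_freq)
  cand <- sample(which(maf >= min_qtl_maf))
  if (length(cand) < spec$n_qtl)
    stop("fewer than ", spec$n_qtl, " markers with MAF >= ", min_qtl_maf)
  chosen <- integer(0)
  for (i in cand) {
    ok <- all(geno$chromosome[chosen] != geno$chromosome[i] |
                abs(geno$position_cM[chosen] - geno$position_cM[i]) >=
                min_spacing_cM)
    if (ok) chosen <- c(chosen, i)
    if (length(chosen) == spec$n_qtl) break
  }
  if (length(chosen) < spec$n_qtl)
    stop("could not place ", spec$n_qtl, " QTLs ", min_spacing_cM,
         " cM apart")
  Qa <- scale(t(geno$dosages[chosen, , drop = FALSE]))  # m x n_qtl, unit var

  eff_env <- spec$effect_by_env[design$environment_ids]
  q_trial <- eff_env[design$trial_env]                   # effect per trial
  e_obs <- drop(design$Z_T %*% q_trial)
  qtl_parts <- (design$Z_G %*% Qa) * e_obs               # n x n_qtl

  G <- compute_grm(geno)
  eg <- eigen(G, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * diag(m))
  draw_g <- function() drop(rt %*% stats::rnorm(m))
  u_G <- drop(design$Z_G %*% draw_g())
  u_GE <- rowSums(vapply(design$environment_ids, function(e)
    design$pi[[e]] * drop(design$Z_G %*% draw_g()), numeric(n)))
  u_GT <- rowSums(vapply(design$trial_ids, function(tr)
    design$Z_T[, tr] * drop(design$Z_G %*% draw_g()), numeric(n)))
  w <- spec$weights
  u <- w[["G"]] * u_G + w[["GE"]] * u_GE + w[["GT"]] * u_GT
  eps <- stats::rnorm(n)

  comp <- list(qtl_parts = qtl_parts, u = u, eps = eps)
  cal <- calibrate_scalars(comp, list(pve_qtl = spec$pve_qtl_target,
                                      h2 = spec$h2_target))
  gen <- rowSums(qtl_parts) + u / cal$omega
  y <- gen + eps / cal$phi

  TRn <- design$TR
  pve_tr <- matrix(NA_real_, spec$n_qtl, TRn,
                   dimnames = list(geno$marker_ids[chosen],
                                   design$trial_ids))
  for (tr in seq_len(TRn)) {
    idx <- design$Z_T[, tr] == 1
    vt <- stats::var(y[idx])
    for (a in seq_len(spec$n_qtl))
      pve_tr[a, tr] <- stats::var(qtl_parts[idx, a]) / vt
  }

  out <- list(values = y,
              truth = list(qtl_ids = geno$marker_ids[chosen],
                           qtl_index = chosen,
                           chromosome = geno$chromosome[chosen],
                           position_cM = geno$position_cM[chosen],
                           effect_by_trial = outer(
                             rep(1, spec$n_qtl), q_trial)),
              realized_pve = cal$pve,
              realized_pve_per_trial = pve_tr,
              realized_h2 = cal$h2,
              omega = cal$omega, phi = cal$phi,
              components = comp, design = design, spec = spec)
  class(out) <- "SimulatedPhenotype"
  out
}

#' Phenotype table from a simulated replicate
#'
#' @param sim A `SimulatedPhenotype`.
#' @return A `PhenotypeTable` suitable for [run_scan()].
#' @export
sim_phenotype_table <- function(sim) {
  d <- sim$design
  as_phenotype_table(data.frame(
    genotype_id = d$genotype_ids[max.col(d$Z_G)],
    trial_id = d$trial_ids[max.col(d$Z_T)],
    environment_id = d$environment_ids[max.col(d$Z_E)],
    value = sim$values, stringsAsFactors = FALSE))
}
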