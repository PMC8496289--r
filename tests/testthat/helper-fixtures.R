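# Shared in-code fixtures: tiny panels, toy files, brute-force oracles.

# GenotypeMatrix built directly from a dosage matrix, bypassing file IO.
make_geno <- function(dosages, chrom = NULL, pos = NULL, maf_threshold = 0) {
  I <- nrow(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("g%02d", seq_len(ncol(dosages)))
  new_genotype_matrix(dosages,
                      marker_ids = sprintf("m%03d", seq_len(I)),
                      chromosome = if (is.null(chrom)) rep("1", I) else chrom,
                      position_cM = if (is.null(pos)) seq_len(I) else pos,
                      maf_threshold = maf_threshold)
}

# Balanced phenotype table: every genotype in every trial.
make_pheno <- function(genotype_ids, trial_env, values = NULL) {
  trials <- names(trial_env)
  df <- expand.grid(genotype_id = genotype_ids, trial_id = trials,
                    stringsAsFactors = FALSE)
  df$environment_id <- unname(trial_env[df$trial_id])
  df$value <- if (is.null(values)) stats::rnorm(nrow(df)) else values
  as_phenotype_table(df)
}

# Write a markers-in-rows genotype CSV and return its path.
write_geno_csv <- function(dosages, path = tempfile(fileext = ".csv")) {
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("g%02d", seq_len(ncol(dosages)))
  df <- data.frame(marker_id = sprintf("m%03d", seq_len(nrow(dosages))),
                   chrom = "1", pos_cM = seq_len(nrow(dosages)))
  df <- cbind(df, as.data.frame(dosages))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Naive double-loop GRM oracle (literal sum over markers and pairs).
grm_loop_oracle <- function(dosages, scale_by_markers = FALSE) {
  p <- rowMeans(dosages) / 2
  m <- ncol(dosages)
  I <- nrow(dosages)
  G <- matrix(0, m, m)
  for (j in seq_len(m))
    for (k in seq_len(m))
      for (i in seq_len(I))
        G[j, k] <- G[j, k] +
          (dosages[i, j] - 2 * p[i]) * (dosages[i, k] - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
  if (scale_by_markers) G <- G / I else G
}

# Brute-force ML of the two-variance mixed model: joint numeric
# maximisation of the multivariate normal log-density over
# (beta, log sigma2_K, log sigma2_eps). Independent of the
# eigendecomposition engine.
mvn_ml_oracle <- function(y, X, K) {
  n <- length(y)
  negll <- function(par) {
    p <- ncol(X)
    beta <- par[seq_len(p)]
    s2k <- exp(par[p + 1])
    s2e <- exp(par[p + 2])
    V <- s2k * K + diag(s2e, n)
    ch <- tryCatch(chol(V), error = function(e) return(NULL))
    if (is.null(ch)) return(1e10)
    r <- y - X %*% beta
    z <- backsolve(ch, r, transpose = TRUE)
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  start <- c(stats::coef(stats::lm.fit(X, y)), log(stats::var(y) / 2),
             log(stats::var(y) / 2))
  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  opt2 <- stats::optim(opt$par, negll, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
  -min(opt$value, opt2$value)
}

# Pairwise brute-force AUC: fraction of (positive, negative) pairs won,
# ties counted one half.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Trapezoidal integration of the empirical ROC curve.
auc_trapezoid_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Small deterministic simulated replicate shared by several test files.
small_replicate <- function(seed = 42, condition = "persistence",
                            m = 48, I = 150) {
  geno <- generate_genotypes(m, I, Fst = 0.1, seed = seed)
  design <- complete_design(geno)
  spec <- simulation_spec(condition, seed = seed + 1)
  sim <- simulate_phenotype(geno, design, spec)
  list(geno = geno, design = design, sim = sim,
       pheno = sim_phenotype_table(sim))
}
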