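#' Wald test for a per-environment QTL effect
#'
#' Computes \eqn{W = \hat\theta^2 / var(\hat\theta)} and its chi-square
#' upper-tail p-value with 1 df. Vectorised over effects.
#'
#' @param theta_hat Estimated effect size(s).
#' @param theta_var Estimated sampling variance(s), same length.
#' @return Named list with `W` and `p`. Non-positive variances give `NA`
#'   with a warning.
#' @export
wald_test <- function(theta_hat, theta_var) {
  stopifnot(length(theta_hat) == length(theta_var))
  bad <- !is.na(theta_var) & theta_var <= 0
  if (any(bad)) {
    warning("non-positive Wald variance; p set to NA")
    theta_var[bad] <- NA_real_
  }
  W <- theta_hat^2 / theta_var
  p <- stats::pchisq(W, df = 1, lower.tail = FALSE)
  list(W = W, p = p)
}

#' Genomic inflation factor from a set of p-values
#'
#' Median-based inflation factor
#' \eqn{\lambda_{GC} = \log_{10}(\mathrm{median}\, p) / \log_{10}(0.5)}:
#' 1 when the observed median matches the uniform null, above 1 under
#' inflation of \eqn{-\log_{10} p}, below 1 under deflation.
#'
#' @param pvalues Numeric vector; NAs dropped.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  if (length(p) == 0) stop("no finite p-values")
  log10(stats::median(p)) / log10(0.5)
}

# Storey-Tibshirani q-values: pi0 estimated on a lambda grid and smoothed
# with a cubic smoothing spline, evaluated at the largest lambda.
.qvalue_storey <- function(p) {
  n <- length(p)
  lam <- seq(0.05, 0.9, by = 0.05)
  pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
  sp <- stats::smooth.spline(lam, pi0_lam, df = 3)
  pi0 <- stats::predict(sp, max(lam))$y
  pi0 <- min(max(pi0, 1e-4), 1)
  o <- order(p)
  q <- pi0 * n * p[o] / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' q-values and FDR significance calls
#'
#' Computes q-values by the Storey-Tibshirani procedure (\eqn{\pi_0}
#' estimated with a smoothing spline over a lambda grid). With fewer than
#' 100 finite p-values, or on request, falls back to Benjamini-Hochberg
#' adjusted p-values. A marker is called significant when its q-value is
#' below `level`.
#'
#' @param pvalues Numeric vector (NAs propagate).
#' @param level FDR level for the significance calls (default 0.05).
#' @param method "storey" (default) or "bh".
#' @return List with `qvalues`, `significant` (logical), and `method` (the
#'   method actually used).
#' @export
fdr_threshold <- function(pvalues, level = 0.05, method = c("storey", "bh")) {
  method <- match.arg(method)
  ok <- is.finite(pvalues)
  if (!any(ok)) stop("no finite p-values")
  q <- rep(NA_real_, length(pvalues))
  if (method == "storey" && sum(ok) < 100) {
    message("fewer than 100 p-values; falling back to Benjamini-Hochberg")
    method <- "bh"
  }
  q[ok] <- if (method == "storey") .qvalue_storey(pvalues[ok])
           else stats::p.adjust(pvalues[ok], method = "BH")
  list(qvalues = q, significant = !is.na(q) & q < level, method = method)
}

# -log10 upper-tail chi-square p computed on the log scale so that extreme
# deviances do not underflow; capped at 300.
.neglog10_chisq <- function(dev, df) {
  nl <- -stats::pchisq(dev, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
  pmin(nl, 300)
}

#' Genome-wide mixed-model scan for QTL and QxE effects
#'
#' Runs the full association pipeline for one trait: genomic relationship
#' matrix, structure covariates, kernel weight estimation by REML on the
#' marker-free model, then a per-marker likelihood-ratio scan against the
#' integrated kernel. Five tests are available:
#' \describe{
#'   \item{add}{additive main effect vs the marker-free model, df 1;}
#'   \item{ammi_all}{AMMI-type main + per-environment terms vs marker-free,
#'     df L + 1;}
#'   \item{gge_all}{GGE-type per-environment terms vs marker-free, df L;}
#'   \item{ammi_int}{AMMI-type vs additive main (interaction only), df L;}
#'   \item{gge_int}{GGE-type vs additive main (interaction only), df L - 1.}
#' }
#' Deviances are \eqn{-2 (LL_{reduced} - LL_{full})} of profile-ML fits
#' sharing one kernel eigendecomposition; p-values come from the chi-square
#' upper tail. Per-environment effect sizes and Wald tests come from the
#' GGE-design GLS fit (its coefficients, one per environment, are the only
#' separately identified per-environment effects).
#'
#' @param geno A `GenotypeMatrix`.
#' @param pheno A `PhenotypeTable` (or data.frame coercible to one).
#' @param scheme Random-effect scheme, default "G+GE+GT" (the recommended
#'   scheme: background G, GxE and GxT kernels integrated).
#' @param tests Subset of c("add","ammi_all","gge_all","ammi_int","gge_int").
#' @param fdr_level FDR level for significance calls, default 0.05.
#' @param n_pcs Number of structure PCs (default 2; 0 disables).
#' @param fdr_method "storey" or "bh" (see [fdr_threshold()]).
#' @param kernel_set Optional precomputed `KernelSet` (skips REML).
#' @param wald Compute per-environment effects and Wald tests from the GGE
#'   fit (default `TRUE`; setting `FALSE` skips the GGE fit when no
#'   GGE-based test is requested).
#' @return An `AssociationResult`: data.frame with one row per marker
#'   (map columns, `neglog10p_*`, `q_*`, `sig_*` per requested test,
#'   `theta_<env>` and `wald_neglog10p_<env>` per environment) with
#'   attributes `lambda_gc` (named per test), `kernel_set`, `design`,
#'   `tests`, `fdr_level`.
#' @export
run_scan <- function(geno, pheno, scheme = "G+GE+GT",
                     tests = c("add", "ammi_all", "gge_all",
                               "ammi_int", "gge_int"),
                     fdr_level = 0.05, n_pcs = 2,
                     fdr_method = c("storey", "bh"), kernel_set = NULL,
                     wald = TRUE) {
  fdr_method <- match.arg(fdr_method)
  all_tests <- c("add", "ammi_all", "gge_all", "ammi_int", "gge_int")
  tests <- match.arg(tests, all_tests, several.ok = TRUE)
  design <- build_design(pheno, colnames(geno$dosages))
  L <- design$L
  if (L == 1 && "gge_int" %in% tests)
    stop("gge_int requires at least 2 environments (df would be 0)")
  y <- design$y
  S <- if (n_pcs > 0)
    compute_structure_covariates(geno, n_pcs, design)$S else NULL
  X_base <- base_fixed_design(design, S)
  if (is.null(kernel_set)) {
    G <- compute_grm(geno)
    kernel_set <- estimate_kernel_set(y, X_base, G, design, scheme)
  }
  ke <- kernel_set$K_eigen
  ll_base <- fit_ml(y, X_base, ke)$loglik_ML

  need_add <- any(c("add", "ammi_int", "gge_int") %in% tests)
  need_ammi <- any(c("ammi_all", "ammi_int") %in% tests)
  need_gge <- wald || any(c("gge_all", "gge_int") %in% tests)
  df_ledger <- c(add = 1, ammi_all = L + 1, gge_all = L,
                 ammi_int = L, gge_int = L - 1)

  I <- nrow(geno$dosages)
  nl <- matrix(NA_real_, I, length(tests),
               dimnames = list(NULL, tests))
  theta <- matrix(NA_real_, I, L)
  wald_nl <- matrix(NA_real_, I, L)
  dev_neg_seen <- FALSE

  dev_of <- function(ll_full, ll_red) {
    dev <- -2 * (ll_red - ll_full)
    if (dev < -1e-6) dev_neg_seen <<- TRUE
    max(dev, 0)
  }

  for (i in seq_len(I)) {
    x_obs <- drop(design$Z_G %*% geno$dosages[i, ])
    if (stats::var(x_obs) == 0) next   # untestable marker, p stays NA
    ll_add <- if (need_add)
      fit_ml(y, cbind(X_base, build_qtl_design(x_obs, "additive_main",
                                               design)$columns), ke)$loglik_ML
      else NA_real_
    ll_ammi <- if (need_ammi)
      fit_ml(y, cbind(X_base, build_qtl_design(x_obs, "ammi",
                                               design)$columns), ke)$loglik_ML
      else NA_real_
    fit_gge <- if (need_gge) {
      qd <- build_qtl_design(x_obs, "gge", design)
      fit_ml(y, cbind(X_base, qd$columns), ke)
    } else NULL
    ll_gge <- if (need_gge) fit_gge$loglik_ML else NA_real_

    for (tn in tests) {
      dev <- switch(tn,
        add      = dev_of(ll_add, ll_base),
        ammi_all = dev_of(ll_ammi, ll_base),
        gge_all  = dev_of(ll_gge, ll_base),
        ammi_int = dev_of(ll_ammi, ll_add),
        gge_int  = dev_of(ll_gge, ll_add))
      nl[i, tn] <- .neglog10_chisq(dev, df_ledger[tn])
    }
    if (need_gge) {
      idx <- ncol(X_base) + seq_len(L)
      th <- fit_gge$beta_hat[idx]
      vr <- diag(fit_gge$beta_cov)[idx]
      # an environment where the marker is monomorphic has no identified
      # coefficient: report it as missing and skip its Wald test
      for (l in seq_len(L)) {
        x_env <- x_obs[design$pi[[l]] == 1]
        if (stats::var(x_env) == 0) th[l] <- vr[l] <- NA_real_
      }
      theta[i, ] <- th
      ok <- !is.na(vr) & vr > 0
      wald_nl[i, ok] <- .neglog10_chisq(th[ok]^2 / vr[ok], 1)
    }
  }
  if (dev_neg_seen)
    warning("deviance below -1e-6 encountered and clamped to 0")

  res <- data.frame(marker_id = geno$marker_ids,
                    chrom = geno$chromosome,
                    pos_cM = geno$position_cM,
                    stringsAsFactors = FALSE)
  lambda <- numeric(0)
  for (tn in tests) {
    p <- 10^(-nl[, tn])
    res[[paste0("neglog10p_", tn)]] <- nl[, tn]
    fd <- fdr_threshold(p, fdr_level, fdr_method)
    res[[paste0("q_", tn)]] <- fd$qvalues
    res[[paste0("sig_", tn)]] <- fd$significant
    lambda[tn] <- genomic_inflation(p)
  }
  for (l in seq_len(L)) {
    env <- design$environment_ids[l]
    res[[paste0("theta_", env)]] <- theta[, l]
    res[[paste0("wald_neglog10p_", env)]] <- wald_nl[, l]
  }
  attr(res, "lambda_gc") <- lambda
  attr(res, "kernel_set") <- kernel_set
  attr(res, "design") <- design
  attr(res, "tests") <- tests
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("AssociationResult", "data.frame")
  res
}

#' Write an association scan to a tab-separated file
#'
#' One row per marker: map columns, \eqn{-\log_{10} p} per test,
#' per-environment effect sizes and Wald statistics, and q-values.
#'
#' @param result An `AssociationResult`.
#' @param path Output TSV path.
#' @param trait Optional trait label written as the first column.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(result, path, trait = NULL) {
  out <- as.data.frame(result)
  if (!is.null(trait)) out <- cbind(trait = trait, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
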