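#' Random-effect covariance components for a scheme
#'
#' Builds the observation-level covariance matrices of the background
#' genetic random effects. With \eqn{B = Z_G G Z_G'} the genomic kernel:
#' \describe{
#'   \item{G}{the single component B (no GxE assumed);}
#'   \item{G+GE}{B plus the genotype-by-environment kernel
#'     \eqn{B \circ Z_E Z_E'} (independent between environments, common
#'     variance);}
#'   \item{G+GT}{B plus the genotype-by-trial kernel \eqn{B \circ Z_T Z_T'};}
#'   \item{G+GE+GT}{all three;}
#'   \item{G+perTrial}{B plus one block-diagonal component per trial
#'     (\eqn{B \circ z_{tr} z_{tr}'}), allowing a different variance, hence
#'     heritability, in every trial.}
#' }
#'
#' @param G m x m genomic relationship matrix.
#' @param design An `ExperimentDesign`.
#' @param scheme One of "G", "G+GE", "G+GT", "G+GE+GT", "G+perTrial".
#' @return Named list of n x n symmetric covariance matrices.
#' @export
build_components <- function(G, design, scheme) {
  schemes <- c("G", "G+GE", "G+GT", "G+GE+GT", "G+perTrial")
  if (!scheme %in% schemes)
    stop("unknown scheme '", scheme, "'; must be one of ",
         paste(schemes, collapse = ", "))
  B <- design$Z_G %*% G %*% t(design$Z_G)
  comps <- list(G = B)
  if (scheme %in% c("G+GE", "G+GE+GT"))
    comps$GE <- B * tcrossprod(design$Z_E)
  if (scheme %in% c("G+GT", "G+GE+GT"))
    comps$GT <- B * tcrossprod(design$Z_T)
  if (scheme == "G+perTrial") {
    for (tr in design$trial_ids)
      comps[[paste0("trial:", tr)]] <- B * tcrossprod(design$Z_T[, tr])
  }
  comps
}

#' Estimate variance components by average-information REML
#'
#' Jointly estimates the variance of each random-effect component plus the
#' residual in the marker-free model \eqn{y = X b + \sum_r u_r + \epsilon}
#' (the fixed part X holds the trial means and structure covariates only).
#' Average-information updates with step halving; non-negativity is enforced
#' by projecting each update onto a small non-negative floor, so components
#' may shrink to (numerically) zero.
#'
#' @param y Response vector.
#' @param X_base Marker-free fixed design (see [base_fixed_design()]).
#' @param components Named list of n x n covariance matrices from
#'   [build_components()].
#' @param max_iter Maximum iterations (default 100).
#' @param tol Relative REML log-likelihood convergence tolerance; two
#'   consecutive near-stationary Newton updates are required, so the
#'   variance components themselves are converged well past `sqrt(tol)`.
#' @return List with `sigma2` (named vector, one per component),
#'   `sigma2_eps`, `loglik_REML`, `converged`, `n_iter`.
#' @export
estimate_variance_components <- function(y, X_base, components,
                                         max_iter = 100, tol = 1e-10) {
  if (length(components) < 1) stop("at least one component required")
  X <- as.matrix(X_base)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  R <- length(components)
  vy <- stats::var(y)
  floor_v <- 1e-8 * vy
  theta <- rep(vy / (R + 1), R + 1)      # components then residual

  reml_ll <- function(theta) {
    V <- diag(theta[R + 1], n)
    for (r in seq_len(R)) V <- V + theta[r] * components[[r]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    logdetV <- 2 * sum(log(diag(ch)))
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    chA <- chol(XtVinvX)
    logdetA <- 2 * sum(log(diag(chA)))
    P <- Vinv - VinvX %*% chol2inv(chA) %*% t(VinvX)
    Py <- P %*% y
    ll <- -0.5 * (logdetV + logdetA + sum(y * Py) +
                    (n - p) * log(2 * pi))
    list(ll = ll, P = P, Py = Py)
  }

  st <- reml_ll(theta)
  converged <- FALSE
  iter <- 0L
  n_small <- 0L
  n_em <- 2L    # gentle EM-REML warm-up before average-information updates
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- st$P
    Py <- st$Py
    if (iter <= n_em) {
      cand <- theta
      for (r in seq_len(R))
        cand[r] <- theta[r] + (theta[r]^2 / n) *
          (sum(Py * (components[[r]] %*% Py)) - sum(P * components[[r]]))
      cand[R + 1] <- theta[R + 1] + (theta[R + 1]^2 / n) *
        (sum(Py^2) - sum(diag(P)))
      cand <- pmax(cand, floor_v)
      st_new <- reml_ll(cand)
      if (is.finite(st_new$ll) && st_new$ll >= st$ll - 1e-12) {
        theta <- cand
        st <- st_new
      }
      next
    }
    CPy <- vector("list", R + 1)
    for (r in seq_len(R)) CPy[[r]] <- components[[r]] %*% Py
    CPy[[R + 1]] <- Py
    grad <- numeric(R + 1)
    for (r in seq_len(R))
      grad[r] <- -0.5 * (sum(P * components[[r]]) - sum(Py * CPy[[r]]))
    grad[R + 1] <- -0.5 * (sum(diag(P)) - sum(Py * Py))
    AI <- matrix(0, R + 1, R + 1)
    PCPy <- lapply(CPy, function(v) P %*% v)
    for (r in seq_len(R + 1))
      for (s in r:(R + 1))
        AI[r, s] <- AI[s, r] <- 0.5 * sum(CPy[[r]] * PCPy[[s]])
    delta <- tryCatch(solve(AI, grad), error = function(e)
      drop(MASS::ginv(AI) %*% grad))
    step <- 1
    improved <- FALSE
    for (half in 1:25) {
      cand <- pmax(theta + step * delta, floor_v)
      st_new <- reml_ll(cand)
      if (is.finite(st_new$ll) && st_new$ll >= st$ll - 1e-12) {
        rel <- abs(st_new$ll - st$ll) / (abs(st$ll) + 1)
        rel_par <- max(abs(cand - theta)) / (sum(abs(theta)) + floor_v)
        theta <- cand
        st <- st_new
        improved <- TRUE
        # require two consecutive near-stationary Newton updates in both
        # the likelihood and the parameters, so the variance components
        # (hence the kernel weights) are polished to solver precision
        n_small <- if (rel < tol && rel_par < 1e-7) n_small + 1L else 0L
        if (n_small >= 2L) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      # no step along the AI direction improves the restricted likelihood:
      # the current iterate is a (possibly boundary) optimum at precision
      converged <- TRUE
    }
    if (converged) break
  }
  if (!converged)
    warning("AI-REML did not converge in ", iter,
            " iterations; returning last iterate")
  sigma2 <- theta[seq_len(R)]
  sigma2[sigma2 <= 2 * floor_v] <- 0
  names(sigma2) <- names(components)
  list(sigma2 = sigma2, sigma2_eps = theta[R + 1],
       loglik_REML = st$ll, converged = converged, n_iter = iter)
}

#' Collapse variance components into a single integrated kernel
#'
#' Normalises the estimated genetic variances into weights
#' \eqn{w_r = \hat\sigma^2_r / \sum_r \hat\sigma^2_r} (the residual is
#' excluded from the normalisation) and assembles the integrated kernel
#' \eqn{K = \sum_r C_r w_r}. The eigendecomposition of K is cached for the
#' genome scan.
#'
#' @param sigma2_hat Named non-negative variance estimates, one per
#'   component.
#' @param components Matching list of covariance matrices.
#' @param sigma2_eps Residual variance estimate (stored for reporting).
#' @return A `KernelSet`: list with `scheme` labels, `components`,
#'   `sigma2_hat`, `weights`, `K`, `K_eigen`, `sigma2_eps`.
#' @export
integrate_kernel <- function(sigma2_hat, components, sigma2_eps = NA_real_) {
  stopifnot(length(sigma2_hat) == length(components))
  tot <- sum(sigma2_hat)
  if (tot <= 0)
    stop("all component variances are zero; refit with scheme 'G' ",
         "(a tiny ridge keeps the kernel positive definite)")
  w <- sigma2_hat / tot
  K <- matrix(0, nrow(components[[1]]), ncol(components[[1]]))
  for (r in seq_along(components)) K <- K + w[r] * components[[r]]
  ks <- list(labels = names(components), components = components,
             sigma2_hat = sigma2_hat, weights = w, K = K,
             K_eigen = kernel_eigen(K), sigma2_eps = sigma2_eps)
  class(ks) <- "KernelSet"
  ks
}

#' Estimate an integrated kernel for one trait and scheme
#'
#' Convenience wrapper: builds the scheme's components, runs AI-REML on the
#' marker-free model once per trait, and returns the integrated kernel with
#' cached eigendecomposition. The weights are frozen and reused for every
#' marker in the scan.
#'
#' @param y Response vector.
#' @param X_base Marker-free fixed design.
#' @param G Genomic relationship matrix.
#' @param design An `ExperimentDesign`.
#' @param scheme Random-effect scheme (see [build_components()]).
#' @return A `KernelSet` (with the REML fit under `$reml`).
#' @export
estimate_kernel_set <- function(y, X_base, G, design, scheme = "G+GE+GT") {
  comps <- build_components(G, design, scheme)
  vc <- estimate_variance_components(y, X_base, comps)
  sigma2 <- vc$sigma2
  if (sum(sigma2) <= 0) {
    # all genetic variances at the zero boundary: the weights are
    # undefined, so keep the kernel shape with equal weights (the
    # per-marker variance-ratio profile can still shrink it to zero)
    warning("all variance components estimated at the zero boundary; ",
            "using equal kernel weights")
    sigma2[] <- 1
  }
  ks <- integrate_kernel(sigma2, comps, vc$sigma2_eps)
  ks$scheme <- scheme
  ks$reml <- vc
  ks
}

#' @export
print.KernelSet <- function(x, ...) {
  cat("KernelSet (", if (!is.null(x$scheme)) x$scheme else "custom", "): ",
      length(x$components), " component(s)\n", sep = "")
  print(round(rbind(sigma2 = x$sigma2_hat, weight = x$weights), 4))
  invisible(x)
}
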