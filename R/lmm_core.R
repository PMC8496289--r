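#' Cache the eigendecomposition of an integrated kernel
#'
#' One O(n^3) eigendecomposition is shared by every marker fit for a given
#' (trait, random-effect scheme): the model is rotated by the eigenvectors,
#' after which each profile-likelihood evaluation is O(n q^2). A small ridge
#' proportional to the mean diagonal guarantees numerical positive
#' definiteness.
#'
#' @param K n x n symmetric kernel matrix.
#' @param ridge Relative ridge added to the diagonal (times `trace(K)/n`).
#' @return List with `U` (eigenvectors), `d` (eigenvalues, descending), `n`.
#' @export
kernel_eigen <- function(K, ridge = 1e-8) {
  n <- nrow(K)
  K <- K + diag(ridge * sum(diag(K)) / n, n)
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0), n = n)
}

# Profile ML log-likelihood of the rotated single-kernel model at a given
# variance ratio h = sigma2_K / (sigma2_K + sigma2_eps). yr, Xr are the
# eigenvector-rotated response and design. Returns the log-likelihood with
# beta and total variance profiled out (ML, not REML).
.profile_ll <- function(h, yr, Xr, d) {
  n <- length(yr)
  v <- h * d + (1 - h)
  w <- 1 / v
  fit <- stats::lm.wfit(Xr, yr, w)
  rss <- sum(w * fit$residuals^2)
  s2 <- rss / n
  -0.5 * (n * log(2 * pi) + sum(log(v)) + n * log(s2) + n)
}

#' Fit the collapsed single-kernel mixed model by profile maximum likelihood
#'
#' Fits \eqn{y = X\beta + u_K + \epsilon}, \eqn{u_K \sim N(0, K\sigma^2_K)},
#' \eqn{\epsilon \sim N(0, I\sigma^2_\epsilon)} by rotating with the cached
#' eigenvectors of K and maximising the profile log-likelihood over the
#' variance ratio \eqn{h = \sigma^2_K/(\sigma^2_K+\sigma^2_\epsilon)} with a
#' bounded one-dimensional optimiser. Maximum likelihood (not REML) is used
#' throughout because the likelihood-ratio tests compare models that differ
#' in their fixed effects.
#'
#' Rank-deficient designs (the AMMI parameterisation) are handled by a
#' minimum-norm generalised-least-squares convention: the log-likelihood
#' depends only on the column space, and reported coefficients come from the
#' Moore-Penrose pseudoinverse of the weighted normal equations.
#'
#' @param y Response vector (length n).
#' @param X Fixed-effect design matrix (n x p). Columns that are entirely
#'   zero are allowed (their coefficients are 0 by the least-norm rule).
#' @param K_eigen Cached decomposition from [kernel_eigen()].
#' @param h_bounds Search interval for the variance ratio.
#' @param tol Optimiser tolerance.
#' @return A `FitResult`: list with `loglik_ML`, `heritability_ratio` (h),
#'   `sigma2_K`, `sigma2_eps`, `beta_hat`, `beta_cov`, `n_obs`, `model_df`
#'   (matrix rank of X; the LRT df ledger is handled by the caller).
#' @export
fit_ml <- function(y, X, K_eigen, h_bounds = c(1e-6, 1 - 1e-6), tol = 1e-9) {
  X <- as.matrix(X)
  stopifnot(length(y) == K_eigen$n, nrow(X) == K_eigen$n,
            all(is.finite(X)))
  yr <- crossprod(K_eigen$U, y)
  Xr <- crossprod(K_eigen$U, X)
  d <- K_eigen$d
  opt <- stats::optimize(.profile_ll, interval = h_bounds, maximum = TRUE,
                         yr = yr, Xr = Xr, d = d, tol = tol)
  h <- opt$maximum
  n <- length(yr)
  v <- h * d + (1 - h)
  w <- 1 / v
  Xw <- Xr * sqrt(w)
  yw <- yr * sqrt(w)
  A <- crossprod(Xw)
  Ainv <- MASS::ginv(A)
  beta <- drop(Ainv %*% crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% beta)^2)
  s2_tot <- rss / n
  beta_cov <- s2_tot * Ainv
  beta_cov <- (beta_cov + t(beta_cov)) / 2
  names(beta) <- colnames(X)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  res <- list(loglik_ML = opt$objective,
              heritability_ratio = h,
              sigma2_K = h * s2_tot,
              sigma2_eps = (1 - h) * s2_tot,
              beta_hat = beta,
              beta_cov = beta_cov,
              n_obs = n,
              model_df = qr(X)$rank)
  class(res) <- "FitResult"
  res
}

#' Profile log-likelihood over a grid of variance ratios
#'
#' Diagnostic companion to [fit_ml()]: evaluates the profile ML
#' log-likelihood exactly at each requested variance ratio.
#'
#' @param y,X,K_eigen As in [fit_ml()].
#' @param ratios Grid of variance ratios in (0, 1).
#' @return Numeric vector of log-likelihoods, one per grid point.
#' @export
profile_grid <- function(y, X, K_eigen, ratios) {
  if (length(ratios) == 0) stop("empty ratio grid")
  if (any(ratios <= 0 | ratios >= 1)) stop("ratios must lie in (0, 1)")
  X <- as.matrix(X)
  yr <- crossprod(K_eigen$U, y)
  Xr <- crossprod(K_eigen$U, X)
  vapply(ratios, .profile_ll, numeric(1), yr = yr, Xr = Xr, d = K_eigen$d)
}
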