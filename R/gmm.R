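# Full-covariance Gaussian mixture fitted by EM. Kept deliberately small:
# k-means initialisation, per-component covariance with a ridge
# (shrinkage towards a scaled identity) so the fit stays well-posed when
# the feature dimension approaches or exceeds the per-component sample
# count, as it routinely does for expression panels.

# log N(x | mu, Sigma) for all rows of X, via Cholesky
.mvn_logdens <- function(X, mu, chol_sigma) {
  d <- ncol(X)
  centered <- sweep(X, 2L, mu)
  z <- backsolve(chol_sigma, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) - 0.5 * d * log(2 * pi)
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' @param X numeric matrix, observations in rows.
#' @param k number of components (>= 2).
#' @param seed integer seed (governs the k-means initialisation).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param ridge covariance shrinkage: each component covariance is
#'   `(1 - ridge) * S + ridge * mean(diag(S)) * I`.
#' @return List with `labels` (hard assignment), `means`, `weights`,
#'   `responsibilities`, `loglik`, `converged`.
#' @export
gmm_cluster <- function(X, k, seed = 1L, max_iter = 200L, tol = 1e-6,
                        ridge = 0.1) {
  n <- nrow(X); d <- ncol(X)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of observations")
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = 5L, iter.max = 100L)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), km$cluster)] <- 1

  loglik_old <- -Inf
  converged <- FALSE
  means <- matrix(0, k, d)
  chols <- vector("list", k)
  weights <- numeric(k)
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-8)
    weights <- nk / n
    for (c in seq_len(k)) {
      means[c, ] <- colSums(X * resp[, c]) / nk[c]
      centered <- sweep(X, 2L, means[c, ])
      S <- crossprod(centered * sqrt(resp[, c])) / nk[c]
      S <- (1 - ridge) * S + ridge * mean(diag(S)) * diag(d)
      diag(S) <- diag(S) + 1e-10
      chols[[c]] <- chol(S)
    }
    # E-step
    logp <- vapply(seq_len(k), function(c)
      .mvn_logdens(X, means[c, ], chols[[c]]) + log(weights[c]),
      numeric(n))
    mx <- apply(logp, 1L, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    resp <- exp(logp - lse)
    loglik <- sum(lse)
    if (is.finite(loglik) && abs(loglik - loglik_old) < tol * abs(loglik)) {
      converged <- TRUE
      break
    }
    loglik_old <- loglik
  }
  list(labels = max.col(resp, ties.method = "first"),
       means = means, weights = weights, responsibilities = resp,
       loglik = loglik_old, converged = converged)
}
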