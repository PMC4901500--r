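#' Rescale a response to the BART working range
#'
#' Affine map sending `min(y)` to -0.5 and `max(y)` to +0.5, the range on
#' which the leaf-mean prior is specified.  The returned transform is
#' invertible; `y = offset + scale * yScaled`.
#'
#' @param y numeric response with `max(y) > min(y)`.
#' @return `list(yScaled, offset, scale)`.
#' @examples
#' rescaleResponse(c(0, 5, 10))$yScaled  # -0.5 0 0.5
#' @export
rescaleResponse <- function(y) {
  if (!all(is.finite(y))) stop("y must be finite")
  rng <- range(y)
  if (rng[2] <= rng[1]) stop("constant response cannot be rescaled")
  scale <- rng[2] - rng[1]
  offset <- (rng[1] + rng[2]) / 2
  list(yScaled = (y - offset) / scale, offset = offset, scale = scale)
}

#' Leaf-mean prior standard deviation
#'
#' The shrinkage prior on each leaf mean is `N(0, sigma_mu^2)` with
#' `kappa * sqrt(M) * sigma_mu = 0.5`, i.e. `sigma_mu = 0.5/(kappa sqrt(M))`:
#' the prior mass of the sum of `M` leaf contributions covers the rescaled
#' response range, and larger `kappa` or `M` shrinks individual leaves
#' harder.
#'
#' @param kappa shrinkage multiplier (default 2).
#' @param M number of trees.
#' @return `sigma_mu`.
#' @examples
#' leafPriorSd(2, 200)  # 0.5/(2*sqrt(200))
#' @export
leafPriorSd <- function(kappa = 2, M = 200) {
  stopifnot(kappa > 0, M >= 1)
  0.5 / (kappa * sqrt(M))
}

#' Calibrate the residual-variance prior scale
#'
#' The residual variance has the conjugate scaled inverse chi-square prior
#' `sigma2 ~ nu * lambda / chisq(nu)`.  `lambda` is chosen so that the prior
#' places probability `q` on `sigma <= sigma_hat`, with `sigma_hat` the
#' sample standard deviation of the (rescaled) response — the only upper
#' bound available when p >> n.  Inverting the prior CDF gives
#' `lambda = sigma_hat^2 * qchisq(1 - q, nu) / nu`.
#'
#' @param yScaled rescaled response (or anything whose SD bounds sigma).
#' @param nu prior degrees of freedom (3 to 10 recommended; warned outside).
#' @param q prior quantile placed at `sigma_hat` (default 0.9).
#' @return `lambda_sigma`.
#' @export
calibrateSigmaPrior <- function(yScaled, nu = 3, q = 0.9) {
  stopifnot(q > 0, q < 1, nu > 0)
  if (nu < 3 || nu > 10)
    warning("nu outside the recommended range [3, 10]")
  sigmaHat <- sd(yScaled)
  if (!is.finite(sigmaHat) || sigmaHat <= 0)
    stop("response has no variance to calibrate against")
  sigmaHat^2 * qchisq(1 - q, nu) / nu
}

#' Partial residuals of the sum-of-trees fit
#'
#' The backfitting target for tree `m`: the response minus the fits of all
#' other trees, `r_m = y - sum_{l != m} fit_l`.
#'
#' @param yScaled rescaled response.
#' @param fits matrix of per-tree fitted vectors (trees in columns).
#' @param m tree index.
#' @return Numeric vector `r_m`.
#' @export
partialResiduals <- function(yScaled, fits, m) {
  fits <- as.matrix(fits)
  stopifnot(m >= 1, m <= ncol(fits), nrow(fits) == length(yScaled))
  yScaled - (rowSums(fits) - fits[, m])
}

#' Marginal log-likelihood of leaf data
#'
#' Closed form of `log integral prod_i N(r_i; mu, sigma_e^2) N(mu; mu_mu,
#' sigma_mu^2) dmu`, the building block of the tree marginal likelihood that
#' drives the Metropolis-Hastings tree updates.
#'
#' @param r residuals in the leaf.
#' @param sigmaE residual SD; @param sigmaMu leaf-prior SD; @param muMu
#'   leaf-prior mean.
#' @return Log marginal likelihood.
#' @export
leafMarginalLogLik <- function(r, sigmaE, sigmaMu, muMu = 0) {
  n <- length(r)
  if (!n) stop("empty leaf")
  s <- sum(r); s2 <- sum(r^2)
  sig2 <- sigmaE^2; sMu2 <- sigmaMu^2
  denom <- sig2 + n * sMu2
  -n / 2 * log(2 * pi * sig2) + 0.5 * log(sig2 / denom) - s2 / (2 * sig2) +
    (sMu2 * s^2 + 2 * muMu * sig2 * s - n * muMu^2 * sig2) / (2 * sig2 * denom)
}

#' Marginal log-likelihood of a whole tree
#'
#' Sum of [leafMarginalLogLik()] over the leaves' row partitions: the
#' probability of the partial residuals given the tree structure, with all
#' leaf means integrated out under their conjugate normal prior.
#'
#' @param tree a tree (see [newTree()]).
#' @param X training predictor matrix; @param r partial residuals.
#' @inheritParams leafMarginalLogLik
#' @return Log marginal likelihood; error if any leaf holds no rows.
#' @export
treeMarginalLogLik <- function(tree, X, r, sigmaE, sigmaMu, muMu = 0) {
  tot <- 0
  for (L in treeLeaves(tree)) {
    rows <- nodeRowsOf(tree, X, L)
    if (!length(rows)) stop("leaf ", L, " holds no training rows")
    tot <- tot + leafMarginalLogLik(r[rows], sigmaE, sigmaMu, muMu)
  }
  tot
}

#' Conjugate draw of the leaf means
#'
#' Each leaf mean is conditionally independent with
#' `post_var = (n_l/sigma_e^2 + 1/sigma_mu^2)^{-1}` and
#' `post_mean = post_var * (sum_l r_i / sigma_e^2 + mu_mu / sigma_mu^2)`.
#'
#' @inheritParams treeMarginalLogLik
#' @return `list(tree, mu)`: the tree with leaf means set, and the named
#'   vector of drawn means (names = leaf ids).
#' @export
drawLeafMeans <- function(tree, X, r, sigmaE, sigmaMu, muMu = 0) {
  leaves <- treeLeaves(tree)
  mu <- numeric(length(leaves))
  names(mu) <- leaves
  for (k in seq_along(leaves)) {
    rows <- nodeRowsOf(tree, X, leaves[k])
    if (!length(rows)) stop("leaf ", leaves[k], " holds no training rows")
    postVar <- 1 / (length(rows) / sigmaE^2 + 1 / sigmaMu^2)
    postMean <- postVar * (sum(r[rows]) / sigmaE^2 + muMu / sigmaMu^2)
    mu[k] <- rnorm(1, postMean, sqrt(postVar))
    tree$nodes[[leaves[k]]]$mu <- mu[k]
  }
  list(tree = tree, mu = mu)
}

#' Conjugate draw of the residual variance
#'
#' Given the total fit, `sigma2 ~ Scale-inv-chisq(nu + n, (nu*lambda + SSE) /
#' (nu + n))` with `SSE = sum (y_i - fit_i)^2`, realized as
#' `(nu*lambda + SSE) / chisq(nu + n)`.
#'
#' @param yScaled rescaled response; @param fit total sum-of-trees fit.
#' @param nu,lambda prior parameters (see [calibrateSigmaPrior()]).
#' @return One draw of `sigma2`.
#' @export
drawSigma <- function(yScaled, fit, nu, lambda) {
  sse <- sum((yScaled - fit)^2)
  (nu * lambda + sse) / rchisq(1, nu + length(yScaled))
}
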