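#' Genomic relationship matrix
#'
#' VanRaden method-1 GRM from observed allele frequencies:
#' `G = Z Z' / (2 sum_k p_k (1 - p_k))` with `Z` the column-centred dosage
#' matrix.  Symmetric positive semi-definite; the diagonal averages about 1
#' under Hardy-Weinberg proportions.
#'
#' @param x [SnpGenotypes-class] or dosage matrix; no monomorphic columns.
#' @return `n x n` kernel matrix.
#' @examples
#' grm(matrix(c(0, 1, 2), 3, 1))  # diag 2, 0, 2
#' @export
grm <- function(x) {
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  f <- colMeans(X) / 2
  if (any(f <= 0 | f >= 1))
    stop("monomorphic column(s) present; apply mafFilter first")
  Z <- sweep(X, 2, 2 * f)
  G <- tcrossprod(Z) / (2 * sum(f * (1 - f)))
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

#' Radial basis function kernel on dosage rows
#'
#' `K_ij = exp(-h * d2_ij)` where `d2_ij` is the squared Euclidean distance
#' between dosage rows divided by the number of SNPs (so the printed
#' bandwidths 0.05-1 act on a per-marker scale regardless of p).
#'
#' @param x genotypes; @param h bandwidth, `h > 0`.
#' @return `n x n` kernel matrix with unit diagonal.
#' @export
rbfKernel <- function(x, h) {
  if (h <= 0) stop("h must be positive")
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  d2 <- squaredDistance(X, X) / ncol(X)
  K <- exp(-h * d2)
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' @rdname rbfKernel
#' @param xTest test genotypes: `rbfCrossKernel` gives the test-by-train
#'   kernel block under the same scaling.
#' @export
rbfCrossKernel <- function(xTest, x, h) {
  Xa <- if (is(xTest, "SnpGenotypes")) genotypes(xTest) else as.matrix(xTest)
  Xb <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  exp(-h * squaredDistance(Xa, Xb) / ncol(Xb))
}

squaredDistance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Cross GRM block for prediction
#'
#' The test-by-train block of the VanRaden relationship matrix, using the
#' training allele frequencies.
#'
#' @param xTest,x test and training genotypes.
#' @return `n_test x n_train` matrix.
#' @export
grmCross <- function(xTest, x) {
  Xa <- if (is(xTest, "SnpGenotypes")) genotypes(xTest) else as.matrix(xTest)
  Xb <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  f <- colMeans(Xb) / 2
  Za <- sweep(Xa, 2, 2 * f)
  Zb <- sweep(Xb, 2, 2 * f)
  tcrossprod(Za, Zb) / (2 * sum(f * (1 - f)))
}

#' Fit a kernel mixed model (GBLUP / RKHS)
#'
#' Maximum-likelihood fit of `y = 1 mu + g + e`, `g ~ N(0, sigma2g K)`,
#' `e ~ N(0, sigma2e I)`, via a one-dimensional search over the variance
#' ratio on the eigenrotated scale.  The predicted genetic values are the
#' BLUP `u = sigma2g K (sigma2g K + sigma2e I)^(-1) (y - 1 mu)`.
#'
#' @param K symmetric PSD kernel over the training individuals.
#' @param y phenotypes.
#' @param kind label stored in the fit (`"grm"` or `"rbf"`).
#' @param h bandwidth stored for bookkeeping (RBF only).
#' @return A [KernelFit-class].
#' @export
kernelRidgeFit <- function(K, y, kind = "grm", h = NA_real_) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (n < 3) stop("need at least three observations")
  if (max(abs(K - t(K))) > 1e-6) stop("K must be symmetric")
  if (var(y) == 0)
    return(new("KernelFit", kind = kind, h = h, mu = mean(y), sigma2g = 0,
               sigma2e = 0, u = rep(0, n), alpha = rep(0, n),
               trainIds = if (is.null(rownames(K))) character(0) else
                 rownames(K)))
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("K must be positive semi-definite")
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- crossprod(U, y)
  onesR <- crossprod(U, rep(1, n))
  profile <- function(logLambda) {
    lambda <- exp(logLambda)              # sigma2g / sigma2e
    w <- lambda * D + 1
    mu <- sum(onesR * yr / w) / sum(onesR^2 / w)
    resid <- yr - mu * onesR
    s2e <- sum(resid^2 / w) / n
    ll <- -0.5 * (sum(log(w)) + n * log(s2e) + n)
    list(ll = ll, mu = mu, s2e = s2e, resid = resid)
  }
  opt <- optimize(function(l) profile(l)$ll, c(-12, 12), maximum = TRUE)
  est <- profile(opt$maximum)
  lambda <- exp(opt$maximum)
  s2e <- est$s2e
  s2g <- lambda * s2e
  w <- lambda * D + 1
  # u = s2g K V^-1 (y - mu) with V = s2g K + s2e I
  alpha <- as.numeric(U %*% (est$resid / (s2e * w)))  # V^-1 (y - mu1)
  u <- as.numeric(s2g * K %*% alpha)
  new("KernelFit", kind = kind, h = h, mu = est$mu, sigma2g = s2g,
      sigma2e = s2e, u = u, alpha = s2g * alpha,
      trainIds = if (is.null(rownames(K))) character(0) else rownames(K))
}

#' Predict from a fitted kernel model
#'
#' Standard BLUP form `yhat* = mu + K_test_train V^(-1) sigma2g (y - 1 mu)`;
#' with `K_test_train` equal to the training kernel this reproduces
#' `mu + u`.
#'
#' @param model a [KernelFit-class].
#' @param Ktest `n_test x n_train` cross-kernel computed under the training
#'   kernel's spec ([grmCross()] or [rbfCrossKernel()]).
#' @return Numeric predictions.
#' @export
kernelPredict <- function(model, Ktest) {
  stopifnot(is(model, "KernelFit"))
  if (ncol(Ktest) != length(model@alpha))
    stop("cross-kernel has ", ncol(Ktest), " training columns; expected ",
         length(model@alpha))
  as.numeric(model@mu + Ktest %*% model@alpha)
}

#' Back-calculated SNP coefficients from a kernel fit
#'
#' Maps predicted genetic values back to per-SNP regression coefficients via
#' `beta_hat = X' Sigma^(-1) u / p`, the Manhattan-plot representation of
#' GBLUP/RKHS fits.  `Sigma` gets a `1e-8` ridge jitter before inversion
#' because PSD kernels are routinely numerically singular.
#'
#' @param x training genotypes; @param Sigma the training kernel;
#' @param u predicted genetic values.
#' @return Numeric vector of length `p` (named by SNP when available).
#' @export
backsolveCoefficients <- function(x, Sigma, u) {
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  p <- ncol(X)
  Sj <- Sigma + diag(1e-8, nrow(Sigma))
  sol <- tryCatch(solve(Sj, u),
                  error = function(e) stop("kernel is singular even after ",
                                           "ridge jitter: ", conditionMessage(e)))
  beta <- as.numeric(crossprod(X, sol)) / p
  names(beta) <- colnames(X)
  beta
}
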