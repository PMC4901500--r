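#' Fit a Bayesian additive regression tree model to SNP data
#'
#' The phenotype is modelled as a sum of `nTree` small regression trees plus
#' Gaussian noise, `y = sum_m f(X; T_m, mu_m) + e`.  Three regularization
#' priors keep each tree small and weak: the depth-penalizing structure
#' prior `alpha (1+d)^(-beta)`, the conjugate `N(0, sigma_mu^2)` prior on
#' leaf means with `kappa sqrt(M) sigma_mu = 0.5` on the rescaled response,
#' and the scaled inverse chi-square prior on the residual variance
#' calibrated so that its `q` quantile sits at the sample SD of the response.
#' Sampling is Bayesian backfitting MCMC: each sweep updates tree `m =
#' 1..M` in fixed order against its partial residuals with a
#' Metropolis-Hastings structural move (grow/prune/change/swap with
#' probabilities 0.25/0.25/0.4/0.1) followed by a conjugate draw of its leaf
#' means, then redraws the residual variance.  Defaults follow the
#' recommended settings (`nTree = 200`, `kappa = 2`, `nu = 3`, `q = 0.9`,
#' 75,000 iterations with 25,000 burn-in thinned to 5,000 draws); runs are
#' bit-reproducible under `set.seed()`.
#'
#' @param x [SnpGenotypes-class] or numeric matrix of training dosages.
#' @param y numeric phenotype vector (original units).
#' @param xTest optional test matrix evaluated on the fly (posterior-mean
#'   predictions stored in `yhatTestMean`, original units).
#' @param nTree number of trees `M`.
#' @param nIter,nBurn,nThin MCMC length, burn-in and thinning.
#' @param kappa leaf-shrinkage multiplier; @param nu,q residual-variance
#'   prior settings.
#' @param alpha,beta tree-structure prior.
#' @param moveProbs proposal probabilities (grow, prune, change, swap).
#' @param maxDepth cap on leaf depth for grow proposals.
#' @param fixSigma2 optional fixed residual variance **on the rescaled
#'   response scale** (disables the sigma draw; used for validation against
#'   enumerable posteriors).
#' @param keepTrees keep serialized tree draws (needed by `predict` and
#'   [partialDependence()]; memory grows with draws x trees).
#' @param keepTrainDraws keep the per-draw in-sample fit matrix.
#' @return A [BartFit-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200, 2, 0.5), 50, 4)
#' y <- 2 * (X[, 1] == 1) + rnorm(50, 0, 0.3)
#' fit <- bart(X, y, nTree = 10, nIter = 400, nBurn = 200)
#' which.max(vip(fit))
#' @export
bart <- function(x, y, xTest = NULL, nTree = 200L, nIter = 75000L,
                 nBurn = 25000L, nThin = max(1L, (nIter - nBurn) %/% 5000L),
                 kappa = 2, nu = 3, q = 0.9, alpha = 0.95, beta = 2,
                 moveProbs = c(0.25, 0.25, 0.4, 0.1), maxDepth = 1000L,
                 fixSigma2 = NULL, keepTrees = TRUE, keepTrainDraws = TRUE) {
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  if (!is.numeric(X) || anyNA(X)) stop("x must be a complete numeric matrix")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(x)")
  if (!all(is.finite(y))) stop("y must be finite")
  if (nrow(X) < 2) stop("need at least two observations")
  if (nBurn >= nIter) stop("burn-in must be shorter than the run")
  if (nThin < 1) stop("thinning interval must be >= 1")
  if (abs(sum(moveProbs) - 1) > 1e-8) stop("moveProbs must sum to 1")
  Xt <- if (is.null(xTest)) matrix(numeric(0), 0, ncol(X))
        else if (is(xTest, "SnpGenotypes")) genotypes(xTest) else as.matrix(xTest)
  if (nrow(Xt) > 0) matchTrainColumns(colnames(Xt), colnames(X))

  sc <- rescaleResponse(y)
  sigmaMu <- leafPriorSd(kappa, nTree)
  lambda <- calibrateSigmaPrior(sc$yScaled, nu = nu, q = q)
  res <- .bart_mcmc_cpp(X, sc$yScaled, Xt, as.integer(nTree),
                        as.integer(nIter), as.integer(nBurn),
                        as.integer(nThin), alpha, beta, sigmaMu, 0,
                        nu, lambda, var(sc$yScaled),
                        as.numeric(moveProbs), as.integer(maxDepth),
                        if (is.null(fixSigma2)) -1 else fixSigma2,
                        keepTrees, keepTrainDraws)
  toOrig <- function(f) sc$offset + sc$scale * f
  mc <- rbind(proposed = res$proposed, accepted = res$accepted)
  colnames(mc) <- c("grow", "prune", "change", "swap")
  new("BartFit",
      yhatTrain = if (keepTrainDraws) toOrig(res$yhat_train) else
        matrix(numeric(0), 0, 0),
      yhatTrainMean = as.numeric(toOrig(res$yhat_train_mean)),
      yhatTestMean = if (nrow(Xt)) as.numeric(toOrig(res$yhat_test_mean))
        else numeric(0),
      sigma2 = as.numeric(res$sigma2) * sc$scale^2,
      varcount = res$varcount,
      trees = if (keepTrees) res$trees else list(),
      scaling = c(offset = sc$offset, scale = sc$scale),
      priors = list(alpha = alpha, beta = beta, kappa = kappa,
                    sigmaMu = sigmaMu, muMu = 0, nu = nu, q = q,
                    lambda = lambda),
      config = list(nTree = nTree, nIter = nIter, nBurn = nBurn,
                    nThin = nThin, moveProbs = moveProbs,
                    maxDepth = maxDepth,
                    fixSigma2 = if (is.null(fixSigma2)) NA_real_ else fixSigma2),
      trainSnps = if (is.null(colnames(X))) character(0) else colnames(X),
      moveCounts = mc)
}

matchTrainColumns <- function(testCols, trainCols) {
  if (is.null(testCols) || is.null(trainCols)) return(invisible(TRUE))
  bad <- c(setdiff(trainCols, testCols), setdiff(testCols, trainCols))
  if (length(bad))
    stop("test SNP columns do not match training columns: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}

#' Posterior-mean prediction from a fitted BART model
#'
#' Evaluates every retained tree-ensemble draw at the new rows and averages:
#' `yhat* = (1/T) sum_t f^t(X*)`, back-transformed to original units.
#'
#' @param object a [BartFit-class] fitted with `keepTrees = TRUE`.
#' @param newdata [SnpGenotypes-class] or matrix with the training columns.
#' @param posteriorDraws return the `T x n*` matrix of per-draw predictions
#'   (original units) instead of the posterior mean.
#' @param ... unused.
#' @return Numeric vector of predictions, or a draws matrix.
#' @export
setMethod("predict", "BartFit",
          function(object, newdata, posteriorDraws = FALSE, ...) {
  if (!length(object@trees))
    stop("fit was run with keepTrees = FALSE; refit keeping trees")
  X <- if (is(newdata, "SnpGenotypes")) genotypes(newdata) else
    as.matrix(newdata)
  matchTrainColumns(colnames(X), object@trainSnps)
  if (length(object@trainSnps) && !is.null(colnames(X)))
    X <- X[, object@trainSnps, drop = FALSE]
  draws <- .bart_predict_cpp(object@trees, X)
  draws <- object@scaling["offset"] + object@scaling["scale"] * draws
  if (posteriorDraws) return(draws)
  colMeans(draws)
})

#' @rdname vip
#' @export
setMethod("vip", "BartFit", function(object, ...) {
  vc <- object@varcount
  tot <- rowSums(vc)
  pi_t <- vc / ifelse(tot == 0, 1, tot)  # zero-split draws contribute zeros
  v <- colMeans(pi_t)
  names(v) <- if (length(object@trainSnps)) object@trainSnps else
    as.character(seq_along(v))
  v
})

#' Partial dependence of the fitted surface on a SNP subset
#'
#' `f_S(x_S) = (1/n) sum_i f(x_S, x_iC)`: the model surface averaged over
#' the training rows' values of the complementary SNPs, evaluated on a grid
#' of genotypes for the SNPs in `S`.  Reveals non-linear (dominance-like)
#' within-SNP action and, for pairs, epistatic interaction.
#'
#' @param object a [BartFit-class] with kept trees.
#' @param x training [SnpGenotypes-class] or matrix.
#' @param S column indices (or SNP names) of the subset.
#' @param grid matrix/data.frame of genotype combinations for `S` (defaults
#'   to all combinations of `{0,1,2}`).
#' @return `data.frame` with the grid columns and the partial dependence
#'   `pd` (original units).
#' @export
partialDependence <- function(object, x, S, grid = NULL) {
  stopifnot(is(object, "BartFit"))
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  if (is.character(S)) S <- match(S, colnames(X))
  if (anyNA(S)) stop("unknown SNP in S")
  if (is.null(grid))
    grid <- as.matrix(expand.grid(rep(list(0:2), length(S))))
  grid <- as.matrix(grid)
  pd <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    Xk <- X
    Xk[, S] <- matrix(grid[k, ], nrow(X), length(S), byrow = TRUE)
    pd[k] <- mean(predict(object, Xk))
  }
  out <- as.data.frame(grid)
  names(out) <- if (!is.null(colnames(X))) colnames(X)[S] else
    paste0("x", S)
  out$pd <- pd
  out
}
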