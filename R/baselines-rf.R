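#' Fit a random forest regression
#'
#' `B` CART regression trees grown greedily on bootstrap resamples of the
#' training rows: at every node the best variance-reduction split is chosen
#' among `k` randomly drawn candidate variables (regression default
#' `k = p/3`), splitting until the node holds at most `nodesize` rows or no
#' split reduces the within-node sum of squares.  Out-of-bag membership is
#' recorded for [rfOobVimp()].
#'
#' @param x training genotypes ([SnpGenotypes-class] or matrix).
#' @param y phenotypes.
#' @param B number of trees.
#' @param k candidate variables per split (default `max(1, floor(p/3))`).
#' @param nodesize minimum node size (default 5).
#' @return A [RandomForestFit-class]; deterministic under `set.seed()`.
#' @export
rfFit <- function(x, y, B = 400L, k = NULL, nodesize = 5L) {
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  stopifnot(nrow(X) == length(y), B >= 1)
  p <- ncol(X)
  if (is.null(k)) k <- max(1L, p %/% 3L)
  if (k < 1 || k > p) stop("k must lie in [1, p]")
  res <- .rf_fit_cpp(X, as.numeric(y), as.integer(B), as.integer(k),
                     as.integer(nodesize))
  new("RandomForestFit", trees = res$trees, inbag = res$inbag,
      config = list(B = as.integer(B), k = as.integer(k),
                    nodesize = as.integer(nodesize)),
      trainSnps = if (is.null(colnames(X))) character(0) else colnames(X))
}

#' Predict from a random forest
#'
#' Averages the `B` per-tree predictions: `yhat* = (1/B) sum_b f_b(X*)`.
#'
#' @param forest a [RandomForestFit-class].
#' @param newdata genotypes with the training columns.
#' @param perTree return the `B x n*` matrix of per-tree predictions.
#' @return Numeric predictions (or the per-tree matrix).
#' @export
rfPredict <- function(forest, newdata, perTree = FALSE) {
  stopifnot(is(forest, "RandomForestFit"))
  X <- if (is(newdata, "SnpGenotypes")) genotypes(newdata) else
    as.matrix(newdata)
  matchTrainColumns(colnames(X), forest@trainSnps)
  if (length(forest@trainSnps) && !is.null(colnames(X)))
    X <- X[, forest@trainSnps, drop = FALSE]
  m <- .rf_predict_cpp(forest@trees, X)
  if (perTree) m else colMeans(m)
}

#' Out-of-bag permutation importance
#'
#' For each tree, the out-of-bag rows are predicted, each variable is
#' permuted among those rows in turn, and the increase in OOB mean squared
#' prediction error is recorded; the importance of a variable is the mean
#' increase over all trees divided by the standard deviation of the per-tree
#' increases.  Variables a tree never splits on cannot change its
#' predictions and contribute an exact zero for that tree, so variables used
#' nowhere score 0.
#'
#' @param forest a [RandomForestFit-class]; @param x,y the training data.
#' @return `list(importance, meanDiff, oobMspe)`: the normalized importance
#'   and raw mean error increases (named by SNP), and the forest-level
#'   out-of-bag MSPE.
#' @export
rfOobVimp <- function(forest, x, y) {
  stopifnot(is(forest, "RandomForestFit"))
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  res <- .rf_oob_vimp_cpp(forest@trees, forest@inbag, X, as.numeric(y))
  if (any(res$oobCount == 0))
    warning(sum(res$oobCount == 0),
            " row(s) are in-bag for every tree; grow more trees")
  imp <- as.numeric(res$importance)
  md <- as.numeric(res$meanDiff)
  if (length(forest@trainSnps)) names(imp) <- names(md) <- forest@trainSnps
  oob <- res$oobErr[is.finite(res$oobErr)]
  list(importance = imp, meanDiff = md,
       oobMspe = if (length(oob)) mean(oob) else NA_real_)
}
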