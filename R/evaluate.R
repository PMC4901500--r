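#' Mean squared prediction error
#'
#' `MSPE = (1/n_test) sum (yhat* - y_test)^2`, the benchmarking criterion
#' used throughout the package (always on original phenotype units).
#'
#' @param yhat predictions; @param ytest observed test phenotypes.
#' @return A single number.
#' @examples
#' mspe(c(0, 0), c(3, 4))  # 12.5
#' @export
mspe <- function(yhat, ytest) {
  if (length(yhat) != length(ytest)) stop("length mismatch")
  if (!length(yhat)) stop("empty test set")
  mean((yhat - ytest)^2)
}

#' Two-generation holdout split
#'
#' Deterministic partition of a pedigree by the `generation` field: train on
#' some generations, test on a later one (e.g. generations 1-4 vs 5).
#'
#' @param pedigree pedigree `data.frame` with `id` and `generation`.
#' @param trainGenerations,testGeneration generation numbers.
#' @return `list(train, test)` of individual ids.
#' @export
generationHoldout <- function(pedigree, trainGenerations, testGeneration) {
  if (any(testGeneration %in% trainGenerations))
    stop("train and test generations overlap")
  train <- pedigree$id[pedigree$generation %in% trainGenerations]
  test <- pedigree$id[pedigree$generation %in% testGeneration]
  if (!length(train) || !length(test))
    stop("empty train or test side; generations present: ",
         paste(sort(unique(pedigree$generation)), collapse = ", "))
  list(train = train, test = test)
}

#' Repeated random sub-sampling splits
#'
#' Each fold is an independent uniform split with `floor(frac * n)` training
#' rows and the remainder as test rows (70/30 by default, as in repeated
#' random sub-sampling validation).
#'
#' @param n number of rows; @param folds number of folds; @param frac
#'   training fraction in (0, 1).
#' @return List of `list(train, test)` integer index pairs.
#' @export
randomSubsampleSplits <- function(n, folds = 5L, frac = 0.7) {
  stopifnot(frac > 0, frac < 1, folds >= 1)
  nTrain <- floor(frac * n)
  if (nTrain < 1 || nTrain >= n) stop("fraction leaves an empty side")
  lapply(seq_len(folds), function(i) {
    train <- sort(sample.int(n, nTrain))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Hyperparameter grid search over cross-validation folds
#'
#' Fits every grid row on every fold's training side, predicts the test
#' side, and records the per-fold and mean MSPE; the row with the smallest
#' mean MSPE is flagged (ties broken toward the smaller model: fewer trees
#' `M`/`B` first, then larger `kappa`).  Adapter failures are recorded per
#' cell rather than aborting the search.
#'
#' @param x genotypes ([SnpGenotypes-class] or matrix); @param y phenotypes.
#' @param adapter a method adapter: `list(name, fit = function(X, y,
#'   params), predict = function(model, X))` — see [bartAdapter()] and
#'   friends.
#' @param grid `data.frame` of hyperparameter combinations (one row per
#'   cell; may have zero columns for parameter-free methods).
#' @param splits list of `list(train, test)` index pairs, e.g. from
#'   [randomSubsampleSplits()], or ids resolved against `rownames`.
#' @return `list(summary, perFold)`: `summary` has one row per cell with
#'   `meanMspe`, `nFolds`, `isMin` and any error message; `perFold` the fold
#'   detail.
#' @export
gridSearch <- function(x, y, adapter, grid, splits) {
  X <- if (is(x, "SnpGenotypes")) genotypes(x) else as.matrix(x)
  stopifnot(nrow(X) == length(y), length(splits) >= 1)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  resolve <- function(idx) {
    if (is.character(idx)) {
      out <- match(idx, rownames(X))
      if (anyNA(out)) stop("split ids absent from genotypes")
      out
    } else as.integer(idx)
  }
  perFold <- list()
  summary <- grid
  summary$meanMspe <- NA_real_
  summary$nFolds <- 0L
  summary$error <- NA_character_
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    errs <- character(0)
    ms <- numeric(0)
    for (f in seq_along(splits)) {
      tr <- resolve(splits[[f]]$train)
      te <- resolve(splits[[f]]$test)
      if (length(intersect(tr, te))) stop("train and test overlap in fold ", f)
      val <- tryCatch({
        fit <- adapter$fit(X[tr, , drop = FALSE], y[tr], params)
        mspe(adapter$predict(fit, X[te, , drop = FALSE]), y[te])
      }, error = function(e) conditionMessage(e))
      if (is.character(val)) errs <- c(errs, val) else {
        ms <- c(ms, val)
        perFold[[length(perFold) + 1L]] <-
          cbind(grid[g, , drop = FALSE],
                data.frame(fold = f, mspe = val, row.names = NULL))
      }
    }
    summary$meanMspe[g] <- if (length(ms)) mean(ms) else NA_real_
    summary$nFolds[g] <- length(ms)
    if (length(errs)) summary$error[g] <- errs[1]
  }
  summary$isMin <- FALSE
  ok <- which(is.finite(summary$meanMspe))
  if (length(ok)) {
    best <- ok[summary$meanMspe[ok] <= min(summary$meanMspe[ok]) + 1e-12]
    if (length(best) > 1) {
      sizeCol <- intersect(c("M", "B", "nTree"), names(grid))
      kapCol <- intersect("kappa", names(grid))
      o <- order(if (length(sizeCol)) summary[[sizeCol[1]]][best] else best,
                 if (length(kapCol)) -summary[[kapCol[1]]][best] else best)
      best <- best[o]
    }
    summary$isMin[best[1]] <- TRUE
  }
  perFold <- if (length(perFold)) do.call(rbind, perFold) else
    data.frame()
  structure(list(summary = summary, perFold = perFold,
                 method = adapter$name), class = "gwpGridSearch")
}

#' @export
print.gwpGridSearch <- function(x, ...) {
  cat("Grid search -", x$method, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Method adapters for the evaluation harness
#'
#' Thin fit/predict wrappers with a common contract, used by [gridSearch()].
#' `bartAdapter` exposes `M`, `kappa`, `q` as grid parameters (MCMC length
#' fixed per adapter); `rfAdapter` exposes `B`; `rkhsAdapter` exposes the
#' bandwidth `h`; `gblupAdapter` and `meanAdapter` (predict the training
#' mean) are parameter-free.
#'
#' @param nIter,nBurn,nThin MCMC settings for every BART cell.
#' @param nodesize random-forest minimum node size.
#' @return An adapter list for [gridSearch()].
#' @export
bartAdapter <- function(nIter = 1500L, nBurn = 500L, nThin = 1L) {
  list(name = "BART",
       fit = function(X, y, params) {
         list(X = X, y = y, params = params)
       },
       predict = function(fit, Xtest) {
         p <- fit$params
         bart(fit$X, fit$y, xTest = Xtest,
              nTree = if (!is.null(p$M)) p$M else 200L,
              kappa = if (!is.null(p$kappa)) p$kappa else 2,
              q = if (!is.null(p$q)) p$q else 0.9,
              nIter = nIter, nBurn = nBurn, nThin = nThin,
              keepTrees = FALSE, keepTrainDraws = FALSE)@yhatTestMean
       })
}

#' @rdname bartAdapter
#' @export
rfAdapter <- function(nodesize = 5L) {
  list(name = "RF",
       fit = function(X, y, params) {
         rfFit(X, y, B = if (!is.null(params$B)) params$B else 400L,
               nodesize = nodesize)
       },
       predict = function(fit, Xtest) rfPredict(fit, Xtest))
}

#' @rdname bartAdapter
#' @export
gblupAdapter <- function() {
  list(name = "GBLUP",
       fit = function(X, y, params) {
         list(model = kernelRidgeFit(grm(X), y, kind = "grm"), X = X)
       },
       predict = function(fit, Xtest)
         kernelPredict(fit$model, grmCross(Xtest, fit$X)))
}

#' @rdname bartAdapter
#' @export
rkhsAdapter <- function() {
  list(name = "RKHS",
       fit = function(X, y, params) {
         h <- if (!is.null(params$h)) params$h else 0.1
         list(model = kernelRidgeFit(rbfKernel(X, h), y, kind = "rbf", h = h),
              X = X, h = h)
       },
       predict = function(fit, Xtest)
         kernelPredict(fit$model, rbfCrossKernel(Xtest, fit$X, fit$h)))
}

#' @rdname bartAdapter
#' @export
meanAdapter <- function() {
  list(name = "mean",
       fit = function(X, y, params) mean(y),
       predict = function(fit, Xtest) rep(fit, nrow(Xtest)))
}
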