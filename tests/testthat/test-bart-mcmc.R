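# sampler-level behaviour of the backfitting MCMC

test_that("single-tree MH chain reproduces the enumerable toy posterior", {
  # one binary SNP, six rows: the only trees are root-only and the stump,
  # so the posterior is available in closed form with sigma fixed
  X <- matrix(c(0, 0, 0, 1, 1, 1), 6, 1)
  r <- c(-0.38, -0.12, -0.25, 0.08, 0.23, 0.31)
  se <- 0.25; sm <- 0.15
  lp0 <- log(1 - 0.95) + leafMarginalLogLik(r, se, sm)
  lp1 <- log(0.95) + 2 * log(1 - 0.95 * 2^-2) +
    leafMarginalLogLik(r[1:3], se, sm) + leafMarginalLogLik(r[4:6], se, sm)
  pStump <- 1 / (1 + exp(lp0 - lp1))
  set.seed(14)
  tr <- newTree()
  hits <- logical(3000)
  for (i in seq_along(hits)) {
    tr <- mhTreeUpdate(tr, X, r, se, sm)$tree
    hits[i] <- length(treeLeaves(tr)) == 2L
  }
  pHat <- mean(hits[-(1:200)])
  seBatch <- sd(colMeans(matrix(hits[-(1:200)], ncol = 40))) / sqrt(40)
  expect_lt(abs(pHat - pStump), 3 * max(seBatch, 0.01))
})

test_that("identical seeds give bit-identical posterior draws", {
  set.seed(21)
  X <- matrix(sample(0:2, 300, replace = TRUE), 60, 5)
  y <- rnorm(60, X[, 2], 1)
  set.seed(99)
  f1 <- bart(X, y, nTree = 5, nIter = 300, nBurn = 100)
  set.seed(99)
  f2 <- bart(X, y, nTree = 5, nIter = 300, nBurn = 100)
  expect_identical(sigma2Draws(f1), sigma2Draws(f2))
  expect_identical(f1@varcount, f2@varcount)
  expect_identical(f1@yhatTrain, f2@yhatTrain)
  set.seed(100)
  f3 <- bart(X, y, nTree = 5, nIter = 300, nBurn = 100)
  expect_false(identical(sigma2Draws(f1), sigma2Draws(f3)))
})

test_that("retained draw bookkeeping and train-set prediction consistency", {
  set.seed(31)
  X <- matrix(sample(0:2, 200, replace = TRUE), 40, 5)
  y <- rnorm(40, 2 * X[, 1], 1)
  fit <- bart(X, y, nTree = 8, nIter = 700, nBurn = 250, nThin = 3)
  expect_length(sigma2Draws(fit), (700 - 250) %/% 3)
  expect_equal(nrow(fit@varcount), (700 - 250) %/% 3)
  # predicting the training matrix reproduces the retained in-sample fits
  expect_equal(predict(fit, X), colMeans(fit@yhatTrain), tolerance = 1e-10)
  expect_equal(unname(colMeans(predict(fit, X, posteriorDraws = TRUE))),
               unname(predict(fit, X)))
  # duplicated test row predicts identically
  pr <- predict(fit, X[c(1, 1, 2), ])
  expect_equal(pr[1], pr[2])
})

test_that("a stump-generated signal is recovered as the top VIP variable", {
  set.seed(41)
  X <- matrix(sample(0:2, 200 * 20, replace = TRUE), 200, 20)
  y <- ifelse(X[, 7] <= 0.5, -2, 2) + rnorm(200, 0, 0.5)
  fit <- bart(X, y, nTree = 20, nIter = 600, nBurn = 300,
              keepTrees = FALSE)
  expect_equal(unname(which.max(vip(fit))), 7L)
})

test_that("strong leaf shrinkage collapses the ensemble fit toward zero", {
  # with kappa huge the leaf prior pins every mu near 0: whatever structure
  # the trees take, the fitted surface carries almost none of the response
  set.seed(51)
  X <- matrix(sample(0:2, 300, replace = TRUE), 60, 5)
  y <- rnorm(60, 2 * X[, 1], 0.5)
  fit <- bart(X, y, nTree = 5, nIter = 500, nBurn = 200, kappa = 100,
              keepTrees = FALSE)
  expect_lt(var(fit@yhatTrainMean), 0.01 * var(y))
})

test_that("increasing kappa does not increase in-sample fit variance", {
  vf <- function(kappa, seed) {
    set.seed(seed)
    X <- matrix(sample(0:2, 50 * 10, replace = TRUE), 50, 10)
    y <- rnorm(50)
    fit <- bart(X, y, nTree = 10, nIter = 500, nBurn = 250, kappa = kappa,
                keepTrees = FALSE)
    var(fit@yhatTrainMean)
  }
  v2 <- mean(vapply(1:3, function(s) vf(2, s), 1))
  v5 <- mean(vapply(1:3, function(s) vf(5, s), 1))
  expect_lte(v5, v2)
})

test_that("fit-time test predictions match tree-based prediction", {
  set.seed(61)
  X <- matrix(sample(0:2, 400, replace = TRUE), 80, 5)
  y <- rnorm(80, X[, 3], 0.7)
  Xt <- matrix(sample(0:2, 50, replace = TRUE), 10, 5)
  set.seed(5)
  fit <- bart(X, y, xTest = Xt, nTree = 6, nIter = 300, nBurn = 100)
  expect_equal(fit@yhatTestMean, unname(predict(fit, Xt)), tolerance = 1e-10)
})

test_that("column mismatch at prediction names the offending SNPs", {
  set.seed(71)
  X <- matrix(sample(0:2, 100, replace = TRUE), 20, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  fit <- bart(X, rnorm(20, X[, 1]), nTree = 3, nIter = 200, nBurn = 100)
  Xbad <- X[, 1:4]
  expect_error(predict(fit, Xbad), "s5")
})

test_that("partial dependence reflects heterozygote-specific gene action", {
  set.seed(81)
  X <- matrix(sample(0:2, 250 * 8, replace = TRUE), 250, 8)
  y <- 4 * (X[, 3] == 1) + rnorm(250, 0, 0.5)   # over-dominant action
  fit <- bart(X, y, nTree = 15, nIter = 600, nBurn = 300)
  pd <- partialDependence(fit, X, S = 3)
  expect_gt(pd$pd[pd[, 1] == 1], pd$pd[pd[, 1] == 0])
  expect_gt(pd$pd[pd[, 1] == 1], pd$pd[pd[, 1] == 2])
  # additive-in-S surface: PD on an inert SNP is nearly flat
  pdNull <- partialDependence(fit, X, S = 8)
  expect_lt(diff(range(pdNull$pd)), diff(range(pd$pd)) / 3)
})
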