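test_that("GRM follows the VanRaden construction", {
  G <- grm(matrix(c(0, 1, 2), 3, 1))
  expect_equal(diag(G), c(2, 0, 2))
  expect_equal(G[1, 3], -2)
  # identical individuals relate as strongly as to themselves
  X <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 0))
  K <- grm(X)
  expect_equal(K["a", "b"], K["a", "a"])
  expect_error(grm(cbind(c(0, 0, 0), c(0, 1, 2))), "monomorphic")
  # mean diagonal near 1 under HWE at large p
  set.seed(1)
  f <- runif(800, 0.1, 0.9)
  Xh <- sapply(f, function(p) rbinom(300, 2, p))
  expect_equal(mean(diag(grm(Xh))), 1, tolerance = 0.05)
})

test_that("RBF kernel scales squared distance per marker", {
  X <- rbind(c(rep(0, 99), 0), c(rep(0, 99), 2))
  K <- rbfKernel(X, 0.5)
  expect_equal(K[1, 2], exp(-0.5 * 4 / 100))
  expect_equal(diag(K), c(1, 1))
  expect_equal(rbfKernel(X, 1e-9)[1, 2], 1, tolerance = 1e-6)
  expect_equal(unname(rbfCrossKernel(X, X, 0.5)), unname(K))
  expect_error(rbfKernel(X, 0), "positive")
})

test_that("kernel mixed model recovers variance structure and BLUP identities", {
  set.seed(2)
  n <- 300
  X <- matrix(rbinom(n * 150, 2, 0.4), n, 150)
  K <- grm(X)
  L <- chol(K + diag(1e-6, n))
  g <- drop(crossprod(L, rnorm(n)))      # Var(g) = K
  y <- 5 + g + rnorm(n, 0, 1)            # true ratio 1
  fit <- kernelRidgeFit(K, y)
  ratio <- fit@sigma2g / fit@sigma2e
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
  # training self-prediction equals mu + u
  expect_equal(kernelPredict(fit, K), fit@mu + fit@u, tolerance = 1e-8)
  # duplicated genotype rows predict identically
  X2 <- rbind(X[1, ], X[1, ], X[2:20, ])
  Kc <- grmCross(X2, X)
  pr <- kernelPredict(fit, Kc)
  expect_equal(pr[1], pr[2])
  # constant response degenerates gracefully
  cf <- kernelRidgeFit(K, rep(2, n))
  expect_equal(cf@sigma2g, 0)
  expect_equal(kernelPredict(cf, K), rep(2, n))
})

test_that("GBLUP equals ridge regression on centred dosages", {
  set.seed(3)
  n <- 60; p <- 30
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  y <- rnorm(n, X[, 1] - X[, 2], 1)
  f <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * f)
  c0 <- 2 * sum(f * (1 - f))
  K <- tcrossprod(Z) / c0
  fit <- kernelRidgeFit(K, y)
  # primal ridge with penalty c0 * s2e / s2g reproduces u
  lam <- c0 * fit@sigma2e / fit@sigma2g
  beta <- solve(crossprod(Z) + diag(lam, p), crossprod(Z, y - fit@mu))
  expect_equal(unname(fit@u), unname(drop(Z %*% beta)), tolerance = 1e-6)
})

test_that("back-solved coefficients are linear in the genetic values", {
  set.seed(4)
  X <- matrix(rbinom(40, 2, 0.5), 20, 2)
  S <- grm(X)
  expect_equal(unname(backsolveCoefficients(X, S, rep(0, 20))), c(0, 0))
  u <- rnorm(20)
  b1 <- backsolveCoefficients(X, S, u)
  expect_equal(backsolveCoefficients(X, S, 3 * u), 3 * b1, tolerance = 1e-6)
  # p = 1, Sigma = I: beta = X'u
  X1 <- matrix(c(1, 2), 2, 1)
  expect_equal(unname(backsolveCoefficients(X1, diag(2), c(0.5, 1))),
               1 * 0.5 + 2 * 1, tolerance = 1e-6)
})

test_that("degenerate forest settings give the bootstrap-mean predictor", {
  set.seed(5)
  X <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  y <- rnorm(20)
  f <- rfFit(X, y, B = 1, k = 2, nodesize = 20)
  pr <- rfPredict(f, X)
  expect_equal(length(unique(round(pr, 12))), 1L)  # root-only tree
  boot <- rep(seq_len(20), f@inbag[, 1])
  expect_equal(pr[1], mean(y[boot]))
})

test_that("forests find a strong additive SNP at the root and are seeded", {
  set.seed(6)
  X <- matrix(sample(0:2, 200 * 10, replace = TRUE), 200, 10)
  y <- 3 * X[, 4] + rnorm(200, 0, 0.5)
  f <- rfFit(X, y, B = 30, k = 10)
  rootVars <- vapply(f@trees, function(tr) tr[1, 3], numeric(1))
  expect_gt(mean(rootVars == 4), 0.5)
  set.seed(77); f1 <- rfFit(X, y, B = 10)
  set.seed(77); f2 <- rfFit(X, y, B = 10)
  expect_identical(f1@trees, f2@trees)
  expect_identical(f1@inbag, f2@inbag)
})

test_that("forest prediction averages trees and respects row order", {
  set.seed(7)
  X <- matrix(sample(0:2, 60 * 4, replace = TRUE), 60, 4)
  y <- rnorm(60, X[, 1])
  f <- rfFit(X, y, B = 25, k = 2)
  per <- rfPredict(f, X, perTree = TRUE)
  expect_equal(rfPredict(f, X), colMeans(per))
  perm <- sample(60)
  expect_equal(rfPredict(f, X[perm, ]), rfPredict(f, X)[perm])
})

test_that("the forest tracks the reference randomForest implementation", {
  skip_if_not_installed("randomForest")
  set.seed(12)
  X <- matrix(sample(0:2, 300 * 15, replace = TRUE), 300, 15)
  y <- 2 * X[, 2] - 1.5 * X[, 9] + rnorm(300, 0, 0.8)
  tr <- 1:210; te <- 211:300
  ours <- rfFit(X[tr, ], y[tr], B = 300, k = 5)
  ref <- randomForest::randomForest(X[tr, ], y[tr], ntree = 300, mtry = 5,
                                    importance = TRUE)
  mOurs <- mspe(rfPredict(ours, X[te, ]), y[te])
  mRef <- mspe(predict(ref, X[te, ]), y[te])
  expect_lt(abs(mOurs - mRef) / mRef, 0.25)
  expect_gt(cor(rfPredict(ours, X[te, ]), predict(ref, X[te, ])), 0.9)
  # both importance routes point at the same causal pair
  v <- rfOobVimp(ours, X[tr, ], y[tr])
  expect_setequal(order(-v$importance)[1:2],
                  order(-randomForest::importance(ref, type = 1)[, 1])[1:2])
})

test_that("OOB permutation importance isolates causal variables", {
  set.seed(8)
  X <- matrix(sample(0:2, 250 * 12, replace = TRUE), 250, 12)
  X[, 12] <- 1L  # constant: can never be split on
  y <- 2.5 * X[, 3] + rnorm(250, 0, 0.7)
  f <- rfFit(X, y, B = 60, k = 4)
  v <- rfOobVimp(f, X, y)
  expect_equal(v$importance[12], 0)
  expect_equal(v$meanDiff[12], 0)
  expect_equal(which.max(v$importance), 3L)
  # monotone y rescaling preserves the importance ranking
  set.seed(99); f2 <- rfFit(X, 2 * y, B = 60, k = 4)
  v2 <- rfOobVimp(f2, X, 2 * y)
  expect_equal(order(-v$importance)[1], order(-v2$importance)[1])
  # OOB error estimates generalization: at least the in-bag fit error
  inbagMse <- mean((rfPredict(f, X) - y)^2)
  expect_gt(v$oobMspe, inbagMse)
})
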