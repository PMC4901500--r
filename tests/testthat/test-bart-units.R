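test_that("response rescaling maps the range onto [-0.5, 0.5] invertibly", {
  sc <- rescaleResponse(c(0, 10))
  expect_equal(sc$yScaled, c(-0.5, 0.5))
  expect_equal(rescaleResponse(c(0, 5, 10))$yScaled, c(-0.5, 0, 0.5))
  set.seed(1)
  y <- rnorm(50, 100, 7)
  sc <- rescaleResponse(y)
  expect_equal(sc$offset + sc$scale * sc$yScaled, y, tolerance = 1e-12)
  expect_error(rescaleResponse(rep(4, 5)), "constant")
})

test_that("leaf prior SD follows kappa sqrt(M) sigma_mu = 0.5", {
  expect_equal(leafPriorSd(2, 200), 0.5 / (2 * sqrt(200)))
  expect_equal(leafPriorSd(2, 1), 0.25)
  expect_equal(leafPriorSd(4, 100), leafPriorSd(2, 100) / 2)
})

test_that("sigma prior calibration places the q quantile at sigma_hat", {
  set.seed(3)
  y <- rnorm(200, 0, 0.23)
  for (q in c(0.75, 0.9, 0.95)) {
    lambda <- calibrateSigmaPrior(y, nu = 3, q = q)
    sigmaHat2 <- sd(y)^2
    # P(sigma2 <= sigmaHat2) under sigma2 = nu*lambda/chisq_nu
    expect_equal(1 - pchisq(3 * lambda / sigmaHat2, 3), q, tolerance = 1e-8)
  }
  # closed form at sigma_hat = 1
  y1 <- c(-1, 1) / sqrt(2) * sqrt(1 / var(c(-1, 1) / sqrt(2)))
  lambda <- calibrateSigmaPrior(y1, nu = 3, q = 0.9)
  expect_equal(lambda, qchisq(0.1, 3) / 3, tolerance = 1e-10)
  # q -> 1 drives lambda to zero
  expect_lt(calibrateSigmaPrior(y, 3, 0.999), calibrateSigmaPrior(y, 3, 0.9))
})

test_that("partial residuals subtract every other tree's fit", {
  y <- c(1, 2, 3)
  expect_equal(partialResiduals(y, matrix(0, 3, 1), 1), y)
  fits <- cbind(c(1, 0, 1), c(0.5, 0.5, 0.5))
  expect_equal(partialResiduals(y, fits, 1), y - fits[, 2])
  expect_equal(partialResiduals(y, fits, 2), y - fits[, 1])
  expect_equal(partialResiduals(y, matrix(0, 3, 5), 3), y)
})

test_that("closed-form leaf marginal likelihood matches quadrature", {
  set.seed(7)
  for (i in 1:6) {
    n <- sample(1:6, 1)
    r <- rnorm(n, sample(c(-1, 0, 2), 1), 1)
    se <- runif(1, 0.2, 2); sm <- runif(1, 0.05, 1.5); mm <- runif(1, -1, 1)
    expect_equal(leafMarginalLogLik(r, se, sm, mm), quadLeafML(r, se, sm, mm),
                 tolerance = 1e-7)
  }
  expect_equal(leafMarginalLogLik(c(0, 0), 1, 1, 0), quadLeafML(c(0, 0), 1, 1, 0),
               tolerance = 1e-8)
})

test_that("R and compiled marginal likelihoods are identical", {
  set.seed(8)
  for (i in 1:10) {
    r <- rnorm(sample(1:9, 1))
    se <- runif(1, 0.3, 2); sm <- runif(1, 0.05, 1); mm <- runif(1, -0.5, 0.5)
    expect_equal(leafMarginalLogLik(r, se, sm, mm),
                 gwpbart:::.leaf_ml_cpp(r, se^2, sm^2, mm),
                 tolerance = 1e-12)
  }
})

test_that("tight leaf prior collapses the marginal to the prior mean fit", {
  r <- c(0.3, -0.2, 0.4)
  expect_equal(leafMarginalLogLik(r, 1, 1e-9, 0.1),
               sum(dnorm(r, 0.1, 1, log = TRUE)), tolerance = 1e-5)
  # and permutation within a leaf is irrelevant
  expect_equal(leafMarginalLogLik(r, 0.7, 0.3), leafMarginalLogLik(rev(r), 0.7, 0.3))
})

test_that("tree marginal likelihood sums leaves and rejects empty ones", {
  X <- matrix(c(0, 0, 1, 2), 4, 1)
  r <- c(-1, -0.8, 0.9, 1.2)
  st <- stumpTree(1L, 0.5)
  expect_equal(treeMarginalLogLik(st, X, r, 1, 0.5),
               leafMarginalLogLik(r[1:2], 1, 0.5) +
                 leafMarginalLogLik(r[3:4], 1, 0.5))
  bad <- stumpTree(1L, 2.5)  # right leaf empty
  expect_error(treeMarginalLogLik(bad, X, r, 1, 0.5), "no training rows")
})

test_that("leaf-mean draws follow the conjugate posterior moments", {
  X <- matrix(c(0, 0, 0, 0), 4, 1)
  r <- c(1.2, 0.9, 1.1, 0.8)  # rbar = 1
  set.seed(5)
  draws <- replicate(20000, drawLeafMeans(newTree(), X, r, 1, 1, 0)$mu)
  expect_lt(abs(mean(draws) - 0.8), 3 * sqrt(0.2 / 20000))
  expect_lt(abs(var(draws) - 0.2), 3 * 0.2 * sqrt(2 / 19999))
  # flat-prior limit: posterior mean -> leaf sample mean
  set.seed(6)
  flat <- replicate(5000, drawLeafMeans(newTree(), X, r, 1, 1e4, 0)$mu)
  expect_equal(mean(flat), 1, tolerance = 0.05)
})

test_that("sigma draws follow the scaled inverse chi-square posterior", {
  set.seed(9)
  y <- rnorm(40); fit <- rep(0, 40)
  nu <- 3; lambda <- 0.4
  draws <- replicate(20000, drawSigma(y, fit, nu, lambda))
  sse <- sum(y^2); n <- 40
  postMean <- (nu * lambda + sse) / (nu + n - 2)
  expect_equal(mean(draws), postMean, tolerance = 4 * sd(draws) / sqrt(20000))
  # permutation of residuals leaves the draw unchanged (SSE is symmetric)
  yp <- sample(y)
  set.seed(42); a <- drawSigma(y, fit, nu, lambda)
  set.seed(42); b <- drawSigma(yp, fit * 0, nu, lambda)
  expect_equal(a, b)
})

test_that("vip normalizes split counts and handles splitless draws", {
  fit <- new("BartFit",
             yhatTrain = matrix(0, 3, 2), yhatTrainMean = c(0, 0),
             yhatTestMean = numeric(0), sigma2 = c(1, 1, 1),
             varcount = rbind(c(2L, 2L, 0L), c(1L, 3L, 0L), c(0L, 0L, 0L)),
             trees = list(), scaling = c(offset = 0, scale = 1),
             priors = list(), config = list(nTree = 1, nIter = 3, nBurn = 0,
                                            nThin = 1),
             trainSnps = c("a", "b", "c"),
             moveCounts = matrix(0, 2, 4,
                                 dimnames = list(c("proposed", "accepted"),
                                                 c("grow", "prune", "change",
                                                   "swap"))))
  v <- vip(fit)
  expect_equal(unname(v), c(mean(c(0.5, 0.25, 0)), mean(c(0.5, 0.75, 0)), 0))
  expect_lte(sum(v), 1)
  expect_named(v, c("a", "b", "c"))
})
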