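test_that("MSPE is the mean squared prediction difference", {
  expect_equal(mspe(c(1, 2), c(1, 2)), 0)
  expect_equal(mspe(c(0, 0), c(3, 4)), 12.5)
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10); p <- sample(10)
  expect_equal(mspe(a[p], b[p]), mspe(a, b))
  expect_error(mspe(1:3, 1:4), "mismatch")
})

test_that("generation holdout partitions the pedigree deterministically", {
  set.seed(2)
  ped <- buildPedigree(simConfig(nFoundersMale = 2, nFoundersFemale = 4,
                                 progenyPerFemale = 5, generations = 3))
  sp <- generationHoldout(ped, 1:2, 3)
  expect_setequal(sp$test, ped$id[ped$generation == 3])
  expect_setequal(sp$train, ped$id[ped$generation %in% 1:2])
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(generationHoldout(ped, 1:3, 3), "overlap")
  expect_error(generationHoldout(ped, 1:2, 9), "empty")
})

test_that("random sub-sampling folds are sized, disjoint and seeded", {
  set.seed(3)
  sp <- randomSubsampleSplits(10, folds = 4, frac = 0.7)
  for (f in sp) {
    expect_length(f$train, 7L)
    expect_length(f$test, 3L)
    expect_setequal(c(f$train, f$test), 1:10)
  }
  set.seed(9); a <- randomSubsampleSplits(50, 3, 0.7)
  set.seed(9); b <- randomSubsampleSplits(50, 3, 0.7)
  expect_identical(a, b)
  expect_error(randomSubsampleSplits(3, 1, 0.01), "empty")
})

test_that("a one-cell grid reduces to a direct fit/predict/mspe call", {
  set.seed(4)
  X <- matrix(sample(0:2, 200, replace = TRUE), 50, 4)
  y <- rnorm(50, X[, 1])
  splits <- list(list(train = 1:35, test = 36:50))
  gs <- gridSearch(X, y, meanAdapter(), data.frame(dummy = 1), splits)
  expect_equal(gs$summary$meanMspe,
               mspe(rep(mean(y[1:35]), 15), y[36:50]))
  expect_true(gs$summary$isMin)
  # mean predictor on standardized y approximates Var(y_test)
  ys <- as.numeric(scale(y))
  gs2 <- gridSearch(X, ys, meanAdapter(), data.frame(dummy = 1),
                    list(list(train = 1:40, test = 41:50)))
  expect_equal(gs2$summary$meanMspe, var(ys[41:50]), tolerance = 0.5)
})

test_that("grid search flags a unique minimum and survives adapter failure", {
  set.seed(5)
  X <- matrix(sample(0:2, 300, replace = TRUE), 60, 5)
  y <- rnorm(60, 2 * X[, 2])
  splits <- randomSubsampleSplits(60, folds = 2, frac = 0.7)
  gs <- gridSearch(X, y, rfAdapter(), data.frame(B = c(10, 40)), splits)
  expect_equal(sum(gs$summary$isMin), 1L)
  expect_equal(gs$summary$nFolds, c(2L, 2L))
  expect_equal(nrow(gs$perFold), 4L)
  expect_equal(gs$summary$meanMspe,
               tapply(gs$perFold$mspe, gs$perFold$B, mean)[c("10", "40")],
               ignore_attr = TRUE)
  failing <- list(name = "bad",
                  fit = function(X, y, params) stop("nope"),
                  predict = function(fit, X) 0)
  gf <- gridSearch(X, y, failing, data.frame(z = 1), splits)
  expect_match(gf$summary$error, "nope")
  expect_false(gf$summary$isMin)
})

test_that("grid search is reproducible from its seed", {
  set.seed(6)
  X <- matrix(sample(0:2, 240, replace = TRUE), 60, 4)
  y <- rnorm(60, X[, 1])
  run <- function() {
    set.seed(123)
    splits <- randomSubsampleSplits(60, 2, 0.7)
    gridSearch(X, y, rfAdapter(), data.frame(B = c(5, 15)), splits)$summary
  }
  expect_identical(run(), run())
})

test_that("genotype TSV and PLINK .raw round-trip through disk", {
  set.seed(7)
  g <- toyGenotypes(matrix(sample(0:2, 24, replace = TRUE), 4, 6), chroms = 2L)
  tsv <- tempfile(fileext = ".tsv")
  writeGenotypes(g, tsv, "tsv_matrix")
  g2 <- readGenotypes(tsv, "tsv_matrix", map = snpMap(g))
  expect_equal(genotypes(g2), genotypes(g))
  expect_equal(snpMap(g2), snpMap(g))
  raw <- tempfile(fileext = ".raw")
  writeGenotypes(g, raw, "plink_raw", phenotype = rnorm(4))
  g3 <- readGenotypes(raw, "plink_raw", map = snpMap(g))
  expect_equal(unname(genotypes(g3)), unname(genotypes(g)))
  expect_equal(colnames(genotypes(g3)), colnames(genotypes(g)))
})

test_that("a hand-written .raw fixture parses and bad dosages are refused", {
  raw <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snpA_A snpB_G",
               "f1 i1 0 0 1 -9 0 1.25",
               "f2 i2 0 0 2 -9 2 0"), raw)
  g <- readGenotypes(raw, "plink_raw")
  expect_equal(unname(genotypes(g)),
               matrix(c(0, 2, 1.25, 0), 2, 2))   # fractional dosage accepted
  expect_equal(colnames(genotypes(g)), c("snpA", "snpB"))
  bad <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snpA_A",
               "f1 i1 0 0 1 -9 2.5"), bad)
  expect_error(readGenotypes(bad, "plink_raw"), "out of \\[0, 2\\]")
})

test_that("pedigree, phenotype, map and architecture files round-trip", {
  set.seed(8)
  cfg <- simConfig(nFoundersMale = 1, nFoundersFemale = 2,
                   progenyPerFemale = 3, generations = 1, targetSnps = 30)
  ped <- buildPedigree(cfg)
  f <- tempfile(fileext = ".csv")
  writePedigree(ped, f)
  expect_equal(readPedigree(f), ped)
  ph <- data.frame(id = ped$id, sex = ped$sex, y = rnorm(nrow(ped)),
                   g_true = rnorm(nrow(ped)), stringsAsFactors = FALSE)
  fp <- tempfile(fileext = ".csv")
  writePhenotypes(ph, fp)
  expect_equal(readPhenotypes(fp)$y, ph$y)
  map <- makeSnpMap(cfg)
  fm <- tempfile(fileext = ".tsv")
  writeSnpMap(map, fm)
  expect_equal(readSnpMap(fm)$pos, map$pos)
  sim <- simulatePopulation(100, simConfig(targetSnps = 300),
                            calibrate = FALSE, rho = 0.5, addChr5 = TRUE)
  fa <- tempfile(fileext = ".json")
  writeArchitecture(sim$architecture, fa)
  arch2 <- readArchitecture(fa)
  expect_equal(qtlLoci(arch2), qtlLoci(sim$architecture))
  expect_equal(qtlPairs(arch2)[[3]]$map,
               qtlPairs(sim$architecture)[[3]]$map, ignore_attr = TRUE)
  g <- geneticValue(sim$haplotypes, sim$genotypes, sim$architecture)
  # imprinting aside, the reloaded architecture scores identically
  g2 <- geneticValue(sim$haplotypes, sim$genotypes, arch2)
  expect_equal(g2, g)
})

test_that("Manhattan export is sorted and joined to the map", {
  map <- data.frame(snp_id = c("a", "b", "c", "d", "e"),
                    chrom = c(2L, 1L, 1L, 2L, 1L),
                    pos = c(50, 30, 10, 20, 20))
  v <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  f <- tempfile(fileext = ".tsv")
  out <- exportManhattan(v, map, f)
  expect_equal(out$snp_id, c("c", "e", "b", "d", "a"))
  expect_equal(out$value, c(3, 5, 2, 4, 1))
  back <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$snp_id, out$snp_id)
  expect_error(exportManhattan(1:3, map, f), "lengths differ")
})
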