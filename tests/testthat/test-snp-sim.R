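test_that("pedigree construction obeys the mating design", {
  set.seed(1)
  cfg <- simConfig(generations = 0)
  ped <- buildPedigree(cfg)
  expect_equal(nrow(ped), 20L)
  expect_true(all(is.na(ped$sire)))

  set.seed(2)
  toy <- simConfig(nFoundersMale = 1, nFoundersFemale = 2,
                   progenyPerFemale = 2, generations = 1)
  ped <- buildPedigree(toy)
  expect_equal(sum(ped$generation == 0), 3L)
  # every founder female mothers exactly one litter of >= 1
  expect_setequal(unique(ped$dam[ped$generation == 1]),
                  ped$id[ped$sex == "female" & ped$generation == 0])
  expect_true(all(table(ped$dam[ped$generation == 1]) >= 1))
  expect_true(all(ped$sire[ped$generation == 1] == "ind1"))
})

test_that("default pedigree size is near the QTLMAS2010 total", {
  set.seed(3)
  ped <- buildPedigree(simConfig())
  expect_gt(nrow(ped), 3226 * 0.9)
  expect_lt(nrow(ped), 3226 * 1.1)
  expect_equal(max(ped$generation), 5L)
})

test_that("gene drop is Mendelian at every locus", {
  set.seed(4)
  cfg <- simConfig(nFoundersMale = 2, nFoundersFemale = 4,
                   progenyPerFemale = 4, generations = 2, chromosomes = 2,
                   targetSnps = 60)
  map <- makeSnpMap(cfg)
  ped <- buildPedigree(cfg)
  founders <- simulateFounderHaplotypes(map, 6, rho = 0.5)
  rownames(founders@paternal) <- rownames(founders@maternal) <-
    ped$id[ped$generation == 0]
  haps <- geneDrop(ped, founders, cfg)
  pat <- paternalHaplotypes(haps); mat <- maternalHaplotypes(haps)
  rowOf <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in which(ped$generation > 0)) {
    s <- rowOf[ped$sire[i]]; d <- rowOf[ped$dam[i]]
    expect_true(all(pat[i, ] == pat[s, ] | pat[i, ] == mat[s, ]))
    expect_true(all(mat[i, ] == pat[d, ] | mat[i, ] == mat[d, ]))
  }
  # dosage = paternal + maternal allele by construction
  expect_true(all(genotypes(toGenotypes(haps)) == pat + mat))
})

test_that("zero recombination transmits intact parental chromosomes", {
  set.seed(5)
  cfg <- simConfig(nFoundersMale = 1, nFoundersFemale = 1,
                   progenyPerFemale = 3, generations = 1, chromosomes = 1,
                   targetSnps = 40, cmPerMb = 0)
  map <- makeSnpMap(cfg)
  ped <- buildPedigree(cfg)
  founders <- simulateFounderHaplotypes(map, 2, rho = 0)
  rownames(founders@paternal) <- rownames(founders@maternal) <-
    ped$id[ped$generation == 0]
  haps <- geneDrop(ped, founders, cfg)
  pat <- paternalHaplotypes(haps)
  for (i in which(ped$generation == 1)) {
    sire <- which(ped$id == ped$sire[i])
    expect_true(identical(pat[i, ], pat[sire, ]) ||
                  identical(pat[i, ], maternalHaplotypes(haps)[sire, ]))
  }
})

test_that("gene drop names a missing founder", {
  cfg <- simConfig(nFoundersMale = 1, nFoundersFemale = 1,
                   progenyPerFemale = 2, generations = 1, targetSnps = 10)
  set.seed(6)
  map <- makeSnpMap(cfg)
  ped <- buildPedigree(cfg)
  founders <- simulateFounderHaplotypes(map, 2, rho = 0)
  rownames(founders@paternal) <- rownames(founders@maternal) <- c("ind1", "zz")
  expect_error(geneDrop(ped, founders, cfg), "ind2")
})

test_that("MAF filtering removes rare and monomorphic columns in order", {
  M <- cbind(a = rep(0, 100),                      # monomorphic
             b = c(1, rep(0, 99)),                 # MAF 0.005
             c = c(rep(1, 30), rep(0, 70)),        # MAF 0.15
             d = rep(2, 100),                      # monomorphic (other allele)
             e = c(rep(2, 60), rep(1, 30), rep(0, 10)))
  g <- toyGenotypes(M)
  flt <- mafFilter(g, 0.01)
  expect_equal(flt$kept, c(3L, 5L))
  expect_equal(colnames(genotypes(flt$genotypes)), c("c1s3", "c1s5"))
  expect_equal(mafFilter(g, 0)$kept, 1:5)
  expect_error(mafFilter(toyGenotypes(cbind(x = rep(0, 4))), 0.01),
               "no SNP")
})

test_that("adjacent LD equals the squared dosage correlation", {
  g <- toyGenotypes(cbind(a = c(0, 1, 1, 2), b = c(0, 1, 2, 1)))
  expect_equal(adjacentLd(g, mafMin = 0)$mean, 0.25)
  dup <- toyGenotypes(cbind(a = c(0, 1, 1, 2), b = c(0, 1, 1, 2)))
  expect_equal(adjacentLd(dup, mafMin = 0)$mean, 1)
  # independent loci at large n: mean r2 near zero
  set.seed(7)
  ind <- toyGenotypes(matrix(rbinom(4000 * 10, 2, 0.5), 4000, 10))
  expect_lt(adjacentLd(ind, mafMin = 0.05)$mean, 0.005)
  # pairs never straddle chromosomes
  twoChr <- toyGenotypes(cbind(a = c(0, 1, 1, 2), b = c(0, 1, 2, 1)),
                         chroms = 2L)
  expect_error(adjacentLd(twoChr, mafMin = 0), "fewer than two")
})

test_that("copula founder haplotypes span the dependence range", {
  map <- toyMap(2)
  set.seed(8)
  indep <- simulateFounderHaplotypes(toyMap(200), 400, rho = 0)
  expect_lt(adjacentLd(toGenotypes(indep), mafMin = 0.05)$mean, 0.01)
  perfect <- simulateFounderHaplotypes(map, 500, rho = 1,
                                       alleleFreq = c(0.5, 0.5))
  expect_equal(adjacentLd(toGenotypes(perfect), mafMin = 0)$mean, 1)
})

test_that("default architecture realizes the 37-QTL design", {
  set.seed(9)
  sim <- simulatePopulation(500, simConfig(targetSnps = 1000),
                            calibrate = FALSE, rho = 0.5)
  arch <- sim$architecture
  loci <- qtlLoci(arch)
  map <- snpMap(sim$genotypes)
  expect_equal(nrow(loci), 33L)  # 2 known + 28 random + 3 imprinted
  expect_length(qtlPairs(arch), 2L)
  pairSnps <- unlist(lapply(qtlPairs(arch), function(p) c(p$snp_a, p$snp_b)))
  allSnps <- c(loci$snp_id, pairSnps)
  expect_equal(length(unique(allSnps)), 37L)
  # nothing on chromosome 5
  expect_true(all(map$chrom[match(allSnps, map$snp_id)] != 5L))
  known <- loci[loci$kind == "additive" & loci$v2 == 3, ]
  expect_equal(nrow(known), 2L)
  expect_equal(known$v0, c(-3, -3))
  expect_equal(known$v1, c(0, 0))
  rand <- loci[loci$kind == "additive" & loci$v2 != 3, ]
  expect_equal(nrow(rand), 28L)
  expect_true(all(abs(rand$v2) < 2))
  expect_equal(loci$imprint_value[loci$kind == "imprinted"], rep(3, 3))
  for (pr in qtlPairs(arch)) {
    expect_equal(pr$map[1, 1], -3 - 3 + 4)      # epistatic bonus cell
    expect_equal(pr$map[3, 3], 6)
    expect_equal(pr$map[2, 2], 0)
  }
})

test_that("chromosome-5 non-additive loci carry the printed genotype values", {
  set.seed(10)
  sim <- simulatePopulation(400, simConfig(targetSnps = 800),
                            calibrate = FALSE, rho = 0.5, addChr5 = TRUE)
  loci <- qtlLoci(sim$architecture)
  dom <- loci[loci$kind == "dominant", ]
  expect_equal(c(dom$v0, dom$v1, dom$v2), c(0, 5, 5.01))
  od <- loci[loci$kind == "overdominant", ]
  expect_equal(c(od$v0, od$v1, od$v2), c(-0.01, 5, 0.01))
  ud <- loci[loci$kind == "underdominant", ]
  expect_equal(c(ud$v0, ud$v1, ud$v2), c(-0.01, -5, 0.01))
  pr <- qtlPairs(sim$architecture)[[3]]
  expect_equal(pr$map[3, 3], 0.01 + 0.01 + 5)
  expect_equal(pr$map[1, 1], -0.02)
  map <- snpMap(sim$genotypes)
  newSnps <- c(dom$snp_id, od$snp_id, ud$snp_id, pr$snp_a, pr$snp_b)
  expect_true(all(map$chrom[match(newSnps, map$snp_id)] == 5L))
  expect_error(addChr5NonAdditive(QtlArchitecture(), sim$genotypes,
                                  snpIds = c("nope1", "nope2", "nope3",
                                             "nope4", "nope5")),
               "missing")
})

test_that("genetic values sum locus, pair and imprinting contributions", {
  map <- toyMap(3)
  G <- rbind(i1 = c(2, 0, 1), i2 = c(0, 0, 1), i3 = c(1, 0, 2))
  colnames(G) <- map$snp_id
  geno <- SnpGenotypes(G, map)
  expect_equal(unname(geneticValue(NULL, geno, QtlArchitecture())), c(0, 0, 0))
  known <- data.frame(snp_id = "c1s1", kind = "additive", v0 = -3, v1 = 0,
                      v2 = 3, imprint_value = 0, imprint_allele = NA_integer_)
  arch <- QtlArchitecture(known)
  expect_equal(unname(geneticValue(NULL, geno, arch)), c(3, -3, 0))
  # imprinting depends on the parental origin of the allele
  pat <- rbind(i1 = c(1L, 0L, 1L), i2 = c(0L, 0L, 0L), i3 = c(0L, 0L, 1L))
  mat <- rbind(i1 = c(1L, 0L, 0L), i2 = c(0L, 0L, 1L), i3 = c(1L, 0L, 1L))
  colnames(pat) <- colnames(mat) <- map$snp_id
  haps <- HaplotypeSet(pat, mat, map)
  imp <- QtlArchitecture(data.frame(snp_id = "c1s3", kind = "imprinted",
                                    v0 = 0, v1 = 0, v2 = 0,
                                    imprint_value = 3, imprint_allele = 1L))
  # i1: paternal allele 1 -> 3; i2: het but allele from dam -> 0; i3: hom -> 3
  expect_equal(unname(geneticValue(haps, geno, imp)), c(3, 0, 3))
  expect_error(geneticValue(NULL, geno, imp), "parental origin")
})

test_that("purely additive architectures reduce to a linear model", {
  set.seed(11)
  for (rep in 1:3) {
    p <- 12
    G <- matrix(sample(0:2, 40 * p, replace = TRUE), 40, p)
    geno <- toyGenotypes(G)
    a <- runif(p, -2, 2)
    loci <- data.frame(snp_id = snpMap(geno)$snp_id, kind = "additive",
                       v0 = -a, v1 = 0, v2 = a, imprint_value = 0,
                       imprint_allele = NA_integer_)
    arch <- QtlArchitecture(loci)
    g <- geneticValue(NULL, geno, arch)
    expect_equal(unname(g), as.numeric(G %*% a - sum(a)), tolerance = 1e-10)
    # invariant to SNP column order: same ids and dosages, reordered columns
    perm <- sample(p)
    mapPerm <- snpMap(geno)[perm, ]
    mapPerm$pos <- sort(mapPerm$pos)  # map positions are arbitrary here
    genoPerm <- SnpGenotypes(G[, perm], mapPerm)
    expect_equal(geneticValue(NULL, genoPerm, arch), g)
  }
})

test_that("phenotype noise realizes the sex-specific heritabilities", {
  set.seed(12)
  g <- rnorm(2000, 0, 3)
  sex <- rep(c("male", "female"), 1000)
  cfg <- simConfig()
  ph <- simulatePhenotypes(g, sex, cfg)
  m <- ph$sex == "male"
  expect_equal(var(ph$g_true[m]) / var(ph$y[m]), 0.52, tolerance = 0.05)
  expect_equal(var(ph$g_true[!m]) / var(ph$y[!m]), 0.39, tolerance = 0.05)
  # h2 = 1 returns the genetic values exactly
  one <- simulatePhenotypes(g, sex, simConfig(h2Male = 1, h2Female = 1))
  expect_equal(one$y, one$g_true)
  # residual variance formula at h2 = 0.5
  half <- simulatePhenotypes(g, sex, simConfig(h2Male = 0.5, h2Female = 0.5))
  expect_equal(var(half$y - half$g_true), var(g), tolerance = 0.1 * var(g))
  expect_error(simulatePhenotypes(rep(1, 10), rep("male", 10), cfg),
               "zero genetic variance")
})

test_that("the population simulator produces consistent desk-scale data", {
  set.seed(13)
  sim <- simulatePopulation(150, simConfig(targetSnps = 400),
                            calibrate = FALSE, rho = 0.6)
  expect_equal(nInd(sim$genotypes), 150L)
  expect_true(all(genotypes(sim$genotypes) %in% 0:2))
  expect_true(all(is.finite(sim$phenotypes$y)))
  expect_equal(sim$phenotypes$id, rownames(genotypes(sim$genotypes)))
  expect_equal(genotypes(toGenotypes(sim$haplotypes)),
               genotypes(sim$genotypes))
})
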