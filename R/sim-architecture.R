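#' Default QTLMAS2010-style trait architecture
#'
#' Builds the 37-QTL architecture of the simulated trait.  The nine known
#' genes split by gene action: two plain additive major loci of effect +3 on
#' chromosome 3 (genotype values -3/0/+3, i.e. half the difference between
#' homozygote means), the four members of the two epistatic pairs (on
#' chromosomes 1 and 2; additive +3 each with an extra effect of 4 when both
#' members of a pair are the low homozygote), and three paternally imprinted
#' loci of effect 3 expressed when the paternal allele is the minor allele.
#' The remaining 28 random loci are additive with effects drawn from
#' N(0, 10) and accepted only when `|a| < 2`.  All loci are placed off
#' chromosome 5, which therefore carries no genetic effect; known genes are
#' drawn among well polymorphic SNPs (MAF >= 0.2), random loci among all
#' SNPs passing the analysis MAF filter.
#'
#' @param x a [SnpGenotypes-class] (post MAF filter): supplies the map and
#'   the allele frequencies used for eligibility.
#' @param config a [simConfig()] (unused fields reserved).
#' @return A [QtlArchitecture-class].
#' @export
defaultArchitecture <- function(x, config = simConfig()) {
  stopifnot(is(x, "SnpGenotypes"))
  map <- snpMap(x)
  f <- colMeans(genotypes(x)) / 2
  maf <- pmin(f, 1 - f)
  offChr5 <- map$chrom != 5L
  eligHigh <- which(offChr5 & maf >= 0.2)
  eligAny <- which(offChr5 & maf >= config$mafFilter)
  pairChrA <- intersect(eligHigh, which(map$chrom == 1L))
  pairChrB <- intersect(eligHigh, which(map$chrom == 2L))
  majorChr <- intersect(eligHigh, which(map$chrom == 3L))
  if (length(majorChr) < 2L) majorChr <- eligHigh
  if (length(eligHigh) < 9L || length(eligAny) < 37L ||
      length(pairChrA) < 2L || length(pairChrB) < 2L)
    stop("insufficient eligible SNPs off chromosome 5 for the architecture")

  pairA <- sample(pairChrA, 2L)
  pairB <- sample(pairChrB, 2L)
  rest <- setdiff(majorChr, c(pairA, pairB))
  known <- sample(rest, 2L)
  rest <- setdiff(eligHigh, c(pairA, pairB, known))
  imprinted <- sample(rest, 3L)
  used <- c(pairA, pairB, known, imprinted)
  randomLoci <- sample(setdiff(eligAny, used), 28L)

  aRandom <- numeric(28L)
  for (i in seq_len(28L)) {
    repeat {
      a <- rnorm(1, 0, sqrt(10))
      if (abs(a) < 2) break
    }
    aRandom[i] <- a
  }

  addRow <- function(idx, a) {
    data.frame(snp_id = map$snp_id[idx], kind = "additive",
               v0 = -a, v1 = 0, v2 = a, imprint_value = 0,
               imprint_allele = NA_integer_, stringsAsFactors = FALSE)
  }
  minorAllele <- function(idx) as.integer(f[idx] < 0.5)
  loci <- rbind(
    addRow(known, rep(3, 2L)),
    addRow(randomLoci, aRandom),
    data.frame(snp_id = map$snp_id[imprinted], kind = "imprinted",
               v0 = 0, v1 = 0, v2 = 0, imprint_value = 3,
               imprint_allele = minorAllele(imprinted),
               stringsAsFactors = FALSE))

  # pair map: additive +3 per member plus 4 when both are the low homozygote
  epiMap <- function(a = 3, bonus = 4) {
    m <- outer(a * (0:2 - 1), a * (0:2 - 1), "+")
    m[1, 1] <- m[1, 1] + bonus
    dimnames(m) <- list(g_a = 0:2, g_b = 0:2)
    m
  }
  pairs <- list(
    list(snp_a = map$snp_id[pairA[1]], snp_b = map$snp_id[pairA[2]],
         map = epiMap()),
    list(snp_a = map$snp_id[pairB[1]], snp_b = map$snp_id[pairB[2]],
         map = epiMap()))
  QtlArchitecture(loci, pairs)
}

#' Add the chromosome-5 non-additive loci
#'
#' Extends an architecture with the four extra gene actions placed on
#' chromosome 5: a (numerically near-complete) dominant locus with genotype
#' values 0 / 5 / 5.01, an over-dominant locus with -0.01 / 5 / 0.01, an
#' under-dominant locus with -0.01 / -5 / 0.01, and an epistatic pair whose
#' members take -0.01 / 0 / 0.01 with an extra 5 when both are the high
#' homozygote.
#'
#' @param arch a [QtlArchitecture-class] to extend.
#' @param x a [SnpGenotypes-class] supplying map and frequencies.
#' @param snpIds optional character vector of five chromosome-5 SNP ids
#'   (dominant, over-dominant, under-dominant, epistatic pair a and b); by
#'   default five well-polymorphic chromosome-5 SNPs are picked at evenly
#'   spread positions.
#' @return The extended [QtlArchitecture-class].
#' @export
addChr5NonAdditive <- function(arch, x, snpIds = NULL) {
  stopifnot(is(arch, "QtlArchitecture"), is(x, "SnpGenotypes"))
  map <- snpMap(x)
  if (is.null(snpIds)) {
    f <- colMeans(genotypes(x)) / 2
    maf <- pmin(f, 1 - f)
    # the added gene actions are constructed to carry (almost) no additive
    # effect, which needs near-balanced allele frequencies: take the most
    # balanced chromosome-5 SNPs, at least 5 Mb apart
    elig <- which(map$chrom == 5L & maf > 0)
    if (length(elig) < 5L)
      stop("fewer than five eligible SNPs on chromosome 5")
    byBalance <- elig[order(maf[elig], decreasing = TRUE)]
    pick <- integer(0)
    for (j in byBalance) {
      if (!length(pick) || all(abs(map$pos[j] - map$pos[pick]) >= 5e6))
        pick <- c(pick, j)
      if (length(pick) == 5L) break
    }
    if (length(pick) < 5L) pick <- byBalance[seq_len(5L)]
    snpIds <- map$snp_id[pick]
  }
  missing <- setdiff(snpIds, map$snp_id)
  if (length(missing))
    stop("designated SNP(s) missing from the map: ",
         paste(missing, collapse = ", "))
  if (length(snpIds) != 5L) stop("exactly five SNP ids are needed")
  extra <- data.frame(
    snp_id = snpIds[1:3],
    kind = c("dominant", "overdominant", "underdominant"),
    v0 = c(0, -0.01, -0.01), v1 = c(5, 5, -5), v2 = c(5.01, 0.01, 0.01),
    imprint_value = 0, imprint_allele = NA_integer_,
    stringsAsFactors = FALSE)
  m <- outer(c(-0.01, 0, 0.01), c(-0.01, 0, 0.01), "+")
  m[3, 3] <- m[3, 3] + 5
  dimnames(m) <- list(g_a = 0:2, g_b = 0:2)
  QtlArchitecture(rbind(qtlLoci(arch), extra),
                  c(qtlPairs(arch),
                    list(list(snp_a = snpIds[4], snp_b = snpIds[5], map = m))))
}

#' True genetic values under an architecture
#'
#' Deterministic genotype-to-value map: single-locus contributions via each
#' locus's genotype value map, pair contributions via the 3x3 pair maps, and
#' imprinted contributions of `imprint_value` whenever the paternally
#' inherited allele equals the designated allele (so homozygous carriers
#' always express, heterozygotes only when the allele came from the sire).
#'
#' @param haps [HaplotypeSet-class] (needed for parental origin; may be
#'   `NULL` when the architecture has no imprinted locus).
#' @param x [SnpGenotypes-class] of the same individuals.
#' @param arch [QtlArchitecture-class].
#' @return Named numeric vector of genetic values, one per individual.
#' @export
geneticValue <- function(haps, x, arch) {
  stopifnot(is(x, "SnpGenotypes"), is(arch, "QtlArchitecture"))
  G <- genotypes(x)
  g <- numeric(nrow(G))
  loci <- qtlLoci(arch)
  missing <- setdiff(c(loci$snp_id,
                       unlist(lapply(qtlPairs(arch),
                                     function(pr) c(pr$snp_a, pr$snp_b)))),
                     colnames(G))
  if (length(missing))
    stop("architecture refers to SNP(s) absent from the genotypes: ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(loci))) {
    dose <- G[, loci$snp_id[i]]
    if (loci$kind[i] == "imprinted") {
      if (is.null(haps))
        stop("imprinted loci require haplotypes with parental origin")
      patAllele <- paternalHaplotypes(haps)[, loci$snp_id[i]]
      g <- g + loci$imprint_value[i] * (patAllele == loci$imprint_allele[i])
    } else {
      vals <- c(loci$v0[i], loci$v1[i], loci$v2[i])
      g <- g + vals[round(dose) + 1L]
    }
  }
  for (pr in qtlPairs(arch)) {
    ga <- round(G[, pr$snp_a]) + 1L
    gb <- round(G[, pr$snp_b]) + 1L
    g <- g + pr$map[cbind(ga, gb)]
  }
  names(g) <- rownames(G)
  g
}

#' Simulate phenotypes at sex-specific heritabilities
#'
#' `y = g + e` with independent Gaussian residuals whose sex-specific
#' variance is set from the realized genetic variance within that sex:
#' `sigma2_sex = Var_sex(g) * (1 - h2_sex) / h2_sex`, so the realized
#' narrow-sense heritability Var(g)/Var(y) within each sex converges to the
#' configured target as n grows.  `h2 = 1` returns `y = g` exactly.
#'
#' @param g named vector of genetic values.
#' @param sex character vector (`"male"`/`"female"`) aligned with `g`.
#' @param config a [simConfig()] supplying `h2Male`, `h2Female`.
#' @return `data.frame` with `id`, `sex`, `y` and the simulation truth
#'   `g_true`.
#' @export
simulatePhenotypes <- function(g, sex, config = simConfig()) {
  stopifnot(length(g) == length(sex), all(sex %in% c("male", "female")))
  h2 <- ifelse(sex == "male", config$h2Male, config$h2Female)
  e <- numeric(length(g))
  for (s in unique(sex)) {
    idx <- sex == s
    vg <- var(g[idx])
    if (!is.finite(vg) || vg <= 0)
      stop("zero genetic variance within sex '", s, "'")
    h <- if (s == "male") config$h2Male else config$h2Female
    sd_e <- sqrt(vg * (1 - h) / h)
    e[idx] <- rnorm(sum(idx), 0, sd_e)
  }
  data.frame(id = if (is.null(names(g))) as.character(seq_along(g)) else names(g),
             sex = sex, y = g + e, g_true = as.numeric(g),
             stringsAsFactors = FALSE)
}
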