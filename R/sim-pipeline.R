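#' Simulate a full QTLMAS2010-style dataset
#'
#' End-to-end pipeline: SNP map, mating pedigree, LD-calibrated founder
#' haplotypes, gene drop, dosage conversion, MAF filter, trait architecture
#' (optionally with the chromosome-5 non-additive loci), genetic values, and
#' phenotypes at the sex-specific heritabilities.
#'
#' @param config a [simConfig()].
#' @param addChr5 also add the chromosome-5 dominant / over-dominant /
#'   under-dominant / epistatic loci and sum their values into `y`.
#' @param calibrate calibrate the founder LD parameter against
#'   `config$targetAdjacentR2` (see [calibrateFounderLd()]); when `FALSE`,
#'   `rho` is used as given.
#' @param rho copula dependence parameter used when `calibrate = FALSE`.
#' @return list with `genotypes` ([SnpGenotypes-class], MAF-filtered),
#'   `haplotypes`, `pedigree`, `phenotypes` (`id`, `sex`, `y`, `g_true`),
#'   `architecture`, `rho` and `keptSnps`.
#' @examples
#' set.seed(7)
#' sim <- simulateQtlmas(simConfig(targetSnps = 300, generations = 2,
#'                                 progenyPerFemale = 4), calibrate = FALSE)
#' nInd(sim$genotypes)
#' @export
simulateQtlmas <- function(config = simConfig(), addChr5 = FALSE,
                           calibrate = TRUE, rho = 0.9) {
  map <- makeSnpMap(config)
  ped <- buildPedigree(config)
  if (calibrate)
    rho <- calibrateFounderLd(map, ped, config)$rho
  nF <- config$nFoundersMale + config$nFoundersFemale
  founders <- simulateFounderHaplotypes(map, nF, rho = rho)
  founderIds <- ped$id[ped$generation == 0L]
  rownames(founders@paternal) <- rownames(founders@maternal) <- founderIds
  haps <- geneDrop(ped, founders, config)
  genoAll <- toGenotypes(haps)
  flt <- mafFilter(genoAll, config$mafFilter)
  geno <- flt$genotypes
  hapsF <- HaplotypeSet(paternalHaplotypes(haps)[, flt$kept, drop = FALSE],
                        maternalHaplotypes(haps)[, flt$kept, drop = FALSE],
                        snpMap(geno))
  arch <- defaultArchitecture(geno, config)
  if (addChr5) arch <- addChr5NonAdditive(arch, geno)
  g <- geneticValue(hapsF, geno, arch)
  phen <- simulatePhenotypes(g, ped$sex, config)
  list(genotypes = geno, haplotypes = hapsF, pedigree = ped,
       phenotypes = phen, architecture = arch, rho = rho, keptSnps = flt$kept)
}

#' Simulate an unpedigreed population sample
#'
#' Draws `n` individuals directly from the founder-haplotype copula model
#' (each individual is two independent haplotypes; one is arbitrarily tagged
#' paternal).  Used for desk-scale method benchmarking where the mating
#' structure is irrelevant; LD is calibrated by bisection directly on the
#' generated dosages.
#'
#' @param n individuals; @param config a [simConfig()] (supplies SNP counts,
#'   chromosomes, target r-squared, MAF filter, heritabilities).
#' @param addChr5 add the chromosome-5 non-additive loci.
#' @param calibrate calibrate `rho` to `config$targetAdjacentR2` on a pilot
#'   sample; otherwise use `rho`.
#' @param rho dependence parameter when `calibrate = FALSE`.
#' @return Same shape as [simulateQtlmas()] but with `pedigree = NULL`.
#' @export
simulatePopulation <- function(n, config = simConfig(), addChr5 = FALSE,
                               calibrate = TRUE, rho = 0.9) {
  map <- makeSnpMap(config)
  if (calibrate) {
    target <- config$targetAdjacentR2
    seed <- sample.int(.Machine$integer.max, 1L)
    nPilot <- min(n, 400L)
    obj <- function(r) {
      set.seed(seed)
      adjacentLd(toGenotypes(simulateFounderHaplotypes(map, nPilot, rho = r)),
                 mafMin = 0.05)$mean
    }
    lo <- 0; hi <- 0.995
    if (obj(lo) < target && obj(hi) > target) {
      for (i in seq_len(10L)) {
        mid <- (lo + hi) / 2
        if (obj(mid) < target) lo <- mid else hi <- mid
      }
      rho <- (lo + hi) / 2
    } else rho <- if (obj(lo) >= target) lo else hi
  }
  haps <- simulateFounderHaplotypes(map, n, rho = rho)
  flt <- mafFilter(toGenotypes(haps), config$mafFilter)
  geno <- flt$genotypes
  hapsF <- HaplotypeSet(paternalHaplotypes(haps)[, flt$kept, drop = FALSE],
                        maternalHaplotypes(haps)[, flt$kept, drop = FALSE],
                        snpMap(geno))
  arch <- defaultArchitecture(geno, config)
  if (addChr5) arch <- addChr5NonAdditive(arch, geno)
  g <- geneticValue(hapsF, geno, arch)
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  phen <- simulatePhenotypes(g, sex, config)
  phen$id <- rownames(genotypes(geno))
  names(g) <- phen$id
  list(genotypes = geno, haplotypes = hapsF, pedigree = NULL,
       phenotypes = phen, architecture = arch, rho = rho, keptSnps = flt$kept)
}
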