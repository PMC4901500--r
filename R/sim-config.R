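#' Simulator configuration
#'
#' Settings of the QTLMAS2010-style population simulator: 20 founders (5
#' males, 15 females), five generations of ~30 progeny per mated female, five
#' 100-Mb chromosomes carrying ~10,000 biallelic SNPs, a target mean adjacent
#' r-squared of 0.100 among SNPs with MAF > 0.05, and sex-specific
#' narrow-sense heritabilities of 0.52 (males) and 0.39 (females).
#'
#' `damsPerGeneration`/`siresPerGeneration` select the parents of each next
#' generation from the current one (the founder generation contributes all 15
#' females and 5 males); with 22 dams per later generation the expected
#' pedigree size is about 3,100 individuals across the five progeny
#' generations.
#'
#' @param nFoundersMale,nFoundersFemale founder counts.
#' @param generations number of progeny generations.
#' @param progenyPerFemale mean litter size (Poisson, truncated to >= 1).
#' @param damsPerGeneration,siresPerGeneration parents selected per later
#'   generation.
#' @param chromosomes number of autosomes.
#' @param chromLengthBp physical length of each chromosome, bp.
#' @param targetSnps total SNPs simulated (split evenly across chromosomes).
#' @param targetAdjacentR2 calibration target for the population mean
#'   adjacent-SNP r-squared among SNPs with MAF > 0.05.
#' @param mafFilter analysis MAF threshold; columns below it are discarded.
#' @param h2Male,h2Female sex-specific narrow-sense heritabilities.
#' @param cmPerMb recombination map density (Haldane model, no interference).
#' @return A validated list of class `simConfig`.
#' @examples
#' cfg <- simConfig(targetSnps = 500, generations = 2)
#' cfg$h2Male
#' @export
simConfig <- function(nFoundersMale = 5L, nFoundersFemale = 15L,
                      generations = 5L, progenyPerFemale = 30,
                      damsPerGeneration = 22L, siresPerGeneration = 5L,
                      chromosomes = 5L, chromLengthBp = 1e8,
                      targetSnps = 10000L, targetAdjacentR2 = 0.100,
                      mafFilter = 0.01, h2Male = 0.52, h2Female = 0.39,
                      cmPerMb = 1) {
  cfg <- list(nFoundersMale = as.integer(nFoundersMale),
              nFoundersFemale = as.integer(nFoundersFemale),
              generations = as.integer(generations),
              progenyPerFemale = progenyPerFemale,
              damsPerGeneration = as.integer(damsPerGeneration),
              siresPerGeneration = as.integer(siresPerGeneration),
              chromosomes = as.integer(chromosomes),
              chromLengthBp = chromLengthBp,
              targetSnps = as.integer(targetSnps),
              targetAdjacentR2 = targetAdjacentR2,
              mafFilter = mafFilter, h2Male = h2Male, h2Female = h2Female,
              cmPerMb = cmPerMb)
  counts <- c(cfg$nFoundersMale, cfg$nFoundersFemale, cfg$chromosomes,
              cfg$targetSnps, cfg$damsPerGeneration, cfg$siresPerGeneration)
  if (any(counts <= 0) || cfg$generations < 0 || cfg$progenyPerFemale <= 0 ||
      cfg$chromLengthBp <= 0)
    stop("all simulator counts must be positive")
  for (h in c(cfg$h2Male, cfg$h2Female))
    if (h <= 0 || h > 1) stop("heritabilities must lie in (0, 1]")
  if (cfg$targetAdjacentR2 < 0 || cfg$targetAdjacentR2 >= 1)
    stop("targetAdjacentR2 must lie in [0, 1)")
  if (cfg$mafFilter < 0 || cfg$mafFilter > 0.5)
    stop("mafFilter must lie in [0, 0.5]")
  class(cfg) <- "simConfig"
  cfg
}

#' Build a SNP map for a simulator configuration
#'
#' Places `targetSnps` markers uniformly at random along the configured
#' chromosomes (sorted, distinct 1-based bp positions).
#'
#' @param config a [simConfig()].
#' @return `data.frame` with `snp_id`, `chrom`, `pos`.
#' @export
makeSnpMap <- function(config) {
  perChrom <- rep(config$targetSnps %/% config$chromosomes, config$chromosomes)
  extra <- config$targetSnps %% config$chromosomes
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  maps <- lapply(seq_len(config$chromosomes), function(c) {
    pos <- sort(sample.int(config$chromLengthBp, perChrom[c]))
    data.frame(chrom = c, pos = pos)
  })
  map <- do.call(rbind, maps)
  map <- data.frame(snp_id = paste0("snp", seq_len(nrow(map))),
                    chrom = map$chrom, pos = map$pos,
                    stringsAsFactors = FALSE)
  map
}
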