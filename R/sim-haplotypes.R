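#' Simulate founder haplotypes with first-order linkage disequilibrium
#'
#' Allele frequencies are drawn per SNP from a U-shaped Beta(0.4, 0.4)
#' truncated to (0.01, 0.99).  Haplotype alleles are generated through a
#' Gaussian-copula Markov chain along each chromosome: a latent AR(1) process
#' with autocorrelation `rho` is thresholded at the normal quantile of each
#' SNP's allele frequency, so `rho = 0` gives mutually independent loci and
#' `rho` close to 1 gives near-perfect dependence between neighbours.  The
#' `rho` that reproduces a target population-level adjacent r-squared after
#' gene drop is found by [calibrateFounderLd()].
#'
#' @param map SNP map (`snp_id`, `chrom`, `pos`).
#' @param nIndividuals number of founder individuals (two haplotypes each).
#' @param rho latent AR(1) autocorrelation in `[0, 1)` (or exactly 1 for the
#'   perfect-dependence limit).
#' @param alleleFreq optional vector of per-SNP allele frequencies overriding
#'   the Beta draw.
#' @return A [HaplotypeSet-class] for the founders (origin tags arbitrary).
#' @examples
#' set.seed(1)
#' map <- data.frame(snp_id = c("a", "b"), chrom = 1L, pos = c(1e3, 2e3))
#' h <- simulateFounderHaplotypes(map, 10, rho = 0)
#' dim(paternalHaplotypes(h))
#' @export
simulateFounderHaplotypes <- function(map, nIndividuals, rho = 0.9,
                                      alleleFreq = NULL) {
  p <- nrow(map)
  nHap <- 2L * nIndividuals
  if (is.null(alleleFreq)) {
    alleleFreq <- rbeta(p, 0.4, 0.4)
    while (any(bad <- alleleFreq <= 0.01 | alleleFreq >= 0.99))
      alleleFreq[bad] <- rbeta(sum(bad), 0.4, 0.4)
  }
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  thr <- qnorm(alleleFreq)
  H <- matrix(0L, nHap, p)
  innov <- sqrt(max(0, 1 - rho^2))
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    z <- rnorm(nHap)
    H[, idx[1]] <- as.integer(z < thr[idx[1]])
    for (j in idx[-1]) {
      z <- rho * z + innov * rnorm(nHap)
      H[, j] <- as.integer(z < thr[j])
    }
  }
  odd <- seq(1L, nHap, by = 2L)
  pat <- H[odd, , drop = FALSE]
  mat <- H[odd + 1L, , drop = FALSE]
  rownames(pat) <- rownames(mat) <- paste0("ind", seq_len(nIndividuals))
  colnames(pat) <- colnames(mat) <- map$snp_id
  HaplotypeSet(pat, mat, map)
}

#' Drop founder haplotypes through a pedigree
#'
#' Each non-founder receives one recombinant gamete from its sire (stored as
#' the paternal haplotype) and one from its dam.  Recombination follows the
#' Haldane model: crossovers are Poisson with mean `chromLengthBp/1e8 *
#' cmPerMb` Morgans per chromosome, placed uniformly, with no interference
#' and no sex difference.
#'
#' @param pedigree pedigree `data.frame` as from [buildPedigree()], parents
#'   before offspring.
#' @param founders [HaplotypeSet-class] whose row names cover all founder
#'   ids.
#' @param config a [simConfig()] (supplies `chromLengthBp` and `cmPerMb`).
#' @return A [HaplotypeSet-class] covering every pedigree individual.
#' @export
geneDrop <- function(pedigree, founders, config = simConfig()) {
  validatePedigree(pedigree)
  map <- snpMap(founders)
  n <- nrow(pedigree)
  p <- nrow(map)
  fnames <- rownames(paternalHaplotypes(founders))
  isFounder <- pedigree$generation == 0L
  missing <- setdiff(pedigree$id[isFounder], fnames)
  if (length(missing))
    stop("founder haplotypes missing for: ", paste(missing, collapse = ", "))
  rowOf <- setNames(seq_len(n), pedigree$id)
  pat <- matrix(0L, n, p)
  mat <- matrix(0L, n, p)
  pat[which(isFounder), ] <- paternalHaplotypes(founders)[pedigree$id[isFounder], , drop = FALSE]
  mat[which(isFounder), ] <- maternalHaplotypes(founders)[pedigree$id[isFounder], , drop = FALSE]
  sireIdx <- ifelse(is.na(pedigree$sire), -1L, rowOf[pedigree$sire] - 1L)
  damIdx <- ifelse(is.na(pedigree$dam), -1L, rowOf[pedigree$dam] - 1L)
  if (any(sireIdx >= seq_len(n) - 1L & sireIdx >= 0) ||
      any(damIdx >= seq_len(n) - 1L & damIdx >= 0))
    stop("pedigree rows must be ordered parents-first")
  chroms <- unique(map$chrom)
  chromFirst <- vapply(chroms, function(c) min(which(map$chrom == c)), 1L) - 1L
  chromLast <- vapply(chroms, function(c) max(which(map$chrom == c)), 1L) - 1L
  res <- .gene_drop_cpp(pat, mat, as.integer(sireIdx), as.integer(damIdx),
                        as.integer(chromFirst), as.integer(chromLast),
                        rep(config$chromLengthBp, length(chroms)),
                        as.numeric(map$pos), config$cmPerMb)
  pat <- res$paternal
  mat <- res$maternal
  rownames(pat) <- rownames(mat) <- pedigree$id
  colnames(pat) <- colnames(mat) <- map$snp_id
  HaplotypeSet(pat, mat, map)
}

#' Collapse phased haplotypes to SNP dosages
#'
#' The dosage of an individual at a SNP is the sum of its two haplotype
#' alleles, hence an integer in `{0, 1, 2}`.
#'
#' @param haps a [HaplotypeSet-class].
#' @return A [SnpGenotypes-class].
#' @export
toGenotypes <- function(haps) {
  d <- paternalHaplotypes(haps) + maternalHaplotypes(haps)
  storage.mode(d) <- "double"
  SnpGenotypes(d, snpMap(haps))
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' Columns whose minor allele frequency is strictly below `threshold` are
#' dropped (monomorphic columns always are, for any positive threshold);
#' the original column order is preserved.
#'
#' @param x a [SnpGenotypes-class].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return `list(genotypes = <filtered SnpGenotypes>, kept = <integer
#'   indices of retained columns>)`.
#' @examples
#' g <- SnpGenotypes(cbind(a = c(0, 0, 0, 0), b = c(0, 1, 2, 1)),
#'                   data.frame(snp_id = c("a", "b"), chrom = 1L,
#'                              pos = c(1, 2)))
#' mafFilter(g, 0.01)$kept
#' @export
mafFilter <- function(x, threshold = 0.01) {
  stopifnot(is(x, "SnpGenotypes"))
  if (threshold < 0 || threshold > 0.5)
    stop("threshold must lie in [0, 0.5]")
  f <- colMeans(genotypes(x)) / 2
  maf <- pmin(f, 1 - f)
  kept <- unname(which(maf >= threshold & (threshold == 0 | maf > 0)))
  if (!length(kept)) stop("no SNP passes the MAF threshold")
  out <- SnpGenotypes(genotypes(x)[, kept, drop = FALSE],
                      snpMap(x)[kept, , drop = FALSE])
  list(genotypes = out, kept = kept)
}

#' Mean adjacent-SNP linkage disequilibrium
#'
#' r-squared is the squared Pearson correlation of unphased dosages, computed
#' for every pair of SNPs that are adjacent within a chromosome after
#' restricting to SNPs with MAF > `mafMin`.
#'
#' @param x a [SnpGenotypes-class].
#' @param mafMin MAF strictly below/at which SNPs are ignored.
#' @return `list(mean, sd, n)` over the adjacent pairs.
#' @examples
#' g <- SnpGenotypes(cbind(a = c(0, 1, 1, 2), b = c(0, 1, 2, 1)),
#'                   data.frame(snp_id = c("a", "b"), chrom = 1L,
#'                              pos = c(1, 2)))
#' adjacentLd(g, mafMin = 0)$mean  # 0.25
#' @export
adjacentLd <- function(x, mafMin = 0.05) {
  stopifnot(is(x, "SnpGenotypes"))
  r2 <- .adjacent_ld_cpp(genotypes(x), as.integer(snpMap(x)$chrom), mafMin)
  if (!length(r2)) stop("fewer than two SNPs pass the MAF threshold")
  list(mean = mean(r2), sd = sd(r2), n = length(r2))
}

#' Calibrate the founder-haplotype dependence parameter
#'
#' Bisection on the copula autocorrelation `rho` of
#' [simulateFounderHaplotypes()] so that the realized mean adjacent
#' r-squared (MAF > 0.05) of the gene-dropped population matches
#' `config$targetAdjacentR2`.  Every bisection step re-simulates the full
#' pipeline under a common random-number seed, which makes the objective an
#' (almost surely) increasing deterministic function of `rho`.
#'
#' @param map SNP map.
#' @param pedigree pedigree to drop through.
#' @param config a [simConfig()].
#' @param tol stop when the achieved r-squared is within `tol` of target.
#' @param maxIter bisection iteration cap.
#' @return `list(rho, achieved)`; if the target is out of reach the closest
#'   endpoint is returned with a warning reporting the achieved value.
#' @export
calibrateFounderLd <- function(map, pedigree, config = simConfig(),
                               tol = 0.004, maxIter = 12L) {
  target <- config$targetAdjacentR2
  seed <- sample.int(.Machine$integer.max, 1L)
  nF <- config$nFoundersMale + config$nFoundersFemale
  founderIds <- pedigree$id[pedigree$generation == 0L]
  obj <- function(rho) {
    set.seed(seed)
    f <- simulateFounderHaplotypes(map, nF, rho = rho)
    f@paternal <- f@paternal[seq_along(founderIds), , drop = FALSE]
    f@maternal <- f@maternal[seq_along(founderIds), , drop = FALSE]
    rownames(f@paternal) <- rownames(f@maternal) <- founderIds
    g <- toGenotypes(geneDrop(pedigree, f, config))
    adjacentLd(g, mafMin = 0.05)$mean
  }
  lo <- 0; hi <- 0.995
  vLo <- obj(lo)
  if (vLo >= target) {
    if (vLo - target > tol)
      warning(sprintf("LD target %.3f below reach; achieved %.3f at rho = 0",
                      target, vLo))
    return(list(rho = lo, achieved = vLo))
  }
  vHi <- obj(hi)
  if (vHi <= target) {
    warning(sprintf("LD target %.3f beyond reach; achieved %.3f at rho = %.3f",
                    target, vHi, hi))
    return(list(rho = hi, achieved = vHi))
  }
  mid <- NA
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    v <- obj(mid)
    if (abs(v - target) <= tol) return(list(rho = mid, achieved = v))
    if (v < target) lo <- mid else hi <- mid
  }
  list(rho = mid, achieved = obj(mid))
}
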