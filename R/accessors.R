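#' @rdname accessors
#' @export
setMethod("genotypes", "SnpGenotypes", function(x) x@dosage)

#' @rdname accessors
#' @export
setMethod("snpMap", "SnpGenotypes", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("snpMap", "HaplotypeSet", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("nInd", "SnpGenotypes", function(x) nrow(x@dosage))

#' @rdname accessors
#' @export
setMethod("nInd", "HaplotypeSet", function(x) nrow(x@paternal))

#' @rdname accessors
#' @export
setMethod("nSnp", "SnpGenotypes", function(x) ncol(x@dosage))

#' @rdname accessors
#' @export
setMethod("nSnp", "HaplotypeSet", function(x) ncol(x@paternal))

#' @rdname accessors
#' @export
setMethod("paternalHaplotypes", "HaplotypeSet", function(x) x@paternal)

#' @rdname accessors
#' @export
setMethod("maternalHaplotypes", "HaplotypeSet", function(x) x@maternal)

#' @rdname accessors
#' @export
setMethod("qtlLoci", "QtlArchitecture", function(x) x@loci)

#' @rdname accessors
#' @export
setMethod("qtlPairs", "QtlArchitecture", function(x) x@pairs)

#' @rdname sigma2Draws
#' @export
setMethod("sigma2Draws", "BartFit", function(object) object@sigma2)

setMethod("show", "SnpGenotypes", function(object) {
  cat("SnpGenotypes:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "SNPs on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  f <- colMeans(object@dosage) / 2
  maf <- pmin(f, 1 - f)
  cat("  mean MAF:", round(mean(maf), 3),
      "| monomorphic:", sum(maf == 0), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", nrow(object@paternal), "individuals x",
      ncol(object@paternal), "SNPs (paternal/maternal phased)\n")
})

setMethod("show", "QtlArchitecture", function(object) {
  k <- table(factor(object@loci$kind,
                    c("additive", "dominant", "overdominant",
                      "underdominant", "imprinted")))
  cat("QtlArchitecture:", nrow(object@loci), "single-locus entries (",
      paste(names(k)[k > 0], k[k > 0], sep = "=", collapse = ", "),
      ") +", length(object@pairs), "epistatic pair(s)\n")
})

setMethod("show", "BartFit", function(object) {
  cat("BartFit: sum of", object@config$nTree, "trees,",
      length(object@sigma2), "retained draws",
      sprintf("(%d iterations, %d burn-in, thin %d)\n",
              object@config$nIter, object@config$nBurn, object@config$nThin))
  cat("  posterior mean sigma2_e:", signif(mean(object@sigma2), 4), "\n")
  acc <- object@moveCounts
  rate <- ifelse(acc["proposed", ] > 0,
                 acc["accepted", ] / acc["proposed", ], NA)
  cat("  move acceptance:",
      paste(colnames(acc), round(rate, 2), sep = "=", collapse = " "), "\n")
})

setMethod("show", "KernelFit", function(object) {
  cat("KernelFit (", object@kind, "): n =", length(object@u),
      "| sigma2_g =", signif(object@sigma2g, 4),
      "| sigma2_e =", signif(object@sigma2e, 4), "\n")
})

setMethod("show", "RandomForestFit", function(object) {
  cat("RandomForestFit:", object@config$B, "trees, k =", object@config$k,
      "vars/split, min node size", object@config$nodesize, "\n")
})
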