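#' @name accessors
#' @title Accessors for gwpbart containers
#' @description Slot accessors for the S4 containers: the dosage matrix and
#'   SNP map of a [SnpGenotypes-class], the dimensions, the haplotype
#'   matrices of a [HaplotypeSet-class] and the architecture components of a
#'   [QtlArchitecture-class].
#' @param x an object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname accessors
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @rdname accessors
#' @export
setGeneric("paternalHaplotypes", function(x) standardGeneric("paternalHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("maternalHaplotypes", function(x) standardGeneric("maternalHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("qtlLoci", function(x) standardGeneric("qtlLoci"))

#' @rdname accessors
#' @export
setGeneric("qtlPairs", function(x) standardGeneric("qtlPairs"))

#' Posterior variable inclusion proportions
#'
#' For each retained posterior draw `t`, the proportion `pi_j^t` of all
#' splitting rules in the tree ensemble that use SNP `j`; the VIP of SNP `j`
#' is the average `nu_j = (1/T) sum_t pi_j^t`.  Draws whose ensemble contains
#' no split at all contribute a zero vector.
#'
#' @param object a [BartFit-class].
#' @param ... unused.
#' @return Named numeric vector of length `p`; entries are nonnegative and
#'   sum to at most 1 (exactly 1 when every retained draw has at least one
#'   split).
#' @seealso [bart()], [rfOobVimp()] for the random-forest analogue
#' @export
setGeneric("vip", function(object, ...) standardGeneric("vip"))

#' Residual-variance draws
#'
#' Retained posterior draws of the residual variance, back-transformed to
#' the squared units of the original response.
#'
#' @param object a [BartFit-class].
#' @return Numeric vector with one entry per retained draw.
#' @export
setGeneric("sigma2Draws", function(object) standardGeneric("sigma2Draws"))
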