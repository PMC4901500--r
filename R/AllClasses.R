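#' SNP genotype container
#'
#' Holds an `n x p` matrix of SNP allele dosages together with the SNP map
#' (chromosome and base-pair position per marker).  Dosages count copies of
#' the reference allele and lie in `[0, 2]`; integer values `{0, 1, 2}` for
#' called genotypes, fractional values for imputed ones.  Rows are
#' individuals, columns are SNPs; `rownames`/`colnames` carry the ids.
#'
#' @slot dosage numeric matrix of dosages in `[0, 2]` with individual ids as
#'   row names and SNP ids as column names.
#' @slot map `data.frame` with columns `snp_id`, `chrom` (integer) and `pos`
#'   (1-based bp), one row per column of `dosage`, positions strictly
#'   increasing within each chromosome.
#' @seealso [SnpGenotypes()] for the constructor, [genotypes()], [snpMap()],
#'   [mafFilter()], [adjacentLd()]
#' @export
setClass("SnpGenotypes",
  representation(dosage = "matrix", map = "data.frame"))

setValidity("SnpGenotypes", function(object) {
  d <- object@dosage
  m <- object@map
  msg <- character()
  if (!is.numeric(d)) msg <- c(msg, "dosage must be a numeric matrix")
  if (ncol(d) != nrow(m)) {
    msg <- c(msg, "map must have one row per SNP column")
  } else {
    if (!all(c("snp_id", "chrom", "pos") %in% names(m)))
      msg <- c(msg, "map needs columns snp_id, chrom, pos")
    else {
      if (anyDuplicated(m$snp_id)) msg <- c(msg, "snp ids must be unique")
      if (!is.null(colnames(d)) && !identical(colnames(d), as.character(m$snp_id)))
        msg <- c(msg, "column names must equal map snp ids")
      bad <- vapply(split(m$pos, m$chrom), function(p) any(diff(p) <= 0),
                    logical(1))
      if (any(bad))
        msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
  }
  if (length(d) && (min(d) < 0 || max(d) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (!is.null(rownames(d)) && anyDuplicated(rownames(d)))
    msg <- c(msg, "individual ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param dosage numeric matrix of allele dosages in `[0, 2]`, individuals in
#'   rows and SNPs in columns.
#' @param map `data.frame` with `snp_id`, `chrom`, `pos` describing the
#'   columns of `dosage`.
#' @return A [SnpGenotypes-class] object.
#' @examples
#' g <- SnpGenotypes(matrix(c(0, 1, 2, 1), 2, 2,
#'                          dimnames = list(c("i1", "i2"), c("s1", "s2"))),
#'                   data.frame(snp_id = c("s1", "s2"), chrom = 1L,
#'                              pos = c(100, 200)))
#' nInd(g)
#' @export
SnpGenotypes <- function(dosage, map) {
  map$snp_id <- as.character(map$snp_id)
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp_id
  if (is.null(rownames(dosage))) rownames(dosage) <- as.character(seq_len(nrow(dosage)))
  rownames(map) <- NULL
  new("SnpGenotypes", dosage = dosage, map = map)
}

#' Phased haplotypes with parental origin
#'
#' Two 0/1 haplotype matrices per individual, tagged by parental origin: the
#' `paternal` matrix holds the sire-transmitted haplotype, `maternal` the
#' dam-transmitted one (founders carry an arbitrary but fixed assignment).
#' The dosage at any SNP is the sum of the two haplotype alleles, and the
#' paternal matrix is what realizes paternal-imprinting gene action.
#'
#' @slot paternal,maternal integer 0/1 matrices, individuals by SNPs.
#' @slot map SNP map as in [SnpGenotypes-class].
#' @seealso [geneDrop()], [toGenotypes()], [geneticValue()]
#' @export
setClass("HaplotypeSet",
  representation(paternal = "matrix", maternal = "matrix", map = "data.frame"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (!identical(dim(object@paternal), dim(object@maternal)))
    msg <- c(msg, "paternal and maternal matrices must have equal dimensions")
  if (!all(object@paternal %in% c(0L, 1L)) || !all(object@maternal %in% c(0L, 1L)))
    msg <- c(msg, "haplotype alleles must be 0/1")
  if (ncol(object@paternal) != nrow(object@map))
    msg <- c(msg, "map must have one row per SNP")
  if (length(msg)) msg else TRUE
})

#' @rdname HaplotypeSet-class
#' @param paternal,maternal 0/1 haplotype matrices.
#' @param map SNP map `data.frame`.
#' @export
HaplotypeSet <- function(paternal, maternal, map) {
  map$snp_id <- as.character(map$snp_id)
  new("HaplotypeSet", paternal = paternal, maternal = maternal, map = map)
}

#' Trait architecture: single-locus QTL and epistatic pairs
#'
#' Describes how genotypes map to genetic values.  Each single-locus entry
#' assigns trait-unit values to the three genotypes (`v0`, `v1`, `v2` for
#' dosages 0/1/2); `imprinted` loci instead contribute `imprint_value`
#' whenever the paternally inherited allele equals `imprint_allele`.
#' Each epistatic pair carries a full 3x3 genotype-combination map.
#'
#' @slot loci `data.frame` with columns `snp_id`, `kind` (one of `additive`,
#'   `dominant`, `overdominant`, `underdominant`, `imprinted`), `v0`, `v1`,
#'   `v2`, `imprint_value`, `imprint_allele`.
#' @slot pairs list of `list(snp_a, snp_b, map)` where `map` is a 3x3 matrix
#'   indexed by genotype (0..2) of each member locus.
#' @seealso [defaultArchitecture()], [addChr5NonAdditive()], [geneticValue()]
#' @export
setClass("QtlArchitecture",
  representation(loci = "data.frame", pairs = "list"))

setValidity("QtlArchitecture", function(object) {
  msg <- character()
  l <- object@loci
  need <- c("snp_id", "kind", "v0", "v1", "v2", "imprint_value", "imprint_allele")
  if (!all(need %in% names(l))) {
    msg <- c(msg, paste("loci needs columns:", paste(need, collapse = ", ")))
  } else {
    kinds <- c("additive", "dominant", "overdominant", "underdominant", "imprinted")
    if (!all(l$kind %in% kinds)) msg <- c(msg, "unknown locus kind")
    if (anyDuplicated(l$snp_id))
      msg <- c(msg, "a snp id may appear in at most one single-locus entry")
    add <- l$kind == "additive"
    if (any(add) &&
        any(abs(l$v1[add] - (l$v0[add] + l$v2[add]) / 2) > 1e-8))
      msg <- c(msg, "additive loci must have v1 at the homozygote midpoint")
  }
  for (pr in object@pairs) {
    if (!all(c("snp_a", "snp_b", "map") %in% names(pr)) ||
        !identical(dim(pr$map), c(3L, 3L))) {
      msg <- c(msg, "each pair needs snp_a, snp_b and a 3x3 map")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname QtlArchitecture-class
#' @param loci single-locus entry `data.frame` (see slots).
#' @param pairs list of epistatic pair entries.
#' @export
QtlArchitecture <- function(loci = NULL, pairs = list()) {
  if (is.null(loci))
    loci <- data.frame(snp_id = character(), kind = character(),
                       v0 = numeric(), v1 = numeric(), v2 = numeric(),
                       imprint_value = numeric(), imprint_allele = integer(),
                       stringsAsFactors = FALSE)
  loci$snp_id <- as.character(loci$snp_id)
  rownames(loci) <- NULL
  new("QtlArchitecture", loci = loci, pairs = pairs)
}

#' Fitted sum-of-trees model with retained posterior draws
#'
#' Returned by [bart()].  Thinned post-burn-in draws of the in-sample fit,
#' the residual variance (original response units) and per-variable split
#' counts; optionally the serialized tree ensembles per draw (needed by
#' [predict()][predict,BartFit-method] and [partialDependence()]).
#'
#' @slot yhatTrain numeric matrix, retained draws by `n`, in-sample fit in
#'   original units (0-row when `keepTrainDraws = FALSE`).
#' @slot yhatTrainMean posterior-mean in-sample fit (original units).
#' @slot yhatTestMean posterior-mean test fit when `xTest` was supplied.
#' @slot sigma2 residual-variance draws, original squared units.
#' @slot varcount integer matrix, draws by `p`: splitting rules per variable.
#' @slot trees list of serialized tree ensembles (possibly empty).
#' @slot scaling `c(offset, scale)` of the internal response rescaling.
#' @slot priors,config lists with the prior settings and the MCMC settings.
#' @slot trainSnps SNP (column) names of the training matrix.
#' @slot moveCounts proposed/accepted counts for the four tree moves.
#' @export
setClass("BartFit",
  representation(yhatTrain = "matrix", yhatTrainMean = "numeric",
                 yhatTestMean = "numeric", sigma2 = "numeric",
                 varcount = "matrix", trees = "list", scaling = "numeric",
                 priors = "list", config = "list", trainSnps = "character",
                 moveCounts = "matrix"))

setValidity("BartFit", function(object) {
  msg <- character()
  if (any(object@sigma2 <= 0)) msg <- c(msg, "sigma2 draws must be positive")
  if (nrow(object@varcount) != length(object@sigma2))
    msg <- c(msg, "varcount and sigma2 must have one row per retained draw")
  if (length(msg)) msg else TRUE
})

#' Fitted genomic kernel model (GBLUP / RKHS)
#'
#' Mixed-model fit of `y = 1*mu + g + e` with `g ~ N(0, sigma2g * K)`,
#' variance components estimated by maximum likelihood on the eigenrotated
#' scale.
#'
#' @slot kind `"grm"` or `"rbf"`; @slot h RBF bandwidth (`NA` for GBLUP).
#' @slot mu fitted intercept; @slot sigma2g,sigma2e variance components.
#' @slot u predicted genetic values of the training individuals.
#' @slot alpha weights such that predictions are `mu + K_test_train %*% alpha`.
#' @slot trainIds training individual ids.
#' @export
setClass("KernelFit",
  representation(kind = "character", h = "numeric", mu = "numeric",
                 sigma2g = "numeric", sigma2e = "numeric", u = "numeric",
                 alpha = "numeric", trainIds = "character"))

#' Random forest regression fit
#'
#' Bagged CART regression trees with per-node random variable subsets,
#' together with the bootstrap in-bag counts needed for out-of-bag error and
#' permutation importance.
#'
#' @slot trees list of serialized trees; @slot inbag `n x B` bootstrap counts.
#' @slot config list with `B`, `k`, `nodesize`; @slot trainSnps column names.
#' @export
setClass("RandomForestFit",
  representation(trees = "list", inbag = "matrix", config = "list",
                 trainSnps = "character"))
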