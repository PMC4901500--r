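#' Read genotypes from disk
#'
#' Two dialects: `"tsv_matrix"` (tab-separated, first column `id`, one
#' column per SNP, values in `[0, 2]`) and `"plink_raw"` (the additive-coded
#' PLINK `.raw` layout: `FID IID PAT MAT SEX PHENOTYPE` followed by dosage
#' columns).  Non-integer dosages in `[0, 2]` (imputed genotypes) are
#' accepted.  A SNP map can be supplied (`data.frame` or path to a map TSV);
#' otherwise a placeholder single-chromosome map is built.
#'
#' @param path file path; @param dialect `"tsv_matrix"` or `"plink_raw"`.
#' @param map optional SNP map (`snp_id`, `chrom`, `pos`) or path to one.
#' @return A [SnpGenotypes-class].
#' @export
readGenotypes <- function(path, dialect = c("tsv_matrix", "plink_raw"),
                          map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, header = TRUE, sep = if (dialect == "tsv_matrix")
    "\t" else "", check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "tsv_matrix") {
    if (names(tab)[1] != "id") stop("first column must be 'id'")
    ids <- as.character(tab$id)
    M <- as.matrix(tab[, -1, drop = FALSE])
    snps <- colnames(M)
  } else {
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(names(tab)[1:6], lead))
      stop(".raw header must start with: ", paste(lead, collapse = " "))
    ids <- as.character(tab$IID)
    M <- as.matrix(tab[, -(1:6), drop = FALSE])
    snps <- sub("_[ACGT0-9]+$", "", colnames(M))
  }
  if (!is.numeric(M)) {
    badRow <- which(apply(M, 1, function(r) anyNA(suppressWarnings(
      as.numeric(r)))))[1]
    stop("malformed genotype row at data line ", badRow)
  }
  bad <- which(M < 0 | M > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop("dosage out of [0, 2] at data line ", bad[1, 1], ", SNP ",
         snps[bad[1, 2]])
  if (is.character(map)) map <- readSnpMap(map)
  if (is.null(map))
    map <- data.frame(snp_id = snps, chrom = 1L, pos = seq_along(snps),
                      stringsAsFactors = FALSE)
  colnames(M) <- snps
  rownames(M) <- ids
  SnpGenotypes(M, map)
}

#' @rdname readGenotypes
#' @param x a [SnpGenotypes-class] to write.
#' @param phenotype optional phenotype column for the `.raw` dialect.
#' @export
writeGenotypes <- function(x, path, dialect = c("tsv_matrix", "plink_raw"),
                           phenotype = NULL) {
  dialect <- match.arg(dialect)
  M <- genotypes(x)
  if (dialect == "tsv_matrix") {
    df <- data.frame(id = rownames(M), M, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(FID = rownames(M), IID = rownames(M), PAT = 0, MAT = 0,
                     SEX = 0,
                     PHENOTYPE = if (is.null(phenotype)) -9 else phenotype,
                     M, check.names = FALSE)
    names(df)[-(1:6)] <- paste0(colnames(M), "_A")
    write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write SNP maps, pedigrees and phenotypes
#'
#' Plain-text sidecar formats: the SNP map as 4-column TSV (`snp_id`,
#' `chrom`, `pos`, `alleles`), the pedigree as CSV (`id,sire,dam,sex,
#' generation`; empty parents for founders) and phenotypes as CSV
#' (`id,sex,y,g_true`).
#'
#' @param path file path.
#' @return The corresponding `data.frame`.
#' @export
readSnpMap <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(m)))
    stop("map needs columns: ", paste(need, collapse = ", "))
  m[, intersect(c(need, "alleles"), names(m))]
}

#' @rdname readSnpMap
#' @param map,pedigree,phenotypes objects to write.
#' @export
writeSnpMap <- function(map, path) {
  if (is.null(map$alleles)) map$alleles <- "A/B"
  write.table(map[, c("snp_id", "chrom", "pos", "alleles")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readSnpMap
#' @export
readPedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE,
                    colClasses = c(id = "character", sire = "character",
                                   dam = "character"))
  ped$sire[ped$sire %in% c("", "0", "NA")] <- NA_character_
  ped$dam[ped$dam %in% c("", "0", "NA")] <- NA_character_
  ped$generation <- as.integer(ped$generation)
  validatePedigree(ped)
  ped
}

#' @rdname readSnpMap
#' @export
writePedigree <- function(pedigree, path) {
  out <- pedigree
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readSnpMap
#' @export
readPhenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   colClasses = c(id = "character"))
  if (!all(c("id", "y") %in% names(ph)))
    stop("phenotype file needs at least columns id and y")
  if (anyNA(ph$y) || !is.numeric(ph$y)) {
    stop("non-numeric or missing phenotype at data line ",
         which(is.na(suppressWarnings(as.numeric(ph$y))))[1])
  }
  ph
}

#' @rdname readSnpMap
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a trait architecture to JSON
#'
#' Loci with their genotype value maps, imprinting entries, and epistatic
#' pairs with full 3x3 maps.
#'
#' @param arch a [QtlArchitecture-class]; @param path file path.
#' @export
writeArchitecture <- function(arch, path) {
  loci <- qtlLoci(arch)
  obj <- list(
    loci = lapply(seq_len(nrow(loci)), function(i) {
      l <- as.list(loci[i, ])
      entry <- list(snp_id = l$snp_id, kind = l$kind,
                    value_map = c(l$v0, l$v1, l$v2),
                    imprint_value = l$imprint_value)
      if (!is.na(l$imprint_allele)) entry$imprint_allele <- l$imprint_allele
      entry
    }),
    pairs = lapply(qtlPairs(arch), function(pr)
      list(snp_a = pr$snp_a, snp_b = pr$snp_b,
           pair_map = unname(as.matrix(pr$map)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeArchitecture
#' @export
readArchitecture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  loci <- do.call(rbind, lapply(obj$loci, function(l) {
    data.frame(snp_id = l$snp_id, kind = l$kind,
               v0 = l$value_map[[1]], v1 = l$value_map[[2]],
               v2 = l$value_map[[3]],
               imprint_value = if (is.null(l$imprint_value)) 0 else
                 l$imprint_value,
               imprint_allele = if (length(l$imprint_allele) != 1L)
                 NA_integer_ else as.integer(l$imprint_allele),
               stringsAsFactors = FALSE)
  }))
  pairs <- lapply(obj$pairs, function(pr) {
    m <- do.call(rbind, lapply(pr$pair_map, unlist))
    dimnames(m) <- list(g_a = 0:2, g_b = 0:2)
    list(snp_a = pr$snp_a, snp_b = pr$snp_b, map = m)
  })
  QtlArchitecture(loci, pairs)
}

#' Export per-SNP values in Manhattan-ready form
#'
#' Writes a TSV (`snp_id`, `chrom`, `pos`, `value`) sorted by chromosome and
#' position, for VIP, RF importance or back-solved coefficients.
#'
#' @param values per-SNP numeric vector aligned with `map`.
#' @param map SNP map; @param path output path.
#' @return The written `data.frame`, invisibly.
#' @export
exportManhattan <- function(values, map, path) {
  if (length(values) != nrow(map)) stop("values and map lengths differ")
  df <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                   value = as.numeric(values), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
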