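# shared builders for small in-code fixtures

toyMap <- function(p, chroms = 1L, spacing = 1000) {
  perChrom <- rep(p %/% chroms, chroms)
  perChrom[seq_len(p %% chroms)] <- perChrom[seq_len(p %% chroms)] + 1L
  do.call(rbind, lapply(seq_len(chroms), function(c)
    data.frame(snp_id = paste0("c", c, "s", seq_len(perChrom[c])),
               chrom = c, pos = spacing * seq_len(perChrom[c]),
               stringsAsFactors = FALSE)))
}

toyGenotypes <- function(M, chroms = 1L) {
  map <- toyMap(ncol(M), chroms)
  colnames(M) <- map$snp_id
  SnpGenotypes(M, map)
}

# a stump: split on `var` at `cut` with leaf means muL / muR
stumpTree <- function(var = 1L, cut = 0.5, muL = NA_real_, muR = NA_real_) {
  tr <- growTree(newTree(), 1L, var, cut)
  tr$nodes[[2]]$mu <- muL
  tr$nodes[[3]]$mu <- muR
  tr
}

# canonical structure signature (invariant to node id relabeling)
treeSignature <- function(tree, id = tree$root) {
  n <- tree$nodes[[id]]
  if (is.na(n$left)) return("L")
  paste0("(", n$var, "@", n$cut, " ", treeSignature(tree, n$left), " ",
         treeSignature(tree, n$right), ")")
}

# quadrature oracle for the leaf marginal likelihood
quadLeafML <- function(r, sigmaE, sigmaMu, muMu = 0) {
  f <- function(mu) {
    vapply(mu, function(m)
      exp(sum(dnorm(r, m, sigmaE, log = TRUE)) +
            dnorm(m, muMu, sigmaMu, log = TRUE)), numeric(1))
  }
  # centre the integrand scale to keep integrate() happy
  shift <- max(sum(dnorm(r, mean(r), sigmaE, log = TRUE)) +
                 dnorm(mean(r), muMu, sigmaMu, log = TRUE),
               -700)
  g <- function(mu) f(mu) * exp(-shift)
  lo <- min(muMu, mean(r)) - 12 * max(sigmaMu, sigmaE)
  hi <- max(muMu, mean(r)) + 12 * max(sigmaMu, sigmaE)
  v <- integrate(g, lo, hi, rel.tol = 1e-10, subdivisions = 400L)$value
  log(v) + shift
}
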