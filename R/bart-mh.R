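#' One Metropolis-Hastings update of a single tree
#'
#' Proposes one of the four structural moves — grow (p=0.25), prune (p=0.25),
#' change (p=0.4), swap (p=0.1) by default — and accepts it with the usual
#' ratio of marginal likelihoods, tree priors and proposal densities, the
#' leaf means being integrated out.  Grow draws a uniform leaf, then a
#' uniform splittable variable, then a uniform candidate cutpoint; prune
#' draws a uniform internal node whose children are both leaves; change
#' re-draws a uniform valid rule at a uniform internal node; swap exchanges
#' rules between a uniform internal node with an internal child and one such
#' child.  Structurally infeasible proposals (and proposals that would route
#' zero training rows to some leaf) count as rejections.  This is the
#' reference R implementation of the update performed in compiled code by
#' [bart()].
#'
#' @param tree current tree.
#' @param X training predictor matrix.
#' @param r partial residuals for this tree.
#' @param sigmaE residual SD; @param sigmaMu,muMu leaf-mean prior.
#' @param alpha,beta tree-structure prior.
#' @param moveProbs probabilities of (grow, prune, change, swap).
#' @param maxDepth cap on leaf depth for grow proposals.
#' @return `list(tree, accepted, move)`.
#' @export
mhTreeUpdate <- function(tree, X, r, sigmaE, sigmaMu, muMu = 0,
                         alpha = 0.95, beta = 2,
                         moveProbs = c(0.25, 0.25, 0.4, 0.1),
                         maxDepth = 1000L) {
  stopifnot(abs(sum(moveProbs) - 1) < 1e-8)
  move <- c("grow", "prune", "change", "swap")[
    findInterval(runif(1), cumsum(c(0, moveProbs)), rightmost.closed = TRUE)]
  reject <- function() list(tree = tree, accepted = FALSE, move = move)
  pSplit <- function(d) alpha * (1 + d)^(-beta)
  mlAt <- function(tr, id, rows) {
    # marginal loglik + rule-assignment log prior over subtree at id
    if (!length(rows)) return(NULL)
    if (isLeafNode(tr, id))
      return(list(ml = leafMarginalLogLik(r[rows], sigmaE, sigmaMu, muMu),
                  rp = 0))
    n <- treeNode(tr, id)
    vs <- validSplits(X, rows)
    cuts <- vs[[as.character(n$var)]]
    if (is.null(cuts) || !length(cuts)) return(NULL)
    lrows <- rows[X[rows, n$var] <= n$cut]
    rrows <- setdiff(rows, lrows)
    a <- mlAt(tr, n$left, lrows)
    b <- mlAt(tr, n$right, rrows)
    if (is.null(a) || is.null(b)) return(NULL)
    list(ml = a$ml + b$ml,
         rp = a$rp + b$rp - log(length(vs)) - log(length(cuts)))
  }
  countPrunable <- function(tr) {
    sum(vapply(treeInternals(tr), function(i) {
      n <- treeNode(tr, i)
      isLeafNode(tr, n$left) && isLeafNode(tr, n$right)
    }, logical(1)))
  }

  leaves <- treeLeaves(tree)
  internals <- treeInternals(tree)

  if (move == "grow") {
    L <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
    d <- treeNode(tree, L)$depth
    if (d >= maxDepth) return(reject())
    rows <- nodeRowsOf(tree, X, L)
    vs <- validSplits(X, rows)
    if (!length(vs)) return(reject())
    jname <- if (length(vs) == 1L) names(vs) else sample(names(vs), 1L)
    cuts <- vs[[jname]]
    cut <- if (length(cuts) == 1L) cuts else sample(cuts, 1L)
    lrows <- rows[X[rows, as.integer(jname)] <= cut]
    rrows <- setdiff(rows, lrows)
    dML <- leafMarginalLogLik(r[lrows], sigmaE, sigmaMu, muMu) +
      leafMarginalLogLik(r[rrows], sigmaE, sigmaMu, muMu) -
      leafMarginalLogLik(r[rows], sigmaE, sigmaMu, muMu)
    newTreeT <- growTree(tree, L, as.integer(jname), cut)
    logRule <- -log(length(vs)) - log(length(cuts))
    logPrior <- log(pSplit(d)) - log(1 - pSplit(d)) +
      2 * log(1 - pSplit(d + 1)) + logRule
    logProp <- (log(moveProbs[2]) - log(countPrunable(newTreeT))) -
      (log(moveProbs[1]) - log(length(leaves)) + logRule)
    if (log(runif(1)) < dML + logPrior + logProp)
      return(list(tree = newTreeT, accepted = TRUE, move = move))
    return(reject())
  }

  if (move == "prune") {
    prunable <- internals[vapply(internals, function(i) {
      n <- treeNode(tree, i)
      isLeafNode(tree, n$left) && isLeafNode(tree, n$right)
    }, logical(1))]
    if (!length(prunable)) return(reject())
    P <- if (length(prunable) == 1L) prunable else sample(prunable, 1L)
    n <- treeNode(tree, P)
    rows <- nodeRowsOf(tree, X, P)
    lrows <- rows[X[rows, n$var] <= n$cut]
    rrows <- setdiff(rows, lrows)
    dML <- leafMarginalLogLik(r[rows], sigmaE, sigmaMu, muMu) -
      leafMarginalLogLik(r[lrows], sigmaE, sigmaMu, muMu) -
      leafMarginalLogLik(r[rrows], sigmaE, sigmaMu, muMu)
    vs <- validSplits(X, rows)
    cuts <- vs[[as.character(n$var)]]
    logRule <- -log(length(vs)) - log(length(cuts))
    d <- n$depth
    logPrior <- -(log(pSplit(d)) - log(1 - pSplit(d)) +
                    2 * log(1 - pSplit(d + 1)) + logRule)
    logProp <- (log(moveProbs[1]) - log(length(leaves) - 1) + logRule) -
      (log(moveProbs[2]) - log(length(prunable)))
    if (log(runif(1)) < dML + logPrior + logProp)
      return(list(tree = pruneTree(tree, P), accepted = TRUE, move = move))
    return(reject())
  }

  if (move == "change") {
    if (!length(internals)) return(reject())
    C <- if (length(internals) == 1L) internals else sample(internals, 1L)
    rows <- nodeRowsOf(tree, X, C)
    vs <- validSplits(X, rows)
    if (!length(vs)) return(reject())
    old <- mlAt(tree, C, rows)
    if (is.null(old)) return(reject())
    oldCuts <- vs[[as.character(treeNode(tree, C)$var)]]
    jname <- if (length(vs) == 1L) names(vs) else sample(names(vs), 1L)
    cuts <- vs[[jname]]
    cut <- if (length(cuts) == 1L) cuts else sample(cuts, 1L)
    cand <- changeRule(tree, C, as.integer(jname), cut)
    new <- mlAt(cand, C, rows)
    if (is.null(new)) return(reject())
    logQf <- -log(length(vs)) - log(length(cuts))
    logQr <- -log(length(vs)) - log(length(oldCuts))
    logA <- (new$ml - old$ml) + (new$rp - old$rp) + (logQr - logQf)
    if (log(runif(1)) < logA)
      return(list(tree = cand, accepted = TRUE, move = move))
    return(reject())
  }

  # swap
  cand <- internals[vapply(internals, function(i) {
    n <- treeNode(tree, i)
    !isLeafNode(tree, n$left) || !isLeafNode(tree, n$right)
  }, logical(1))]
  if (!length(cand)) return(reject())
  P <- if (length(cand) == 1L) cand else sample(cand, 1L)
  pn <- treeNode(tree, P)
  ic <- c(pn$left, pn$right)
  ic <- ic[!vapply(ic, function(i) isLeafNode(tree, i), logical(1))]
  C <- if (length(ic) == 1L) ic else sample(ic, 1L)
  rows <- nodeRowsOf(tree, X, P)
  old <- mlAt(tree, P, rows)
  if (is.null(old)) return(reject())
  swapped <- swapRule(tree, P, C)
  new <- mlAt(swapped, P, rows)
  if (is.null(new)) return(reject())
  if (log(runif(1)) < (new$ml - old$ml) + (new$rp - old$rp))
    return(list(tree = swapped, accepted = TRUE, move = move))
  reject()
}
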