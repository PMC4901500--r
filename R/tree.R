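#' Binary regression trees (reference implementation)
#'
#' A light list-based representation of the binary decision trees that the
#' sum-of-trees sampler manipulates: every node has zero or two children,
#' internal nodes carry a decision rule `(var, cut)` meaning "go left iff
#' `x[var] <= cut`", and leaves carry the real-valued parameter `mu`.  Node
#' ids are dense integers (root = 1) and are reassigned on structural
#' changes; structural equality is up to id relabeling.  These functions are
#' the module surface used by the tests and small-scale experiments; the
#' production sampler in [bart()] runs the same algorithms in compiled code.
#'
#' @param mu leaf parameter of the root.
#' @return `newTree()` returns a root-only tree.
#' @seealso [growTree()], [treeLogPrior()], [mhTreeUpdate()]
#' @export
newTree <- function(mu = NA_real_) {
  structure(list(nodes = list(list(id = 1L, parent = NA_integer_,
                                   left = NA_integer_, right = NA_integer_,
                                   depth = 0L, var = NA_integer_,
                                   cut = NA_real_, mu = mu)),
                 root = 1L),
            class = "bartTree")
}

treeNode <- function(tree, id) tree$nodes[[id]]

isLeafNode <- function(tree, id) is.na(tree$nodes[[id]]$left)

#' @rdname treeQueries
#' @export
treeLeaves <- function(tree) {
  which(vapply(tree$nodes, function(n) is.na(n$left), logical(1)))
}

#' @name treeQueries
#' @title Query a regression tree
#' @description `treeLeaves()`/`treeInternals()` list node ids by kind;
#'   `leafOf()` routes a predictor row to its leaf (left iff
#'   `x[var] <= cut`); `predictTree()` evaluates the tree fit for each row
#'   of a matrix; `nodeRowsOf()` returns the training rows routed to a node.
#' @param tree a tree from [newTree()] and the move functions.
#' @param x a numeric predictor row.
#' @param X numeric matrix of predictor rows.
#' @param id a node id.
#' @return Node ids, a leaf id, a numeric vector of fits, or row indices.
NULL

#' @rdname treeQueries
#' @export
treeInternals <- function(tree) {
  which(vapply(tree$nodes, function(n) !is.na(n$left), logical(1)))
}

#' @rdname treeQueries
#' @export
leafOf <- function(tree, x) {
  id <- tree$root
  while (!isLeafNode(tree, id)) {
    n <- treeNode(tree, id)
    id <- if (x[n$var] <= n$cut) n$left else n$right
  }
  id
}

#' @rdname treeQueries
#' @export
predictTree <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  mus <- vapply(tree$nodes, function(n) n$mu, numeric(1))
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    L <- leafOf(tree, X[i, ])
    if (is.na(mus[L])) stop("leaf ", L, " has no mu set")
    out[i] <- mus[L]
  }
  out
}

#' @rdname treeQueries
#' @export
nodeRowsOf <- function(tree, X, id) {
  rows <- integer(0)
  for (i in seq_len(nrow(X))) {
    u <- leafOf(tree, X[i, ])
    while (!is.na(u) && u != id) u <- treeNode(tree, u)$parent
    if (!is.na(u) && u == id) rows <- c(rows, i)
  }
  rows
}

#' Valid splitting rules at a node
#'
#' A variable is splittable when it takes at least two distinct values among
#' the rows reaching the node; its candidate cutpoints are the midpoints of
#' consecutive sorted unique observed values (for `{0,1,2}` dosages these
#' are the separating members of `{0.5, 1.5}`).
#'
#' @param X predictor matrix.
#' @param rows row indices reaching the node.
#' @return Named list, one numeric vector of candidate cutpoints per
#'   splittable variable (names are column indices).
#' @examples
#' X <- cbind(c(0, 1, 2, 2), c(1, 1, 1, 1))
#' validSplits(X, 1:4)   # only variable 1, cutpoints 0.5 and 1.5
#' @export
validSplits <- function(X, rows) {
  out <- list()
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[rows, j]))
    if (length(v) >= 2)
      out[[as.character(j)]] <- (v[-1] + v[-length(v)]) / 2
  }
  out
}

renumberTree <- function(tree) {
  ids <- vapply(tree$nodes, function(n) n$id, integer(1))
  old2new <- integer(max(ids))
  old2new[ids] <- seq_along(ids)
  remap <- function(i) if (is.na(i)) i else old2new[i]
  tree$nodes <- lapply(tree$nodes, function(n) {
    n$id <- remap(n$id); n$parent <- remap(n$parent)
    n$left <- remap(n$left); n$right <- remap(n$right)
    n
  })
  names(tree$nodes) <- NULL
  tree$root <- remap(tree$root)
  tree
}

#' Structural tree moves
#'
#' The four reversible structural alterations of the tree sampler.
#' `growTree()` splits a leaf with a rule; `pruneTree()` collapses an
#' internal node whose children are both leaves; `changeRule()` re-draws the
#' rule of an internal node; `swapRule()` exchanges the rules of an internal
#' parent-child pair.  All four are persistent (the input tree is never
#' modified) and return `NULL` as a rejection signal when the target is
#' invalid, so a sampler can count infeasible proposals.
#'
#' @param tree a tree.
#' @param leafId,internalId,parentId,childId target node ids.
#' @param var,cut the decision rule.
#' @return The altered tree (node ids re-densified), or `NULL`.
#' @examples
#' t1 <- growTree(newTree(), 1L, var = 1L, cut = 0.5)
#' treeLeaves(t1)
#' is.null(pruneTree(newTree(), 1L))  # root-only: invalid
#' @export
growTree <- function(tree, leafId, var, cut) {
  if (leafId > length(tree$nodes) || !isLeafNode(tree, leafId)) return(NULL)
  k <- length(tree$nodes)
  d <- treeNode(tree, leafId)$depth
  tree$nodes[[leafId]]$var <- as.integer(var)
  tree$nodes[[leafId]]$cut <- cut
  tree$nodes[[leafId]]$left <- k + 1L
  tree$nodes[[leafId]]$right <- k + 2L
  tree$nodes[[leafId]]$mu <- NA_real_
  for (s in 1:2) {
    tree$nodes[[k + s]] <- list(id = k + s, parent = leafId,
                                left = NA_integer_, right = NA_integer_,
                                depth = d + 1L, var = NA_integer_,
                                cut = NA_real_, mu = NA_real_)
  }
  tree
}

#' @rdname growTree
#' @export
pruneTree <- function(tree, internalId) {
  if (internalId > length(tree$nodes) || isLeafNode(tree, internalId))
    return(NULL)
  n <- treeNode(tree, internalId)
  if (!isLeafNode(tree, n$left) || !isLeafNode(tree, n$right)) return(NULL)
  tree$nodes[[internalId]]$left <- NA_integer_
  tree$nodes[[internalId]]$right <- NA_integer_
  tree$nodes[[internalId]]$var <- NA_integer_
  tree$nodes[[internalId]]$cut <- NA_real_
  tree$nodes <- tree$nodes[-c(n$left, n$right)]
  renumberTree(tree)
}

#' @rdname growTree
#' @export
changeRule <- function(tree, internalId, var, cut) {
  if (internalId > length(tree$nodes) || isLeafNode(tree, internalId))
    return(NULL)
  tree$nodes[[internalId]]$var <- as.integer(var)
  tree$nodes[[internalId]]$cut <- cut
  tree
}

#' @rdname growTree
#' @export
swapRule <- function(tree, parentId, childId) {
  if (parentId > length(tree$nodes) || childId > length(tree$nodes))
    return(NULL)
  pn <- treeNode(tree, parentId)
  cn <- treeNode(tree, childId)
  if (isLeafNode(tree, parentId) || isLeafNode(tree, childId)) return(NULL)
  if (!(childId %in% c(pn$left, pn$right))) return(NULL)
  tree$nodes[[parentId]]$var <- cn$var
  tree$nodes[[parentId]]$cut <- cn$cut
  tree$nodes[[childId]]$var <- pn$var
  tree$nodes[[childId]]$cut <- pn$cut
  tree
}

#' Serialize a tree to JSON and back
#'
#' Writes the node table (id, parent, children, depth, rule, leaf mean) for
#' posterior snapshots and debugging; `treeFromJson()` restores an
#' equivalent tree.
#'
#' @param tree a tree.
#' @param path file path (`.json`).
#' @return `treeToJson()` the path invisibly; `treeFromJson()` a tree.
#' @export
treeToJson <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(n) {
    out <- list(id = n$id, depth = n$depth)
    if (!is.na(n$parent)) out$parent <- n$parent
    if (!is.na(n$left)) {
      out$left <- n$left; out$right <- n$right
      out$rule <- list(var = n$var, cut = n$cut)
    } else if (!is.na(n$mu)) out$mu <- n$mu
    out
  })
  jsonlite::write_json(list(root = tree$root, nodes = nodes), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname treeToJson
#' @export
treeFromJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(n) {
    list(id = as.integer(n$id),
         parent = if (is.null(n$parent)) NA_integer_ else as.integer(n$parent),
         left = if (is.null(n$left)) NA_integer_ else as.integer(n$left),
         right = if (is.null(n$right)) NA_integer_ else as.integer(n$right),
         depth = as.integer(n$depth),
         var = if (is.null(n$rule)) NA_integer_ else as.integer(n$rule$var),
         cut = if (is.null(n$rule)) NA_real_ else as.numeric(n$rule$cut),
         mu = if (is.null(n$mu)) NA_real_ else as.numeric(n$mu))
  })
  structure(list(nodes = nodes, root = as.integer(obj$root)),
            class = "bartTree")
}

#' Log prior probability of a tree
#'
#' The tree-structure prior: a node at depth `d` is internal with probability
#' `alpha * (1 + d)^(-beta)` (the depth-penalizing form; with the defaults
#' `alpha = 0.95`, `beta = 2` deeper splits become rapidly unlikely), so the
#' log prior sums `log(p_split(d))` over internal nodes and
#' `log(1 - p_split(d))` over leaves.  When the training matrix `X` is
#' supplied, the log probability of each internal node's rule under the
#' uniform rule-assignment prior (uniform over splittable variables, then
#' uniform over that variable's candidate cutpoints, both conditional on the
#' rows reaching the node) is added.
#'
#' @param tree a tree.
#' @param alpha,beta prior parameters, `0 < alpha < 1`, `beta >= 0`.
#' @param X optional training predictor matrix for the rule-assignment part.
#' @return Log prior (structure only when `X` is missing).
#' @examples
#' treeLogPrior(newTree(), 0.95, 2)  # log(0.05)
#' @export
treeLogPrior <- function(tree, alpha = 0.95, beta = 2, X = NULL) {
  stopifnot(alpha > 0, alpha < 1, beta >= 0)
  lp <- 0
  for (n in tree$nodes) {
    ps <- alpha * (1 + n$depth)^(-beta)
    lp <- lp + if (is.na(n$left)) log(1 - ps) else log(ps)
  }
  if (!is.null(X)) {
    for (id in treeInternals(tree)) {
      rows <- nodeRowsOf(tree, X, id)
      vs <- validSplits(X, rows)
      n <- treeNode(tree, id)
      cuts <- vs[[as.character(n$var)]]
      if (is.null(cuts) || !length(cuts))
        return(-Inf)  # rule not expressible at this node's data
      lp <- lp - log(length(vs)) - log(length(cuts))
    }
  }
  lp
}
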