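## Neighbor-joining tree construction and bootstrap support.
##
## The agglomeration is implemented here (Saitou-Nei Q-criterion, ties
## broken by lexicographic pair order, negative branch-length estimates
## clamped to zero with the deficit moved to the sibling edge); `ape`
## provides the tree container, Newick serialization and an independent
## NJ implementation used for cross-checking in the test suite.

#' Neighbor-joining tree from a distance matrix
#'
#' @param d Symmetric non-negative distance matrix with dimnames (>= 3
#'   taxa), or a `dist` object.
#' @return An unrooted `ape::phylo` tree. On an additive matrix the tree's
#'   path-length matrix reproduces the input exactly.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix")
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (any(d < 0)) stop("distance matrix contains negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  quote_label <- function(x)
    ifelse(grepl("[^A-Za-z0-9_.]", x), paste0("'", x, "'"), x)
  # active nodes carry their newick subtree strings
  nwk <- setNames(as.list(quote_label(labels)), labels)
  D <- d
  dimnames(D) <- list(labels, labels)
  active <- labels
  while (length(active) > 3L) {
    m <- length(active)
    Ds <- D[active, active]
    r <- rowSums(Ds)
    Q <- (m - 2) * Ds - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pairs <- cbind(active[cand[, 1L]], active[cand[, 2L]])
    pairs <- t(apply(pairs, 1L, sort))
    o <- order(pairs[, 1L], pairs[, 2L])
    i <- pairs[o[1L], 1L]; j <- pairs[o[1L], 2L]
    dij <- D[i, j]
    bi <- dij / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + (0 - bi); bi <- 0 }
    if (bj < 0) { bi <- bi + (0 - bj); bj <- 0 }
    new <- paste0("(", nwk[[i]], ":", format(bi, digits = 15), ",",
                  nwk[[j]], ":", format(bj, digits = 15), ")")
    rest <- setdiff(active, c(i, j))
    dnew <- (D[i, rest] + D[j, rest] - dij) / 2
    dnew <- pmax(dnew, 0)
    key <- paste0("__n", n - length(active) + 1L)
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- key
    D[key, rest] <- D[rest, key] <- dnew
    nwk[[key]] <- new
    active <- c(rest, key)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  ba <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  bb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  bc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0)
  txt <- paste0("(", nwk[[a]], ":", format(ba, digits = 15), ",",
                nwk[[b]], ":", format(bb, digits = 15), ",",
                nwk[[c3]], ":", format(bc, digits = 15), ");")
  ape::read.tree(text = txt)
}

#' p-distance matrix from an alignment
#'
#' Proportion of differing columns, with pairwise gap deletion: columns
#' holding a gap in either row of a pair are skipped for that pair.
#'
#' @param aln An [alignment()].
#' @return Symmetric distance matrix; a pair with no comparable columns
#'   yields `NaN`.
#' @export
p_distance <- function(aln) {
  n <- length(aln$ids)
  chs <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    x <- chs[[i]]; y <- chs[[j]]
    ok <- x != "-" & y != "-"
    d[i, j] <- d[j, i] <- if (!any(ok)) NaN else sum(x[ok] != y[ok]) / sum(ok)
  }
  d
}

## canonical key of the bipartition induced by a clade's leaf set:
## the side not containing the lexicographically smallest taxon
split_key <- function(leafset, all_taxa) {
  ref <- min(all_taxa)
  side <- if (ref %in% leafset) setdiff(all_taxa, leafset) else leafset
  paste(sort(side), collapse = "|")
}

## all internal-edge bipartition keys of an unrooted phylo
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  all_taxa <- tree$tip.label
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 1L]), root)
  nodes <- tree$edge[, 2L][tree$edge[, 2L] > ntip]
  keys <- character(0)
  for (nd in nodes) {
    leaves <- tree$tip.label[leaf_descendants(tree, nd)]
    if (length(leaves) >= 2L && length(leaves) <= ntip - 2L)
      keys[as.character(nd)] <- split_key(leaves, all_taxa)
  }
  keys
}

leaf_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= ntip) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
  }
  out
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports for each internal edge of
#' the reference tree the percentage of replicates containing the same
#' bipartition. Supports are attached as `tree$node.label` (empty at the
#' root) and returned as a table.
#'
#' @param aln An [alignment()] (>= 4 taxa for meaningful supports).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; fixing it makes supports
#'   reproducible.
#' @return List with `tree` (reference NJ `phylo`, node labels = support
#'   percentages), `support` (named numeric vector keyed by bipartition)
#'   and `n_reps`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(p_distance(aln))
  keys <- tree_splits(ref)
  counts <- setNames(numeric(length(keys)), keys)
  chs <- do.call(rbind, lapply(aln$rows, function(r) strsplit(r, "")[[1]]))
  L <- ncol(chs)
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rows <- apply(chs[, idx, drop = FALSE], 1L, paste, collapse = "")
    bt <- try(nj_tree(p_distance(alignment(aln$ids, rows))), silent = TRUE)
    if (inherits(bt, "try-error")) next
    bk <- tree_splits(bt)
    hit <- keys %in% bk
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  ntip <- length(ref$tip.label)
  nnode <- ref$Nnode
  labs <- rep("", nnode)
  node_ids <- as.integer(names(keys))
  labs[node_ids - ntip] <- format(round(support, 1), trim = TRUE)
  ref$node.label <- labs
  list(tree = ref, support = setNames(unname(support), keys),
       n_reps = n_reps)
}

#' Clades supported above a bootstrap threshold
#'
#' @param bs A [bootstrap_support()] result (or a `phylo` with numeric
#'   node labels).
#' @param min_support Minimum support percentage (default 50).
#' @return List of character vectors, each the leaf set of a supported
#'   clade, ordered by decreasing size.
#' @export
clades_at <- function(bs, min_support = 50) {
  tree <- if (inherits(bs, "phylo")) bs else bs$tree
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  nodes <- which(!is.na(sup) & sup >= min_support) + ntip
  clades <- lapply(nodes, function(nd)
    sort(tree$tip.label[leaf_descendants(tree, nd)]))
  clades[order(-vapply(clades, length, integer(1)),
               vapply(clades, `[`, character(1), 1L))]
}
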