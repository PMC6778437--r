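# Gene-tree curation: midpoint rooting, paralogous-subfamily detection and
# in-paralogue filtering. Trees are ape::phylo objects; internal node labels
# carry bootstrap supports (percent).

# Undirected adjacency of a phylo tree. For each edge we keep the two incident
# nodes, the branch length, and the support label of the bipartition the edge
# induces (= the newick label of the edge's child endpoint, if internal).
.treeGraph <- function(tree) {
  n <- length(tree$tip.label)
  lab <- tree$node.label
  childLab <- function(v) {
    if (v <= n) return("")
    l <- if (is.null(lab)) "" else lab[v - n]
    if (is.na(l)) "" else l
  }
  edges <- data.frame(a = tree$edge[, 1], b = tree$edge[, 2],
                      len = tree$edge.length,
                      sup = vapply(tree$edge[, 2], childLab, character(1)),
                      stringsAsFactors = FALSE)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], i)
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], i)
  }
  list(edges = edges, adj = adj, ntip = n, labels = tree$tip.label)
}

# Recursively build a newick fragment for the subtree reached by crossing
# `edgeIdx` into `node`. Degree-2 pass-through nodes (e.g. the old root of a
# rooted input) are suppressed and their branch lengths summed; the surviving
# edge keeps the first support label encountered walking outward (all merged
# edges induce the same bipartition).
.newickFrom <- function(g, node, edgeIdx, len, sup) {
  nbr <- setdiff(g$adj[[node]], edgeIdx)
  if (node <= g$ntip) {
    return(sprintf("%s:%.12g", g$labels[node], len))
  }
  if (length(nbr) == 1L) {
    e <- g$edges[nbr, ]
    other <- if (e$a == node) e$b else e$a
    keep <- if (nzchar(sup)) sup else e$sup
    return(.newickFrom(g, other, nbr, len + e$len, keep))
  }
  parts <- vapply(nbr, function(i) {
    e <- g$edges[i, ]
    other <- if (e$a == node) e$b else e$a
    .newickFrom(g, other, i, e$len, e$sup)
  }, character(1))
  sprintf("(%s)%s:%.12g", paste(parts, collapse = ","), sup, len)
}

# Root a tree at a point along edge `edgeIdx`, at distance `dFromA` from
# endpoint `a` of that edge. The split edge's support label is attached to
# both root children (both represent the same bipartition).
.rootOnEdge <- function(g, edgeIdx, a, dFromA) {
  e <- g$edges[edgeIdx, ]
  b <- if (e$a == a) e$b else e$a
  dFromA <- max(0, min(dFromA, e$len))  # clamp float noise at edge ends
  fragA <- .newickFrom(g, a, edgeIdx, dFromA, e$sup)
  fragB <- .newickFrom(g, b, edgeIdx, e$len - dFromA, e$sup)
  ape::read.tree(text = sprintf("(%s,%s);", fragA, fragB))
}

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf (patristic)
#' path, so that the two maximal root-to-leaf depths are equal. Bootstrap
#' supports stay attached to the bipartitions they measure: the support of the
#' split edge is carried by both root children, and supports of all other
#' clades are preserved. Pairwise leaf distances are unchanged.
#'
#' Ties for the longest path are broken by the lexicographically smallest leaf
#' pair; a midpoint falling exactly on an internal node yields a zero-length
#' root edge.
#'
#' @param tree an \code{ape::phylo} tree (rooted or unrooted) with branch
#'   lengths and at least two leaves.
#' @return A rooted \code{phylo} tree.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1,C:4);")
#' midpointRoot(tr)
midpointRoot <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop("midpoint rooting needs at least 2 leaves")
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (all(tree$edge.length == 0)) stop("all branch lengths are zero: midpoint undefined")
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n), drop = FALSE]
  dm <- max(d)
  cand <- which(d == dm, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  lab <- tree$tip.label
  ord <- order(pmin(lab[cand[, 1]], lab[cand[, 2]]),
               pmax(lab[cand[, 1]], lab[cand[, 2]]))
  i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
  path <- ape::nodepath(tree, i, j)
  g <- .treeGraph(tree)
  # cumulative distance from leaf i along the path
  cum <- 0
  target <- dm / 2
  for (k in seq_len(length(path) - 1L)) {
    eIdx <- which((g$edges$a == path[k] & g$edges$b == path[k + 1L]) |
                  (g$edges$b == path[k] & g$edges$a == path[k + 1L]))[1]
    len <- g$edges$len[eIdx]
    if (cum + len >= target - 1e-12) {
      out <- .rootOnEdge(g, eIdx, path[k], target - cum)
      return(out)
    }
    cum <- cum + len
  }
  stop("internal error: midpoint not located on the longest path")
}

.tipsUnderNode <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tipsUnderNode, tree = tree))
}

#' Find paralogous subfamilies in a rooted gene tree
#'
#' A paralogous subfamily marks a gene-duplication node: an internal node
#' whose two child clades each contain at least two distinct species codes
#' and share at least one species code. Nodes with more than two children
#' (unresolved polytomies) are not evaluated.
#'
#' @param tree a rooted \code{ape::phylo} tree; species codes are extracted
#'   from leaf names with [leafSpeciesCodes()].
#' @return A list of \linkS4class{ParalogSubfamily} objects (possibly empty).
#' @export
findParalogSubfamilies <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("findParalogSubfamilies() requires a rooted tree")
  n <- length(tree$tip.label)
  codes <- leafSpeciesCodes(tree$tip.label)
  out <- list()
  for (node in (n + 1L):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) != 2L) next
    left <- unique(codes[.tipsUnderNode(tree, kids[1])])
    right <- unique(codes[.tipsUnderNode(tree, kids[2])])
    if (length(left) < 2L || length(right) < 2L) next
    shared <- intersect(left, right)
    if (!length(shared)) next
    out[[length(out) + 1L]] <- new("ParalogSubfamily", node = as.integer(node),
                                   left = sort(left), right = sort(right),
                                   shared = sort(shared))
  }
  out
}

#' Filter in-paralogues from a rooted gene tree
#'
#' Within each paralogous subfamily (see [findParalogSubfamilies()]), a
#' non-query species represented by several leaves is restricted to the single
#' leaf closest to the query: the leaf with the smallest patristic distance to
#' the nearest query leaf is kept, ties broken by lexicographic leaf name.
#' Query-species leaves (in-paralogues of the query proteome) are always kept,
#' as are same-species duplicates that fall outside any paralogous subfamily.
#' Degree-2 nodes created by pruning are suppressed with branch lengths summed.
#'
#' @param tree a rooted \code{ape::phylo} tree containing at least one leaf of
#'   the query species.
#' @param queryCode species code marking query-proteome leaves (default "DCMF").
#' @return The pruned \code{phylo} tree (the input when nothing is pruned).
#' @export
filterInparalogs <- function(tree, queryCode = "DCMF") {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("filterInparalogs() requires a rooted tree")
  codes <- leafSpeciesCodes(tree$tip.label)
  qtips <- tree$tip.label[codes == queryCode]
  if (!length(qtips))
    stop(sprintf("no leaf with query code '%s' in tree", queryCode))
  subfams <- findParalogSubfamilies(tree)
  if (!length(subfams)) return(tree)
  d <- ape::cophenetic.phylo(tree)
  distToQuery <- apply(d[, qtips, drop = FALSE], 1, min)
  drop <- character(0)
  for (sf in subfams) {
    tipIdx <- .tipsUnderNode(tree, sf@node)
    tl <- tree$tip.label[tipIdx]
    cd <- codes[tipIdx]
    for (sp in unique(cd[cd != queryCode])) {
      members <- tl[cd == sp]
      if (length(members) > 1L) {
        keep <- members[order(distToQuery[members], members)][1]
        drop <- union(drop, setdiff(members, keep))
      }
    }
  }
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}
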