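# Independent oracles used to cross-check the implementation.

# Brute-force clade assignment: enumerate every internal node of the rooted
# tree, keep those whose clade contains the query leaf, at least one
# non-query leaf, and a support at or above the threshold, and return the
# smallest such clade (clades containing the query are nested, so the
# smallest is unique). Implemented over ape::extract.clade, independently of
# the package's ancestral walk.
oracleAssign <- function(tree, queryLeaf, threshold = 50, queryCode = "DCMF") {
  n <- length(tree$tip.label)
  codes <- sub(".*_", "", tree$tip.label)
  nonqueryTips <- tree$tip.label[codes != queryCode]
  if (!length(nonqueryTips))
    return(list(none = TRUE, fallback = FALSE, species = character(0),
                support = NA_real_))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  best <- NULL
  for (nd in (n + 1L):(n + tree$Nnode)) {
    tips <- if (nd == n + 1L) tree$tip.label
            else ape::extract.clade(tree, nd)$tip.label
    if (!(queryLeaf %in% tips)) next
    nq <- intersect(tips, nonqueryTips)
    s <- sup[nd - n]
    if (!length(nq) || is.na(s) || s < threshold) next
    if (is.null(best) || length(tips) < best$size)
      best <- list(size = length(tips),
                   species = sort(unique(sub(".*_", "", nq))), support = s)
  }
  if (is.null(best))
    return(list(none = FALSE, fallback = TRUE,
                species = sort(unique(sub(".*_", "", nonqueryTips))),
                support = NA_real_))
  list(none = FALSE, fallback = FALSE, species = best$species,
       support = best$support)
}

# Brute-force paralogous-subfamily detection via ape::extract.clade on each
# child of each bifurcating internal node.
oracleParalogNodes <- function(tree) {
  n <- length(tree$tip.label)
  codes <- sub(".*_", "", tree$tip.label)
  names(codes) <- tree$tip.label
  hits <- integer(0)
  for (nd in (n + 1L):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(kids) != 2L) next
    sets <- lapply(kids, function(k) {
      tips <- if (k <= n) tree$tip.label[k]
              else ape::extract.clade(tree, k)$tip.label
      unique(unname(codes[tips]))
    })
    if (length(sets[[1]]) >= 2 && length(sets[[2]]) >= 2 &&
        length(intersect(sets[[1]], sets[[2]])) >= 1)
      hits <- c(hits, nd)
  }
  hits
}

# Gotoh affine-gap global alignment score (gap of length L costs
# open + L * ext), written directly from the recurrences.
gotohScore <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) Ix[i, 1] <- -open - ext * (i - 1)
  if (m >= 1) for (j in 2:(m + 1)) Iy[1, j] <- -open - ext * (j - 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                      Iy[i - 1, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                      Ix[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# depths of the two root subtrees (max root-to-leaf path length each side)
rootSubtreeDepths <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  kids <- tree$edge[tree$edge[, 1] == n + 1L, 2]
  tipsOf <- function(k) {
    if (k <= n) return(k)
    which(tree$tip.label %in% ape::extract.clade(tree, k)$tip.label)
  }
  vapply(kids, function(k) max(depth[tipsOf(k)]), numeric(1))
}
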