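# TaxaMap clade assignment: walk ancestrally from the query leaf to the
# smallest bootstrap-supported clade containing a non-query homologue, then
# map the clade's species codes onto six taxonomic ranks.

.parentOf <- function(tree, node) {
  hit <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(hit)) NA_integer_ else hit[1]
}

#' Assign a query protein to the smallest supported clade
#'
#' Starting at the query leaf's parent, the walk ascends the rooted tree until
#' it reaches the first node whose clade has a bootstrap support of at least
#' \code{supportThreshold} percent (inclusive) and contains at least one
#' non-query leaf; the clade's non-query species codes and support are
#' returned. Nodes without a support value fail the support condition. If the
#' root is reached without satisfying both conditions, all non-query species
#' codes of the tree are returned with the root-fallback flag set. A tree with
#' no non-query leaves at all yields a "None" assignment.
#'
#' @param tree a rooted \code{ape::phylo} tree.
#' @param queryLeaf name of the query leaf to walk from.
#' @param supportThreshold minimum clade support in percent (default 50,
#'   inclusive).
#' @param queryCode species code marking query leaves (default "DCMF"); other
#'   query-code leaves never count as homologues.
#' @param protein identifier recorded on the assignment (defaults to
#'   \code{queryLeaf}).
#' @return A \linkS4class{CladeAssignment}.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((Q1_DCMF:0.1,g1_SPEC1:0.1)90:0.2,g2_SPEC2:0.4);")
#' assignClade(tr, "Q1_DCMF")
assignClade <- function(tree, queryLeaf, supportThreshold = 50,
                        queryCode = "DCMF", protein = queryLeaf) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("assignClade() requires a rooted tree")
  if (supportThreshold < 0 || supportThreshold > 100)
    stop("supportThreshold must lie in [0, 100]")
  tips <- tree$tip.label
  qi <- match(queryLeaf, tips)
  if (is.na(qi)) stop(sprintf("query leaf '%s' not found in tree", queryLeaf))
  n <- length(tips)
  codes <- leafSpeciesCodes(tips)
  nonquery <- which(codes != queryCode)
  if (!length(nonquery))
    return(CladeAssignment(protein, character(0), NA_real_,
                           rootFallback = FALSE, noneFlag = TRUE,
                           threshold = supportThreshold))
  sup <- nodeSupports(tree)
  root <- n + 1L
  node <- .parentOf(tree, qi)
  repeat {
    tipsHere <- .tipsUnderNode(tree, node)
    nq <- intersect(tipsHere, nonquery)
    s <- sup[node - n]
    if (length(nq) && !is.na(s) && s >= supportThreshold)
      return(CladeAssignment(protein, sort(unique(codes[nq])), s,
                             rootFallback = FALSE, noneFlag = FALSE,
                             threshold = supportThreshold))
    if (node == root)
      return(CladeAssignment(protein, sort(unique(codes[nonquery])), NA_real_,
                             rootFallback = TRUE, noneFlag = FALSE,
                             threshold = supportThreshold))
    node <- .parentOf(tree, node)
  }
}

# Label for a species code unresolved at rank index ri: the name at the lowest
# known more-inclusive rank plus the missing rank's abbreviation, e.g.
# "Firmicutes fam." for a code known only to phylum level.
.unknownLabel <- function(entry, ri) {
  rks <- taxRanks()
  for (j in seq(ri + 1L, length(rks))) {
    nm <- entry[[rks[j]]]
    if (!is.na(nm)) return(paste(nm, .RANK_ABBREV[[rks[ri]]]))
  }
  "Unclassified"
}

#' Map a clade assignment onto six taxonomic ranks
#'
#' Each assigned species code contributes its taxon name at every rank from
#' species to phylum. A code lacking a name at a rank contributes an
#' unknown-taxon label built from its lowest known higher rank (e.g.
#' \code{"Firmicutes fam."} for an unknown family within Firmicutes). The
#' per-rank taxa lists are de-duplicated so each taxon contributes equally
#' downstream. Species codes absent from the taxonomy table are recorded in
#' the \code{unmapped} slot, reported via a warning, and contribute the
#' reserved label \code{"Unmapped"} at every rank. "None" assignments map to
#' the reserved taxon \code{"None"} at every rank.
#'
#' @param assignment a \linkS4class{CladeAssignment}.
#' @param taxonomy a \linkS4class{TaxonomyTable}.
#' @return A \linkS4class{RankAssignment}.
#' @export
mapToRanks <- function(assignment, taxonomy) {
  stopifnot(is(assignment, "CladeAssignment"), is(taxonomy, "TaxonomyTable"))
  rks <- taxRanks()
  if (assignment@noneFlag) {
    taxa <- stats::setNames(rep(list("None"), length(rks)), rks)
    return(new("RankAssignment", protein = assignment@protein, taxa = taxa,
               unmapped = character(0)))
  }
  codes <- assignment@species
  known <- codes %in% speciesCodes(taxonomy)
  unmapped <- codes[!known]
  if (length(unmapped))
    warning(sprintf("protein '%s': species code(s) not in taxonomy: %s",
                    assignment@protein, paste(unmapped, collapse = ", ")))
  df <- taxonomy@data
  rows <- df[match(codes[known], df$species_code), , drop = FALSE]
  taxa <- stats::setNames(vector("list", length(rks)), rks)
  for (ri in seq_along(rks)) {
    vals <- character(0)
    if (nrow(rows)) {
      vals <- vapply(seq_len(nrow(rows)), function(k) {
        nm <- rows[[rks[ri]]][k]
        if (!is.na(nm)) nm
        else if (ri == length(rks)) "Unclassified"
        else .unknownLabel(rows[k, ], ri)
      }, character(1))
    }
    if (length(unmapped)) vals <- c(vals, "Unmapped")
    taxa[[ri]] <- sort(unique(vals))
  }
  new("RankAssignment", protein = assignment@protein, taxa = taxa,
      unmapped = unmapped)
}
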