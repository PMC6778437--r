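# Combination of per-protein rank assignments into proteome-level profiles:
# equal-split (unweighted) and bootstrap-weighted scoring with iterative
# exclusion of taxa scoring below a threshold.

#' Equal-split shares of one protein over its assigned taxa
#'
#' A protein ambiguously assigned to k taxa gives each taxon 1/k, so that
#' every protein contributes exactly one unit of mass: a protein mapped to
#' five taxa gives each 0.2.
#'
#' @param taxa character vector of taxon names (de-duplicated internally).
#' @return Named numeric vector of shares summing to 1.
#' @export
#' @examples
#' unweightedShares(c("Peptococcaceae", "Clostridiaceae"))
unweightedShares <- function(taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("empty taxon set: use 'None' for none assignments")
  stats::setNames(rep(1 / length(taxa), length(taxa)), taxa)
}

#' Bootstrap-weighted shares of one protein over its assigned taxa
#'
#' The equal-split shares are multiplied by the clade's bootstrap support as a
#' fraction: with two taxa and 80% support each receives 0.4 (= 0.5 x 0.8).
#' Root-fallback assignments carry no clade support and use weight 1.0.
#'
#' @param taxa character vector of taxon names.
#' @param support clade bootstrap support in percent (0-100); ignored when
#'   \code{fallback} is TRUE.
#' @param fallback TRUE for root-fallback (or "None") assignments: weight 1.0.
#' @return Named numeric vector of shares summing to \code{support / 100}
#'   (or to 1 for fallback).
#' @export
#' @examples
#' weightedShares(c("Peptococcaceae", "Clostridiaceae"), support = 80)
weightedShares <- function(taxa, support, fallback = FALSE) {
  u <- unweightedShares(taxa)
  if (fallback) return(u)
  if (is.na(support) || support < 0 || support > 100)
    stop("support must lie in [0, 100] (or set fallback = TRUE)")
  u * (support / 100)
}

.scoreSets <- function(sets, weights = NULL) {
  k <- lengths(sets)
  w <- if (is.null(weights)) rep(1, length(sets)) else weights
  contrib <- rep(w / k, k)
  tapply(contrib, unlist(sets), sum)
}

#' Iterative exclusion of low-scoring taxa
#'
#' Given per-protein taxon sets, repeatedly removes every taxon whose combined
#' equal-split score across proteins falls below \code{threshold}, re-splitting
#' each affected protein's unit mass equally among its remaining taxa, until
#' no retained taxon is below threshold. A protein that loses all its taxa is
#' reassigned to the reserved taxon \code{"None"} so total mass is conserved.
#' Reserved pseudo-taxa ("None", "Unmapped", "Unclassified") are never
#' excluded. The iteration terminates in at most one round per distinct taxon.
#'
#' @param sets list of character vectors: each protein's taxa at one rank.
#' @param threshold exclusion threshold on the combined unweighted score
#'   (default 1.0).
#' @param maxRounds optional cap on exclusion rounds (default unlimited);
#'   mainly for inspecting intermediate states.
#' @return List with \code{sets} (the stable per-protein taxon sets),
#'   \code{excluded} (taxa removed) and \code{rounds} (iterations used).
#' @export
iterateExclusion <- function(sets, threshold = 1, maxRounds = Inf) {
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    if (!length(s)) "None" else s
  })
  excluded <- character(0)
  rounds <- 0L
  repeat {
    if (rounds >= maxRounds) break
    sc <- .scoreSets(sets)
    bad <- names(sc)[sc < threshold - 1e-12]
    bad <- setdiff(bad, .RESERVED_TAXA)
    if (!length(bad)) break
    rounds <- rounds + 1L
    excluded <- c(excluded, bad)
    sets <- lapply(sets, function(s) {
      s <- setdiff(s, bad)
      if (!length(s)) "None" else s
    })
  }
  list(sets = sets, excluded = sort(excluded), rounds = rounds)
}

#' Combine per-protein taxon sets into a rank profile
#'
#' Sums equal-split shares per taxon across proteins, applies the iterative
#' exclusion of [iterateExclusion()] (default), then computes bootstrap-
#' weighted scores over the surviving taxon sets. With
#' \code{resplit = FALSE}, sub-threshold taxa are instead dropped from the
#' report without redistributing their proteins' mass (shares keep their
#' original denominators), and percentages are renormalised over the
#' surviving mass.
#'
#' @param taxonSets list of character vectors: each protein's taxa at this
#'   rank (an empty set or \code{"None"} marks a none assignment).
#' @param weights per-protein weights in [0, 1]: clade support / 100, or 1.0
#'   for root-fallback and none assignments. Default all 1.
#' @param exclusionThreshold minimum combined unweighted score a taxon needs
#'   to be retained (default 1.0).
#' @param resplit redistribute excluded proteins' mass among their remaining
#'   taxa (default TRUE).
#' @param rank rank name recorded on the profile.
#' @return A \linkS4class{RankProfile}.
#' @export
combineRank <- function(taxonSets, weights = NULL, exclusionThreshold = 1,
                        resplit = TRUE, rank = NA_character_) {
  n <- length(taxonSets)
  if (n < 1L) stop("at least one assignment is required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must match the number of proteins")
  if (any(is.na(weights) | weights < 0 | weights > 1))
    stop("weights must lie in [0, 1]")
  taxonSets <- lapply(taxonSets, function(s) {
    s <- unique(as.character(s))
    if (!length(s)) "None" else s
  })
  if (resplit) {
    fx <- iterateExclusion(taxonSets, exclusionThreshold)
    sets <- fx$sets
    unweighted <- .scoreSets(sets)
    weighted <- .scoreSets(sets, weights)
    weighted <- weighted[names(unweighted)]
  } else {
    k0 <- lengths(taxonSets)
    active <- sort(unique(unlist(taxonSets)))
    repeat {
      sc <- vapply(active, function(t)
        sum((1 / k0)[vapply(taxonSets, function(s) t %in% s, logical(1))]),
        numeric(1))
      bad <- setdiff(active[sc < exclusionThreshold - 1e-12], .RESERVED_TAXA)
      if (!length(bad)) break
      active <- setdiff(active, bad)
    }
    sets <- lapply(taxonSets, function(s) intersect(s, active))
    dead <- !vapply(sets, length, integer(1))
    # fully excluded proteins keep their unit mass under "None"
    unw <- c(unlist(mapply(function(s, k) rep(1 / k, length(s)), sets, k0,
                           SIMPLIFY = FALSE)),
             rep(1, sum(dead)))
    wgt <- c(unlist(mapply(function(s, k, w) rep(w / k, length(s)), sets, k0,
                           weights, SIMPLIFY = FALSE)),
             weights[dead])
    labs <- c(unlist(sets), rep("None", sum(dead)))
    unweighted <- tapply(unw, labs, sum)
    weighted <- tapply(wgt, labs, sum)[names(unweighted)]
  }
  taxa <- names(unweighted)
  unweighted <- as.numeric(unweighted)
  weighted <- as.numeric(weighted)
  pw <- if (sum(weighted) > 0) weighted / sum(weighted) * 100 else weighted
  pu <- if (sum(unweighted) > 0) unweighted / sum(unweighted) * 100 else unweighted
  new("RankProfile", rank = rank, taxa = taxa, unweighted = unweighted,
      weighted = weighted, percentWeighted = pw, percentUnweighted = pu,
      nProteins = as.integer(n))
}

#' Combine clade assignments into profiles at all six ranks
#'
#' Convenience wrapper: takes matched lists of \linkS4class{CladeAssignment}
#' and \linkS4class{RankAssignment} objects and produces one
#' \linkS4class{RankProfile} per rank. Per-protein weights are clade support
#' divided by 100, or 1.0 for root-fallback and none assignments.
#'
#' @param assignments list of \linkS4class{CladeAssignment}.
#' @param rankAssignments matched list of \linkS4class{RankAssignment}.
#' @param exclusionThreshold passed to [combineRank()] (default 1.0).
#' @param resplit passed to [combineRank()] (default TRUE).
#' @return Named list of six \linkS4class{RankProfile} objects.
#' @export
combineAssignments <- function(assignments, rankAssignments,
                               exclusionThreshold = 1, resplit = TRUE) {
  stopifnot(length(assignments) == length(rankAssignments),
            length(assignments) >= 1L)
  weights <- vapply(assignments, function(a) {
    if (a@rootFallback || a@noneFlag || is.na(a@support)) 1 else a@support / 100
  }, numeric(1))
  out <- lapply(taxRanks(), function(r) {
    sets <- lapply(rankAssignments, function(ra) ra@taxa[[r]])
    combineRank(sets, weights, exclusionThreshold, resplit, rank = r)
  })
  stats::setNames(out, taxRanks())
}
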