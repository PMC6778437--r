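#' @import methods
NULL

#' Taxonomic ranks used throughout the package
#'
#' Returns the six ranks handled by the pipeline, ordered from least inclusive
#' (species) to most inclusive (phylum).
#'
#' @return Character vector of rank names.
#' @export
#' @examples
#' taxRanks()
taxRanks <- function() {
  c("species", "genus", "family", "order", "class", "phylum")
}

# Abbreviations used for unknown-taxon labels, e.g. "Firmicutes fam." marks an
# unknown family inside the phylum Firmicutes. Phylum has no abbreviation: if
# any rank of an entry is known its phylum is known too (rank-ladder invariant).
.RANK_ABBREV <- c(species = "sp.", genus = "gen.", family = "fam.",
                  order = "ord.", class = "cl.")

# Reserved pseudo-taxa: "None" for proteins without non-query homologues,
# "Unmapped" for species codes absent from the taxonomy table, "Unclassified"
# for codes whose taxonomy entry is entirely empty.
.RESERVED_TAXA <- c("None", "Unmapped", "Unclassified")

#' TaxonomyTable: species codes mapped to six taxonomic ranks
#'
#' Holds one row per species mnemonic code (UniProt style, e.g. \code{"DESAJ"})
#' with names at the six ranks species, genus, family, order, class, phylum.
#' Ranks may be missing (\code{NA}), but only from the specific end upward: if
#' a rank is present, every more inclusive rank up to phylum must be present
#' too (the "rank ladder" invariant).
#'
#' @slot data data.frame with columns \code{species_code} plus the six ranks,
#'   all character; missing ranks are \code{NA}.
#' @export
setClass("TaxonomyTable", representation(data = "data.frame"))

setValidity("TaxonomyTable", function(object) {
  df <- object@data
  wanted <- c("species_code", taxRanks())
  if (!identical(colnames(df), wanted))
    return(sprintf("columns must be exactly: %s", paste(wanted, collapse = ", ")))
  if (!all(vapply(df, is.character, logical(1))))
    return("all columns must be character")
  codes <- df$species_code
  if (any(is.na(codes) | !nzchar(codes)))
    return("species_code entries must be nonempty")
  if (anyDuplicated(codes))
    return(sprintf("duplicated species_code: %s",
                   paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  # rank ladder: scanning species -> phylum, once a rank is present every
  # later (more inclusive) rank must be present as well
  rk <- as.matrix(df[, taxRanks(), drop = FALSE])
  present <- !is.na(rk) & nzchar(rk)
  for (i in seq_len(nrow(rk))) {
    p <- present[i, ]
    if (any(p) && any(!p[seq(which(p)[1], length(p))]))
      return(sprintf("entry '%s': rank present below an absent higher rank", codes[i]))
  }
  TRUE
})

#' Construct a TaxonomyTable
#'
#' @param data data.frame with columns \code{species_code}, \code{species},
#'   \code{genus}, \code{family}, \code{order}, \code{class}, \code{phylum}.
#'   Empty strings are converted to \code{NA} (absent rank).
#' @return A \linkS4class{TaxonomyTable}.
#' @export
TaxonomyTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (j in seq_along(data)) {
    data[[j]] <- as.character(data[[j]])
    data[[j]][!is.na(data[[j]]) & !nzchar(data[[j]])] <- NA_character_
  }
  rownames(data) <- NULL
  new("TaxonomyTable", data = data)
}

#' CladeAssignment: result of the ancestral clade walk for one protein
#'
#' @slot protein identifier of the query protein (its tree or leaf name).
#' @slot species species codes of the non-query leaves of the qualifying
#'   clade (empty when \code{noneFlag}).
#' @slot support bootstrap support (percent) of the qualifying clade;
#'   \code{NA} for root fallback or none assignments.
#' @slot rootFallback TRUE when no clade on the ancestral path qualified and
#'   the full tree was used.
#' @slot noneFlag TRUE when the tree contains no non-query leaves at all.
#' @slot threshold the support threshold (percent) the walk used.
#' @export
setClass("CladeAssignment", representation(
  protein = "character", species = "character", support = "numeric",
  rootFallback = "logical", noneFlag = "logical", threshold = "numeric"))

setValidity("CladeAssignment", function(object) {
  if (length(object@protein) != 1L || !nzchar(object@protein))
    return("protein must be a single nonempty string")
  if (length(object@support) != 1L || length(object@rootFallback) != 1L ||
      length(object@noneFlag) != 1L || length(object@threshold) != 1L)
    return("support, rootFallback, noneFlag, threshold must be scalars")
  if (object@noneFlag && length(object@species))
    return("noneFlag assignments must carry an empty species set")
  if (!object@noneFlag && !object@rootFallback && !length(object@species))
    return("non-none, non-fallback assignments must carry species codes")
  if (!is.na(object@support) && (object@support < 0 || object@support > 100))
    return("support must lie in [0, 100]")
  if (!is.na(object@support) && !object@rootFallback && !object@noneFlag &&
      object@support < object@threshold)
    return("qualifying clade support below the walk threshold")
  if (anyDuplicated(object@species))
    return("species codes must be unique")
  TRUE
})

CladeAssignment <- function(protein, species, support, rootFallback = FALSE,
                            noneFlag = FALSE, threshold = 50) {
  new("CladeAssignment", protein = protein,
      species = as.character(species), support = as.numeric(support),
      rootFallback = rootFallback, noneFlag = noneFlag,
      threshold = as.numeric(threshold))
}

#' RankAssignment: a clade assignment mapped onto the six taxonomic ranks
#'
#' @slot protein query protein identifier.
#' @slot taxa named list (species ... phylum) of de-duplicated taxon-name sets;
#'   unresolved entries use labels such as \code{"Firmicutes fam."}.
#' @slot unmapped species codes that were absent from the taxonomy table.
#' @export
setClass("RankAssignment", representation(
  protein = "character", taxa = "list", unmapped = "character"))

setValidity("RankAssignment", function(object) {
  if (!identical(names(object@taxa), taxRanks()))
    return("taxa must be a list named by the six ranks")
  if (!all(vapply(object@taxa, is.character, logical(1))))
    return("each rank entry must be a character vector")
  if (any(vapply(object@taxa, function(x) length(x) == 0L, logical(1))))
    return("each rank set must be nonempty (use 'None' for none assignments)")
  if (any(vapply(object@taxa, anyDuplicated, integer(1)) > 0L))
    return("rank sets must be de-duplicated")
  TRUE
})

#' RankProfile: combined proteome-level profile at one taxonomic rank
#'
#' @slot rank the taxonomic rank profiled.
#' @slot taxa taxon names (including reserved pseudo-taxa such as "None").
#' @slot unweighted combined equal-split scores (sum to the number of
#'   contributing proteins under the default re-split exclusion).
#' @slot weighted bootstrap-weighted scores.
#' @slot percentWeighted weighted scores normalised to 100.
#' @slot percentUnweighted unweighted scores as percent of proteins.
#' @slot nProteins number of proteins that contributed.
#' @export
setClass("RankProfile", representation(
  rank = "character", taxa = "character", unweighted = "numeric",
  weighted = "numeric", percentWeighted = "numeric",
  percentUnweighted = "numeric", nProteins = "integer"))

setValidity("RankProfile", function(object) {
  n <- length(object@taxa)
  if (length(object@unweighted) != n || length(object@weighted) != n ||
      length(object@percentWeighted) != n || length(object@percentUnweighted) != n)
    return("score vectors must match the number of taxa")
  if (anyDuplicated(object@taxa)) return("taxa must be unique")
  if (n > 0 && (any(object@unweighted < -1e-9) || any(object@weighted < -1e-9)))
    return("scores must be non-negative")
  if (n > 0 && abs(sum(object@percentWeighted) - 100) > 1e-6)
    return("weighted percentages must sum to 100")
  TRUE
})

#' IdentityMatrix: all-by-all global percent identities
#'
#' Pairwise identity is defined as identical aligned positions divided by the
#' length of the shorter sequence, times 100, from an optimal global alignment.
#'
#' @slot percent symmetric numeric matrix with 100 on the diagonal.
#' @export
setClass("IdentityMatrix", representation(percent = "matrix"))

setValidity("IdentityMatrix", function(object) {
  m <- object@percent
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must carry identical row and column names")
  if (any(m < -1e-9 | m > 100 + 1e-9)) return("identities must lie in [0, 100]")
  if (max(abs(m - t(m))) > 1e-6) return("matrix must be symmetric")
  if (nrow(m) > 0 && max(abs(diag(m) - 100)) > 1e-6)
    return("diagonal must be 100")
  TRUE
})

#' ParalogSubfamily: a gene-duplication node in a rooted gene tree
#'
#' A node qualifies when its two child clades each contain at least two
#' distinct species codes and share at least one species code.
#'
#' @slot node internal node number (ape convention).
#' @slot left species codes of the first child clade.
#' @slot right species codes of the second child clade.
#' @slot shared species codes occurring in both child clades.
#' @export
setClass("ParalogSubfamily", representation(
  node = "integer", left = "character", right = "character",
  shared = "character"))

setValidity("ParalogSubfamily", function(object) {
  if (length(unique(object@left)) < 2L || length(unique(object@right)) < 2L)
    return("each child clade must contain at least two distinct species")
  if (!length(object@shared))
    return("child clades must share at least one species")
  if (!setequal(object@shared, intersect(object@left, object@right)))
    return("shared set must equal the intersection of the child clades")
  TRUE
})
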