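#' Species codes stored in an object
#'
#' @param x a \linkS4class{TaxonomyTable}.
#' @return Character vector of species mnemonic codes.
#' @export
setGeneric("speciesCodes", function(x) standardGeneric("speciesCodes"))

#' Tabular view of a profile or matrix object
#'
#' @param x a \linkS4class{RankProfile}.
#' @param ... unused.
#' @return A data.frame, rows ordered by decreasing weighted score.
#' @export
setGeneric("profileTable", function(x, ...) standardGeneric("profileTable"))

#' Pairwise identity values
#'
#' @param x an \linkS4class{IdentityMatrix}.
#' @return Numeric matrix of percent identities.
#' @export
setGeneric("identities", function(x) standardGeneric("identities"))

#' @describeIn TaxonomyTable species codes of the table
#' @param x a TaxonomyTable
#' @export
setMethod("speciesCodes", "TaxonomyTable", function(x) x@data$species_code)

#' @describeIn IdentityMatrix the percent identity matrix
#' @param x an IdentityMatrix
#' @export
setMethod("identities", "IdentityMatrix", function(x) x@percent)

#' @describeIn RankProfile data.frame of taxa and scores, ordered by
#'   decreasing weighted score then taxon name
#' @param x a RankProfile
#' @param ... unused
#' @export
setMethod("profileTable", "RankProfile", function(x, ...) {
  df <- data.frame(taxon = x@taxa,
                   unweighted = x@unweighted,
                   weighted = x@weighted,
                   percent_weighted = x@percentWeighted,
                   percent_unweighted = x@percentUnweighted,
                   stringsAsFactors = FALSE)
  df[order(-df$weighted, df$taxon), , drop = FALSE]
})

setMethod("show", "TaxonomyTable", function(object) {
  df <- object@data
  cat(sprintf("TaxonomyTable with %d species codes\n", nrow(df)))
  for (r in rev(taxRanks())) {
    v <- df[[r]]
    cat(sprintf("  %-8s %d named, %d absent\n", r,
                sum(!is.na(v)), sum(is.na(v))))
  }
  invisible(object)
})

setMethod("show", "CladeAssignment", function(object) {
  cat(sprintf("CladeAssignment for '%s'\n", object@protein))
  if (object@noneFlag) {
    cat("  no non-query homologue in tree (None)\n")
  } else if (object@rootFallback) {
    cat(sprintf("  root fallback: full tree used (%d species)\n",
                length(object@species)))
  } else {
    cat(sprintf("  clade support %.1f%% (threshold %.1f%%), %d species: %s\n",
                object@support, object@threshold, length(object@species),
                paste(object@species, collapse = ", ")))
  }
  invisible(object)
})

setMethod("show", "RankAssignment", function(object) {
  cat(sprintf("RankAssignment for '%s'\n", object@protein))
  for (r in taxRanks())
    cat(sprintf("  %-8s %s\n", r, paste(object@taxa[[r]], collapse = "; ")))
  if (length(object@unmapped))
    cat("  unmapped codes:", paste(object@unmapped, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "RankProfile", function(object) {
  cat(sprintf("RankProfile at rank '%s' (%d proteins, %d taxa)\n",
              object@rank, object@nProteins, length(object@taxa)))
  df <- profileTable(object)
  top <- utils::head(df, 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-30s weighted %8.3f  (%.1f%%)\n",
                top$taxon[i], top$weighted[i], top$percent_weighted[i]))
  if (nrow(df) > 5L) cat(sprintf("  ... and %d more taxa\n", nrow(df) - 5L))
  invisible(object)
})

setMethod("show", "IdentityMatrix", function(object) {
  m <- object@percent
  cat(sprintf("IdentityMatrix over %d sequences", nrow(m)))
  if (nrow(m) > 1) {
    off <- m[upper.tri(m)]
    cat(sprintf("; off-diagonal identity %.2f-%.2f%% (mean %.2f%%)",
                min(off), max(off), mean(off)))
  }
  cat("\n")
  invisible(object)
})

setMethod("show", "ParalogSubfamily", function(object) {
  cat(sprintf("ParalogSubfamily at node %d: {%s} | {%s}, shared {%s}\n",
              object@node, paste(object@left, collapse = ","),
              paste(object@right, collapse = ","),
              paste(object@shared, collapse = ",")))
  invisible(object)
})
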