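#' Extract species mnemonic codes from leaf identifiers
#'
#' Leaf names follow the UniProt \code{GENE_SPECIES} convention: the suffix
#' after the last underscore is the species code. Names without an underscore
#' are taken to be bare species codes.
#'
#' @param labels character vector of leaf identifiers.
#' @return Character vector of species codes, same length as \code{labels}.
#' @export
#' @examples
#' leafSpeciesCodes(c("mdh_DESAJ", "Q1_DCMF", "DEHRE"))
leafSpeciesCodes <- function(labels) {
  sub(".*_", "", labels)
}

#' Numeric bootstrap supports of a gene tree's internal nodes
#'
#' Internal-node newick labels are interpreted as bootstrap percentages in
#' [0, 100]. Empty or missing labels yield \code{NA} (absent support). Labels
#' are parsed with a decimal point only; any other non-numeric label is an
#' error, as is a value outside [0, 100].
#'
#' @param tree an \code{ape::phylo} tree.
#' @return Numeric vector of length \code{tree$Nnode}; element \code{i} is the
#'   support of internal node \code{Ntip(tree) + i}.
#' @export
nodeSupports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- rep(NA_real_, tree$Nnode)
  has <- !is.na(lab) & nzchar(lab)
  if (any(has)) {
    # strict numeric syntax: optional sign, digits, optional decimal point
    ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", lab[has])
    if (!all(ok))
      stop(sprintf("non-numeric internal node label(s): %s",
                   paste(unique(lab[has][!ok]), collapse = ", ")))
    v <- as.numeric(lab[has])
    if (any(v < 0 | v > 100))
      stop(sprintf("bootstrap support outside [0, 100]: %s",
                   paste(unique(v[v < 0 | v > 100]), collapse = ", ")))
    sup[has] <- v
  }
  sup
}

#' Read gene trees from a newick file
#'
#' Parses one or more newick trees from a file. Internal-node labels are
#' interpreted as bootstrap percentages (0-100); values in (0, 1] are taken
#' literally, never rescaled, so fraction-encoded supports must be converted
#' explicitly (see \code{rescale}).
#'
#' @param path path to a newick file (one or more trees, each ending in ";").
#' @param rescale if TRUE, multiply all supports by 100 (for files that encode
#'   supports as fractions). Default FALSE.
#' @return A list of \code{ape::phylo} trees.
#' @export
readGeneTrees <- function(path, rescale = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  chunks <- strsplit(txt, ";", fixed = TRUE)[[1]]
  chunks <- chunks[nzchar(trimws(chunks))]
  if (!length(chunks)) stop(sprintf("no newick trees found in %s", path))
  trees <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    tr <- tryCatch(ape::read.tree(text = paste0(trimws(chunks[i]), ";")),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
      stop(sprintf("tree %d: malformed newick", i))
    if (anyDuplicated(tr$tip.label))
      stop(sprintf("tree %d: duplicated leaf identifiers", i))
    if (rescale && !is.null(tr$node.label)) {
      has <- !is.na(tr$node.label) & nzchar(tr$node.label)
      tr$node.label[has] <-
        as.character(100 * as.numeric(tr$node.label[has]))
    }
    sup <- tryCatch(nodeSupports(tr), error = function(e)
      stop(sprintf("tree %d: %s", i, conditionMessage(e)), call. = FALSE))
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      stop(sprintf("tree %d: negative branch lengths", i))
    trees[[i]] <- tr
  }
  trees
}

#' Write gene trees to a newick file
#'
#' Inverse of [readGeneTrees()]: bootstrap supports are written as internal
#' node labels, branch lengths with full double precision.
#'
#' @param trees a single \code{phylo} or a list of them.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGeneTrees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, function(tr) ape::write.tree(tr, digits = 12),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' The file must be tab-separated with the fixed header
#' \code{species_code, species, genus, family, order, class, phylum}.
#' Empty cells mark absent ranks and are stored as \code{NA}.
#'
#' @param path path to the TSV file.
#' @return A \linkS4class{TaxonomyTable}.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = NULL,
                          blank.lines.skip = TRUE)
  wanted <- c("species_code", taxRanks())
  if (!identical(colnames(df), wanted))
    stop(sprintf("taxonomy header must be: %s", paste(wanted, collapse = "\t")))
  TaxonomyTable(df)
}

#' Write a taxonomy table to TSV
#'
#' @param taxonomy a \linkS4class{TaxonomyTable}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  stopifnot(is(taxonomy, "TaxonomyTable"))
  df <- taxonomy@data
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Wrapped and unwrapped records are equivalent. Identifiers are the first
#' whitespace-delimited token of each header. Empty sequences and duplicated
#' identifiers are errors.
#'
#' @param path path to a FASTA file.
#' @return A \code{Biostrings::BStringSet} (alphabet-agnostic).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(is.na(names(x)) | !nzchar(names(x))))
    stop("FASTA records must carry identifiers")
  if (anyDuplicated(names(x)))
    stop(sprintf("duplicated FASTA identifiers: %s",
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequences are not allowed")
  x
}

#' Write sequences to FASTA
#'
#' @param seqs an \code{XStringSet} or a named character vector.
#' @param path output path.
#' @param width line-wrap width in residues (default 60).
#' @return Invisibly, the path.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::BStringSet(seqs)
  }
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequences are not allowed")
  if (anyDuplicated(names(seqs))) stop("duplicated sequence identifiers")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
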