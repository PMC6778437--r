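# Global pairwise identity utilities: optimal global (Needleman-Wunsch style)
# alignment identity relative to the shorter sequence, greedy non-redundant
# reduction keeping the longer representative, and multi-copy consensus and
# identity statistics.

.NUC_CHARS <- c("A", "C", "G", "T", "U", "N", "-")

.guessAlphabet <- function(s) {
  ch <- unique(strsplit(toupper(s), "")[[1]])
  if (all(ch %in% .NUC_CHARS)) "nucleotide" else "protein"
}

.asCharSeqs <- function(seqs) {
  if (is.character(seqs)) {
    x <- seqs
  } else {
    x <- as.character(seqs)
    if (is.null(names(x))) names(x) <- names(seqs)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named")
  if (anyDuplicated(names(x))) stop("duplicated sequence identifiers")
  x
}

.subMatrix <- function(letters, match, mismatch) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global percent identity between two sequences
#'
#' Aligns the two sequences with an optimal global (Needleman-Wunsch style)
#' alignment under affine gap costs and returns identical aligned positions
#' divided by the length of the shorter sequence, times 100. Comparison is
#' case-insensitive and symmetric. Default scoring: match +1, mismatch -1,
#' gap open 2, gap extend 1 (a length-L gap costs 2 + L).
#'
#' @param a,b sequences: single characters or \code{XString}/length-1
#'   \code{XStringSet} objects. Both must be of the same alphabet
#'   (nucleotide or protein).
#' @param match,mismatch substitution scores (ignored when
#'   \code{substitutionMatrix} is given).
#' @param gapOpening,gapExtension affine gap costs (positive numbers).
#' @param substitutionMatrix optional scoring matrix, or the name of a matrix
#'   shipped with Biostrings (e.g. \code{"BLOSUM62"}) for protein scoring.
#' @return Percent identity in [0, 100].
#' @export
#' @examples
#' globalIdentity("ACGT", "ACGA")  # 75
globalIdentity <- function(a, b, match = 1, mismatch = -1,
                           gapOpening = 2, gapExtension = 1,
                           substitutionMatrix = NULL) {
  a <- toupper(as.character(a)[1])
  b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  # canonical argument order (shorter, then lexicographic) so that identity
  # is exactly symmetric even when several optimal alignments exist with
  # different match counts
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  if (.guessAlphabet(a) != .guessAlphabet(b))
    stop("alphabet mismatch: one sequence looks nucleotide, the other protein")
  if (is.null(substitutionMatrix)) {
    letters <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
    mat <- .subMatrix(letters, match, mismatch)
  } else if (is.character(substitutionMatrix)) {
    e <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
    mat <- get(substitutionMatrix, envir = e)
  } else {
    mat <- substitutionMatrix
  }
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = gapOpening,
                                      gapExtension = gapExtension)
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b)) * 100
}

#' All-by-all global identity matrix
#'
#' @param seqs a named \code{XStringSet} or named character vector.
#' @param ... passed to [globalIdentity()].
#' @return An \linkS4class{IdentityMatrix}.
#' @export
identityMatrix <- function(seqs, ...) {
  x <- .asCharSeqs(seqs)
  n <- length(x)
  m <- matrix(100, n, n, dimnames = list(names(x), names(x)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- globalIdentity(x[i], x[j], ...)
      }
    }
  }
  new("IdentityMatrix", percent = m)
}

#' Non-redundant reduction of a sequence set
#'
#' Greedy reduction at a global-identity threshold: sequences are processed in
#' decreasing length order (ties broken by identifier) and a sequence is
#' discarded when its identity to any already-retained sequence reaches the
#' threshold, so the longer member of each redundant pair is the one kept.
#' All pairwise identities among retained sequences are below the threshold.
#'
#' @param seqs a named \code{XStringSet} or named character vector.
#' @param threshold redundancy threshold in percent of the shorter sequence
#'   (default 99).
#' @param ... passed to [globalIdentity()].
#' @return The retained subset of \code{seqs}, in the input order.
#' @export
nrReduce <- function(seqs, threshold = 99, ...) {
  x <- .asCharSeqs(seqs)
  if (!length(x)) stop("at least one sequence is required")
  ord <- order(-nchar(x), names(x))
  retained <- character(0)
  for (id in names(x)[ord]) {
    redundant <- FALSE
    for (r in retained) {
      if (globalIdentity(x[[id]], x[[r]], ...) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, id)
  }
  seqs[names(x)[names(x) %in% retained]]
}

#' Mean identity and consensus of a set of sequence copies
#'
#' Computes the mean of [globalIdentity()] over all unordered pairs (reported
#' to two decimals, round-half-even) and a per-column majority consensus. The
#' consensus uses the longest copy (ties by identifier) as the reference: all
#' other copies are globally aligned to it, and each reference column takes
#' the majority residue among the aligned residues, ties broken by the
#' alphabetically first residue; columns where most copies have a gap are
#' dropped.
#'
#' @param seqs a named \code{XStringSet} or named character vector of at
#'   least two sequences.
#' @param ... passed to [globalIdentity()].
#' @return List with \code{meanIdentity} (percent, 2 decimals),
#'   \code{consensus} (character) and \code{nPairs}.
#' @export
#' @examples
#' copyIdentityStats(c(a = "ACGT", b = "ACGT", c = "ACGA"))
copyIdentityStats <- function(seqs, ...) {
  x <- .asCharSeqs(seqs)
  n <- length(x)
  if (n < 2L) stop("at least two sequences are required")
  ids <- numeric(0)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      ids <- c(ids, globalIdentity(x[i], x[j], ...))
  refId <- names(x)[order(-nchar(x), names(x))][1]
  ref <- toupper(x[[refId]])
  refChars <- strsplit(ref, "")[[1]]
  votes <- matrix("-", nrow = n, ncol = nchar(ref))
  votes[1, ] <- refChars
  others <- setdiff(names(x), refId)
  letters <- sort(unique(unlist(strsplit(toupper(unlist(x)), ""))))
  mat <- .subMatrix(letters, 1, -1)
  for (k in seq_along(others)) {
    pa <- Biostrings::pairwiseAlignment(toupper(x[[others[k]]]), ref,
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    votes[k + 1L, ] <- ap[as_ != "-"]
  }
  cons <- vapply(seq_len(ncol(votes)), function(col) {
    v <- votes[, col]
    res <- v[v != "-"]
    if (length(res) * 2L < length(v)) return("")  # mostly gapped column
    tab <- table(res)
    names(tab)[tab == max(tab)][1]  # table() is alphabetical: tie -> first
  }, character(1))
  list(meanIdentity = round(mean(ids), 2),
       consensus = paste(cons, collapse = ""),
       nPairs = length(ids))
}
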