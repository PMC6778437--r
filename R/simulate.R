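# Synthetic-data generator with planted ground truth: taxonomies, gene trees
# with a planted well-supported source clade, and sequence sets with planted
# redundancy. All generators are deterministic under the configured seed.

#' Configuration for the synthetic-data generators
#'
#' Defaults define the study conditions the generators emulate: 200 gene
#' trees whose planted source clade carries bootstrap support 95 against
#' distractor supports drawn uniformly from [5, 30], a fully populated
#' six-rank taxonomy, and 16S-like sequence sets (parent length 1500 nt,
#' copy identity 0.9987) with planted redundancy at the 99% level.
#'
#' @param seed integer seed driving every generator.
#' @param nTrees number of gene trees.
#' @param leavesRange integer range (min, max) of leaves per tree, query
#'   included.
#' @param nPhyla,classesPerPhylum,ordersPerClass,familiesPerOrder,generaPerFamily,speciesPerGenus
#'   taxonomy shape counts, all >= 1.
#' @param trueTaxon name of the source taxon the planted clade is drawn from;
#'   \code{NULL} picks the first genus of the simulated taxonomy.
#' @param trueRank rank of \code{trueTaxon} (default "genus").
#' @param cladeSpeciesRange range of the number of source-taxon species
#'   placed inside the planted clade.
#' @param supportTrue bootstrap support (percent) planted on the source clade.
#' @param supportLow range (min, max) of supports planted on all other
#'   internal nodes.
#' @param inparalogueRate probability that the query is duplicated into two
#'   in-paralogue leaves.
#' @param queryCode species code marking query leaves.
#' @param nParents,copiesPerParent,seqLength sequence-set shape: number of
#'   parent sequences, mutated copies per parent, parent length (>= 10 nt).
#' @param copyIdentity target identity of each copy to its parent, in (0, 1];
#'   point substitutions are applied at rate 1 - copyIdentity.
#' @param maxTrimFrac copies are truncated by 1 to \code{maxTrimFrac * length}
#'   trailing residues so parents are strictly longer than their copies.
#' @param indelRate optional per-site insertion/deletion rate (default 0:
#'   substitution-only, so planted identity is analytically controlled).
#' @param nrThreshold redundancy threshold (percent) used to plant truth.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, nTrees = 200L, leavesRange = c(8L, 16L),
                      nPhyla = 3L, classesPerPhylum = 1L, ordersPerClass = 1L,
                      familiesPerOrder = 2L, generaPerFamily = 2L,
                      speciesPerGenus = 3L,
                      trueTaxon = NULL, trueRank = "genus",
                      cladeSpeciesRange = c(2L, 3L),
                      supportTrue = 95, supportLow = c(5, 30),
                      inparalogueRate = 0.1, queryCode = "DCMF",
                      nParents = 6L, copiesPerParent = 3L, seqLength = 1500L,
                      copyIdentity = 0.9987, maxTrimFrac = 0.05,
                      indelRate = 0, nrThreshold = 99) {
  cfg <- list(seed = as.integer(seed), nTrees = as.integer(nTrees),
              leavesRange = as.integer(leavesRange), nPhyla = as.integer(nPhyla),
              classesPerPhylum = as.integer(classesPerPhylum),
              ordersPerClass = as.integer(ordersPerClass),
              familiesPerOrder = as.integer(familiesPerOrder),
              generaPerFamily = as.integer(generaPerFamily),
              speciesPerGenus = as.integer(speciesPerGenus),
              trueTaxon = trueTaxon, trueRank = trueRank,
              cladeSpeciesRange = as.integer(cladeSpeciesRange),
              supportTrue = supportTrue, supportLow = supportLow,
              inparalogueRate = inparalogueRate, queryCode = queryCode,
              nParents = as.integer(nParents),
              copiesPerParent = as.integer(copiesPerParent),
              seqLength = as.integer(seqLength), copyIdentity = copyIdentity,
              maxTrimFrac = maxTrimFrac, indelRate = indelRate,
              nrThreshold = nrThreshold)
  counts <- c("nTrees", "nPhyla", "classesPerPhylum", "ordersPerClass",
              "familiesPerOrder", "generaPerFamily", "speciesPerGenus",
              "nParents", "copiesPerParent")
  for (f in counts)
    if (cfg[[f]] < 1L) stop(sprintf("%s must be >= 1", f))
  if (any(cfg$leavesRange < 3L) || cfg$leavesRange[1] > cfg$leavesRange[2])
    stop("leavesRange must be an increasing range with minimum >= 3")
  if (cfg$inparalogueRate < 0 || cfg$inparalogueRate > 1)
    stop("inparalogueRate must lie in [0, 1]")
  if (cfg$indelRate < 0 || cfg$indelRate > 1)
    stop("indelRate must lie in [0, 1]")
  if (cfg$copyIdentity <= 0 || cfg$copyIdentity > 1)
    stop("copyIdentity must lie in (0, 1]")
  if (cfg$seqLength < 10L) stop("seqLength must be >= 10")
  if (cfg$supportTrue < 0 || cfg$supportTrue > 100 ||
      any(cfg$supportLow < 0) || any(cfg$supportLow > 100))
    stop("supports must lie in [0, 100]")
  if (!cfg$trueRank %in% taxRanks()) stop("trueRank must be one of taxRanks()")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a fully populated six-rank taxonomy
#'
#' Builds a nested taxonomy of the configured shape with systematic names
#' (Phylum01, Class01, ..., Genus001) and species codes SP001, SP002, ...
#' The construction is deterministic: identical configurations give identical
#' tables.
#'
#' @param config a [simConfig()] list.
#' @return A \linkS4class{TaxonomyTable}.
#' @export
simulateTaxonomy <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  rows <- list()
  ic <- io <- ifa <- ig <- isp <- 0L
  for (ip in seq_len(config$nPhyla)) {
    phylum <- sprintf("Phylum%02d", ip)
    for (jc in seq_len(config$classesPerPhylum)) {
      ic <- ic + 1L; cls <- sprintf("Class%02d", ic)
      for (jo in seq_len(config$ordersPerClass)) {
        io <- io + 1L; ord <- sprintf("Order%02d", io)
        for (jf in seq_len(config$familiesPerOrder)) {
          ifa <- ifa + 1L; fam <- sprintf("Family%02d", ifa)
          for (jg in seq_len(config$generaPerFamily)) {
            ig <- ig + 1L; gen <- sprintf("Genus%03d", ig)
            for (js in seq_len(config$speciesPerGenus)) {
              isp <- isp + 1L
              rows[[isp]] <- data.frame(
                species_code = sprintf("SP%03d", isp),
                species = sprintf("%s species%d", gen, js),
                genus = gen, family = fam, order = ord,
                class = cls, phylum = phylum, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  TaxonomyTable(do.call(rbind, rows))
}

.fmtLen <- function(x) sprintf("%.6f", x)

# join newick fragments pairwise in random order; sups[k] is the label given
# to the k-th join (NA = no label). The last join forms the fragment root.
.joinRandom <- function(frags, sups) {
  stopifnot(length(sups) == length(frags) - 1L)
  k <- 0L
  while (length(frags) > 1L) {
    k <- k + 1L
    pick <- sample.int(length(frags), 2L)
    lab <- if (is.na(sups[k])) "" else sprintf("%g", sups[k])
    merged <- sprintf("(%s:%s,%s:%s)%s",
                      frags[pick[1]], .fmtLen(stats::rexp(1, 10)),
                      frags[pick[2]], .fmtLen(stats::rexp(1, 10)), lab)
    frags <- c(frags[-pick], merged)
  }
  frags
}

.lowSup <- function(config, n) {
  round(stats::runif(n, config$supportLow[1], config$supportLow[2]), 1)
}

#' Simulate one gene tree with a planted source clade
#'
#' Generates a random bifurcating gene tree containing one query leaf (two
#' when an in-paralogue is planted), a "true clade" of source-taxon species
#' around the query carrying support \code{supportTrue}, and distractor
#' leaves from other taxa; every other internal node carries a support drawn
#' from \code{supportLow}. Branch lengths are exponential. The returned truth
#' record states the clade the assignment stage must recover.
#'
#' Draws from the current RNG stream (no re-seeding), so it can be called in
#' sequence; use [simulateGeneTrees()] for a seeded batch.
#'
#' @param taxonomy a \linkS4class{TaxonomyTable}.
#' @param config a [simConfig()] list.
#' @return List with \code{tree} (a rooted \code{phylo}) and \code{truth}
#'   (list: \code{queryLeaf}, \code{clade} species codes, \code{support},
#'   \code{trueTaxon}, \code{trueRank}).
#' @export
simulateGeneTree <- function(taxonomy, config = simConfig()) {
  stopifnot(is(taxonomy, "TaxonomyTable"), inherits(config, "SimConfig"))
  df <- taxonomy@data
  if (!nrow(df)) stop("taxonomy is empty")
  trueTaxon <- config$trueTaxon
  if (is.null(trueTaxon)) trueTaxon <- sort(unique(df$genus))[1]
  inTrue <- !is.na(df[[config$trueRank]]) & df[[config$trueRank]] == trueTaxon
  if (!any(inTrue))
    stop(sprintf("true source taxon '%s' absent from taxonomy at rank %s",
                 trueTaxon, config$trueRank))
  trueCodes <- df$species_code[inTrue]
  otherCodes <- df$species_code[!inTrue]
  nClade <- sample(seq(config$cladeSpeciesRange[1],
                       config$cladeSpeciesRange[2]), 1L)
  nClade <- min(nClade, length(trueCodes))
  cladeCodes <- sort(sample(trueCodes, nClade))
  nLeaves <- sample(seq(config$leavesRange[1], config$leavesRange[2]), 1L)
  nDistract <- max(1L, nLeaves - nClade - 1L)
  nDistract <- min(nDistract, length(otherCodes))
  if (nDistract < 1L) stop("taxonomy too small for distractor leaves")
  distractCodes <- sample(otherCodes, nDistract)

  queryFrag <- sprintf("Q1_%s", config$queryCode)
  inpar <- stats::runif(1) < config$inparalogueRate
  if (inpar) {
    queryFrag <- sprintf("(Q1_%s:%s,Q2_%s:%s)%g",
                         config$queryCode, .fmtLen(stats::rexp(1, 20)),
                         config$queryCode, .fmtLen(stats::rexp(1, 20)),
                         .lowSup(config, 1))
  }
  cladeLeaves <- sprintf("g%02d_%s", seq_along(cladeCodes), cladeCodes)
  cladeFrags <- c(queryFrag, cladeLeaves)
  nJoin <- length(cladeFrags) - 1L
  cladeSups <- c(.lowSup(config, max(0L, nJoin - 1L)), config$supportTrue)
  clade <- .joinRandom(cladeFrags, cladeSups)

  distractLeaves <- sprintf("d%02d_%s", seq_along(distractCodes), distractCodes)
  outerFrags <- c(clade, distractLeaves)
  nJoin <- length(outerFrags) - 1L
  outerSups <- c(.lowSup(config, max(0L, nJoin - 1L)), NA)
  nwk <- sprintf("%s;", .joinRandom(outerFrags, outerSups))
  tree <- ape::read.tree(text = nwk)
  list(tree = tree,
       truth = list(queryLeaf = sprintf("Q1_%s", config$queryCode),
                    clade = cladeCodes,
                    support = config$supportTrue, trueTaxon = trueTaxon,
                    trueRank = config$trueRank,
                    inparalogue = inpar))
}

#' Simulate a seeded batch of gene trees
#'
#' Seeds the RNG from \code{config$seed} and generates \code{config$nTrees}
#' trees with [simulateGeneTree()]; identical configurations give identical
#' batches.
#'
#' @param taxonomy a \linkS4class{TaxonomyTable}.
#' @param config a [simConfig()] list.
#' @param reseed seed the RNG from the config first (default TRUE).
#' @return List with \code{trees} (named list of \code{phylo}) and
#'   \code{truth} (matched named list of truth records).
#' @export
simulateGeneTrees <- function(taxonomy, config = simConfig(), reseed = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  if (reseed) set.seed(config$seed)
  sims <- lapply(seq_len(config$nTrees), function(i)
    simulateGeneTree(taxonomy, config))
  nm <- sprintf("tree%03d", seq_len(config$nTrees))
  list(trees = stats::setNames(lapply(sims, `[[`, "tree"), nm),
       truth = stats::setNames(lapply(sims, `[[`, "truth"), nm))
}

.truthQueryLeaf <- function(cfg) sprintf("Q1_%s", cfg$queryCode)

#' Simulate a sequence set with planted redundancy
#'
#' Generates \code{nParents} independent random nucleotide parent sequences
#' plus \code{copiesPerParent} mutated copies of each: copies are truncated
#' at the 3' end (so parents are strictly longer) and carry point
#' substitutions at rate \code{1 - copyIdentity}; an optional indel rate adds
#' insertions/deletions (default 0, keeping identity analytically
#' controlled). The truth record lists each copy's realised identity to its
#' parent and the set a redundancy reduction at \code{nrThreshold} percent
#' must retain.
#'
#' @param config a [simConfig()] list.
#' @param reseed seed the RNG from the config first (default TRUE).
#' @return List with \code{sequences} (a \code{DNAStringSet}) and
#'   \code{truth} (list: \code{parents}, \code{retained},
#'   \code{redundantPairs} data.frame).
#' @export
simulateSequences <- function(config = simConfig(), reseed = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  if (reseed) set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  L <- config$seqLength
  maxTrim <- max(1L, as.integer(round(config$maxTrimFrac * L)))
  seqs <- character(0)
  pairs <- list()
  for (i in seq_len(config$nParents)) {
    pid <- sprintf("parent%02d", i)
    parent <- sample(bases, L, replace = TRUE)
    seqs[pid] <- paste(parent, collapse = "")
    for (j in seq_len(config$copiesPerParent)) {
      cid <- sprintf("copy%02d_%02d", i, j)
      trim <- sample.int(maxTrim, 1L)
      cp <- parent[seq_len(L - trim)]
      subs <- which(stats::runif(length(cp)) < 1 - config$copyIdentity)
      for (s in subs) cp[s] <- sample(setdiff(bases, cp[s]), 1L)
      realised <- (length(cp) - length(subs)) / length(cp) * 100
      if (config$indelRate > 0) {
        keep <- stats::runif(length(cp)) >= config$indelRate / 2
        cp <- cp[keep]
        ins <- which(stats::runif(length(cp)) < config$indelRate / 2)
        for (s in rev(ins)) cp <- append(cp, sample(bases, 1L), after = s)
        realised <- NA_real_  # no longer analytic
      }
      seqs[cid] <- paste(cp, collapse = "")
      pairs[[length(pairs) + 1L]] <- data.frame(
        copy = cid, parent = pid, identity = realised,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  redundant <- !is.na(pairs$identity) & pairs$identity >= config$nrThreshold
  parents <- sprintf("parent%02d", seq_len(config$nParents))
  retained <- c(parents, pairs$copy[!redundant])
  list(sequences = Biostrings::DNAStringSet(seqs),
       truth = list(parents = parents, retained = sort(retained),
                    pairs = pairs,
                    redundantPairs = pairs[redundant, , drop = FALSE]))
}

#' Simulate a complete dataset from one seed
#'
#' Seeds the RNG once from \code{config$seed} and draws, in this order: the
#' taxonomy, the gene trees, the sequence set. Identical configurations give
#' identical datasets.
#'
#' @param config a [simConfig()] list.
#' @return List with \code{taxonomy}, \code{trees}, \code{truth} (per tree),
#'   \code{sequences}, \code{seqTruth} and the \code{config}.
#' @export
simulateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  taxonomy <- simulateTaxonomy(config)
  tr <- simulateGeneTrees(taxonomy, config, reseed = FALSE)
  sq <- simulateSequences(config, reseed = FALSE)
  list(taxonomy = taxonomy, trees = tr$trees, truth = tr$truth,
       sequences = sq$sequences, seqTruth = sq$truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes one newick file per tree under \code{dir/trees/}, the taxonomy as
#' TSV, the sequence set as FASTA and the truth records as JSON.
#'
#' @param dataset result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeSimulation <- function(dataset, dir) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset$trees))
    writeGeneTrees(dataset$trees[[nm]], file.path(dir, "trees",
                                                  paste0(nm, ".nwk")))
  writeTaxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  writeFasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  truth <- list(trees = dataset$truth, sequences = dataset$seqTruth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
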