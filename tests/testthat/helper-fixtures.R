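# Shared fixtures: small hand-built trees and taxonomies, random generators
# used by the property-style tests. Everything is built in code at test time.

# taxonomy with two Peptococcaceae genera, one other Firmicutes family and
# one partial entry known only to phylum level
makeTestTaxonomy <- function() {
  TaxonomyTable(data.frame(
    species_code = c("DESAJ", "DESAC", "DEHRE", "CLOAB", "PARTX"),
    species = c("Desulfosporosinus acidiphilus", "Desulfosporosinus acididurans",
                "Dehalobacter restrictus", "Clostridium acetobutylicum", NA),
    genus = c("Desulfosporosinus", "Desulfosporosinus", "Dehalobacter",
              "Clostridium", NA),
    family = c("Peptococcaceae", "Peptococcaceae", "Peptococcaceae",
               "Clostridiaceae", NA),
    order = c("Clostridiales", "Clostridiales", "Clostridiales",
              "Clostridiales", NA),
    class = c("Clostridia", "Clostridia", "Clostridia", "Clostridia", NA),
    phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes"),
    stringsAsFactors = FALSE))
}

# random rooted tree whose tips carry species codes (queryCopies of them the
# query code) and whose internal nodes carry random supports, some absent
randomSupportTree <- function(nTips = 10, queryCopies = 1, nSpecies = 6,
                              naFrac = 0.2, queryCode = "DCMF") {
  stopifnot(nTips > queryCopies)
  tr <- ape::rtree(nTips)
  codes <- c(rep(queryCode, queryCopies),
             sample(sprintf("SP%03d", seq_len(nSpecies)),
                    nTips - queryCopies, replace = TRUE))
  codes <- sample(codes)
  tr$tip.label <- sprintf("g%02d_%s", seq_len(nTips), codes)
  lab <- as.character(round(stats::runif(tr$Nnode, 0, 100), 1))
  lab[stats::runif(tr$Nnode) < naFrac] <- ""
  lab[1] <- ""  # root support is conventionally absent
  tr$node.label <- lab
  tr
}

# random unrooted tree with branch lengths, for midpoint-rooting properties
randomUnrootedTree <- function(nTips = 8) {
  tr <- ape::unroot(ape::rtree(nTips))
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.05, 1), 4)
  tr
}

randomFastaRecords <- function(n = 50) {
  len <- sample(5:120, n, replace = TRUE)
  seqs <- vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  stats::setNames(seqs, sprintf("rec%03d", seq_len(n)))
}
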