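test_that("simulated taxonomies have the configured shape and are deterministic", {
  cfg <- simConfig(nPhyla = 1, classesPerPhylum = 1, ordersPerClass = 1,
                   familiesPerOrder = 1, generaPerFamily = 2,
                   speciesPerGenus = 2)
  tax <- simulateTaxonomy(cfg)
  expect_equal(length(speciesCodes(tax)), 4)
  expect_equal(unique(tax@data$family), "Family01")
  expect_equal(length(unique(tax@data$genus)), 2)

  expect_identical(simulateTaxonomy(simConfig(seed = 9))@data,
                   simulateTaxonomy(simConfig(seed = 9))@data)

  tax3 <- simulateTaxonomy(simConfig(nPhyla = 3))
  expect_gte(length(unique(tax3@data$phylum)), 3)
  # every rank column fully populated
  expect_false(anyNA(tax3@data))

  expect_error(simConfig(speciesPerGenus = 0), ">= 1")
})

test_that("simulated gene trees plant a supported clade around the query", {
  cfg <- simConfig(seed = 3, supportTrue = 95)
  tax <- simulateTaxonomy(cfg)
  set.seed(cfg$seed)
  sim <- simulateGeneTree(tax, cfg)
  expect_true(ape::is.rooted(sim$tree))
  expect_true(sim$truth$queryLeaf %in% sim$tree$tip.label)
  expect_true(all(sim$truth$clade %in%
                    leafSpeciesCodes(sim$tree$tip.label)))
  expect_equal(sim$truth$support, 95)
  # the planted clade is recoverable by the assignment walk
  a <- assignClade(sim$tree, sim$truth$queryLeaf, 50)
  expect_equal(a@species, sim$truth$clade)
  expect_equal(a@support, 95)

  # in-paralogue rate 1 forces two query copies
  cfg2 <- simConfig(seed = 4, inparalogueRate = 1)
  set.seed(cfg2$seed)
  sim2 <- simulateGeneTree(tax, cfg2)
  expect_equal(sum(leafSpeciesCodes(sim2$tree$tip.label) == "DCMF"), 2)

  # a missing source taxon is an error
  bad <- simConfig(trueTaxon = "NotATaxon")
  expect_error(simulateGeneTree(tax, bad), "absent from taxonomy")
})

test_that("gene tree batches are deterministic under the seed", {
  cfg <- simConfig(seed = 12, nTrees = 10)
  tax <- simulateTaxonomy(cfg)
  b1 <- simulateGeneTrees(tax, cfg)
  b2 <- simulateGeneTrees(tax, cfg)
  expect_identical(lapply(b1$trees, ape::write.tree),
                   lapply(b2$trees, ape::write.tree))
  expect_identical(b1$truth, b2$truth)
})

test_that("sequence sets realise the planted identity and redundancy", {
  # identity target 0.95 on length 1000: measured within 0.95 +/- 0.02
  cfg <- simConfig(seed = 21, nParents = 2, copiesPerParent = 2,
                   seqLength = 1000, copyIdentity = 0.95)
  sim <- simulateSequences(cfg)
  x <- as.character(sim$sequences)
  for (i in 1:2) {
    for (j in 1:2) {
      cid <- sprintf("copy%02d_%02d", i, j)
      pid <- sprintf("parent%02d", i)
      m <- globalIdentity(x[[cid]], x[[pid]])
      expect_gte(m, 93)
      expect_lte(m, 97)
    }
  }

  # identity target 1.0 with minimal trimming plants exact-duplicate pairs
  dup <- simulateSequences(simConfig(seed = 5, nParents = 1,
                                     copiesPerParent = 1, seqLength = 200,
                                     copyIdentity = 1))
  expect_equal(nrow(dup$truth$redundantPairs), 1)
  expect_equal(dup$truth$redundantPairs$identity, 100)
  expect_equal(dup$truth$retained, "parent01")

  # same seed twice gives byte-identical FASTA
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(simulateSequences(simConfig(seed = 33))$sequences, f1)
  writeFasta(simulateSequences(simConfig(seed = 33))$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simConfig(copyIdentity = 0), "copyIdentity")
  expect_error(simConfig(copyIdentity = 1.2), "copyIdentity")
  expect_error(simConfig(seqLength = 5), "seqLength")
})

test_that("realised copy identity stays within three binomial sd of target", {
  p <- 0.9
  L <- 800
  cfg <- simConfig(seed = 55, nParents = 3, copiesPerParent = 2,
                   seqLength = L, copyIdentity = p)
  sim <- simulateSequences(cfg)
  sd3 <- 3 * sqrt(p * (1 - p) / L) * 100
  x <- as.character(sim$sequences)
  expect_equal(nrow(sim$truth$pairs), 6)
  for (k in seq_len(nrow(sim$truth$pairs))) {
    pr <- sim$truth$pairs[k, ]
    expect_lt(abs(pr$identity - 100 * p), sd3)
    # the generator's analytic identity agrees with the measured global
    # alignment identity (substitution-only copies align gaplessly; the
    # aligner may rescue the odd extra match)
    measured <- globalIdentity(x[[pr$copy]], x[[pr$parent]])
    expect_gte(measured, pr$identity - 1e-9)
    expect_lt(measured - pr$identity, 0.5)
  }
})

test_that("whole datasets are deterministic and internally consistent", {
  ds1 <- simulateDataset(simConfig(seed = 77, nTrees = 5))
  ds2 <- simulateDataset(simConfig(seed = 77, nTrees = 5))
  expect_identical(lapply(ds1$trees, ape::write.tree),
                   lapply(ds2$trees, ape::write.tree))
  expect_identical(as.character(ds1$sequences), as.character(ds2$sequences))
  # truth refers only to generated elements
  codes <- speciesCodes(ds1$taxonomy)
  for (t in ds1$truth) expect_true(all(t$clade %in% codes))
  expect_true(all(ds1$seqTruth$retained %in% names(ds1$sequences)))
})
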