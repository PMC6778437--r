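test_that("equal-split shares divide one unit of mass per protein", {
  expect_equal(unname(unweightedShares(paste0("t", 1:5))), rep(0.2, 5))
  expect_equal(unname(unweightedShares("only")), 1)
  expect_error(unweightedShares(character(0)), "empty")

  withr::local_seed(7)
  for (i in 1:1000) {
    taxa <- sample(letters, sample(1:10, 1))
    expect_equal(sum(unweightedShares(taxa)), 1, tolerance = 1e-12)
  }
})

test_that("bootstrap weighting multiplies shares by support/100", {
  w <- weightedShares(c("X", "Y"), support = 80)
  expect_equal(unname(w), c(0.4, 0.4))
  expect_equal(unname(weightedShares("X", 100)), 1)
  expect_equal(unname(weightedShares(c("X", "Y"), 0, fallback = TRUE)),
               c(0.5, 0.5))
  expect_error(weightedShares("X", 120), "\\[0, 100\\]")
  expect_error(weightedShares("X", NA_real_), "\\[0, 100\\]")

  withr::local_seed(13)
  for (i in 1:1000) {
    taxa <- sample(letters, sample(1:8, 1))
    s <- round(stats::runif(1, 0, 100), 1)
    expect_equal(weightedShares(taxa, s), unweightedShares(taxa) * s / 100,
                 tolerance = 1e-12)
  }
})

test_that("iterative exclusion re-splits shares and reaches a fixed point", {
  # hand-computed two-step iteration: P1 {X}, P2 {X, Y}; Y starts at 0.5,
  # is excluded, P2 re-splits to {X}, final X = 2.0
  p <- combineRank(list("X", c("X", "Y")))
  tab <- profileTable(p)
  expect_equal(tab$taxon, "X")
  expect_equal(tab$unweighted, 2)
  expect_equal(tab$percent_unweighted, 100)

  # three proteins uniquely on X
  p3 <- combineRank(list("X", "X", "X"))
  expect_equal(profileTable(p3)$unweighted, 3)
  expect_equal(profileTable(p3)$percent_weighted, 100)

  # a protein that loses every taxon moves to the reserved None bucket
  pn <- combineRank(list(c("A", "B"), "C", "C"))
  tn <- profileTable(pn)
  expect_setequal(tn$taxon, c("C", "None"))
  expect_equal(tn$unweighted[tn$taxon == "C"], 2)
  expect_equal(tn$unweighted[tn$taxon == "None"], 1)
})

test_that("exclusion conserves mass, terminates and is a fixed point", {
  withr::local_seed(29)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    pool <- paste0("tax", seq_len(sample(3:8, 1)))
    sets <- replicate(n, sample(pool, sample(1:3, 1)), simplify = FALSE)
    weights <- round(stats::runif(n), 3)
    fx <- iterateExclusion(sets)
    # termination within one round per distinct taxon
    expect_lte(fx$rounds, length(pool))
    # fixed point: a second pass changes nothing
    fx2 <- iterateExclusion(fx$sets)
    expect_identical(fx2$sets, fx$sets)
    expect_equal(fx2$rounds, 0)
    p <- combineRank(sets, weights)
    # conservation: unweighted mass equals the number of proteins
    expect_equal(sum(p@unweighted), n, tolerance = 1e-9)
    # no retained real taxon below the threshold
    real <- !p@taxa %in% c("None")
    expect_true(all(p@unweighted[real] >= 1 - 1e-9))
    # percentages sum to 100
    expect_equal(sum(p@percentWeighted), 100, tolerance = 1e-6)
    expect_equal(sum(p@percentUnweighted), 100, tolerance = 1e-6)
    # weighted never exceeds unweighted when weights are <= 1
    expect_true(all(p@weighted <= p@unweighted + 1e-12))
  }
})

test_that("mass conservation holds at every exclusion round", {
  withr::local_seed(37)
  sets <- replicate(10, sample(paste0("t", 1:6), sample(1:3, 1)),
                    simplify = FALSE)
  full <- iterateExclusion(sets)
  for (r in 0:full$rounds) {
    part <- iterateExclusion(sets, maxRounds = r)
    k <- lengths(part$sets)
    expect_equal(sum(rep(1 / k, k)), 10, tolerance = 1e-9)
  }
})

test_that("profiles are invariant to the order of input proteins", {
  withr::local_seed(41)
  n <- 20
  sets <- replicate(n, sample(paste0("t", 1:5), sample(1:3, 1)),
                    simplify = FALSE)
  weights <- round(stats::runif(n), 3)
  perm <- sample(n)
  p1 <- profileTable(combineRank(sets, weights))
  p2 <- profileTable(combineRank(sets[perm], weights[perm]))
  expect_equal(p1, p2)
})

test_that("renormalise mode drops sub-threshold taxa without re-splitting", {
  # P1 {X}, P2 {X, Y}: Y (0.5) is dropped; X keeps 1.5 (no re-split) and
  # percentages renormalise over the surviving mass
  p <- combineRank(list("X", c("X", "Y")), resplit = FALSE)
  tab <- profileTable(p)
  expect_equal(tab$taxon, "X")
  expect_equal(tab$unweighted, 1.5)
  expect_equal(tab$percent_unweighted, 100)
})

test_that("combineAssignments profiles all six ranks with support weights", {
  tax <- makeTestTaxonomy()
  a1 <- CladeAssignment("p1", c("DESAJ", "DESAC"), 80)
  a2 <- CladeAssignment("p2", "DEHRE", 100)
  a3 <- CladeAssignment("p3", character(0), NA_real_, noneFlag = TRUE)
  ranked <- lapply(list(a1, a2, a3), mapToRanks, taxonomy = tax)
  prof <- combineAssignments(list(a1, a2, a3), ranked)
  expect_named(prof, taxRanks())
  fam <- profileTable(prof$family)
  pep <- fam[fam$taxon == "Peptococcaceae", ]
  # p1 (0.8 weight, single family) + p2 (1.0 weight, same family)
  expect_equal(pep$unweighted, 2)
  expect_equal(pep$weighted, 1.8)
  expect_true("None" %in% fam$taxon)
})
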