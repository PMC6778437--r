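test_that("midpoint rooting bisects the longest leaf-to-leaf path", {
  # pendant lengths 1,1,4: longest path 1 + 4 = 5, root 2.5 from each end,
  # i.e. on the long pendant branch 1.5 past the internal node
  tr <- ape::read.tree(text = "(A:1,B:1,C:4);")
  m <- midpointRoot(tr)
  expect_true(ape::is.rooted(m))
  d <- rootSubtreeDepths(m)
  expect_equal(sort(d), c(2.5, 2.5))
  co <- ape::cophenetic.phylo(m)
  expect_equal(co["A", "C"], 5)
  expect_equal(co["A", "B"], 2)

  # perfectly symmetric quartet roots at the central edge midpoint
  sym <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ms <- midpointRoot(ape::unroot(sym))
  expect_equal(rootSubtreeDepths(ms), c(2, 2))
})

test_that("midpoint rooting equalises root depths and preserves distances", {
  withr::local_seed(23)
  for (i in 1:100) {
    tr <- randomUnrootedTree(sample(4:15, 1))
    m <- midpointRoot(tr)
    d <- rootSubtreeDepths(m)
    expect_lt(abs(d[1] - d[2]), 1e-9)
    co1 <- ape::cophenetic.phylo(tr)
    co2 <- ape::cophenetic.phylo(m)[rownames(co1), colnames(co1)]
    expect_equal(co2, co1, tolerance = 1e-9)
  }
})

test_that("midpoint rooting keeps supports on their bipartitions", {
  tr <- ape::read.tree(
    text = "((A_S1:0.1,B_S2:0.1)80:0.05,(C_S3:0.2,D_S4:0.3)60:0.1,E_S5:0.9);")
  m <- midpointRoot(tr)
  # clade {A,B} still carries 80, clade {C,D} still carries 60
  n <- length(m$tip.label)
  sup <- nodeSupports(m)
  cladeOf <- function(s) {
    for (nd in (n + 1L):(n + m$Nnode)) {
      tips <- sort(ape::extract.clade(m, nd)$tip.label)
      if (identical(tips, sort(s))) return(sup[nd - n])
    }
    NA_real_
  }
  expect_equal(cladeOf(c("A_S1", "B_S2")), 80)
  expect_equal(cladeOf(c("C_S3", "D_S4")), 60)
})

test_that("midpoint rooting rejects degenerate trees", {
  one <- ape::read.tree(text = "(A:1);")
  expect_error(midpointRoot(one), "2 leaves")
  z <- ape::read.tree(text = "(A:0,B:0,C:0);")
  expect_error(midpointRoot(z), "zero")
  nolen <- ape::read.tree(text = "(A,B,C);")
  expect_error(midpointRoot(nolen), "branch lengths")
})

test_that("paralogous subfamilies require two 2+-species children sharing one", {
  # child clades {A,B} and {A,C}: both have 2 species, share A -> reported
  tr <- ape::read.tree(text = paste0(
    "(((g1_SPA:1,g2_SPB:1)90:1,(g3_SPA:1,g4_SPC:1)80:1)70:1,g5_SPD:1);"))
  sf <- findParalogSubfamilies(tr)
  expect_length(sf, 1)
  expect_equal(sf[[1]]@shared, "SPA")
  expect_setequal(sf[[1]]@left, c("SPA", "SPB"))
  expect_setequal(sf[[1]]@right, c("SPA", "SPC"))

  # a cherry of two leaves from different species fails the >=2-species rule
  cherry <- ape::read.tree(text = "((g1_SPA:1,g2_SPB:1)90:1,g3_SPC:1);")
  expect_length(findParalogSubfamilies(cherry), 0)

  expect_error(findParalogSubfamilies(ape::read.tree(text = "(A:1,B:1,C:1);")),
               "rooted")
})

test_that("paralogous subfamily detection agrees with the per-node oracle", {
  withr::local_seed(31)
  for (i in 1:100) {
    tr <- randomSupportTree(sample(6:18, 1), queryCopies = sample(1:2, 1),
                            nSpecies = sample(3:6, 1))
    got <- sort(vapply(findParalogSubfamilies(tr), slot, integer(1), "node"))
    expect_equal(got, sort(oracleParalogNodes(tr)))
  }
})

test_that("in-paralogue filtering keeps the closest homologue per species", {
  # two SPA leaves inside a paralogous subfamily at patristic distances
  # 0.3 and 0.7 from the query: the 0.3 one is kept
  tr <- ape::read.tree(text = paste0(
    "(((Q1_DCMF:0.1,g1_SPA:0.2)50:0.2,(g2_SPA:0.2,g3_SPB:1)60:0.2)40:1,g4_SPC:1);"))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["g1_SPA", "Q1_DCMF"], 0.3)
  expect_equal(co["g2_SPA", "Q1_DCMF"], 0.7)
  out <- filterInparalogs(tr)
  expect_true("g1_SPA" %in% out$tip.label)
  expect_false("g2_SPA" %in% out$tip.label)
  expect_true(all(c("Q1_DCMF", "g3_SPB", "g4_SPC") %in% out$tip.label))

  # query in-paralogues are always kept
  tq <- ape::read.tree(text = paste0(
    "(((Q1_DCMF:1,Q2_DCMF:1)90:1,(g1_SPA:1,g2_SPB:1)80:1)70:1,g3_SPC:1);"))
  expect_identical(filterInparalogs(tq)$tip.label, tq$tip.label)

  # no paralogous subfamilies: identity transformation
  plain <- ape::read.tree(text = "((Q1_DCMF:1,g1_SPA:1)90:1,g2_SPB:1);")
  expect_identical(filterInparalogs(plain), plain)

  expect_error(filterInparalogs(plain, queryCode = "NOPE"), "query code")
})

test_that("in-paralogue filtering is idempotent and removes within-subfamily duplicates", {
  withr::local_seed(47)
  for (i in 1:60) {
    tr <- randomSupportTree(sample(8:18, 1), queryCopies = sample(1:2, 1),
                            nSpecies = sample(3:5, 1))
    once <- filterInparalogs(tr)
    twice <- filterInparalogs(once)
    expect_identical(ape::write.tree(twice), ape::write.tree(once))
    # within any remaining paralogous subfamily no non-query species twice
    codes <- leafSpeciesCodes(once$tip.label)
    for (sf in findParalogSubfamilies(once)) {
      tips <- ape::extract.clade(once, sf@node)$tip.label
      cd <- leafSpeciesCodes(tips)
      cd <- cd[cd != "DCMF"]
      expect_false(anyDuplicated(cd) > 0)
    }
  }
})
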