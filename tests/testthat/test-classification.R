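test_that("leaf sister to a single anchor inherits its label fully", {
  tr <- ape::read.tree(text = "((q1:1,atA:1):1,(atB:1,q2:1):1);")
  anc <- data.frame(leaf_id = c("atA", "atB"),
                    subfamily = c("XII", "XI-1"),
                    stringsAsFactors = FALSE)
  a <- assignSubfamilies(tr, anc)
  expect_equal(a$subfamily[a$gene_id == "q1"], "XII")
  expect_equal(a$subfamily[a$gene_id == "q2"], "XI-1")
  expect_equal(a$support[a$gene_id == "q1"], 1.0)
  expect_false(any(a$ambiguous))
  # anchors keep their given labels
  expect_equal(a$subfamily[a$gene_id == "atA"], "XII")
})

test_that("majority rule in the deciding clade with support share", {
  tr <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(a3:1,q:1):1):1,out:9);")
  anc <- data.frame(leaf_id = c("a1", "a2", "a3", "out"),
                    subfamily = c("XI-1", "XI-1", "XII", "XV"),
                    stringsAsFactors = FALSE)
  a <- assignSubfamilies(tr, anc)
  # smallest anchored clade for q is {a3, q}: label XII
  expect_equal(a$subfamily[a$gene_id == "q"], "XII")
  # force a clade with mixed anchors: query hanging off the mixed clade
  tr2 <- ape::read.tree(
    text = "((((a1:1,a2:1):1,a3:1):1,q:1):1,out:9);")
  a2 <- assignSubfamilies(tr2, anc)
  expect_equal(a2$subfamily[a2$gene_id == "q"], "XI-1")
  expect_equal(a2$support[a2$gene_id == "q"], 2 / 3)
})

test_that("ties break by patristic distance, residual ties lexicographic", {
  # nearest anchor among tied labels decides
  tr <- ape::read.tree(
    text = "(((aXII:0.1,q:0.1):1,aXI:5):1,out:9);")
  anc <- data.frame(leaf_id = c("aXII", "aXI", "out"),
                    subfamily = c("XII", "XI-1", "XV"),
                    stringsAsFactors = FALSE)
  a <- assignSubfamilies(tr, anc)
  expect_equal(a$subfamily[a$gene_id == "q"], "XII")
  expect_false(a$ambiguous[a$gene_id == "q"])
  # perfectly symmetric distances: ambiguous, lexicographically first
  tr2 <- ape::read.tree(
    text = "(((aXII:1,aXI:1):1,q:1):1,out:9);")
  a2 <- assignSubfamilies(tr2, anc)
  expect_true(a2$ambiguous[a2$gene_id == "q"])
  expect_equal(a2$subfamily[a2$gene_id == "q"], "XI-1")
})

test_that("anchored-tree errors are reported", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_error(assignSubfamilies(tr, data.frame(leaf_id = character(0),
                                                subfamily = character(0))),
               "no anchor")
  expect_error(assignSubfamilies(
    tr, data.frame(leaf_id = "A", subfamily = "made-up")),
    "labels")
})

test_that("assignment is invariant to leaf rotation of the newick", {
  sim <- cachedSim(101, 80, 20)
  a1 <- assignSubfamilies(sim@tree, sim@anchors)
  rot <- ape::rotateConstr(sim@tree, rev(sim@tree$tip.label))
  a2 <- assignSubfamilies(rot, sim@anchors)
  a2 <- a2[match(a1$gene_id, a2$gene_id), ]
  expect_equal(a1$subfamily, a2$subfamily)
})

test_that("planted labels recovered at zero misplacement, rate respected", {
  sim <- cachedSim(101, 80, 20)
  a <- assignSubfamilies(sim@tree, sim@anchors)
  fam <- a[!a$is_anchor, ]
  truth <- familyAssignments(sim)
  expect_equal(fam$subfamily[match(truth$gene_id, fam$gene_id)],
               truth$subfamily)
  # with misplacement p, mislabel fraction tracks p (<= p plus CI slack)
  simM <- cachedSim(55, 150, 40, treeMisplacement = 0.1)
  aM <- assignSubfamilies(simM@tree, simM@anchors)
  famM <- aM[!aM$is_anchor, ]
  truthM <- familyAssignments(simM)
  mis <- mean(famM$subfamily[match(truthM$gene_id, famM$gene_id)] !=
                truthM$subfamily)
  ciHalf <- 1.96 * sqrt(0.1 * 0.9 / nrow(truthM))
  expect_lte(mis, 0.1 + ciHalf)
})

test_that("topology comparison measures label stability", {
  sim <- cachedSim(101, 80, 20)
  a <- assignSubfamilies(sim@tree, sim@anchors)
  expect_equal(compareTopologies(a, a)$overall, 1.0)
  # relabel 5% of the leaves: stability drops by exactly that fraction
  b <- a
  idx <- which(!b$is_anchor)[seq_len(ceiling(0.05 * nrow(b)))]
  b$subfamily[idx] <- ifelse(b$subfamily[idx] == "XII", "XI-1", "XII")
  expect_equal(compareTopologies(a, b)$overall,
               1 - length(idx) / nrow(a))
  expect_error(compareTopologies(a, a[-1, ]), "leaf set")
})

test_that("subfamily tabulation reproduces printed-percentage arithmetic", {
  expect_equal(subfamilyPercentages(c("XI-1" = 75), total = 298)$pct, 25.2)
  expect_equal(subfamilyPercentages(c("XII" = 102), total = 511)$pct, 20.0)
  expect_equal(subfamilyPercentages(c("I" = 41), total = 213)$pct, 19.2)
  # empty assignments give an empty table
  empty <- data.frame(gene_id = character(0), species = character(0),
                      subfamily = character(0))
  expect_equal(nrow(tabulateSubfamilies(empty)), 0)
  # percentages sum to 100 within rounding
  sim <- cachedSim(101, 80, 20)
  a <- assignSubfamilies(sim@tree, sim@anchors)
  a$species[!a$is_anchor] <- "sim"
  tab <- tabulateSubfamilies(a)
  expect_lt(abs(sum(tab$pct) - 100), 0.5)
})
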