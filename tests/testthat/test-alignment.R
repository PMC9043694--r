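test_that("exhaustive enumeration validates the independent R dynamic program", {
  set.seed(21)
  alpha <- c("A", "C", "G", "T", "N", "R", "-", "Y")
  for (i in 1:60) {
    x <- randSeq(sample(1:6, 1), alpha)
    y <- randSeq(sample(1:6, 1), alpha)
    expect_equal(rDpAlignCost(x, y), enumAlignCost(x, y))
  }
})

test_that("the aligner matches the independent DP oracle on random pairs", {
  set.seed(22)
  alpha <- c("A", "C", "G", "T", "N", "W", "K")
  for (i in 1:200) {
    x <- randSeq(sample(1:12, 1), alpha)
    y <- randSeq(sample(1:12, 1), alpha)
    al <- alignPair(x, y)
    expect_equal(alignmentCost(al), rDpAlignCost(x, y))
  }
})

test_that("alignment invariants hold on random pairs", {
  set.seed(23)
  for (i in 1:40) {
    x <- randSeq(sample(4:20, 1))
    y <- mutateSeq(randSeq(nchar(x)), 3)
    al <- alignPair(x, y)
    g <- gappedStrings(al)
    ## gap stripping recovers the inputs
    expect_equal(gsub("-", "", g[[1]]), x)
    expect_equal(gsub("-", "", g[[2]]), y)
    ## no gap-vs-gap column
    cols <- cbind(strsplit(g[[1]], "")[[1]], strsplit(g[[2]], "")[[1]])
    expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
    ## cost identities
    expect_equal(alignmentCost(al), sequenceDistance(g[[1]], g[[2]]))
    expect_equal(alignmentCost(al), alignmentCost(alignPair(y, x)))
    ## upper bound for equal-length inputs: the as-given column distance
    expect_lte(alignmentCost(al), sequenceDistance(x, y))
  }
})

test_that("identity alignments are gapless with zero cost", {
  x <- "ACGTRWMKSYDVHBN"
  al <- alignPair(x, x)
  expect_equal(alignmentCost(al), 0L)
  expect_equal(al@ops, strrep("M", nchar(x)))
})

test_that("an extra residue is aligned to one gap column", {
  al <- alignPair("ACGT", "ACGGT")
  expect_equal(alignmentCost(al), 4L)
  g <- gappedStrings(al)
  xs <- strsplit(g[[1]], "")[[1]]
  ys <- strsplit(g[[2]], "")[[1]]
  expect_equal(sum(xs == "-"), 1L)
  expect_equal(sum(ys == "-"), 0L)
  expect_equal(ys[xs == "-"], "G")
})

test_that("alignment is deterministic, including under ties", {
  a1 <- alignPair("AAAA", "AA")
  a2 <- alignPair("AAAA", "AA")
  expect_identical(a1, a2)
  set.seed(24)
  for (i in 1:10) {
    x <- randSeq(8)
    y <- randSeq(8)
    expect_identical(alignPair(x, y), alignPair(x, y))
  }
})

test_that("a band wide enough for the edits reproduces the full matrix", {
  set.seed(25)
  x <- randSeq(300)
  y <- mutateSeq(x, 4)
  ## delete a short stretch so lengths differ
  y <- paste0(substr(y, 1, 150), substr(y, 154, 300))
  expect_equal(alignmentCost(alignPair(x, y, band = 30L)),
               alignmentCost(alignPair(x, y)))
})

test_that("empty sequences are rejected", {
  expect_error(alignPair("", "ACGT"), "empty")
  expect_error(alignPair("ACGT", ""), "empty")
})

test_that("homolog ranking sorts by cost with input-order tie-breaking", {
  set.seed(26)
  q <- randSeq(30)
  db <- c(far = mutateSeq(q, 6), near = mutateSeq(q, 1),
          same = q, mid = mutateSeq(q, 3))
  hits <- rankHomologs(q, db)
  ## oracle: sort brute-force costs with index tie-break
  costs <- vapply(db, function(s) rDpAlignCost(q, s), numeric(1))
  ord <- order(costs, seq_along(costs))
  expect_equal(hits$subjectId, names(db)[ord])
  expect_equal(hits$cost, unname(as.integer(costs[ord])))
  expect_equal(hits$rank, seq_along(db))
  expect_equal(hits$subjectId[1], "same")
  expect_equal(hits$cost[1], 0L)
})

test_that("equal-cost subjects rank in input order", {
  q <- "ACGTACGT"
  db <- c(b1 = "ACGTACGA", b2 = "ACGTACGA", b3 = "ACGTACGT")
  hits <- rankHomologs(q, db)
  expect_equal(hits$subjectId, c("b3", "b1", "b2"))
  expect_error(rankHomologs(q, character(0)), "at least one")
})
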