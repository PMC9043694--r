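test_that("the symbol table encodes the four-level hierarchy", {
  tab <- latticeSymbols()
  expect_equal(nrow(tab), 16L)
  expect_equal(as.integer(table(tab$level)), c(4L, 6L, 5L, 1L))
  ## base sets at the same level are pairwise distinct
  for (lv in 1:4) {
    sets <- tab$bases[tab$level == lv]
    expect_equal(anyDuplicated(sets), 0L)
  }
  expect_equal(latticeLevel(c("A", "Y", "-", "N")), c(1L, 2L, 3L, 4L))
  expect_equal(latticeBases("D"), c("A", "G", "T"))
  expect_equal(latticeBases("-"), "-")
})

test_that("generalization and distance reproduce the printed examples", {
  expect_equal(generalizeSymbols("C", "A"), "M")
  expect_equal(generalizeSymbols("T", "-"), "N")
  expect_equal(generalizeSymbols("A", "R"), "R")
  expect_equal(generalizeSymbols("A", "A"), "A")
  expect_equal(generalizeSymbols("R", "Y"), bruteGeneralize("R", "Y"))
  expect_equal(generalizeSymbols("R", "Y"), "N")
  expect_equal(symbolDistance("C", "C"), 0L)
  expect_equal(symbolDistance("C", "A"), 2L)
  expect_equal(symbolDistance("T", "-"), 4L)
  expect_equal(symbolDistance("A", "R"), 1L)
})

test_that("lattice algebra holds exhaustively over all 256 symbol pairs", {
  syms <- latticeSymbols()$code
  for (a in syms) {
    for (b in syms) {
      g <- generalizeSymbols(a, b)
      ## brute-force minimal-superset oracle
      expect_identical(g, bruteGeneralize(a, b))
      ## soundness: bases(g) contains bases(a) union bases(b)
      un <- union(latticeBases(a), latticeBases(b))
      expect_true(all(un %in% latticeBases(g)))
      ## minimality: no strictly lower-level symbol contains the union
      for (s in syms)
        if (latticeLevel(s) < latticeLevel(g))
          expect_false(all(un %in% latticeBases(s)))
      ## monotone level
      expect_gte(latticeLevel(g), max(latticeLevel(a), latticeLevel(b)))
      ## decomposition identity
      d <- symbolDistance(a, b)
      expect_identical(d, symbolDistance(a, g) + symbolDistance(b, g))
      ## symmetry, commutativity, zero-iff-equal
      expect_identical(d, symbolDistance(b, a))
      expect_identical(g, generalizeSymbols(b, a))
      expect_identical(d == 0L, a == b)
    }
  }
})

test_that("sequence distance and pair obfuscation match the worked example", {
  expect_equal(sequenceDistance("CCTGTAAA", "CA-GTRAA"), 7L)
  ob <- obfuscatePair("CCTGTAAA", "CA-GTRAA")
  expect_equal(ob$generalized, "CMNGTRAA")
  expect_equal(ob$cost, 7L)
  expect_equal(ob$events$column, c(2L, 3L, 6L))
  expect_equal(ob$events$generalized, c("M", "N", "R"))
  expect_equal(ob$events$cost, c(2L, 4L, 1L))
})

test_that("pair obfuscation is the identity on equal sequences", {
  x <- "ACGTRWMKSYDVHB-N"
  ob <- obfuscatePair(x, x)
  expect_equal(ob$generalized, x)
  expect_equal(ob$cost, 0L)
  expect_equal(nrow(ob$events), 0L)
})

test_that("sequence distance equals the column-wise oracle on random pairs", {
  set.seed(11)
  alpha <- c("A", "C", "G", "T", "R", "Y", "N", "-")
  for (i in 1:25) {
    x <- randSeq(50, alpha)
    y <- randSeq(50, alpha)
    expect_equal(sequenceDistance(x, y), oracleSeqDist(x, y))
    expect_equal(sequenceDistance(x, y), sequenceDistance(y, x))
    expect_equal(obfuscatePair(x, y)$cost, sequenceDistance(x, y))
  }
})

test_that("lowercase is upcased and invalid input is named precisely", {
  expect_equal(generalizeSymbols("c", "a"), "M")
  expect_equal(sequenceDistance("ccTGtaaa", "CA-GTRAA"), 7L)
  expect_error(sequenceDistance("ACGU", "ACGT"), "RNA base 'U'.*position 4")
  expect_error(latticeLevel("Z"), "invalid symbol 'Z'")
  expect_error(symbolDistance("A", "X"), "invalid symbol 'X'")
  expect_error(sequenceDistance("ACG", "ACGT"), "3 and 4")
})
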