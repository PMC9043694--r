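test_that("two sequences form a single pair cluster equal to pair obfuscation", {
  ds <- c(a = "ACGTACGTAA", b = "ACGTTCGTAA")
  res <- iterMegablast(ds, k = 2, seed = 1)
  expect_equal(nClusters(res), 1L)
  expect_equal(clusterSizes(res), 2L)
  cl <- clusterRecords(res)[[1]]
  al <- alignPair(ds[[cl@memberIds[1]]], ds[[cl@memberIds[2]]])
  ob <- obfuscatePair(al@leftGapped, al@rightGapped)
  expect_equal(cl@generalizedSeq, ob$generalized)
  expect_equal(cl@totalDistance, ob$cost)
})

test_that("three sequences form one triple via chained double obfuscation", {
  ## equal lengths, few substitutions: the optimal alignments are gapless,
  ## so the chained fold must equal the column-wise three-way lattice join
  set.seed(41)
  ds <- mutantFamily(3, 40, nsub = 2)
  res <- iterMegablast(ds, k = 2, seed = 5)
  expect_equal(clusterSizes(res), 3L)
  cl <- clusterRecords(res)[[1]]
  cols <- do.call(rbind, strsplit(unname(ds[cl@memberIds]), ""))
  join3 <- vapply(seq_len(ncol(cols)), function(j)
    bruteGeneralize(bruteGeneralize(cols[1, j], cols[2, j]), cols[3, j]),
    character(1))
  expect_equal(cl@generalizedSeq, paste(join3, collapse = ""))
  ## per-member distances measured against the final generalized sequence
  expect_equal(unname(cl@perMemberDistance),
               vapply(cl@memberIds, function(m)
                 oracleSeqDist(ds[[m]], cl@generalizedSeq), numeric(1),
                 USE.NAMES = FALSE))
})

test_that("exact duplicate pairs are always clustered together at cost zero", {
  base <- c("ACGTACGTACGTACGT", "TTGCAATTGGCCAATT", "GGGTTTAAACCCGGGA")
  ds <- setNames(rep(base, each = 2),
                 c("a1", "a2", "b1", "b2", "c1", "c2"))
  for (seed in 1:10) {
    res <- iterMegablast(ds, k = 2, seed = seed)
    expect_equal(sort(clusterSizes(res)), rep(2L, 3))
    expect_equal(unname(totalDistances(res)), rep(0L, 3))
    for (cl in clusterRecords(res))
      expect_equal(substr(cl@memberIds[1], 1, 1),
                   substr(cl@memberIds[2], 1, 1))
  }
})

test_that("partition, cluster sizes and anonymity degree hold across seeds", {
  set.seed(42)
  for (trial in 1:60) {
    n <- sample(2:15, 1)
    ds <- mutantFamily(n, 30, nsub = 2)
    res <- iterMegablast(ds, k = 2, seed = trial)
    expect_true(methods::validObject(res))
    members <- unlist(memberIds(res))
    expect_setequal(members, names(ds))
    expect_equal(length(members), n)
    sizes <- clusterSizes(res)
    expect_gte(min(sizes), 2L)
    expect_equal(sum(sizes == 3L), as.integer(n %% 2 == 1))
    expect_true(all(sizes %in% c(2L, 3L)))
    doa <- degreeOfAnonymity(res)
    expKmin <- if (n == 3L) 3L else 2L
    expect_equal(doa$kMin, expKmin)
    expect_equal(doa$reidentificationBound, 1 / expKmin)
  }
})

test_that("identical input, k and seed give byte-identical results", {
  set.seed(43)
  ds <- mutantFamily(9, 35, nsub = 3)
  r1 <- iterMegablast(ds, k = 2, seed = 7)
  r2 <- iterMegablast(ds, k = 2, seed = 7)
  expect_identical(r1, r2)
})

test_that("generalization is sound end to end, including indels and Ns", {
  cfg <- simConfig(9, 80, substitutionRate = 0.05, indelRate = 0.02,
                   ambiguityRate = 0.03, seed = 13)
  ds <- simulateDataset(cfg)
  res <- iterMegablast(ds, k = 2, seed = 3)
  for (cl in clusterRecords(res)) {
    gCols <- strsplit(cl@generalizedSeq, "")[[1]]
    for (m in seq_along(cl@alignedMembers)) {
      mCols <- strsplit(cl@alignedMembers[[m]], "")[[1]]
      for (j in seq_along(gCols))
        expect_true(all(ORACLE_BASES[[mCols[j]]] %in%
                        ORACLE_BASES[[gCols[j]]]))
      ## projection recovers the input residues
      expect_equal(gsub("-", "", cl@alignedMembers[[m]]),
                   as.character(ds)[[cl@memberIds[m]]])
    }
  }
})

test_that("pair clusters satisfy the decomposition identity", {
  set.seed(44)
  ds <- mutantFamily(6, 50, nsub = 3)
  res <- iterMegablast(ds, k = 2, seed = 9)
  for (cl in clusterRecords(res)) {
    expect_equal(cl@totalDistance,
                 sequenceDistance(cl@alignedMembers[[1]],
                                  cl@alignedMembers[[2]]))
  }
})

test_that("k = 3 clustering produces k-anonymous sizes with one leftover", {
  set.seed(45)
  ds <- mutantFamily(10, 30, nsub = 2)
  res <- iterMegablast(ds, k = 3, seed = 2)
  expect_equal(sort(clusterSizes(res)), c(3L, 3L, 4L))
  expect_equal(degreeOfAnonymity(res)$kMin, 3L)
  ds9 <- ds[1:9]
  res9 <- iterMegablast(ds9, k = 3, seed = 2)
  expect_equal(sort(clusterSizes(res9)), c(3L, 3L, 3L))
})

test_that("invalid clustering inputs are rejected", {
  expect_error(iterMegablast(c(a = "ACGT"), k = 2, seed = 1),
               "at least k = 2")
  expect_error(iterMegablast(c(a = "ACGT", a = "ACGG"), k = 2, seed = 1),
               "unique")
  expect_error(iterMegablast(c(a = "ACGT", b = "ACGG"), k = 1, seed = 1),
               "at least 2")
  expect_error(obfuscateCluster(c(a = "ACGT")), "at least 2")
  expect_error(obfuscateCluster(c(a = "ACGT", b = "ACG"), aligned = TRUE),
               "equal length")
})

test_that("the seeded draw does not disturb the caller's RNG stream", {
  set.seed(46)
  before <- runif(1)
  set.seed(46)
  invisible(iterMegablast(c(a = "ACGTAC", b = "ACGTAA"), seed = 99))
  expect_identical(runif(1), before)
})
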