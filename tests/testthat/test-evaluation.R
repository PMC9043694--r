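test_that("deterministic methods report zero spread regardless of repeats", {
  set.seed(61)
  ds <- mutantFamily(8, 25, nsub = 2)
  ev <- evaluateMethods(ds, methods = c("mwm", "greedy"), repeats = 10,
                        seed = 1)
  expect_equal(ev$repeats, c(1L, 1L))
  expect_equal(ev$sdPerSequence, c(0, 0))
  expect_equal(ev$sdPerCluster, c(0, 0))
  ev2 <- evaluateMethods(ds, methods = c("mwm", "greedy"), repeats = 3,
                         seed = 999)
  expect_equal(ev$meanPerSequence, ev2$meanPerSequence)
})

test_that("a duplicates dataset scores zero under every similarity-aware method", {
  ds <- setNames(rep(c("ACGTACGTAC", "TTGCAATTGG"), each = 2),
                 c("a1", "a2", "b1", "b2"))
  ev <- evaluateMethods(ds, methods = c("itermegablast", "mwm", "greedy"),
                        repeats = 3, seed = 2)
  expect_equal(ev$meanPerSequence, rep(0, 3))
  expect_equal(ev$meanPerCluster, rep(0, 3))
})

test_that("report arithmetic is re-derivable from the written meta file", {
  set.seed(62)
  ds <- mutantFamily(7, 30, nsub = 3)
  res <- iterMegablast(ds, k = 2, seed = 11)
  rep1 <- resultReport(res)
  f <- tempfile(fileext = ".tsv")
  writeMetaInfo(res, f)
  rep2 <- reportFromMeta(readMetaInfo(f))
  expect_equal(rep2$nSequences, rep1$nSequences)
  expect_equal(rep2$nClusters, rep1$nClusters)
  expect_equal(rep2$totalDistance, rep1$totalDistance)
  expect_equal(rep2$avgPerSequence, rep1$avgPerSequence)
  expect_equal(rep2$avgPerCluster, rep1$avgPerCluster)
  ## the average-per-cluster identity holds by construction
  expect_equal(rep1$avgPerCluster,
               sum(totalDistances(res)) / nClusters(res))
  expect_equal(rep1$avgPerSequence,
               sum(perMemberDistances(res)) / length(ds))
})

test_that("the obfuscated FASTA round-trips and carries cluster metadata", {
  set.seed(63)
  ds <- mutantFamily(6, 40, nsub = 2)
  res <- mwmCluster(ds)
  f <- tempfile(fileext = ".fasta")
  writeObfuscatedFasta(res, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(length(back), nClusters(res))
  expect_equal(unname(as.character(back)),
               unname(as.character(generalizedSequences(res))))
  expect_true(all(grepl("method=mwm;k=2;members=", names(back))))
})

test_that("the size sweep is consistent with single evaluations", {
  set.seed(64)
  ds <- mutantFamily(8, 20, nsub = 2)
  sw <- sweepN(ds, c(4, 6, 8), methods = c("mwm", "greedy"),
               repeats = 2, seed = 3)
  expect_equal(nrow(sw), 6L)
  expect_equal(sw$n, rep(c(4, 6, 8), each = 2))
  ## the full-size row equals a direct evaluation
  ev <- evaluateMethods(ds, methods = c("mwm", "greedy"), repeats = 2,
                        seed = 3)
  full <- sw[sw$n == 8, names(ev)]
  rownames(full) <- NULL
  expect_equal(full, ev)
  ## matching dominates greedy at every size
  for (n in unique(sw$n))
    expect_lte(sw$meanPerSequence[sw$n == n & sw$method == "mwm"],
               sw$meanPerSequence[sw$n == n & sw$method == "greedy"])
})

test_that("evaluation inputs are validated", {
  ds <- c(a = "ACGTAC", b = "ACGTAA", c = "ACGTTT", d = "ACCTAA")
  expect_error(evaluateMethods(ds, methods = "hillclimb"),
               "unknown method")
  expect_error(evaluateMethods(ds, repeats = 0), "repeats")
  expect_error(evaluateMethods(ds, methods = c("itermegablast", "mwm"),
                               k = 3), "k = 2 only")
  expect_error(sweepN(ds, c(2, 10)), "exceeds dataset size")
})
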