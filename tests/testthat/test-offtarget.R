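test_that("mask-pair counts follow C(k,d) * 3^d and d=0 is the identity", {
  mp <- genMaskPairs(strrep("ACGT", 5), maxD = 1)   # k = 20
  expect_equal(sum(mp$d == 1), 60L)                 # 20 positions x 3
  mp <- genMaskPairs("ACG", maxD = 3)
  expect_equal(as.vector(table(mp$d)), c(1L, 9L, 27L, 27L))  # C(3,d)*3^d
  ident <- mp[mp$d == 0, ]
  expect_equal(applyMaskPairs("ACG", ident), "ACG")
  expect_error(genMaskPairs("ACG", maxD = 4), "0..k")
})

test_that("mask pairs enumerate each exact-distance neighbor exactly once", {
  q <- "ACGT"
  mp <- genMaskPairs(q, maxD = 4)
  for (d in 0:4) {
    got <- applyMaskPairs(q, mp[mp$d == d, ])
    expect_equal(sort(got), sort(oracleNeighborhood(q, d)))
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("neighbor counts against a toy space match the brute force", {
  sp <- encodeSeqSpace(c(chr1 = "ACGT"), k = 2)
  expect_equal(countSeqNeighbors(sp, "AC", maxD = 2)["AC", ],
               c(d0 = 1L, d1 = 0L, d2 = 2L))  # CG and GT at distance 2
  expect_equal(countSeqNeighbors(sp, "AA", maxD = 2)["AA", ],
               c(d0 = 0L, d1 = 1L, d2 = 2L))  # only AC at distance 1
  empty <- encodeSeqSpace(c(chr1 = ""), k = 2)
  expect_equal(unname(countSeqNeighbors(empty, c("AC", "GG"), maxD = 2)),
               matrix(0L, 2, 3))
})

test_that("count database stores exact two-strand occurrence counts", {
  db <- encodeCountDatabase(c(chr1 = "AAAA"), k = 2, b = 3)
  expect_equal(seqCount(db, c("AA", "TT")), c(3, 3))
  others <- setdiff(oracleAllKmers(2), c("AA", "TT"))
  expect_equal(seqCount(db, others), rep(0, length(others)))
  expect_error(encodeCountDatabase(c(chr1 = "AAAA"), k = 2, b = 1), ">= 2")
})

test_that("saturated counters overflow into the exact-count map", {
  # 8 A's = 7 AA windows; with b = 3 the cell saturates at 2^3-1 = 7
  db <- encodeCountDatabase(c(chr1 = strrep("A", 8)), k = 2, b = 3)
  expect_equal(seqCount(db, "AA"), 7)
  expect_length(db@overflowKeys, 2L)                   # AA and TT
  expect_equal(db@overflowCounts, c(7, 7))
  db2 <- encodeCountDatabase(c(chr1 = strrep("A", 30)), k = 2, b = 3)
  expect_equal(seqCount(db2, c("AA", "TT")), c(29, 29))
})

test_that("exact off-site profiles and lowercase marking", {
  # query planted once, one distance-1 neighbor planted twice; N separators
  # keep every other window out of the index
  q <- "AAACCCGG"
  nb <- "AGACCCGG"
  genome <- c(chr1 = paste(c(q, nb, nb), collapse = "NN"))
  db <- encodeCountDatabase(genome, k = 8, b = 3)
  res <- countOffSites(db, q, maxD = 3, mark = TRUE)
  expect_equal(res$n0, 1)
  expect_equal(res$n1, 2)
  expect_equal(res$totalOffSites, res$n1 + res$n2 + res$n3)
  expect_equal(res$offSiteCounts,
               paste(res$n0, res$n1, res$n2, res$n3, sep = "/"))
  marked <- res$neighbors[[1]]
  hit <- marked[marked$sequence == "AgACCCGG", ]
  expect_equal(hit$count, 2)
  expect_equal(hit$mismatches, 1L)
  # absent query in an empty genome: all zeros
  empty <- encodeCountDatabase(c(chr1 = ""), k = 8, b = 3)
  res0 <- countOffSites(empty, q)
  expect_equal(unlist(res0[c("n0", "n1", "n2", "n3")]),
               c(n0 = 0, n1 = 0, n2 = 0, n3 = 0))
})

test_that("both counters equal genome brute force; presence <= multiplicity", {
  set.seed(47)
  genome <- c(c1 = randomGenome(4000), c2 = randomGenome(2000))
  for (pam in c("", "NGG")) {
    sp <- encodeSeqSpace(genome, k = 6, pam = if (nzchar(pam)) pam)
    db <- encodeCountDatabase(genome, k = 6, b = 3,
                              pam = if (nzchar(pam)) pam)
    reads <- oracleReads(genome, 6, pam)
    queries <- c(sample(unique(reads), 15), "AAAAAA", "GCGCGC")
    for (qq in queries) {
      want <- oracleNeighborCounts(reads, qq, 3)
      expect_equal(unname(countSeqNeighbors(sp, qq, 3)[1, ]),
                   want$presence)
      prof <- countOffSites(db, qq, 3)
      expect_equal(unlist(prof[c("n0", "n1", "n2", "n3")], use.names = FALSE),
                   want$multiplicity)
      expect_true(all(want$presence <= want$multiplicity))
    }
  }
})

test_that("prefixed divide-and-conquer sums reproduce unprefixed counts", {
  set.seed(53)
  genome <- c(chr1 = randomGenome(20000))
  prefixes <- sortedPrefixesForTest(2)
  spFull <- encodeSeqSpace(genome, k = 8, pam = "NGG")
  dbFull <- encodeCountDatabase(genome, k = 8, b = 3, pam = "NGG")
  spSubs <- lapply(prefixes, function(p)
    encodeSeqSpace(genome, k = 8, pam = "NGG", prefix = p))
  dbSubs <- lapply(prefixes, function(p)
    encodeCountDatabase(genome, k = 8, b = 3, pam = "NGG", prefix = p))
  queries <- vapply(1:25, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""), "")
  expect_equal(countSeqNeighbors(spSubs, queries, 3),
               countSeqNeighbors(spFull, queries, 3))
  expect_equal(countOffSites(dbSubs, queries, 3),
               countOffSites(dbFull, queries, 3))
})

test_that("count databases round-trip through their gz format", {
  set.seed(61)
  db <- encodeCountDatabase(c(chr1 = strrep("A", 20), chr2 = randomGenome(900)),
                            k = 5, b = 2, pam = "NGG", genome = "toy")
  path <- tempfile(fileext = ".countdb.gz")
  saveCountDatabase(db, path)
  back <- loadCountDatabase(path)
  expect_identical(back@cells, db@cells)
  expect_identical(back@overflowKeys, db@overflowKeys)
  expect_identical(back@overflowCounts, db@overflowCounts)
  expect_identical(list(back@k, back@b, back@pam, back@genome),
                   list(5L, 2L, "NGG", "toy"))
  all5 <- oracleAllKmers(5)
  expect_equal(seqCount(back, all5), seqCount(db, all5))
  junk <- tempfile()
  writeLines("not a database", junk)
  expect_error(loadCountDatabase(junk), "bad magic")
})

test_that("site records annotate with their off-target profiles", {
  set.seed(59)
  genome <- c(chr1 = randomGenome(3000))
  sites <- sortToBed(scanGenome(genome, "XXXXXXNGG", outdir = tempfile(),
                                prefixLen = 2))
  db <- encodeCountDatabase(genome, k = 6, b = 3, pam = "NGG")
  ann <- annotateOffTargets(sites, db)
  md <- S4Vectors::mcols(ann)
  expect_equal(md$totalOffSites,
               md$n1mismatches + md$n2mismatches + md$n3mismatches)
  expect_equal(md$offSiteCounts,
               paste(md$n0mismatches, md$n1mismatches, md$n2mismatches,
                     md$n3mismatches, sep = "/"))
})
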