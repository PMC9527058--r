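# build a synthetic extended-BED database in memory
makeSiteDb <- function(n, seed = 1, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(5e6, n)
  n1 <- rpois(n, 0.5); n2 <- rpois(n, 3); n3 <- rpois(n, 10)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = 20),
                               strand = sample(c("+", "-"), n, TRUE))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("%d.1/Q%d", seq_len(n), seq_len(n)),
    score = 1L,
    spacer = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), ""),
    copyNumber = 1L + rpois(n, 0.2),
    percentGC = 5L * sample(0:20, n, TRUE),
    longestTandemT = sample(0:8, n, TRUE),
    n0mismatches = 1L, n1mismatches = n1, n2mismatches = n2,
    n3mismatches = n3, totalOffSites = n1 + n2 + n3,
    offSiteCounts = paste(1, n1, n2, n3, sep = "/"))
  gr
}

oracleBestN <- function(db, region, filters, keyCols, n) {
  keep <- rep(TRUE, length(db))
  md <- S4Vectors::mcols(db)
  for (f in filters) keep <- keep & f(db)
  ov <- IRanges::overlapsAny(db, region)
  cand <- which(keep & ov)
  ord <- do.call(order, c(lapply(keyCols, function(kc) kc(db)[cand]),
                          list(as.integer(GenomicRanges::seqnames(db))[cand],
                               GenomicRanges::start(db)[cand],
                               as.integer(GenomicRanges::strand(db))[cand])))
  cand[ord][seq_len(min(n, length(cand)))]
}

test_that("filters restrict and compose monotonically", {
  db <- makeSiteDb(2000, seed = 61)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e6))
  all <- queryDB(db, reg)
  f1 <- queryDB(db, reg, filters = "totalOffSites<=10")
  f2 <- queryDB(db, reg, filters = c("totalOffSites<=10", "percentGC:40-60"))
  f3 <- queryDB(db, reg, filters = c("totalOffSites<=10", "percentGC:40-60",
                                     "n1==0"))
  expect_true(length(all) >= length(f1))
  expect_true(length(f1) >= length(f2))
  expect_true(length(f2) >= length(f3))
  md <- S4Vectors::mcols(f3)
  expect_true(all(md$totalOffSites <= 10))
  expect_true(all(md$percentGC >= 40 & md$percentGC <= 60))
  expect_true(all(md$n1mismatches == 0))
  expect_error(queryDB(db, reg, filters = "bogusField<=3"), "unknown")
})

test_that("region overlap semantics require >= 1 bp and dedup the union", {
  db <- makeSiteDb(500, seed = 67)
  i <- which(as.character(GenomicRanges::seqnames(db)) == "chr1")[1]
  w <- GenomicRanges::start(db)[i]
  touching <- GenomicRanges::GRanges("chr1", IRanges::IRanges(w + 19, w + 50))
  disjoint <- GenomicRanges::GRanges("chr1", IRanges::IRanges(w + 20, w + 50))
  expect_true(recKeys(db[i]) %in% recKeys(queryDB(db, touching)))
  expect_false(recKeys(db[i]) %in% recKeys(queryDB(db, disjoint)))
  # two-region query equals the deduplicated union of single-region queries
  r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e6))
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e6, 5e6))
  both <- queryDB(db, c(r1, r2))
  expect_equal(sitesToKeys(both),
               sort(union(recKeys(queryDB(db, r1)), recKeys(queryDB(db, r2)))))
  # empty region list -> empty result
  expect_length(queryDB(db, GenomicRanges::GRanges()), 0L)
})

test_that("streaming BEST-n equals filter/full-sort/take-n", {
  db <- makeSiteDb(5000, seed = 71)
  reg <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                IRanges::IRanges(c(1, 1e6), c(4e6, 5e6)))
  got <- queryDB(db, reg, filters = c("percentGC:30-70", "n1<=1"),
                 sortKeys = c("totalOffSites:asc", "percentGC:desc"),
                 bestN = 12)
  md <- S4Vectors::mcols(got)
  for (r in 1:2) {
    ours <- which(md$region == r)
    want <- oracleBestN(
      db, reg[r],
      filters = list(
        function(d) S4Vectors::mcols(d)$percentGC >= 30 &
          S4Vectors::mcols(d)$percentGC <= 70,
        function(d) S4Vectors::mcols(d)$n1mismatches <= 1),
      keyCols = list(function(d) S4Vectors::mcols(d)$totalOffSites,
                     function(d) -S4Vectors::mcols(d)$percentGC),
      n = 12)
    expect_equal(S4Vectors::mcols(got)$name[ours],
                 S4Vectors::mcols(db)$name[want])
  }
  expect_error(queryDB(db, reg, bestN = 5), "sortKeys")
})

test_that("best-n selections are minimal under the sort key", {
  db <- makeSiteDb(3000, seed = 73)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e6))
  got <- queryDB(db, reg, sortKeys = "totalOffSites", bestN = 12)
  expect_lte(length(got), 12L)
  inReg <- queryDB(db, reg)
  excluded <- setdiff(recKeys(inReg), recKeys(got))
  exVals <- S4Vectors::mcols(inReg)$totalOffSites[
    recKeys(inReg) %in% excluded]
  expect_true(all(S4Vectors::mcols(got)$totalOffSites <= min(exVals)))
})

test_that("the published six-filter selection returns exactly the planted set", {
  # cluster db: decoys violate one predicate each, targets satisfy all six
  n <- 400
  set.seed(79)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1000, by = 12000,
                                                    length.out = n),
                                                width = sample(3000:11000, n,
                                                               TRUE)))
  md <- S4Vectors::DataFrame(
    name = sprintf("%d.20/C%d", 1:n, 1:n),
    score = 20L,
    clusterSize = sample(20:40, n, TRUE),
    totalOffSites = sample(0:30, n, TRUE),
    n1mismatches = 0L,
    percentGC = sample(seq(40L, 60L, 5L), n, TRUE),
    longestTandemT = sample(0:3, n, TRUE))
  breaker <- sample(1:6, n, replace = TRUE)
  md$totalOffSites[breaker == 1] <- sample(31:99, sum(breaker == 1), TRUE)
  md$percentGC[breaker == 2] <- sample(c(0:35, 65:100), sum(breaker == 2), TRUE)
  md$n1mismatches[breaker == 3] <- sample(1:5, sum(breaker == 3), TRUE)
  md$clusterSize[breaker == 4] <- sample(2:19, sum(breaker == 4), TRUE)
  md$longestTandemT[breaker == 5] <- sample(4:9, sum(breaker == 5), TRUE)
  keepWide <- breaker != 6
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(GenomicRanges::start(gr),
                     width = ifelse(keepWide, sample(500:5000, n, TRUE),
                                    sample(5001:9000, n, TRUE))))
  mustPass <- sample(1:n, 25)
  md$totalOffSites[mustPass] <- sample(0:30, 25, TRUE)
  md$percentGC[mustPass] <- sample(seq(40L, 60L, 5L), 25, TRUE)
  md$n1mismatches[mustPass] <- 0L
  md$clusterSize[mustPass] <- sample(20:40, 25, TRUE)
  md$longestTandemT[mustPass] <- sample(0:3, 25, TRUE)
  gr[mustPass] <- GenomicRanges::resize(gr[mustPass],
                                        sample(500:5000, 25, TRUE))
  S4Vectors::mcols(gr) <- md
  filters <- c("totalOffSites<=30", "percentGC:40-60", "n1==0",
               "clusterSize>=20", "longestTandemT<4", "span<=5000")
  got <- queryDB(gr, GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(1, 6e6)),
                 filters = filters)
  want <- which(md$totalOffSites <= 30 & md$percentGC >= 40 &
                  md$percentGC <= 60 & md$n1mismatches == 0 &
                  md$clusterSize >= 20 & md$longestTandemT < 4 &
                  GenomicRanges::width(gr) <= 5000)
  expect_setequal(S4Vectors::mcols(got)$name, md$name[want])
  expect_true(all(mustPass %in% match(S4Vectors::mcols(got)$name, md$name)))
})
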