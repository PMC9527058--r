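pat20 <- "XXXXXXXXXXXXXXXXXXXXNGG"

clusterPipeline <- function(sim, window = 10000, minCopies = 2) {
  sites <- sortToBed(scanGenome(sim$genome, pat20, outdir = tempfile(),
                                prefixLen = 2))
  callClusters(sites, window = window, minCopies = minCopies)
}

test_that("a planted 5-copy cluster within 3 kb is recovered exactly", {
  plan <- fixturePlan(c(chr1 = 12000), seed = 101,
                      plants = list(list(spacer = "ACGTTGCAGGATCCTAGCAA",
                                         copies = 5, chrom = "chr1",
                                         region = c(2000, 5000))))
  sim <- simulateGenome(plan)
  cl <- clusterPipeline(sim)
  expect_length(cl, 1L)
  md <- S4Vectors::mcols(cl)
  expect_equal(md$clusterSize, 5L)
  expect_equal(md$blockCount, 5L)
  expect_equal(md$spacer, "ACGTTGCAGGATCCTAGCAA")
  expect_equal(length(strsplit(md$blockSizes, ",")[[1]]), 5L)
  expect_true(all(as.integer(strsplit(md$blockSizes, ",")[[1]]) == 20L))
  expect_lte(GenomicRanges::width(cl), 3020L)
  # blocks tile exactly the positions reported by sortToBed
  sites <- sortToBed(scanGenome(sim$genome, pat20, outdir = tempfile(),
                                prefixLen = 2))
  copies <- sites[S4Vectors::mcols(sites)$spacer == md$spacer]
  rel <- sort(GenomicRanges::start(copies)) - GenomicRanges::start(cl)
  expect_equal(as.integer(strsplit(md$chromStarts, ",")[[1]]), rel)
})

test_that("a copy on another chromosome breaks exclusivity", {
  spacer <- "ACGTTGCAGGATCCTAGCAA"
  plan <- fixturePlan(c(chr1 = 9000, chr2 = 3000), seed = 103,
                      plants = list(
                        list(spacer = spacer, copies = 5, chrom = "chr1",
                             region = c(1000, 4000)),
                        list(spacer = spacer, copies = 1, chrom = "chr2")))
  sim <- simulateGenome(plan)
  cl <- clusterPipeline(sim)
  expect_false(spacer %in% S4Vectors::mcols(cl)$spacer)
})

test_that("the span rule is containment within the window", {
  spacer <- "TGCAACGTAGGATCGTTACC"
  plan <- fixturePlan(c(chr1 = 20000), seed = 107,
                      plants = list(
                        list(spacer = spacer,
                             positions = data.frame(
                               chrom = "chr1",
                               pos = c(1000, 4000, 7000, 10000, 12980),
                               strand = "+"))))
  sim <- simulateGenome(plan)   # span = 12980+19 - 1000 + 1 = 12000
  expect_length(clusterPipeline(sim, window = 10000), 0L)
  cl <- clusterPipeline(sim, window = 15000)
  expect_length(cl, 1L)
  expect_equal(S4Vectors::mcols(cl)$clusterSize, 5L)
  expect_equal(GenomicRanges::width(cl), 12000L)
})

test_that("cluster calls are monotone in minCopies and window", {
  set.seed(109)
  spacers <- vapply(1:6, function(i) paste(
    sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), "")
  copies <- c(2L, 3L, 5L, 12L, 24L, 30L)
  plants <- lapply(seq_along(spacers), function(i)
    list(spacer = spacers[i], copies = copies[i], chrom = paste0("c", i),
         region = c(500, 500 + c(1000, 2000, 4000, 6000, 8000, 9000)[i])))
  lens <- setNames(rep(12000, 6), paste0("c", 1:6))
  sim <- simulateGenome(fixturePlan(lens, seed = 113, plants = plants,
                                    maxRetries = 100))
  sites <- sortToBed(scanGenome(sim$genome, pat20, outdir = tempfile(),
                                prefixLen = 2))
  nClusters <- vapply(c(2L, 4L, 12L, 24L), function(m)
    length(callClusters(sites, window = 10000, minCopies = m)), integer(1))
  expect_equal(nClusters, c(6L, 4L, 3L, 2L))
  expect_true(all(diff(nClusters) <= 0))
  # non-decreasing in window
  nW <- vapply(c(2000, 5000, 10000), function(w)
    length(callClusters(sites, window = w, minCopies = 2L)), integer(1))
  expect_true(all(diff(nW) >= 0))
})

test_that("degenerate cluster parameters are rejected", {
  sites <- sortToBed(scanGenome(c(chr1 = "AAACGGTTT"), "XXXNGG",
                                outdir = tempfile(), prefixLen = 2))
  expect_error(callClusters(sites, window = 0), "window")
  expect_error(callClusters(sites, minCopies = 1), "minCopies")
})
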