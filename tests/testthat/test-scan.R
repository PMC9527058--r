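test_that("single-site genomes scan to the expected strand and position", {
  res <- scanGenome(c(chr1 = "AAACGG"), "XXXNGG", outdir = tempfile(),
                    prefixLen = 3)
  sites <- sortToBed(res)
  expect_length(sites, 1L)
  expect_equal(S4Vectors::mcols(sites)$spacer, "AAA")
  expect_equal(as.character(GenomicRanges::strand(sites)), "+")
  expect_equal(GenomicRanges::start(sites), 1L)   # BED: chr1 0 3
  expect_equal(GenomicRanges::end(sites), 3L)

  # spacer window containing an ambiguous base is skipped
  res <- scanGenome(c(chr1 = "AANCGG"), "XXXNGG", outdir = tempfile(),
                    prefixLen = 3)
  expect_length(res$binFiles, 0L)

  # minus strand: revcomp read "AAACGG" matches; spacer maps to plus 4..6
  res <- scanGenome(c(chr1 = "CCGTTT"), "XXXNGG", outdir = tempfile(),
                    prefixLen = 3)
  recs <- readBinFile(res$binFiles[[1L]])
  expect_equal(recs$pos, -4L)
  sites <- sortToBed(res)
  expect_equal(S4Vectors::mcols(sites)$spacer, "AAA")
  expect_equal(as.character(GenomicRanges::strand(sites)), "-")
  expect_equal(GenomicRanges::start(sites) - 1L, 3L)  # BED: chr1 3 6
})

test_that("records are routed to bins by spacer prefix", {
  genome <- c(chr1 = paste0("ATGAGCTTTTTTTTTTTTTTAGG",
                            "CCCCCCCCCCCCCCCCCCCCTGG"))
  res <- scanGenome(genome, "XXXXXXXXXXXXXXXXXXXXNGG", outdir = tempfile())
  expect_true("ATGAGC" %in% names(res$binFiles))
  recs <- readBinFile(res$binFiles[["ATGAGC"]])
  expect_true(all(startsWith(nucKeyDecode(recs$key, k = 20), "ATGAGC")))
})

test_that("bin-file round trip is exact and corruption is detected", {
  set.seed(3)
  recs <- data.frame(
    key = nucKeyEncode(vapply(1:1000, function(i)
      paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""), "")),
    chrID = sample(0:5, 1000, TRUE),
    pos = sample(c(-1e6:-1, 1:1e6), 1000),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bin")
  writeBinFile(recs, path)
  expect_equal(file.info(path)$size, 16 * 1000)
  expect_equal(readBinFile(path), recs, ignore_attr = TRUE)

  # write-read-write reproduces the file byte for byte
  path2 <- tempfile(fileext = ".bin")
  writeBinFile(readBinFile(path), path2)
  expect_identical(readBin(path, "raw", 16000), readBin(path2, "raw", 16000))

  writeBin(as.raw(1:15), truncated <- tempfile())
  expect_error(readBinFile(truncated), "not a multiple")
})

test_that("first-base partitions are disjoint and union to the full run", {
  set.seed(21)
  genome <- c(c1 = randomGenome(3000), c2 = randomGenome(1500))
  full <- sortToBed(scanGenome(genome, "XXXXXXNGG", outdir = tempfile(),
                               prefixLen = 2))
  parts <- lapply(c("A", "C", "G", "T"), function(b)
    sortToBed(scanGenome(genome, "XXXXXXNGG", outdir = tempfile(),
                         prefixLen = 2, firstBase = b)))
  partKeys <- lapply(parts, recKeys)
  expect_equal(sum(lengths(partKeys)), length(full))       # disjoint
  expect_equal(sort(unlist(partKeys)), sitesToKeys(full))  # same records
  cnFull <- setNames(S4Vectors::mcols(full)$copyNumber, recKeys(full))
  for (p in parts)
    expect_equal(S4Vectors::mcols(p)$copyNumber,
                 unname(cnFull[recKeys(p)]))
})

test_that("scan equals the naive two-strand oracle on random genomes", {
  set.seed(9)
  genome <- c(chrA = randomGenome(8000), chrB = randomGenome(5000))
  got <- sortToBed(scanGenome(genome, "XXXXXNGG", outdir = tempfile(),
                              prefixLen = 2))
  want <- oracleScan(genome, "XXXXXNGG")
  expect_equal(sitesToKeys(got),
               siteKeys(want$chrom, want$pos, want$spacer))

  # every emitted site's window re-read from the genome matches the pattern
  sp <- S4Vectors::mcols(got)$spacer
  minus <- as.character(GenomicRanges::strand(got)) == "-"
  chrom <- as.character(GenomicRanges::seqnames(got))
  s <- GenomicRanges::start(got)
  readBack <- ifelse(minus,
    vapply(seq_along(got), function(i) oracleRevcompStr(
      substr(genome[[chrom[i]]], s[i], s[i] + 4L)), ""),
    substring(unname(genome[chrom]), s, s + 4L))
  expect_equal(readBack, sp)
  pamRead <- ifelse(minus,
    vapply(seq_along(got), function(i) oracleRevcompStr(
      substr(genome[[chrom[i]]], s[i] - 3L, s[i] - 1L)), ""),
    substring(unname(genome[chrom]), s + 5L, s + 7L))
  expect_true(all(substr(pamRead, 2L, 3L) == "GG"))
})

test_that("gzipped FASTA input and chromosome tables round-trip", {
  set.seed(5)
  genome <- c(chr1 = randomGenome(400), chr2 = randomGenome(300))
  fa <- tempfile(fileext = ".fa.gz")
  con <- gzfile(fa, "w")
  writeLines(c(">chr1 descriptive text", genome[[1]],
               ">chr2", genome[[2]]), con)
  close(con)
  res <- scanGenome(fa, "XXXXNGG", outdir = tempfile(), prefixLen = 2)
  expect_equal(res$chromTable$name, c("chr1", "chr2"))  # description dropped
  expect_equal(res$chromTable$chrID, c(0L, 1L))
  tab <- readChromTable(file.path(res$outdir, "ref.txt"))
  expect_equal(tab, res$chromTable, ignore_attr = TRUE)
})
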