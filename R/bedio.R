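# Extended BED I/O following the one-copy and multicopy AutoSql schemas:
# one-copy: chrom chromStart chromEnd name score strand thickStart thickEnd
#   reserved n0mismatches n1mismatches n2mismatches n3mismatches
#   totalOffSites offSiteCounts spacerSeq percentGC longestTandemT
# multicopy adds blockCount blockSizes chromStarts clusterSize between
#   reserved and n0mismatches.

offCols <- c("n0mismatches", "n1mismatches", "n2mismatches", "n3mismatches",
             "totalOffSites", "offSiteCounts")

offColumn <- function(gr, col, n) {
  v <- mcols(gr)[[col]]
  if (is.null(v)) {
    if (col == "offSiteCounts") rep("0/0/0/0", n) else rep(0L, n)
  } else v
}

#' Write and read extended BED site databases
#'
#' Writes one tab-separated line per site record in the one-copy extended
#' BED column order (18 columns: BED9 with `thickStart`/`thickEnd` equal to
#' the interval, `reserved` 0, then the off-target profile `n0mismatches` ..
#' `totalOffSites`, the slash-separated `offSiteCounts` string, the spacer
#' sequence, GC percent and longest T run). Records lacking off-target
#' annotation are written with zero profiles. `readSitesBed()` inverts the
#' format bit-exactly into the [sortToBed()] GRanges representation.
#'
#' @param sites GRanges from [sortToBed()] (optionally annotated by
#'   [annotateOffTargets()]).
#' @param path output path.
#' @param chromTable optional chromosome table to restore seqlengths on read.
#' @return `writeSitesBed`: the path, invisibly; `readSitesBed`: a GRanges.
#' @export
writeSitesBed <- function(sites, path) {
  n <- length(sites)
  df <- data.frame(
    chrom = as.character(seqnames(sites)),
    chromStart = start(sites) - 1L,
    chromEnd = end(sites),
    name = mcols(sites)$name,
    score = mcols(sites)$score,
    strand = as.character(strand(sites)),
    thickStart = start(sites) - 1L,
    thickEnd = end(sites),
    reserved = rep(0L, n),
    stringsAsFactors = FALSE)
  for (col in offCols) df[[col]] <- offColumn(sites, col, n)
  df$spacerSeq <- mcols(sites)$spacer
  df$percentGC <- mcols(sites)$percentGC
  df$longestTandemT <- mcols(sites)$longestTandemT
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeSitesBed
#' @export
readSitesBed <- function(path, chromTable = NULL) {
  cols <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
            "thickStart", "thickEnd", "reserved", offCols,
            "spacerSeq", "percentGC", "longestTandemT")
  df <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                   colClasses = c("character", rep("integer", 2),
                                  "character", "integer", "character",
                                  rep("integer", 3), rep("integer", 4),
                                  "integer", "character", "character",
                                  rep("integer", 2)))
  gr <- GRanges(df$chrom, IRanges(df$chromStart + 1L, df$chromEnd),
                strand = df$strand)
  info <- parseSiteNames(df$name)
  mcols(gr) <- DataFrame(
    name = df$name, score = df$score, spacer = df$spacerSeq,
    copyNumber = info$copy, percentGC = df$percentGC,
    longestTandemT = df$longestTandemT,
    n0mismatches = df$n0mismatches, n1mismatches = df$n1mismatches,
    n2mismatches = df$n2mismatches, n3mismatches = df$n3mismatches,
    totalOffSites = df$totalOffSites, offSiteCounts = df$offSiteCounts)
  if (!is.null(chromTable))
    seqlengths(gr) <- setNames(chromTable$length, chromTable$name)[seqlevels(gr)]
  gr
}

#' Write and read extended BED cluster databases
#'
#' Blocked (BED12-style) records in the multicopy extended BED column order
#' (22 columns): BED9, `blockCount`/`blockSizes`/`chromStarts` describing
#' every copy of the spacer within the cluster span, `clusterSize`, then the
#' same off-target / spacer-property tail as the one-copy schema.
#'
#' @param clusters GRanges from [callClusters()].
#' @param path output path.
#' @param chromTable optional chromosome table to restore seqlengths on read.
#' @return `writeClustersBed`: the path, invisibly; `readClustersBed`: a
#'   GRanges.
#' @export
writeClustersBed <- function(clusters, path) {
  n <- length(clusters)
  df <- data.frame(
    chrom = as.character(seqnames(clusters)),
    chromStart = start(clusters) - 1L,
    chromEnd = end(clusters),
    name = mcols(clusters)$name,
    score = mcols(clusters)$score,
    strand = as.character(strand(clusters)),
    thickStart = start(clusters) - 1L,
    thickEnd = end(clusters),
    reserved = rep(0L, n),
    blockCount = mcols(clusters)$blockCount,
    blockSizes = mcols(clusters)$blockSizes,
    chromStarts = mcols(clusters)$chromStarts,
    clusterSize = mcols(clusters)$clusterSize,
    stringsAsFactors = FALSE)
  for (col in offCols) df[[col]] <- offColumn(clusters, col, n)
  df$spacerSeq <- mcols(clusters)$spacer
  df$percentGC <- mcols(clusters)$percentGC
  df$longestTandemT <- mcols(clusters)$longestTandemT
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeClustersBed
#' @export
readClustersBed <- function(path, chromTable = NULL) {
  cols <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
            "thickStart", "thickEnd", "reserved", "blockCount", "blockSizes",
            "chromStarts", "clusterSize", offCols,
            "spacerSeq", "percentGC", "longestTandemT")
  df <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                   colClasses = c("character", rep("integer", 2),
                                  "character", "integer", "character",
                                  rep("integer", 3), "integer",
                                  rep("character", 2), "integer",
                                  rep("integer", 4), "integer", "character",
                                  "character", rep("integer", 2)))
  gr <- GRanges(df$chrom, IRanges(df$chromStart + 1L, df$chromEnd),
                strand = df$strand)
  mcols(gr) <- DataFrame(
    name = df$name, score = df$score, blockCount = df$blockCount,
    blockSizes = df$blockSizes, chromStarts = df$chromStarts,
    clusterSize = df$clusterSize, spacer = df$spacerSeq,
    percentGC = df$percentGC, longestTandemT = df$longestTandemT,
    n0mismatches = df$n0mismatches, n1mismatches = df$n1mismatches,
    n2mismatches = df$n2mismatches, n3mismatches = df$n3mismatches,
    totalOffSites = df$totalOffSites, offSiteCounts = df$offSiteCounts)
  if (!is.null(chromTable))
    seqlengths(gr) <- setNames(chromTable$length, chromTable$name)[seqlevels(gr)]
  gr
}
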