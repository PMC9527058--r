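#' Call multicopy gRNA clusters
#'
#' A spacer forms a cluster when it has at least `minCopies` genome-wide
#' copies, ALL of them on one chromosome, and the total span from the first
#' copy's start to the last copy's end is at most `window`. The
#' "exclusively within a window" rule is strict: a spacer with any copy on
#' another chromosome, or spread wider than the window, is rejected
#' entirely. Copies may mix strands; the record takes the leftmost copy's
#' strand (the schema has a single strand slot). Each qualifying spacer
#' yields one blocked record whose blocks are its copies in ascending
#' coordinate order.
#'
#' @param sites GRanges from [sortToBed()] (must carry `spacer` and
#'   `copyNumber`).
#' @param window maximum cluster span in bp (default 10000).
#' @param minCopies minimum copy number (default 2).
#' @return a GRanges with metadata columns `name`, `score`, `blockCount`,
#'   `blockSizes`, `chromStarts` (comma-separated, starts relative to
#'   `chromStart`), `clusterSize`, `spacer`, `percentGC`, `longestTandemT`,
#'   plus any off-target profile columns present on the input.
#' @examples
#' # see simulateGenome() for building genomes with planted clusters
#' @export
callClusters <- function(sites, window = 10000L, minCopies = 2L) {
  window <- as.integer(window)
  minCopies <- as.integer(minCopies)
  if (window <= 0L) stop("window must be > 0")
  if (minCopies < 2L) stop("minCopies must be >= 2")
  keep <- mcols(sites)$copyNumber >= minCopies
  sites <- sites[keep]
  if (!length(sites)) return(emptyClusters(sites))
  groups <- split(seq_along(sites), mcols(sites)$spacer)
  rows <- lapply(groups, function(ix) {
    g <- sites[ix]
    if (length(unique(as.character(seqnames(g)))) != 1L) return(NULL)
    lo <- min(start(g)); hi <- max(end(g))
    if (hi - lo + 1L > window) return(NULL)
    ix[order(start(g), as.character(strand(g)))]
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  names(rows) <- NULL
  if (!length(rows)) return(emptyClusters(sites))
  k <- nchar(mcols(sites)$spacer[[1L]])
  recs <- lapply(rows, function(ix) {
    g <- sites[ix]
    lo <- min(start(g))
    list(chrom = as.character(seqnames(g))[1L],
         start = lo, end = max(end(g)),
         strand = as.character(strand(g))[1L],
         blockCount = length(g),
         blockSizes = paste(width(g), collapse = ","),
         chromStarts = paste(start(g) - lo, collapse = ","),
         i1 = ix[1L])
  })
  first <- sites[vapply(recs, function(r) r$i1, integer(1))]
  gr <- GRanges(
    seqnames = factor(vapply(recs, `[[`, "", "chrom"),
                      levels = seqlevels(sites)),
    ranges = IRanges(vapply(recs, `[[`, 1L, "start"),
                     vapply(recs, `[[`, 1L, "end")),
    strand = vapply(recs, `[[`, "", "strand"))
  seqlengths(gr) <- seqlengths(sites)
  md <- DataFrame(
    name = mcols(first)$name,
    score = pmin(mcols(first)$copyNumber, 1000L),
    blockCount = vapply(recs, `[[`, 1L, "blockCount"),
    blockSizes = vapply(recs, `[[`, "", "blockSizes"),
    chromStarts = vapply(recs, `[[`, "", "chromStarts"),
    clusterSize = mcols(first)$copyNumber,
    spacer = mcols(first)$spacer,
    percentGC = mcols(first)$percentGC,
    longestTandemT = mcols(first)$longestTandemT)
  for (col in intersect(offCols, names(mcols(first))))
    md[[col]] <- mcols(first)[[col]]
  mcols(gr) <- md
  names(gr) <- NULL
  gr[order(as.integer(seqnames(gr)), start(gr))]
}

emptyClusters <- function(sites) {
  gr <- GRanges()
  seqlevels(gr) <- seqlevels(sites)
  seqlengths(gr) <- seqlengths(sites)
  mcols(gr) <- DataFrame(name = character(), score = integer(),
                         blockCount = integer(), blockSizes = character(),
                         chromStarts = character(), clusterSize = integer(),
                         spacer = character(), percentGC = integer(),
                         longestTandemT = integer())
  gr
}
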