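#' Sort KeyedPosition bins into BED site records with copy numbers
#'
#' Loads KeyedPosition records, sorts them by NucKey so that all occurrences
#' of one spacer sequence become adjacent, and computes each spacer's
#' genome-wide copy number as the length of its run. Because bin files
#' partition records by spacer prefix, the per-bin copy numbers are already
#' genome-wide; per-prefix outputs concatenate to the genome-wide database.
#' Ties among equal NucKeys are ordered by (chrID, |pos|, strand) for
#' deterministic output.
#'
#' Each occurrence yields one record named `<NucKey>.<copyNumber>/<spacer>`.
#' The BED score is `min(copyNumber, 1000)` (bigBed validators cap score at
#' 1000); the exact copy number is kept in the `copyNumber` column and in
#' the name. Intervals cover the spacer only (0-based half-open, width k);
#' the PAM position is recoverable from the strand.
#'
#' @param binFiles paths to `.bin` files (or the list from [scanGenome()],
#'   which also supplies the chromosome table and k).
#' @param chromTable chromosome table data.frame, path to `ref.txt`, or
#'   `NULL` to look for `ref.txt` next to the first bin file.
#' @param k spacer length; taken from the scan result when available,
#'   otherwise inferred as the longest key in the bins. A key encoding more
#'   than k nucleotides (a mixed-k bin set) is an error.
#' @return a [GenomicRanges::GRanges] in NucKey order with metadata columns
#'   `name`, `score`, `spacer`, `copyNumber`, `percentGC`, `longestTandemT`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "AAACGGTTTT"), fa)
#' res <- scanGenome(fa, "XXXNGG", outdir = tempfile())
#' sortToBed(res)
#' @export
sortToBed <- function(binFiles, chromTable = NULL, k = NULL) {
  if (is.list(binFiles) && !is.null(binFiles$binFiles)) {
    if (is.null(chromTable)) chromTable <- binFiles$chromTable
    if (is.null(k) && is(binFiles$pattern, "PatternSpec"))
      k <- binFiles$pattern@k
    binFiles <- binFiles$binFiles
  }
  if (is.null(chromTable))
    chromTable <- readChromTable(file.path(dirname(binFiles[[1L]]), "ref.txt"))
  if (is.character(chromTable)) chromTable <- readChromTable(chromTable)
  recs <- do.call(rbind, lapply(binFiles, readBinFile))
  if (is.null(recs) || nrow(recs) == 0L)
    return(emptySites(chromTable))
  srt <- cpp_sort_keyed(recs$key, recs$chrID, recs$pos)
  recs <- recs[srt$order, , drop = FALSE]
  if (is.null(k)) k <- max(nchar(nucKeyDecode(recs$key)))
  spacer <- tryCatch(nucKeyDecode(recs$key, k = k), error = function(e)
    stop("bin files mix k-mer lengths (", conditionMessage(e), ")",
         call. = FALSE))
  idx <- match(recs$chrID, chromTable$chrID)
  if (anyNA(idx)) stop("record chrID missing from chromosome table")
  props <- annotateProperties(spacer)
  gr <- GRanges(
    seqnames = factor(chromTable$name[idx], levels = chromTable$name),
    ranges = IRanges(start = abs(recs$pos), width = k),
    strand = ifelse(recs$pos > 0, "+", "-"))
  seqlengths(gr) <- setNames(chromTable$length, chromTable$name)
  mcols(gr) <- DataFrame(
    name = paste0(recs$key, ".", srt$copy, "/", spacer),
    score = pmin(srt$copy, 1000L),
    spacer = spacer,
    copyNumber = srt$copy,
    percentGC = props$percentGC,
    longestTandemT = props$longestTandemT)
  gr
}

emptySites <- function(chromTable) {
  gr <- GRanges()
  seqlevels(gr) <- chromTable$name
  seqlengths(gr) <- setNames(chromTable$length, chromTable$name)
  mcols(gr) <- DataFrame(name = character(), score = integer(),
                         spacer = character(), copyNumber = integer(),
                         percentGC = integer(), longestTandemT = integer())
  gr
}

#' Spacer sequence properties: GC percentage and longest T run
#'
#' `percentGC` is 100*(G+C)/k rounded half-up to an integer;
#' `longestTandemT` is the length of the longest maximal run of T (0 when
#' the spacer has no T).
#'
#' @param spacers character vector of ACGT spacer sequences.
#' @return data.frame with integer columns `percentGC`, `longestTandemT`.
#' @examples
#' annotateProperties("ACGTTTTACGACGACGACGA")
#' @export
annotateProperties <- function(spacers) {
  spacers <- toupper(as.character(spacers))
  if (any(grepl("[^ACGT]", spacers))) stop("spacers must be pure A/C/G/T")
  gc <- nchar(gsub("[^GC]", "", spacers))
  pct <- as.integer(floor(100 * gc / nchar(spacers) + 0.5))
  trun <- vapply(gregexpr("T+", spacers), function(m) {
    if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
  data.frame(percentGC = pct, longestTandemT = trun)
}

#' Parse site/cluster record names
#'
#' Splits `<NucKey>.<copy>/<spacer>` names back into their components.
#'
#' @param names character vector of record names.
#' @return data.frame with columns `key`, `copy`, `spacer`.
#' @export
parseSiteNames <- function(names) {
  m <- regmatches(names, regexec("^([0-9]+)\\.([0-9]+)/([ACGT]+)$", names))
  if (any(lengths(m) != 4L)) stop("malformed site name")
  data.frame(key = vapply(m, `[`, "", 2L),
             copy = as.integer(vapply(m, `[`, "", 3L)),
             spacer = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}
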