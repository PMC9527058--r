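#' Scan a genome for pattern-matching sites into prefix bin files
#'
#' Streams both strands of every chromosome and, for each window matching
#' the pattern (constraint positions satisfied, spacer pure A/C/G/T after
#' uppercasing soft-masked bases), emits one KeyedPosition record: the
#' spacer's NucKey, the chromosome id, and the 1-based leftmost plus-strand
#' coordinate of the spacer with its sign encoding the strand (positive =
#' plus, negative = minus). Records are appended to one binary file per
#' `prefixLen`-base spacer prefix (`<prefix>.bin`), and a chromosome id
#' table is written alongside. Restricting `firstBase` to a subset of
#' A/C/G/T yields a disjoint partition of the full run, so four single-base
#' scans can be concatenated to reproduce an unpartitioned scan.
#'
#' @param fasta path to a FASTA file (optionally gzipped) or a
#'   [Biostrings::DNAStringSet]. Chromosome names are taken up to the first
#'   whitespace and ids are assigned in order of appearance, starting at 0.
#' @param pattern pattern string or [PatternSpec-class].
#' @param outdir directory for `<prefix>.bin` files and `ref.txt`.
#' @param prefixLen bases of the spacer used to name bin files (<= k).
#' @param firstBase subset of `c("A","C","G","T")`: only spacers starting
#'   with one of these bases are recorded.
#' @return invisibly, a list with `binFiles` (named character vector),
#'   `chromTable` (data.frame: chrID, name, length), `pattern` and `outdir`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "AAACGGTTTT"), fa)
#' res <- scanGenome(fa, "XXXNGG", outdir = tempfile())
#' readBinFile(res$binFiles[[1]])
#' @export
scanGenome <- function(fasta, pattern, outdir = tempfile("kenum_bins_"),
                       prefixLen = 6L, firstBase = c("A", "C", "G", "T")) {
  spec <- parsePattern(pattern)
  prefixLen <- as.integer(prefixLen)
  if (prefixLen < 1L || prefixLen > spec@k)
    stop("prefixLen must be in 1..k")
  firstBase <- match.arg(firstBase, several.ok = TRUE)
  fbMask <- sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[unique(firstBase)])
  genome <- loadGenome(fasta)
  lens <- vapply(genome, nchar, integer(1))
  if (any(lens > 2^31 - 2))
    stop("chromosome longer than 2^31-1: position field would overflow")
  chromTable <- data.frame(chrID = seq_along(genome) - 1L,
                           name = names(genome), length = unname(lens),
                           stringsAsFactors = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  opened <- character()
  for (i in seq_along(genome)) {
    hits <- cpp_scan_chrom(genome[[i]], spec@k, spec@windowLen,
                           spec@spacerOffset, spec@constraints$offset,
                           spec@constraints$mask, fbMask)
    if (!length(hits$key)) next
    pre <- substr(hits$spacer, 1L, prefixLen)
    for (grp in split(seq_along(pre), pre)) {
      path <- file.path(outdir, paste0(pre[grp[1L]], ".bin"))
      writeBinFile(data.frame(key = hits$key[grp],
                              chrID = chromTable$chrID[i],
                              pos = hits$pos[grp],
                              stringsAsFactors = FALSE),
                   path, append = path %in% opened)
      opened <- union(opened, path)
    }
  }
  writeChromTable(chromTable, file.path(outdir, "ref.txt"))
  binFiles <- sort(list.files(outdir, pattern = "\\.bin$", full.names = TRUE))
  names(binFiles) <- sub("\\.bin$", "", basename(binFiles))
  invisible(list(binFiles = binFiles, chromTable = chromTable,
                 pattern = spec, outdir = outdir))
}

# Read FASTA (or accept a DNAStringSet / named character vector) into a
# named character vector of uppercase-insensitive sequences.
loadGenome <- function(fasta) {
  if (is(fasta, "DNAStringSet")) {
    seqs <- as.character(fasta)
  } else if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- as.character(readDNAStringSet(fasta))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    seqs <- fasta
  } else {
    stop("fasta must be a file path, DNAStringSet, or named character vector")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names in FASTA")
  seqs
}

#' Read and write KeyedPosition bin files
#'
#' Fixed 16-byte little-endian records: 8-byte unsigned NucKey, 4-byte
#' unsigned chromosome id, 4-byte signed position. A file whose size is not
#' a multiple of 16 is rejected as corrupt.
#'
#' @param records data.frame with columns `key` (decimal NucKey strings),
#'   `chrID`, `pos`.
#' @param path file path.
#' @param append append to an existing file instead of overwriting.
#' @return `readBinFile`: the records data.frame; `writeBinFile`: the path,
#'   invisibly.
#' @export
writeBinFile <- function(records, path, append = FALSE) {
  bytes <- cpp_records_to_raw(records$key, as.integer(records$chrID),
                              as.integer(records$pos))
  con <- file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

#' @rdname writeBinFile
#' @export
readBinFile <- function(path) {
  n <- file.info(path)$size
  if (is.na(n)) stop("cannot read bin file: ", path)
  bytes <- readBin(path, what = "raw", n = n)
  as.data.frame(cpp_raw_to_records(bytes), stringsAsFactors = FALSE)
}

#' Read and write the chromosome id table
#'
#' Tab-separated, no header: chromosome id (0-based, in FASTA order), name,
#' length.
#'
#' @param chromTable data.frame with columns `chrID`, `name`, `length`.
#' @param path file path.
#' @return `readChromTable`: the data.frame; `writeChromTable`: the path,
#'   invisibly.
#' @export
writeChromTable <- function(chromTable, path) {
  write.table(chromTable[, c("chrID", "name", "length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeChromTable
#' @export
readChromTable <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrID", "name", "length"),
                    colClasses = c("integer", "character", "integer"))
  tab
}
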