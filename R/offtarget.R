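#' Generate AND/OR mask pairs for hamming-neighbor enumeration
#'
#' For a 2-bit-encoded query, each mask pair rewrites a chosen set of d
#' base positions: `query_mut = bitwAnd(query, and_mask) | or_mask`. The
#' AND-mask clears exactly the d chosen 2-bit fields and the OR-mask writes
#' replacement codes there. Replacements always differ from the query's
#' original base at every chosen position, so applying all pairs for a given
#' d produces each hamming-distance-d neighbor exactly once: C(k,d) * 3^d
#' pairs. d = 0 contributes the identity pair.
#'
#' @param query the spacer the masks are generated for (replacement codes
#'   must avoid its bases, so masks are query-specific).
#' @param maxD maximum number of substituted positions (0..k).
#' @return data.frame with numeric `and_mask`, `or_mask` and integer `d`;
#'   attribute `k` records the query length.
#' @examples
#' nrow(subset(genMaskPairs("ACGT", 1), d == 1))  # 4 positions x 3 = 12
#' @seealso [applyMaskPairs()]
#' @export
genMaskPairs <- function(query, maxD) {
  query <- toupper(as.character(query))
  df <- cpp_gen_mask_pairs(query, as.integer(maxD))
  attr(df, "k") <- nchar(query)
  df
}

#' @rdname genMaskPairs
#' @param pairs a data.frame from `genMaskPairs()`.
#' @return `applyMaskPairs`: character vector of the neighbor sequences
#'   produced by each pair.
#' @export
applyMaskPairs <- function(query, pairs) {
  cpp_apply_mask_pairs(toupper(as.character(query)),
                       pairs$and_mask, pairs$or_mask)
}

#' Count distinct sequence neighbors present in a genome
#'
#' For each query, counts the number of DISTINCT k-mer sequences at hamming
#' distance exactly d (d = 0..maxD) whose presence bit is set in the
#' sequence space -- sequence presence, not genomic site multiplicity, so
#' the distance-0 entry is 0 or 1. A complete list of prefixed subspaces
#' may be supplied instead of one full space; per-subspace counts are
#' summed (each neighbor belongs to exactly one prefix).
#'
#' @param space a [SeqSpace-class], or a list of prefixed subspaces
#'   covering every prefix exactly once.
#' @param queries character vector of spacers, or a sites GRanges from
#'   [sortToBed()] (its `spacer` column is used).
#' @param maxD maximum mismatch count (default 3).
#' @return integer matrix, one row per query, columns `d0`..`d<maxD>`.
#' @examples
#' sp <- encodeSeqSpace(c(chr1 = "ACGT"), k = 2)
#' countSeqNeighbors(sp, c("AC", "AA"), maxD = 2)
#' @export
countSeqNeighbors <- function(space, queries, maxD = 3L) {
  queries <- querySpacers(queries)
  maxD <- as.integer(maxD)
  spaces <- asSpaceSet(space, "SeqSpace")
  out <- matrix(0L, nrow = length(queries), ncol = maxD + 1L,
                dimnames = list(queries, paste0("d", 0:maxD)))
  for (sp in spaces) {
    counts <- do.call(rbind, lapply(queries, function(q)
      cpp_count_seq_neighbors(sp@bits, sp@k, sp@prefix, q, maxD)))
    if (!is.null(counts)) out <- out + counts
  }
  out
}

#' Encode a genome's exact k-mer copy-number database
#'
#' Same scanning and PAM/prefix semantics as [encodeSeqSpace()], but each
#' qualifying window increments b-bit counters at both the forward and the
#' reverse-complement index. Counts up to 2^b-2 live in the cell; larger
#' counts set the cell to the sentinel 2^b-1 and are tracked exactly in an
#' ordered overflow map, so [seqCount()] lookups are always exact.
#'
#' @inheritParams encodeSeqSpace
#' @param b bits per counter cell (>= 2; default 3 allows exact in-cell
#'   counts up to 6).
#' @return a [CountSpace-class].
#' @examples
#' db <- encodeCountDatabase(c(chr1 = "AAAA"), k = 2, b = 3)
#' seqCount(db, c("AA", "TT", "AC"))   # 3 3 0
#' @export
encodeCountDatabase <- function(fasta, k, b = 3L, pam = NULL, prefix = NULL,
                                genome = "") {
  k <- as.integer(k)
  b <- as.integer(b)
  if (b < 2L) stop("b must be >= 2 (one value is reserved as the sentinel)")
  pam <- toupper(if (is.null(pam)) "" else as.character(pam))
  prefix <- toupper(if (is.null(prefix)) "" else as.character(prefix))
  seqs <- loadGenome(fasta)
  enc <- cpp_encode_countdb(unname(seqs), k, b, pam, prefix)
  new("CountSpace", k = k, pam = pam, prefix = prefix, genome = genome,
      b = b, cells = enc$cells, overflowKeys = as.character(enc$overflowKeys),
      overflowCounts = as.numeric(enc$overflowCounts))
}

#' Exact genome-wide occurrence counts of k-mers
#'
#' @param db a [CountSpace-class].
#' @param seqs character vector of k-mers.
#' @return numeric counts; `NA` for sequences outside a prefixed subspace.
#' @export
seqCount <- function(db, seqs) {
  stopifnot(is(db, "CountSpace"))
  cpp_count_lookup(db@cells, db@b, db@k, db@prefix, db@overflowKeys,
                   db@overflowCounts, toupper(as.character(seqs)))
}

#' Exact off-target site counts for query spacers
#'
#' For each query, sums the exact genomic occurrence counts of every
#' sequence at hamming distance exactly d (d = 0..maxD): `n0` is the
#' genomic copy number of the query itself and `totalOffSites = n1+n2+n3`.
#' With `mark = TRUE`, every off-target sequence with a nonzero count is
#' reported with its substituted positions in lowercase. A complete list of
#' prefixed subspace databases may be supplied; per-subspace profiles are
#' summed (the divide-and-conquer contract).
#'
#' @param db a [CountSpace-class] or list of prefixed subspace databases.
#' @param queries character vector of spacers or a sites GRanges.
#' @param maxD maximum mismatch count (default 3).
#' @param mark also return the lowercase-marked off-target sequences.
#' @return data.frame with one row per query: `n0`..`n<maxD>`,
#'   `totalOffSites`, the slash-separated `offSiteCounts` string, and (when
#'   `mark`) a list column `neighbors` of data.frames (`sequence`,
#'   `mismatches`, `count`).
#' @examples
#' db <- encodeCountDatabase(c(chr1 = "ACGTTTAGGTCCAGGTCC"), k = 4)
#' countOffSites(db, "ACGT", mark = TRUE)
#' @export
countOffSites <- function(db, queries, maxD = 3L, mark = FALSE) {
  queries <- querySpacers(queries)
  maxD <- as.integer(maxD)
  dbs <- asSpaceSet(db, "CountSpace")
  prof <- matrix(0, nrow = length(queries), ncol = maxD + 1L)
  nbrs <- if (mark) rep(list(NULL), length(queries))
  for (d in dbs) {
    for (i in seq_along(queries)) {
      res <- cpp_count_off_sites(d@cells, d@b, d@k, d@prefix,
                                 d@overflowKeys, d@overflowCounts,
                                 queries[i], maxD, mark)
      prof[i, ] <- prof[i, ] + res$profile
      if (mark) nbrs[[i]] <- rbind(nbrs[[i]], res$neighbors)
    }
  }
  out <- as.data.frame(prof)
  names(out) <- paste0("n", 0:maxD)
  out$totalOffSites <- rowSums(prof[, -1L, drop = FALSE])
  out$offSiteCounts <- apply(prof, 1L, paste, collapse = "/")
  rownames(out) <- NULL
  out <- cbind(data.frame(query = queries, stringsAsFactors = FALSE), out)
  if (mark) {
    out$neighbors <- lapply(nbrs, function(x) {
      x <- x[order(x$mismatches, x$sequence), , drop = FALSE]
      rownames(x) <- NULL
      x
    })
  }
  out
}

#' Attach off-target profiles to site or cluster records
#'
#' Runs [countOffSites()] on each record's spacer (deduplicated) and stores
#' the profile in the extended BED columns `n0mismatches` ..
#' `totalOffSites` and `offSiteCounts`.
#'
#' @param records GRanges from [sortToBed()] or [callClusters()].
#' @param db a [CountSpace-class] or list of prefixed subspace databases.
#' @param maxD maximum mismatch count (default 3).
#' @return the GRanges with profile columns added.
#' @export
annotateOffTargets <- function(records, db, maxD = 3L) {
  spacers <- unique(mcols(records)$spacer)
  prof <- countOffSites(db, spacers, maxD = maxD)
  i <- match(mcols(records)$spacer, spacers)
  for (d in 0:maxD)
    mcols(records)[[paste0("n", d, "mismatches")]] <-
      as.integer(prof[[paste0("n", d)]][i])
  mcols(records)$totalOffSites <- as.integer(prof$totalOffSites[i])
  mcols(records)$offSiteCounts <- prof$offSiteCounts[i]
  records
}

#' Save and load count databases
#'
#' Gzip-compressed stream: magic `"SQCB1"`, k, b, the PAM/prefix/genome
#' strings, the overflow entry count, the cell byte count, the packed cell
#' payload, then one `index<TAB>count` line per overflow entry.
#'
#' @param db a [CountSpace-class].
#' @param path file path (conventionally `*.countdb.gz`).
#' @return `saveCountDatabase`: the path, invisibly; `loadCountDatabase`:
#'   the restored [CountSpace-class].
#' @export
saveCountDatabase <- function(db, path) {
  stopifnot(is(db, "CountSpace"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SQCB1"), con)
  writeBin(c(db@k, db@b), con, size = 4L, endian = "little")
  for (s in c(db@pam, db@prefix, db@genome)) writeHeaderString(con, s)
  writeBin(length(db@overflowKeys), con, size = 4L, endian = "little")
  writeBin(as.numeric(length(db@cells)), con, size = 8L, endian = "little")
  writeBin(db@cells, con)
  if (length(db@overflowKeys))
    writeLines(paste(db@overflowKeys, db@overflowCounts, sep = "\t"), con)
  invisible(path)
}

#' @rdname saveCountDatabase
#' @export
loadCountDatabase <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  if (!identical(magic, "SQCB1"))
    stop("not a count database file (bad magic): ", path)
  kb <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  pam <- readHeaderString(con)
  prefix <- readHeaderString(con)
  genome <- readHeaderString(con)
  nOv <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  nCells <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  cells <- readBin(con, "raw", nCells)
  if (length(cells) != nCells) stop("truncated count database payload")
  ov <- if (nOv > 0L) strsplit(readLines(con, nOv), "\t") else list()
  new("CountSpace", k = kb[1L], b = kb[2L], pam = pam, prefix = prefix,
      genome = genome, cells = cells,
      overflowKeys = vapply(ov, `[`, "", 1L),
      overflowCounts = as.numeric(vapply(ov, `[`, "", 2L)))
}

# normalize query input: character spacers or a GRanges with $spacer
querySpacers <- function(queries) {
  if (is(queries, "GRanges")) queries <- mcols(queries)$spacer
  toupper(as.character(queries))
}

# normalize a space argument: single object or complete prefixed set
asSpaceSet <- function(space, class) {
  if (is(space, class)) return(list(space))
  stopifnot(is.list(space), length(space) > 0L,
            all(vapply(space, is, TRUE, class)))
  prefs <- vapply(space, spacePrefix, character(1))
  p <- unique(nchar(prefs))
  k <- unique(vapply(space, spaceK, integer(1)))
  if (length(p) != 1L || p == 0L || length(k) != 1L)
    stop("expected one ", class, " or a complete set of prefixed subspaces")
  missing <- setdiff(sortedPrefixes(p), prefs)
  if (length(missing))
    stop("missing prefix subspace(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(prefs)) stop("duplicate prefix subspace")
  space
}
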