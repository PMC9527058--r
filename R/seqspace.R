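#' Encode a genome's k-mer sequence space as a presence bit array
#'
#' Allocates one bit per possible k-mer (4^k bits = 2^(2k-3) bytes for the
#' full space) and scans every chromosome with the sliding 2-bit indices:
#' for each pure-ACGT window, the forward index and the reverse-complement
#' index address the bits that are set. With a PAM (e.g. `"NGG"`) a window
#' only registers its forward k-mer when the PAM follows on the plus
#' strand, and only registers its reverse-complement k-mer when the genome
#' shows the PAM's reverse complement immediately 5' of the window (a
#' minus-strand site), so every set bit corresponds to a bindable site.
#' With a `prefix`, only k-mers beginning with that prefix are recorded,
#' indexed by their suffix; 4^p such subspaces tile the full space (see
#' [mergeSubspaces()]).
#'
#' @param fasta FASTA path, DNAStringSet, or named character vector.
#' @param k k-mer length (memory is 4^k bits; use `prefix` for large k).
#' @param pam optional PAM string over A/C/G/T/N, evaluated 3' of the k-mer
#'   on its own strand.
#' @param prefix optional A/C/G/T prefix selecting a subspace.
#' @param genome provenance label stored in the object.
#' @return a [SeqSpace-class].
#' @examples
#' sp <- encodeSeqSpace(c(chr1 = "ACGT"), k = 2)
#' seqSpacePopcount(sp)          # AC, CG, GT
#' hasSequence(sp, c("AC", "AA"))
#' @export
encodeSeqSpace <- function(fasta, k, pam = NULL, prefix = NULL, genome = "") {
  k <- as.integer(k)
  pam <- toupper(if (is.null(pam)) "" else as.character(pam))
  prefix <- toupper(if (is.null(prefix)) "" else as.character(prefix))
  if (nzchar(pam) && grepl("[^ACGTN]", pam))
    stop("PAM may contain only A/C/G/T/N")
  seqs <- loadGenome(fasta)
  bits <- cpp_encode_seqspace(unname(seqs), k, pam, prefix)
  new("SeqSpace", k = k, pam = pam, prefix = prefix, genome = genome,
      bits = bits)
}

#' Number of k-mers present in a sequence space
#'
#' @param space a [SeqSpace-class].
#' @return the number of set bits.
#' @export
seqSpacePopcount <- function(space) {
  stopifnot(is(space, "SeqSpace"))
  cpp_space_popcount(space@bits)
}

#' Test k-mer presence in a sequence space
#'
#' @param space a [SeqSpace-class].
#' @param seqs character vector of k-mers (length must equal `spaceK(space)`).
#' @return logical vector; `NA` for sequences outside a prefixed subspace.
#' @export
hasSequence <- function(space, seqs) {
  stopifnot(is(space, "SeqSpace"))
  cpp_space_get(space@bits, toupper(as.character(seqs)), space@k,
                space@prefix)
}

#' Save and load sequence spaces as compressed seqbits files
#'
#' The gzip-compressed stream holds a fixed header (magic `"SEQB1"`, k, the
#' PAM and prefix strings, the bit count) followed by the packed bit
#' payload; `loadSeqSpace()` inverts `saveSeqSpace()` exactly and rejects
#' files with a wrong magic or a truncated payload.
#'
#' @param space a [SeqSpace-class].
#' @param path file path (conventionally `*.seqbits.gz`).
#' @return `saveSeqSpace`: the path, invisibly; `loadSeqSpace`: the
#'   restored [SeqSpace-class].
#' @export
saveSeqSpace <- function(space, path) {
  stopifnot(is(space, "SeqSpace"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SEQB1"), con)
  writeBin(space@k, con, size = 4L, endian = "little")
  writeHeaderString(con, space@pam)
  writeHeaderString(con, space@prefix)
  writeHeaderString(con, space@genome)
  nbits <- 4^(space@k - nchar(space@prefix))
  writeBin(nbits, con, size = 8L, endian = "little")
  writeBin(space@bits, con)
  invisible(path)
}

#' @rdname saveSeqSpace
#' @export
loadSeqSpace <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  if (!identical(magic, "SEQB1"))
    stop("not a seqbits file (bad magic): ", path)
  k <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  pam <- readHeaderString(con)
  prefix <- readHeaderString(con)
  genome <- readHeaderString(con)
  nbits <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  if (!length(nbits) || nbits != 4^(k - nchar(prefix)))
    stop("seqbits header bit count does not match k/prefix")
  nbytes <- max(1, nbits / 8)
  bits <- readBin(con, "raw", nbytes)
  if (length(bits) != nbytes) stop("truncated seqbits payload")
  new("SeqSpace", k = k, pam = pam, prefix = prefix, genome = genome,
      bits = bits)
}

writeHeaderString <- function(con, s) {
  writeBin(nchar(s), con, size = 4L, endian = "little")
  if (nzchar(s)) writeBin(charToRaw(s), con)
}

readHeaderString <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(n)) stop("truncated seqbits header")
  if (n == 0L) "" else rawToChar(readBin(con, "raw", n))
}

#' Merge a complete set of prefixed subspaces into the full space
#'
#' Given all 4^p subspaces of a p-base prefix division (identical k and
#' PAM), places each subspace's bits at its prefix offset; the result is
#' bit-for-bit identical to encoding the unprefixed space directly.
#'
#' @param spaces list of prefixed [SeqSpace-class] objects covering every
#'   prefix exactly once.
#' @return an unprefixed [SeqSpace-class].
#' @export
mergeSubspaces <- function(spaces) {
  stopifnot(length(spaces) > 0L, all(vapply(spaces, is, TRUE, "SeqSpace")))
  k <- unique(vapply(spaces, spaceK, integer(1)))
  pam <- unique(vapply(spaces, spacePam, character(1)))
  if (length(k) != 1L || length(pam) != 1L)
    stop("subspaces must share k and PAM")
  prefs <- vapply(spaces, spacePrefix, character(1))
  p <- unique(nchar(prefs))
  if (length(p) != 1L || p == 0L)
    stop("all inputs must be prefixed subspaces of equal prefix length")
  if (k - p < 2L)
    stop("merging needs k - prefix length >= 2 (byte-aligned subspaces)")
  want <- sortedPrefixes(p)
  if (anyDuplicated(prefs)) stop("duplicate prefix: ",
                                 prefs[duplicated(prefs)][1L])
  missing <- setdiff(want, prefs)
  if (length(missing))
    stop("missing prefix subspace(s): ", paste(missing, collapse = ", "))
  spaces <- spaces[match(want, prefs)]  # ascending 2-bit prefix code order
  bits <- do.call(c, lapply(spaces, function(s) s@bits))
  new("SeqSpace", k = k, pam = pam, prefix = "",
      genome = spaces[[1L]]@genome, bits = bits)
}

# all p-base prefixes in ascending 2-bit code order (A < C < G < T)
sortedPrefixes <- function(p) {
  bases <- c("A", "C", "G", "T")
  out <- ""
  for (i in seq_len(p)) out <- as.vector(t(outer(out, bases, paste0)))
  out
}
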