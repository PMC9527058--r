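#' Parse a site-matching pattern string
#'
#' The pattern grammar uses `X` for enumerated spacer positions and
#' `A`/`C`/`G`/`T`/`N` for fixed constraint positions (e.g. a PAM). The `X`
#' run must be contiguous; constraint letters may appear on either side of
#' it, so both suffix-PAM (`"XXX...XNGG"`, SpCas9) and prefix-PAM
#' (`"TTTNXXX...X"`, Cas12a-style) nucleases are supported. `N` matches any
#' base. Lowercase input is accepted and uppercased.
#'
#' @param pattern pattern string, e.g. `"XXXXXXXXXXXXXXXXXXXXNGG"`.
#' @return a [PatternSpec-class].
#' @examples
#' parsePattern("XXXXXXXXXXXXXXXXXXXXNGG")
#' parsePattern("TTTNXXXXXXXXXXXXXXXXXXXX")
#' @export
parsePattern <- function(pattern) {
  if (is(pattern, "PatternSpec")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("pattern must be non-empty")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("X", "A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("illegal pattern character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  xpos <- which(chars == "X")
  if (!length(xpos)) stop("pattern contains no X (spacer) position")
  if (any(diff(xpos) != 1L))
    stop(sprintf("X-run is not contiguous: gap at position %d",
                 xpos[which(diff(xpos) != 1L)[1L]] + 1L))
  k <- length(xpos)
  if (k > 20L)
    stop("k must be <= 20 (NucKey capacity: 3k+3 <= 64 bits)")
  maskOf <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  cons <- which(!chars %in% c("X", "N"))
  new("PatternSpec",
      raw = pattern,
      k = k,
      windowLen = length(chars),
      spacerOffset = xpos[1L] - 1L,
      constraints = data.frame(
        offset = cons - 1L,
        letter = chars[cons],
        mask = unname(maskOf[chars[cons]]),
        stringsAsFactors = FALSE))
}

#' 3-bit NucKey codec for k-mers
#'
#' Encodes each nucleotide in 3 bits (A=000, C=001, T=010, G=011), first
#' base in the most significant occupied bits, then appends a 3-bit
#' end-of-string marker (111) in the low bits. The marker makes k-mers of
#' different lengths distinguishable under one fixed-width integer, and the
#' most-significant-first packing makes integer order agree with
#' lexicographic order (in A<C<T<G code order) so that sorting groups equal
#' sequences. Keys can reach 63 bits for k = 20, beyond exact double
#' precision, so they are represented in R as decimal character strings.
#'
#' Because A encodes as 000, leading A's vanish into the integer's unused
#' high bits: `"AAC"` and `"AC"` share one key value. Decoding therefore
#' takes the k-mer length `k` to restore the exact sequence; with `k = NULL`
#' the shortest consistent sequence is returned. All pipeline code works at
#' one fixed k, where equal values imply equal sequences.
#'
#' @param seqs character vector of ACGT sequences, 1-20 nt (lowercase ok).
#' @param keys character vector of decimal NucKey strings.
#' @param k k-mer length used to restore leading A's (`NULL` for shortest).
#' @return `nucKeyEncode`: decimal key strings; `nucKeyDecode`: sequences.
#' @examples
#' nucKeyEncode(c("A", "AC"))   # "7", "15"
#' nucKeyDecode("15")           # "AC"
#' nucKeyDecode("15", k = 4)    # "AAAC"
#' @export
nucKeyEncode <- function(seqs) cpp_nuckey_encode(as.character(seqs))

#' @rdname nucKeyEncode
#' @export
nucKeyDecode <- function(keys, k = NULL) {
  cpp_nuckey_decode(as.character(keys),
                    if (is.null(k)) 0L else as.integer(k))
}

#' 2-bit sequence-space indices with sliding updates
#'
#' `seqIndexEncode()` packs a k-mer at 2 bits per base (A=00, C=01, G=10,
#' T=11), most significant first, returning both the forward index and the
#' index of the reverse complement. `seqIndexSlide()` advances a window by
#' one base in O(1): the forward index shifts left two bits and takes the
#' new base's code in its least significant bits, while the reverse index
#' shifts right and takes the complement code in its most significant
#' occupied bits. Indices are exact doubles, so k is capped at 26 here
#' (2k <= 52 bits).
#'
#' @param seq an ACGT string (k <= 26).
#' @param idx named numeric `c(fwd=, rev=)` as returned by these functions.
#' @param k window length.
#' @param nextBase single incoming base.
#' @return named numeric vector `c(fwd=, rev=)`.
#' @examples
#' seqIndexEncode("ACGT")        # fwd 27, rev 27 (its own revcomp)
#' seqIndexSlide(seqIndexEncode("AC"), k = 2, nextBase = "G")  # "CG"
#' @export
seqIndexEncode <- function(seq) cpp_seqindex_encode(as.character(seq))

#' @rdname seqIndexEncode
#' @export
seqIndexSlide <- function(idx, k, nextBase) {
  stopifnot(is.numeric(idx), all(c("fwd", "rev") %in% names(idx)))
  cpp_seqindex_slide(idx[["fwd"]], idx[["rev"]], as.integer(k),
                     as.character(nextBase))
}

# reverse complement for plain character vectors (internal)
revComp <- function(seqs) cpp_revcomp(as.character(seqs))
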