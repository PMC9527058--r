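#' PatternSpec: a parsed site-matching pattern
#'
#' A pattern string such as `"XXXXXXXXXXXXXXXXXXXXNGG"` describes the shape
#' of a target site: a contiguous run of `X` positions (the k-nt spacer that
#' is enumerated and encoded) plus fixed-letter constraint positions such as
#' a PAM. Constraint letters may flank the spacer on either side, so
#' prefix-PAM nucleases (e.g. `"TTTNXXXX..."` for Cas12a) are expressible.
#' `N` positions are part of the window but impose no restriction.
#'
#' @slot raw the original pattern string (uppercased).
#' @slot k number of `X` positions (spacer length).
#' @slot windowLen total window length (spacer + constraint positions).
#' @slot spacerOffset 0-based offset of the spacer within the window.
#' @slot constraints data.frame with 0-based `offset`, `letter`, and the
#'   allowed-base bit `mask` (A=1, C=2, G=4, T=8) for every restrictive
#'   (non-`X`, non-`N`) position.
#'
#' @seealso [parsePattern()]
#' @export
setClass("PatternSpec", representation(
  raw = "character",
  k = "integer",
  windowLen = "integer",
  spacerOffset = "integer",
  constraints = "data.frame"
))

setValidity("PatternSpec", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (object@k > 20L)
    msg <- c(msg, "k must be <= 20 (NucKey capacity: 3k+3 <= 64 bits)")
  if (object@windowLen != nchar(object@raw))
    msg <- c(msg, "windowLen must equal nchar(raw)")
  if (object@spacerOffset < 0L ||
      object@spacerOffset + object@k > object@windowLen)
    msg <- c(msg, "spacer must lie within the window")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatternSpec", function(object) {
  cat("PatternSpec \"", object@raw, "\"\n", sep = "")
  cat("  k = ", object@k, ", window = ", object@windowLen,
      ", spacer offset = ", object@spacerOffset, "\n", sep = "")
  if (nrow(object@constraints) == 0L) {
    cat("  no constraint positions\n")
  } else {
    cat("  constraints: ",
        paste0(object@constraints$letter, "@", object@constraints$offset,
               collapse = " "), "\n", sep = "")
  }
})

#' KmerSpace: shared geometry of sequence-space indexes
#'
#' Virtual parent of [SeqSpace-class] and [CountSpace-class]: the k-mer
#' length, optional PAM constraint, optional prefix restricting the index to
#' the subspace of k-mers beginning with that prefix (indexed by their
#' suffix), and a free-text genome provenance tag.
#'
#' @slot k k-mer length.
#' @slot pam PAM string (`""` for none); evaluated on the k-mer's own strand.
#' @slot prefix prefix of the encoded subspace (`""` for the full space).
#' @slot genome provenance identifier of the encoded genome.
#' @export
setClass("KmerSpace", representation("VIRTUAL",
  k = "integer",
  pam = "character",
  prefix = "character",
  genome = "character"
))

setValidity("KmerSpace", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L ||
      object@k > 32L)
    msg <- c(msg, "k must be a single integer in 1..32")
  if (nchar(object@prefix) >= object@k)
    msg <- c(msg, "prefix must be shorter than k")
  if (nchar(object@prefix) > 0L && grepl("[^ACGT]", object@prefix))
    msg <- c(msg, "prefix must contain only A/C/G/T")
  if (nchar(object@pam) > 0L && grepl("[^ACGTN]", object@pam))
    msg <- c(msg, "PAM must contain only A/C/G/T/N")
  if (length(msg)) msg else TRUE
})

#' SeqSpace: presence bit array over k-mer sequence space
#'
#' One bit per possible k-mer (4^k bits for the full space, 4^(k-p) for a
#' p-base prefix subspace), set to 1 when the k-mer occurs in the genome on
#' either strand (honoring the PAM when one is set). Built with sliding
#' 2-bit forward/reverse-complement indices.
#'
#' @slot bits raw vector holding the packed bit array.
#' @seealso [encodeSeqSpace()], [countSeqNeighbors()], [mergeSubspaces()]
#' @export
setClass("SeqSpace", contains = "KmerSpace", representation(bits = "raw"))

setValidity("SeqSpace", function(object) {
  p <- nchar(object@prefix)
  want <- max(1, 4^(object@k - p) / 8)
  if (length(object@bits) != want)
    return(sprintf("bit array has %d bytes; expected %d for k=%d prefix '%s'",
                   length(object@bits), want, object@k, object@prefix))
  TRUE
})

#' CountSpace: b-bit saturating counter array over k-mer sequence space
#'
#' Like [SeqSpace-class] but each k-mer owns a b-bit counter recording its
#' exact genome-wide occurrence count up to 2^b-2. Counters that would
#' exceed 2^b-2 are set to the sentinel 2^b-1 and the exact count is kept in
#' an ordered overflow map keyed by the 2-bit k-mer index, so lookups are
#' always exact.
#'
#' @slot b bits per counter cell (>= 2).
#' @slot cells raw vector holding the packed counter array.
#' @slot overflowKeys decimal string keys (2-bit k-mer indices) of
#'   overflowed cells, in ascending key order.
#' @slot overflowCounts exact counts for the overflowed cells.
#' @seealso [encodeCountDatabase()], [countOffSites()], [seqCount()]
#' @export
setClass("CountSpace", contains = "KmerSpace", representation(
  b = "integer",
  cells = "raw",
  overflowKeys = "character",
  overflowCounts = "numeric"
))

setValidity("CountSpace", function(object) {
  msg <- character()
  if (object@b < 2L) msg <- c(msg, "b must be >= 2")
  if (length(object@overflowKeys) != length(object@overflowCounts))
    msg <- c(msg, "overflow keys and counts must have equal length")
  p <- nchar(object@prefix)
  want <- ceiling(4^(object@k - p) * object@b / 8)
  if (length(object@cells) != want)
    msg <- c(msg, sprintf("cell array has %d bytes; expected %d",
                          length(object@cells), want))
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerSpace", function(object) {
  cat(class(object), ": k = ", object@k, sep = "")
  if (nchar(object@pam)) cat(", PAM ", object@pam, sep = "")
  if (nchar(object@prefix)) cat(", prefix ", object@prefix, sep = "")
  if (is(object, "CountSpace")) {
    cat(", b = ", object@b, " bits/cell, ", length(object@overflowKeys),
        " overflowed cells", sep = "")
  } else {
    cat(", ", format(cpp_space_popcount(object@bits), big.mark = ","),
        " k-mers present", sep = "")
  }
  if (nchar(object@genome)) cat("  [", object@genome, "]", sep = "")
  cat("\n")
})
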