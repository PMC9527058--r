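#' Accessors for sequence-space objects
#'
#' `spaceK()`, `spacePam()` and `spacePrefix()` return the k-mer length, PAM
#' constraint (`""` when unconstrained) and subspace prefix (`""` for the
#' full space) of a [SeqSpace-class] or [CountSpace-class].
#'
#' @param x a `SeqSpace` or `CountSpace`.
#' @return a length-1 integer (`spaceK`) or character (`spacePam`,
#'   `spacePrefix`).
#' @examples
#' sp <- encodeSeqSpace(c(chr1 = "ACGTACGT"), k = 4)
#' spaceK(sp)
#' @export
setGeneric("spaceK", function(x) standardGeneric("spaceK"))

#' @rdname spaceK
#' @export
setGeneric("spacePam", function(x) standardGeneric("spacePam"))

#' @rdname spaceK
#' @export
setGeneric("spacePrefix", function(x) standardGeneric("spacePrefix"))

#' @rdname spaceK
#' @export
setMethod("spaceK", "KmerSpace", function(x) x@k)

#' @rdname spaceK
#' @export
setMethod("spacePam", "KmerSpace", function(x) x@pam)

#' @rdname spaceK
#' @export
setMethod("spacePrefix", "KmerSpace", function(x) x@prefix)
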