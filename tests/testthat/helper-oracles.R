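# Independent brute-force oracles, deliberately written in plain R against
# character strings (no NucKeys, no bit arrays) so they share nothing with
# the implementation they check.

oracleRevcompStr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "")[[1L]]),
        collapse = "")
}

# Enumerate every pattern-matching window on both strands of each
# chromosome. Returns chrom, signed 1-based leftmost spacer coordinate
# (negative = minus strand), spacer sequence.
oracleScan <- function(seqs, pattern) {
  chars <- strsplit(toupper(pattern), "")[[1L]]
  W <- length(chars)
  xp <- which(chars == "X")
  k <- length(xp)
  s0 <- xp[1L] - 1L
  scanOne <- function(S) {
    n <- nchar(S)
    if (n < W) return(NULL)
    starts <- 1:(n - W + 1L)
    ok <- rep(TRUE, length(starts))
    for (j in seq_len(W)) {
      if (chars[j] %in% c("X", "N")) next
      ok <- ok & substring(S, starts + j - 1L, starts + j - 1L) == chars[j]
    }
    sp <- substring(S, starts + s0, starts + s0 + k - 1L)
    ok <- ok & !grepl("[^ACGT]", sp)
    list(start = starts[ok], spacer = sp[ok])
  }
  out <- NULL
  for (chrom in names(seqs)) {
    S <- toupper(seqs[[chrom]])
    n <- nchar(S)
    f <- scanOne(S)
    if (length(f$start))
      out <- rbind(out, data.frame(chrom = chrom, pos = f$start + s0,
                                   spacer = f$spacer,
                                   stringsAsFactors = FALSE))
    r <- scanOne(oracleRevcompStr(S))
    if (length(r$start)) {
      # match at position j of the reverse strand maps to plus-strand
      # window start i = n - j - W + 2; spacer leftmost = i + W - s0 - k
      out <- rbind(out, data.frame(chrom = chrom,
                                   pos = -(n - r$start + 2L - s0 - k),
                                   spacer = r$spacer,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# The multiset of strand-reads a sequence-space scan registers: k-mers with
# the PAM on their own strand (pam = "" for unconstrained presence).
oracleReads <- function(seqs, k, pam = "") {
  hits <- oracleScan(seqs, paste0(strrep("X", k), pam))
  if (is.null(hits)) character(0) else hits$spacer
}

oracleHamming <- function(query, seqs) {
  k <- nchar(query)
  if (!length(seqs)) return(integer(0))
  q <- strsplit(query, "")[[1L]]
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = k)
  as.integer(colSums(m != q))
}

# precomputed distinct-read index for fast repeated profile queries
oracleReadIndex <- function(reads, k) {
  tab <- table(reads)
  m <- if (length(tab))
    matrix(unlist(strsplit(names(tab), ""), use.names = FALSE), nrow = k)
  else matrix(character(0), nrow = k)
  list(counts = as.numeric(tab), m = m, k = k)
}

oracleProfileFromIndex <- function(idx, query, maxD) {
  if (!ncol(idx$m))
    return(list(presence = integer(maxD + 1),
                multiplicity = numeric(maxD + 1)))
  dist <- colSums(idx$m != strsplit(query, "")[[1L]])
  presence <- vapply(0:maxD, function(d) sum(dist == d), numeric(1))
  multiplicity <- vapply(0:maxD, function(d)
    sum(idx$counts[dist == d]), numeric(1))
  list(presence = as.integer(presence), multiplicity = multiplicity)
}

# presence (distinct sequences) and multiplicity (genomic sites) neighbor
# profiles for one query against a read multiset
oracleNeighborCounts <- function(reads, query, maxD) {
  oracleProfileFromIndex(oracleReadIndex(reads, nchar(query)), query, maxD)
}

# all sequences at hamming distance exactly d from query (tiny k only)
oracleAllKmers <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

oracleNeighborhood <- function(query, d) {
  all <- oracleAllKmers(nchar(query))
  all[oracleHamming(query, all) == d]
}

sortedPrefixesForTest <- function(p) {
  out <- ""
  for (i in seq_len(p))
    out <- as.vector(t(outer(out, c("A", "C", "G", "T"), paste0)))
  out
}

randomGenome <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

writeTempFasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

# site set comparison helper: signed-position records as sortable strings
siteKeys <- function(chrom, pos, spacer) sort(paste(chrom, pos, spacer))

recKeys <- function(gr) {
  pos <- GenomicRanges::start(gr)
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  paste(as.character(GenomicRanges::seqnames(gr)),
        ifelse(neg, -pos, pos), S4Vectors::mcols(gr)$spacer)
}

sitesToKeys <- function(gr) sort(recKeys(gr))
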