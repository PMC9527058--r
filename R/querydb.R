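#' Filter, sort and extract gRNA records over regions of interest
#'
#' Returns the database records that overlap (by at least 1 bp) any query
#' region and pass every filter. With `bestN`, a bounded array of size n is
#' maintained while the candidates of each region are traversed, keeping
#' the n minimal records under the lexicographic sort keys (ties broken by
#' chromosome, start, strand) -- so at most n records are returned PER
#' region, and a record overlapping two regions is eligible in each
#' independently. Without `bestN`, all passing records are returned once,
#' in coordinate order.
#'
#' Filters are compact strings over the record fields:
#' `"totalOffSites<=30"`, `"n1==0"`, `"percentGC:40-60"` (inclusive range),
#' `"longestTandemT<4"`, `"clusterSize>=20"`, `"span<=5000"`. Recognized
#' fields are `copyNumber`, `clusterSize`, `blockCount`, `n0`..`n3` (or
#' `n0mismatches` ..), `totalOffSites`, `percentGC`, `longestTandemT`,
#' `score`, and `span` (the record's interval width, i.e. a cluster's
#' span); an unknown field is an error.
#'
#' @param db GRanges database: sites from [sortToBed()] /
#'   [readSitesBed()] or clusters from [callClusters()] /
#'   [readClustersBed()].
#' @param regions query regions: a GRanges, or a data.frame/matrix with
#'   columns chrom, start, end in BED convention (0-based half-open).
#' @param filters character vector of filter strings (all must pass).
#' @param sortKeys character vector like `"totalOffSites:asc"` or
#'   `"percentGC:desc"` (`:asc` may be omitted); required when `bestN` is
#'   given.
#' @param bestN optional cap on records returned per region.
#' @return a GRanges of matching records; with `bestN` it carries a
#'   `region` metadata column giving the 1-based index of the query region
#'   each record was selected for.
#' @examples
#' # see the vignette for an end-to-end example
#' @export
queryDB <- function(db, regions, filters = character(), sortKeys = NULL,
                    bestN = NULL) {
  regions <- asRegions(regions)
  if (!is.null(bestN) && is.null(sortKeys))
    stop("bestN requires sortKeys")
  pass <- applyFilters(db, filters)
  if (length(regions) == 0L) {
    out <- db[integer(0)]
    if (!is.null(bestN)) mcols(out)$region <- integer(0)
    return(out)
  }
  hits <- findOverlaps(regions, db, minoverlap = 1L)
  if (is.null(bestN)) {
    ix <- sort(unique(subjectHits(hits)))
    ix <- ix[pass[ix]]
    out <- db[ix]
    return(out[order(as.integer(seqnames(out)), start(out))])
  }
  bestN <- as.integer(bestN)
  keys <- sortKeyMatrix(db, sortKeys)
  picked <- integer(0)
  regionOf <- integer(0)
  for (r in seq_along(regions)) {
    cand <- subjectHits(hits)[queryHits(hits) == r]
    cand <- cand[pass[cand]]
    buf <- integer(0)  # BEST-n array, kept sorted best-first
    for (i in cand) {
      lo <- 1L
      while (lo <= length(buf) && !keyLess(keys, i, buf[lo])) lo <- lo + 1L
      buf <- append(buf, i, after = lo - 1L)
      if (length(buf) > bestN) buf <- buf[seq_len(bestN)]
    }
    picked <- c(picked, buf)
    regionOf <- c(regionOf, rep.int(r, length(buf)))
  }
  out <- db[picked]
  mcols(out)$region <- regionOf
  out
}

# is record a strictly better (smaller) than b under the key matrix?
keyLess <- function(keys, a, b) {
  for (j in seq_len(ncol(keys))) {
    if (keys[a, j] < keys[b, j]) return(TRUE)
    if (keys[a, j] > keys[b, j]) return(FALSE)
  }
  FALSE
}

sortKeyMatrix <- function(db, sortKeys) {
  parts <- strsplit(sortKeys, ":", fixed = TRUE)
  cols <- lapply(parts, function(p) {
    dir <- if (length(p) > 1L) match.arg(p[2L], c("asc", "desc")) else "asc"
    v <- fieldValues(db, p[1L])
    if (dir == "desc") -v else v
  })
  keys <- do.call(cbind, cols)
  # deterministic tie-break: chromosome, start, strand
  cbind(keys, as.integer(seqnames(db)), start(db), as.integer(strand(db)))
}

applyFilters <- function(db, filters) {
  pass <- rep(TRUE, length(db))
  for (f in filters) pass <- pass & evalFilter(db, f)
  pass
}

evalFilter <- function(db, f) {
  f <- gsub("\\s", "", f)
  m <- regmatches(f, regexec("^([A-Za-z0-9]+):(-?[0-9.]+)-(-?[0-9.]+)$", f))[[1L]]
  if (length(m) == 4L) {
    v <- fieldValues(db, m[2L])
    return(v >= as.numeric(m[3L]) & v <= as.numeric(m[4L]))
  }
  m <- regmatches(f, regexec("^([A-Za-z0-9]+)(<=|>=|==|!=|<|>|=)(-?[0-9.]+)$",
                             f))[[1L]]
  if (length(m) != 4L) stop("cannot parse filter: ", f)
  v <- fieldValues(db, m[2L])
  x <- as.numeric(m[4L])
  switch(m[3L],
         "<=" = v <= x, ">=" = v >= x, "<" = v < x, ">" = v > x,
         "==" = v == x, "=" = v == x, "!=" = v != x)
}

fieldValues <- function(db, field) {
  aliases <- c(n0 = "n0mismatches", n1 = "n1mismatches",
               n2 = "n2mismatches", n3 = "n3mismatches")
  if (field %in% names(aliases)) field <- aliases[[field]]
  if (field == "span") return(width(db))
  v <- mcols(db)[[field]]
  if (is.null(v) || !is.numeric(v))
    stop("unknown filter/sort field: ", field)
  v
}

asRegions <- function(regions) {
  if (is(regions, "GRanges")) return(regions)
  if (is.matrix(regions)) regions <- as.data.frame(regions)
  if (is.data.frame(regions)) {
    if (ncol(regions) < 3L) stop("regions need chrom, start, end columns")
    return(GRanges(as.character(regions[[1L]]),
                   IRanges(as.integer(regions[[2L]]) + 1L,
                           as.integer(regions[[3L]]))))
  }
  stop("regions must be a GRanges or a BED-like data.frame")
}
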