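#' Describe a synthetic genome with planted sites and neighbors
#'
#' A fixture plan specifies chromosome lengths, background base
#' composition, a PAM shared by all plants, the spacers to plant (at fixed
#' or randomly drawn positions), and derived neighbor plants at controlled
#' hamming distances. With `exclusion = TRUE` (the default), background
#' sequence is rejection-resampled until no window on either strand lies
#' within `exclusionMaxD` mismatches of any planted sequence, so planted
#' copy numbers, cluster spans and off-target profiles are exactly the ones
#' the plan implies; resampling is bounded by `maxRetries` and an
#' infeasible plan raises an error rather than silently biasing the genome.
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param gcFraction background GC fraction (default 0.41, a typical
#'   mammalian genome-wide value).
#' @param seed integer seed; recorded in the FASTA headers.
#' @param pam PAM planted 3' of every spacer and used for ground-truth
#'   profiles (`""` for none).
#' @param plants list of entries `list(spacer=, positions=)` where
#'   `positions` is a data.frame with columns chrom, pos (1-based leftmost
#'   spacer coordinate), strand -- or `list(spacer=, copies=, chrom=,
#'   region=, strand=)` to draw `copies` non-overlapping random positions
#'   (optionally confined to a chromosome and a `c(start, end)` region).
#' @param neighbors list of entries `list(of=, distance=, count=)`: `count`
#'   distinct sequences at exactly `distance` mismatches from the spacer
#'   `of` are generated and planted once each at random positions.
#' @param exclusion guarantee planted sequences (and their
#'   `exclusionMaxD`-neighborhoods) occur nowhere else.
#' @param exclusionMaxD neighborhood radius of the exclusion guarantee.
#' @param maxRetries resampling rounds before declaring the plan infeasible.
#' @return a `fixturePlan` list, input to [simulateGenome()].
#' @export
fixturePlan <- function(chromLengths, gcFraction = 0.41, seed = 1L,
                        pam = "NGG", plants = list(), neighbors = list(),
                        exclusion = TRUE, exclusionMaxD = 3L,
                        maxRetries = 50L) {
  stopifnot(is.numeric(chromLengths), !is.null(names(chromLengths)),
            gcFraction > 0, gcFraction < 1)
  plan <- list(chromLengths = chromLengths, gcFraction = gcFraction,
               seed = as.integer(seed), pam = toupper(pam), plants = plants,
               neighbors = neighbors, exclusion = isTRUE(exclusion),
               exclusionMaxD = as.integer(exclusionMaxD),
               maxRetries = as.integer(maxRetries))
  class(plan) <- "fixturePlan"
  plan
}

#' Simulate a genome from a fixture plan
#'
#' Draws background sequence, writes every plant (spacer plus PAM on the
#' requested strand) into it, enforces the exclusion guarantee by
#' resampling offending background windows, and computes ground truth for
#' every planted sequence by brute-force window counting on the realized
#' genome: PAM-qualified occurrence positions, copy numbers, cluster spans,
#' and off-target profiles n0..n3. Deterministic for a fixed seed.
#'
#' @param plan a [fixturePlan()].
#' @return a list with `genome` (a [Biostrings::DNAStringSet]; headers
#'   carry `seed=<seed>`), `truth` (list of data.frames: `sites`,
#'   `spacers`, `clusters`), and `plan` (with neighbor entries resolved to
#'   concrete sequences).
#' @examples
#' plan <- fixturePlan(c(chr1 = 3000), seed = 7,
#'                     plants = list(list(spacer = "ACGTACGTGGATCCAATTGC",
#'                                        copies = 3)))
#' sim <- simulateGenome(plan)
#' sim$truth$spacers
#' @export
simulateGenome <- function(plan) {
  stopifnot(inherits(plan, "fixturePlan"))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(plan$seed)
  pam <- plan$pam
  pamLen <- nchar(pam)
  chroms <- lapply(plan$chromLengths, function(n) drawBases(n, plan$gcFraction))
  plants <- plan$plants
  # resolve neighbor entries into concrete plants
  planted <- toupper(vapply(plants, `[[`, "", "spacer"))
  for (nb in plan$neighbors) {
    seqs <- character(0)
    while (length(seqs) < nb$count) {
      s <- mutateSpacer(toupper(nb$of), nb$distance)
      if (!(s %in% c(planted, seqs))) seqs <- c(seqs, s)
    }
    for (s in seqs)
      plants <- c(plants, list(list(spacer = s, copies = 1L)))
    planted <- c(planted, seqs)
  }
  # resolve random positions and place every plant
  occupied <- list()  # per chrom: 2-col matrix of footprint start/end
  sitesTruth <- NULL
  for (pl in plants) {
    spacer <- toupper(pl$spacer)
    k <- nchar(spacer)
    pos <- pl$positions
    if (is.null(pos)) {
      pos <- drawPositions(pl, k, pamLen, plan$chromLengths, occupied)
    }
    for (i in seq_len(nrow(pos))) {
      chrom <- as.character(pos$chrom[i]); p <- as.integer(pos$pos[i])
      strand <- as.character(pos$strand[i])
      fp <- footprint(p, k, pamLen, strand)
      if (fp[1L] < 1L || fp[2L] > plan$chromLengths[[chrom]])
        stop("plant does not fit inside chromosome ", chrom)
      if (overlapsAny(occupied[[chrom]], fp))
        stop("plants overlap on ", chrom, " near position ", p)
      occupied[[chrom]] <- rbind(occupied[[chrom]], fp)
      piece <- if (strand == "+") paste0(spacer, pam) else
        revComp(paste0(spacer, pam))
      chroms[[chrom]] <- writePiece(chroms[[chrom]], fp[1L], piece)
      sitesTruth <- rbind(sitesTruth,
                          data.frame(spacer = spacer, chrom = chrom, pos = p,
                                     strand = strand, stringsAsFactors = FALSE))
    }
  }
  if (plan$exclusion)
    chroms <- enforceExclusion(chroms, planted, sitesTruth, occupied, plan)
  seqs <- vapply(chroms, paste, "", collapse = "")
  truth <- groundTruth(seqs, planted, pam, plan$exclusionMaxD)
  plan$plants <- plants
  genome <- DNAStringSet(seqs)
  names(genome) <- paste0(names(seqs), " seed=", plan$seed)
  list(genome = genome, truth = truth, plan = plan)
}

drawBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

mutateSpacer <- function(spacer, d) {
  ch <- strsplit(spacer, "")[[1L]]
  at <- sample(length(ch), d)
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

footprint <- function(pos, k, pamLen, strand) {
  if (strand == "+") c(pos, pos + k + pamLen - 1L)
  else c(pos - pamLen, pos + k - 1L)
}

overlapsAny <- function(occ, fp) {
  !is.null(occ) && any(occ[, 1L] <= fp[2L] & occ[, 2L] >= fp[1L])
}

writePiece <- function(chrom, at, piece) {
  chrom[at:(at + nchar(piece) - 1L)] <- strsplit(piece, "")[[1L]]
  chrom
}

drawPositions <- function(pl, k, pamLen, chromLengths, occupied) {
  copies <- pl$copies
  if (is.null(copies)) stop("plant needs either positions or copies")
  strandOpt <- if (is.null(pl$strand)) "both" else pl$strand
  out <- NULL
  for (i in seq_len(copies)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      chrom <- if (!is.null(pl$chrom)) pl$chrom else
        sample(names(chromLengths), 1L, prob = chromLengths)
      strand <- if (strandOpt == "both") sample(c("+", "-"), 1L) else strandOpt
      lo <- if (strand == "+") 1L else pamLen + 1L
      hi <- chromLengths[[chrom]] - k - pamLen + 1L +
        (if (strand == "+") 0L else pamLen)
      hi <- min(hi, chromLengths[[chrom]] - k + 1L)
      if (!is.null(pl$region)) {
        lo <- max(lo, pl$region[1L]); hi <- min(hi, pl$region[2L] - k + 1L)
      }
      if (hi < lo) stop("no room to place plant")
      p <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      fp <- footprint(p, k, pamLen, strand)
      occ <- rbind(occupied[[chrom]],
                   if (!is.null(out)) do.call(rbind, lapply(
                     which(out$chrom == chrom),
                     function(j) footprint(out$pos[j], k, pamLen, out$strand[j]))))
      if (!overlapsAny(occ, fp)) {
        out <- rbind(out, data.frame(chrom = chrom, pos = p, strand = strand,
                                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible plan: too many plants for the genome length")
  }
  out
}

# resample background windows that fall inside the exclusion neighborhood
# of any planted sequence (plant positions themselves are expected hits)
enforceExclusion <- function(chroms, planted, sitesTruth, occupied, plan) {
  for (round in seq_len(plan$maxRetries)) {
    dirty <- FALSE
    for (chrom in names(chroms)) {
      seqStr <- paste(chroms[[chrom]], collapse = "")
      expected <- sitesTruth$pos[sitesTruth$chrom == chrom]
      occ <- occupied[[chrom]]
      for (target in unique(planted)) {
        k <- nchar(target)
        hits <- cpp_hamming_scan(seqStr, target, plan$exclusionMaxD)
        bad <- setdiff(hits$pos, expected)
        for (w in bad) {
          free <- setdiff(w:(w + k - 1L), occupiedPositions(occ, w, w + k - 1L))
          if (!length(free))
            stop("infeasible plan: accidental neighbor inside planted bases")
          chroms[[chrom]][free] <- drawBases(length(free), plan$gcFraction)
          dirty <- TRUE
        }
        if (length(bad)) seqStr <- paste(chroms[[chrom]], collapse = "")
      }
    }
    if (!dirty) return(chroms)
  }
  stop("infeasible plan: exclusion not achieved within maxRetries rounds")
}

occupiedPositions <- function(occ, lo, hi) {
  if (is.null(occ)) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(occ)))
    if (occ[i, 1L] <= hi && occ[i, 2L] >= lo)
      out <- c(out, max(occ[i, 1L], lo):min(occ[i, 2L], hi))
  out
}

# brute-force PAM-qualified ground truth on the realized genome
groundTruth <- function(seqs, planted, pam, maxD) {
  planted <- unique(planted)
  sites <- NULL
  profiles <- NULL
  for (q in planted) {
    k <- nchar(q)
    prof <- numeric(maxD + 1L)
    for (chrom in names(seqs)) {
      hits <- cpp_hamming_scan(seqs[[chrom]], q, maxD)
      ok <- pamQualified(seqs[[chrom]], hits$pos, hits$strand, k, pam)
      hits <- hits[ok, , drop = FALSE]
      for (d in 0:maxD) prof[d + 1L] <- prof[d + 1L] + sum(hits$dist == d)
      zero <- hits[hits$dist == 0L, , drop = FALSE]
      if (nrow(zero))
        sites <- rbind(sites, data.frame(spacer = q, chrom = chrom,
                                         pos = zero$pos, strand = zero$strand,
                                         stringsAsFactors = FALSE))
    }
    profiles <- rbind(profiles, data.frame(
      spacer = q, copyNumber = prof[1L],
      n0 = prof[1L], n1 = prof[2L],
      n2 = if (maxD >= 2) prof[3L] else 0,
      n3 = if (maxD >= 3) prof[4L] else 0,
      totalOffSites = sum(prof[-1L]), stringsAsFactors = FALSE))
  }
  clusters <- NULL
  for (q in unique(sites$spacer)) {
    s <- sites[sites$spacer == q, , drop = FALSE]
    k <- nchar(q)
    clusters <- rbind(clusters, data.frame(
      spacer = q, copies = nrow(s),
      oneChrom = length(unique(s$chrom)) == 1L,
      span = if (length(unique(s$chrom)) == 1L)
        max(s$pos + k - 1L) - min(s$pos) + 1L else NA_integer_,
      chrom = if (length(unique(s$chrom)) == 1L) s$chrom[1L] else NA_character_,
      stringsAsFactors = FALSE))
  }
  list(sites = sites, spacers = profiles, clusters = clusters)
}

# PAM check at brute-force hit windows (1-based window start w):
# plus strand: genome[w+k .. w+k+|pam|-1] matches pam letter-wise;
# minus strand: pam base t must equal the complement of genome[w - t].
pamQualified <- function(seqStr, pos, strand, k, pam) {
  if (!nchar(pam)) return(rep(TRUE, length(pos)))
  pamCh <- strsplit(pam, "")[[1L]]
  L <- nchar(seqStr)
  ok <- logical(length(pos))
  for (i in seq_along(pos)) {
    w <- pos[i]
    good <- TRUE
    for (t in seq_along(pamCh)) {
      if (pamCh[t] == "N") next
      g <- if (strand[i] == "+") {
        if (w + k + t - 1L > L) "" else substr(seqStr, w + k + t - 1L,
                                               w + k + t - 1L)
      } else {
        if (w - t < 1L) "" else
          chartr("ACGT", "TGCA", substr(seqStr, w - t, w - t))
      }
      if (!identical(g, pamCh[t])) { good <- FALSE; break }
    }
    ok[i] <- good
  }
  ok
}
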