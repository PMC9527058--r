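---
title: "Enumerating CRISPR target sites and counting their off-targets with kenum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating CRISPR target sites and counting their off-targets with kenum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(kenum)
  library(GenomicRanges)
})
```

## The problem

Genome and epigenome editing wants target sequences that occur exactly once
in a genome; live-cell genome imaging and loop engineering instead want
*multicopy* spacers whose copies cluster inside a small region, so that one
guide RNA recruits many fluorophores to one locus. Both designs start from
the same primitive: enumerate **every** k-mer site matching a
pattern-constrained motif — for SpCas9, a 20-nt spacer followed by the NGG
protospacer-adjacent motif (PAM) — on both strands of the genome, know each
spacer's genome-wide copy number, and score its off-target burden as the
number of genomic sites within a few mismatches. Per-locus design tools do
this one query at a time; building a genome-wide database of millions of
candidates needs an enumeration-first design, which is what this package
implements.

## Site enumeration and copy numbers

A pattern such as `XXXXXXXXXXXXXXXXXXXXNGG` is parsed into a contiguous run
of k spacer positions plus fixed constraint positions (`N` is
unconstrained). Constraints may also precede the spacer
(`TTTNXXX...`), so prefix-PAM nucleases are expressible. `scanGenome()`
slides over each chromosome; a window matches on the plus strand when its
constraint positions match directly, and on the minus strand when the
reverse-complement read matches. Each match is stored as a 16-byte
KeyedPosition record:

* **NucKey** — the spacer packed at 3 bits per nucleotide
  (A=000, C=001, T=010, G=011) with a 3-bit end-of-string marker appended
  after the last base. Packing is most-significant-first, so integer order
  groups identical sequences (and agrees with lexicographic order in code
  order). Because A encodes as zero bits, the k-mer length is an external
  parameter when decoding; the whole pipeline operates at one fixed k.
* **chrID** — index into a chromosome table written next to the bins.
* **pos** — the 1-based leftmost plus-strand coordinate of the spacer, with
  the sign encoding the strand. Positions are 1-based precisely so that the
  sign trick is well defined (0 has no sign); all BED output is 0-based
  half-open. The BED interval covers the spacer only; the PAM's location
  follows from the strand.

Records are appended to one file per spacer prefix (default 6 bases), and a
scan can be restricted to spacers starting with a chosen first base. The
four single-base scans are disjoint and their union equals the full run, so
coarse parallelism needs no shared state. `sortToBed()` then sorts each
bin by NucKey — identical spacers become adjacent runs, the run length *is*
the genome-wide copy number (prefix partitioning guarantees all copies
share a bin) — and emits extended BED records named
`<NucKey>.<copy>/<spacer>`. Ties among equal keys are ordered by
(chrID, |pos|, strand) so output is deterministic. The BED score stores
`min(copy, 1000)` because bigBed validators cap scores at 1000; the exact
copy number lives in the name and the `copyNumber` column.

A window whose spacer contains an ambiguous base is skipped, and a
constraint position reading `N` fails unless the pattern letter is `N`.
Soft-masked (lowercase) bases are uppercased and included: repeat-derived
multicopy clusters are a first-class use case, not noise. A palindromic
spacer whose PAM is present on both strands yields two records at the same
coordinates — each strand is an independent binding event — and
consistently counts twice in copy numbers and count databases.

## Sequence-space indexes and off-target counting

Off-target burden is evaluated against an index of k-mer *sequence space*.
`encodeSeqSpace()` allocates 4^k bits (2^(2k-3) bytes) and scans the
genome with two sliding 2-bit indices (A=00, C=01, G=10, T=11): the
forward index shifts left by two bits as the scan advances, the
reverse-complement index shifts right with the complement code entering at
the top. Every pure-ACGT window sets the bits addressed by both indices.
With a PAM, a window only registers its forward k-mer when the PAM follows
on the plus strand, and only registers its reverse-complement k-mer when
the genome shows the reverse complement of the PAM immediately 5' of the
window — so a set bit always denotes a *bindable* site, consistent with
the scanner's site definition. The byte cap per array is 2 GB; beyond
that, spaces are built as prefixed subspaces (all k-mers sharing a p-base
prefix, indexed by their suffix) which `mergeSubspaces()` or the counting
functions recombine exactly. Sixteen 2-base subspaces cover k = 20.

`countSeqNeighbors()` answers "how many *distinct* sequences at exactly d
mismatches from this query exist in the genome?". It prebuilds AND/OR mask
pairs: the AND mask clears the 2-bit fields of a chosen position subset,
the OR mask writes replacement codes there, and
`(query AND mask) OR or-mask` is a neighbor index probed in constant time.
Replacement codes always differ from the query's base at each chosen
position, so each neighbor at exact distance d is generated exactly once —
C(k,d)·3^d probes — rather than enumerating all 4^d value combinations and
classifying realized distances, which would double-count lower-distance
neighbors.

`encodeCountDatabase()` swaps the presence bit for a b-bit saturating
counter (b ≥ 2, default 3): counts up to 2^b−2 live in the cell; a cell at
the sentinel 2^b−1 has its exact count in an ordered overflow map keyed by
the k-mer index, so `seqCount()` is always exact. `countOffSites()` runs
the same neighbor enumeration against the counters: `n0` is the query's
own genomic copy number, `totalOffSites = n1+n2+n3`, and with
`mark = TRUE` each off-target sequence is reported with its substituted
positions lowercased. The two counters intentionally disagree at d = 0:
presence (0/1) for the neighbor counter, multiplicity for the exact
counter. For every enumerated site, `n0` equals its `copyNumber` when the
database uses the same pattern — the cross-check the acceptance suite
enforces.

## Clusters, queries, density

`callClusters()` implements the imaging-oriented cluster definition: a
spacer qualifies iff it has ≥ `minCopies` copies, **all** on one
chromosome, and the total span (max end − min start) is at most the window
(default 10 kb). The span-containment reading was chosen over
start-anchored windows because the rule is about the sites lying
exclusively within a region; any copy elsewhere disqualifies the spacer
entirely. Copies may mix strands; the record takes the leftmost copy's
strand since the blocked-BED schema has a single strand slot. Output rows
follow the multicopy AutoSql column order (blockCount/blockSizes/
chromStarts/clusterSize between BED9 and the off-target tail).

`queryDB()` filters records overlapping (≥ 1 bp, browser-style; containment
is not required) a region list, with compact filter strings over the
schema fields (`"totalOffSites<=30"`, `"percentGC:40-60"`, `"span<=5000"`).
With `BEST n`, a bounded array of n records is maintained during traversal
under lexicographic sort keys, ties broken by (chrom, start, strand);
selection is per region, so a record overlapping two regions is eligible
in each — matching per-element library design, where every promoter or
enhancer gets its own n best guides. `binDensity()` tiles chromosomes into
fixed bins (1 Mb default), assigns each record to the bin containing its
start coordinate — a record straddling a boundary counts once, keeping
totals conserved — and rescales the terminal partial bin to the full bin
length.

## The synthetic-genome simulator

`simulateGenome()` draws i.i.d. background bases at a configurable GC
fraction (default 0.41, a typical mammalian genome-wide value), plants
spacer+PAM copies at fixed or randomly drawn non-overlapping positions on
either strand, and derives neighbor plants at controlled hamming
distances. With exclusion on (default), background windows on either
strand falling within `exclusionMaxD` (default 3) mismatches of any
planted sequence are resampled; the repair loop is bounded and an
infeasible plan errors rather than silently biasing the genome. Ground
truth (occurrence positions, copy numbers, cluster spans, n0..n3 profiles)
is computed on the *realized* genome by direct window comparison, so it
stays correct even for coincidences the plan did not anticipate (e.g. a
reverse-complement read of one plant acquiring a PAM context from adjacent
background). The seed is recorded in the FASTA headers and the whole
simulation is byte-deterministic for a fixed seed.

What the simulator does not emulate: repeat families, GC isochores,
assembly gaps and soft-masking structure of real genomes. Passing tests on
these fixtures therefore demonstrate *algorithmic* correctness — exact
agreement with brute-force enumeration under controlled truth — not
robustness to the compositional quirks of any particular reference.

```{r example}
plan <- fixturePlan(c(chr1 = 9000), seed = 7,
                    plants = list(list(spacer = "ACGTTGCAGGATCCTAGCAA",
                                       copies = 4, region = c(1000, 4000),
                                       chrom = "chr1")))
sim <- simulateGenome(plan)
sites <- sortToBed(scanGenome(sim$genome, "XXXXXXXXXXXXXXXXXXXXNGG",
                              outdir = tempfile(), prefixLen = 2))
callClusters(sites, window = 10000, minCopies = 2)
```

## Numerical and representation choices

* **NucKeys in R are decimal strings.** Keys reach 63 bits at k = 20;
  doubles are exact only to 2^53, so keys cross the R boundary as decimal
  character strings and all sorting/grouping happens in C++ on `uint64_t`.
  2-bit indices and masks are returned as exact doubles, which caps the
  standalone codec helpers at k ≤ 26 (2k ≤ 52 bits); pipeline internals
  support k ≤ 32.
* **k is capped at 20 for enumeration** (3k+3 ≤ 64 bits of NucKey).
* **percentGC** rounds half-up to an integer; **longestTandemT** is the
  longest maximal T run (0 without any T).
* **Window restarts.** Any non-ACGT base invalidates the sliding indices
  for the next k−1 positions; windows are restarted, not masked per
  position.
* **File formats.** Bin files are fixed 16-byte little-endian records;
  seqbits/countdb files are gzip streams with a magic, the space geometry
  (k, PAM, prefix, bit/cell counts) and the packed payload; both round-trip
  bit-exactly. Extended BED output is plain text in the AutoSql column
  orders (18 columns one-copy, 22 multicopy); binary bigBed conversion is
  delegated to the external `bedToBigBed`.
* **Degenerate inputs.** Empty genomes give valid all-zero spaces;
  chromosomes longer than 2^31−1 are a hard error (position overflow);
  mixed-k bin sets are rejected; `b < 2` is rejected (the sentinel needs
  one spare value).

## Problem sizes used in the checks

The test suite validates against brute force at sizes where brute force is
exact and quick: site enumeration and copy numbers on twenty random
100–200 kb genomes (k = 8 with NGG), one thousand random off-target
queries at up to three mismatches, 16-way prefix divide-and-conquer on the
same genomes, planted clusters of 2–30 copies spanning 1–9 kb, and BEST-n
selection over a 10^5-record database. Full-genome runs at k = 20 use the
same code paths with prefixed subspaces; only their memory footprint, not
their logic, differs.

## Known limitations

* Off-target model is substitutions-only (hamming distance); DNA/RNA
  bulges are out of scope, as is activity scoring — counts, not cut
  efficiencies.
* Off-target *counts* are reported, not locations (the count database
  stores multiplicities, not coordinates).
* The neighbor counter's d = 0 entry is presence, not multiplicity, by
  design; use `countOffSites()` when exact on-target copy numbers matter.
* Whether a reference genome's soft-masked regions should be included is a
  design decision of the caller; this package includes them (uppercasing),
  which changes absolute site counts relative to tools that skip masked
  sequence.
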