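---
title: "Parallel BAM access by indexed scatter/gather: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel BAM access by indexed scatter/gather: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamscatter)
```

## The access model

A BAM file is a BGZF stream: a sequence of gzip members, each at most
64 KiB of compressed data framed with a `BC` extra subfield that records
the member's total size, terminated by a fixed 28-byte empty member (the
EOF marker). Because every block decompresses independently, a byte
position in the decompressed stream can be addressed by a *virtual
offset* — the pair (compressed offset of the containing block, offset
within its decompressed payload), packed as `coffset * 2^16 + uoffset`.
Any two virtual offsets therefore delimit a range that a worker can read
without touching, or being affected by, any other worker.

Two mechanisms turn this into parallel access:

1. **Indexed files.** The BAI index stores, per reference, a hierarchy
   of bins holding chunk intervals, plus a *linear index*: for every
   16-kb genomic window, the smallest virtual offset of any record
   overlapping it. The linear index is effectively a precomputed
   partition of the file: window boundaries are virtual offsets, so the
   genome can be tiled into windows and each window's data handed to an
   independent worker.

2. **Unindexed data.** Unsorted/unindexed files, and the unplaced-record
   tail of indexed files (records with no reference assignment are
   stored last and are not reachable through the BAI), have no
   precomputed partition. Here a heuristic scanner recovers parse start
   points directly: first the next valid BGZF block (magic bytes,
   plausible `BC` size, and a full test-inflation with the CRC32
   verified — magic bytes alone occur by chance inside compressed
   payloads), then the first valid record start within the decompressed
   stream.

### The record-validation predicate

A candidate record start at offset *o* is accepted when a *chain* of
`k_confirm` consecutive candidates (each beginning where the previous
record's declared size ends) all satisfy: `block_size` in `[32, 2^25]`;
`refID` in `[-1, n_ref)`; position `-1` (for unplaced) or within the
named reference; read-name length in `[1, 255]` with a NUL byte exactly
at its declared end; all CIGAR opcodes `<= 8`; `l_seq` in `[0, 2^28]`;
and the computed size of fixed plus variable fields not exceeding
`block_size`. Each check is cheap, and the conjunction across a chain
makes the false-positive probability on arbitrary bytes negligible.
`k_confirm` defaults to 4: one or two confirmations leave measurable
false-positive risk on adversarial payloads, while four passed an
empirical zero-false-positive budget (500 randomized probes per fixture
in the test suite). Scanning is left-to-right and the earliest
validating offset wins, so results are deterministic. A chain shorter
than `k_confirm` is accepted only when it ends exactly at the end of the
buffer, so files with fewer than four trailing records still partition
exactly.

### Deterministic scatter/gather

Workers must be pure functions of their job, and the merge must be
associative; results are always folded in job-ordinal order regardless
of completion order. This gives a strong contract checked by the tests:
byte-identical output for 1, 2, 4 and 8 workers, including under
injected random worker delays. Jobs for windowed pipelines group
contiguous windows into about `4 * n_workers` groups — enough pieces for
load balancing without oversubscription — and site-parallel pipelines
group consecutive VCF sites greedily until each job's estimated
compressed span (sum of `coffset` distances over the region's merged
chunks) reaches `total / n_jobs`. The worker pool is base R's forked
`parallel::mclapply`; on platforms without fork the engine degrades to
sequential execution with identical output, which is the point of the
contract.

## The two ported applications

**flagstat.** Per-window flag counters under samtools category
semantics: `mapped` excludes the UNMAP bit; secondary and supplementary
records are excluded from all pairing-related counters; properly paired
requires PAIRED and PROPER_PAIR and not UNMAP; singletons are mapped
reads with an unmapped mate; mate-different-reference requires both ends
mapped. Counters are kept separately for QC-pass and QC-fail records.
Reads that overlap a window boundary are counted in the *earlier*
window, implemented as start-based assignment — a record belongs to the
window containing its alignment start, which is unique per record, so
nothing is double-counted and the gather is plain summation. The
13-category report layout is pinned (the classic samtools layout); the
test suite checks numeric agreement with the samtools CLI per category
rather than byte parity, because newer samtools versions add extra
lines.

**snp-pileup.** For each bi-allelic SNP site from a VCF, and each input
BAM, every overlapping read is classified by walking its CIGAR to the
site: an aligned base matching the VCF reference allele counts as R, the
alternate allele as A, any other base as E, and a deletion spanning the
site as D. Reference skips (N) contribute nothing; insertions cannot
land on a site because they consume no reference; soft clips contribute
nothing. Reads matching the exclusion mask (default
UNMAP|SECONDARY|QCFAIL|DUP) or below the mapping-quality threshold are
ignored, as are aligned bases below the base-quality threshold — with
the convention that quality 255 means *missing*, not low, and passes any
threshold (deletions carry no base quality and are never
quality-filtered). The depth limit is deliberately built into the
per-site count structure: every read is considered in file order and
counting simply stops when R+A+E+D reaches the cap. This is a different
admission rule from htslib's pileup iterator (which stops adding reads
until one leaves the iterator) and is documented as an intentional
divergence; it yields more even coverage near the cap. Overlapping mates
are counted independently — no mate-overlap deduplication is attempted.

Duplicate VCF coordinates are all retained and each row is processed
independently; in particular a bi-allelic row at a position whose first
occurrence is *not* a bi-allelic SNP is still processed (a known failure
mode of the stock preprocessing tool). Sites on chromosomes absent from
a BAM header produce zero-count rows with a warning rather than
aborting, so multi-sample runs with heterogeneous headers degrade
gracefully.

### Default thresholds

`min_map_quality = 0`, `min_base_quality = 0`, `max_depth = 0`
(unlimited) and `min_total_depth = 0`. Neutral defaults make the oracle
tests exact (every classified read appears in the counts); all four are
settable per call and on the command line.

## The simulator and what passing tests mean

The simulator emulates a small paired-end shotgun experiment against an
*implicit* deterministic reference (`base(ref, pos) = ACGT[(3 pos +
7 ref) mod 4]` — no FASTA is emitted). Defaults: three references
totalling 2.4 Mb; 25 000 pairs of 100 bp (about 2× coverage); fragment
length 350 ± 50 with the proper-pair flag set when both mates map to one
reference within mean ± 4 sd; base errors at 0.2%; 5% duplicate, 2%
unmapped (half fully unplaced, half placed singletons), 2% secondary and
1% QC-fail pairs, so every flagstat category is exercised; CIGARs are
mostly match-only with occasional soft-clip, deletion and insertion
shapes. Base qualities come from a two-level alphabet (35 and 12) so
quality-threshold tests have exact expected effects. Ground truth —
block boundaries, record virtual offsets, flag tallies, and per-site
R/A/E/D under the default mask and zero thresholds — is recorded *during
generation* and never re-derived from the emitted bytes, keeping the
oracle independent of the code under test.

What the generator does **not** emulate: realistic error and quality
models, reference bias, indel realignment artefacts, chimeric and
supplementary alignments, or real genome repeat structure. Passing
tests therefore demonstrate format correctness, exactness of the
parallel decomposition, and the engine's counting semantics — not
robustness to every artefact of real libraries.

Problem sizes used by the test suite, chosen as comfortable desk-scale
conditions: the main fixture holds ≥50 000 records on three references
with 120 variant sites (200 random region queries, 500 scanner probes,
16-segment partitions); the allele-fraction fixture puts ~600× coverage
on a 2-kb reference so that injected fractions {0, 0.25, 0.5, 1} are
tested at ≥500× depth against exact 99% binomial intervals (with a ±0.01
allowance for injected sequencing error).

## Numerical and format choices

* **Virtual-offset scalars.** R has no native 64-bit integers, so packed
  virtual offsets live in doubles: exact while `coffset < 2^37`
  (compressed files up to 128 GiB). `voff_pack()` refuses larger values
  rather than silently rounding. Index structures and comparisons
  otherwise operate on packed doubles throughout; BAI I/O reads the two
  32-bit halves separately.
* **Block framing.** Written blocks cap payloads at 65 280 bytes (the
  conventional margin keeping even incompressible blocks within the
  65 536-byte frame); `bgzf_write_block()` accepts up to 65 535 bytes
  and errors if the compressed frame would overflow. Compression level
  is fixed at zlib level 6 and output is deterministic at a fixed level;
  an empty payload reproduces the standard EOF marker byte-for-byte.
  CRCs are always verified on read — the scanner relies on decode
  failures to reject false block candidates. A missing EOF marker is a
  warning, not an error, so truncated files remain scannable.
* **Linear-index gaps.** Windows with no overlapping records have no
  offset of their own; on serialisation they receive the *next*
  non-empty window's offset (trailing gaps the last value). This keeps
  the array monotone and the lower-bound pruning in queries sound
  (records relevant to an empty window's queries can only start at or
  after the next non-empty window). Emptiness is not recoverable from a
  file written by other producers, so `window_start_offsets()` on an
  externally read index collapses runs of equal offsets to their last
  window.
* **Degenerate inputs.** A mapped record with an empty CIGAR is treated
  as spanning one base so zero-width intervals cannot vanish from window
  assignment. Header-only files yield empty scans, all-zero flagstats
  and header-only CSVs. Records with `refID = -1` are not indexed and
  are reached through the scanner-partitioned tail.
* **The `bin` field** of written records is recomputed from the
  record's coordinates rather than trusted, so written files are always
  internally consistent for indexing. Tags are carried as opaque bytes
  and never decoded — no consumer here needs them and round-trip safety
  is preserved.

## Known limitations

CRAM, remote/streamed access, CSI indices (references longer than 2^29)
and SAM text are out of scope. The packed-offset double representation
bounds addressable compressed files at 128 GiB. The pure-R record
parser favours clarity and testability over raw speed; the
scatter/gather design is the contribution, and the per-record code paths
are written so a compiled parser could be dropped in behind the same
surfaces. Mate-overlap double counting at pileup sites is intentional
(documented above); genotype likelihoods, indel alleles and BED-region
pileups are out of scope.
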