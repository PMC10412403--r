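Package: bamscatter
Title: Parallel BAM File Access by Indexed Scatter/Gather
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Block-level access to BGZF-compressed BAM files designed for
    parallel reading: a BGZF codec addressed by virtual offsets, a BAM
    record parser and writer, BAI index construction and region queries
    driven by the 16-kb linear index, a heuristic scanner that recovers
    record boundaries in unindexed or unsorted files, and a deterministic
    scatter/gather engine whose output is independent of worker count.
    Ships two ported applications built on the engine: a windowed
    flagstat and a multi-sample snp-pileup producing FACETS-style
    per-site allele counts, plus a deterministic read simulator that
    generates BAM/BAI/VCF fixtures with exhaustive ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: parallel, stats, utils, vcfR
Suggests: testthat (>= 3.0.0), Rsamtools, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
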