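Package: dloopmapr
Title: Single-Molecule D-Loop Footprint Mapping from Non-Denaturing
    Bisulfite Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls single-molecule D-loop footprints as C-to-T conversion
    peaks on non-denaturing bisulfite-treated long-read amplicon data.
    Provides a donor-reference model with per-strand cytosine indexing and
    supercoiling-derived length caps, a topology-constrained synthetic-data
    generator with ground truth, per-read conversion-track calling with
    indel masking and strand assignment from conversion asymmetry, a
    threshold-based sliding-window peak caller over consecutive cytosines,
    and per-sample profiling (percent of reads with a footprint, footprint
    length statistics, non-exclusive positional binning, 5'-to-3' read
    clustering and footprint-map export).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
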