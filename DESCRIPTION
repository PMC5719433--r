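Package: mirphase
Title: Discovery of Phased and Half-Phased miRNA-Like RNAs on miRNA Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects additional small-RNA species beyond the canonical mature
    miRNA on miRNA precursors from collapsed small-RNA sequencing reads.
    Reads are mapped to precursors without mismatches, clustered into blocks
    around their most abundant representative, filtered, and classified by
    the 5' offset of each block from the major miRNA into canonical, isomiR,
    phased or half-phased miRNA-like RNAs. Candidate miRNA/miRNA* duplexes
    are validated for ~2-nt 3' overhangs on the hairpin structure, with a
    base-pair-maximizing folding fallback. Includes qRT-PCR 2^-ddCT relative
    quantification with a no-template-control detection rule, reads-per-million
    cross-library fold changes, PCR amplicon sequence concordance scoring,
    cleavage-site positional classification for 5' RACE clones, and a seeded
    hairpin read simulator with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
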