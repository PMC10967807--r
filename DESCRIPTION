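Package: dehydrinr
Title: Dehydrin Segment Annotation, Architecture Typing and Promoter
    Cis-Element Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing dehydrins (group-2 late embryogenesis
    abundant proteins, Pfam PF00257). Locates the conserved K, Y, S and F
    segments in protein sequences with degenerate consensus patterns scored
    by position-specific probability matrices, classifies sequences into the
    canonical dehydrin architectural types (Kn, KnS, SKn, YnKn, YnSKn, FSKn,
    FnKn), flags rare His- and Lys-rich motifs, computes biochemical
    properties (molecular weight, isoelectric point, GRAVY, fold index,
    residue percentages) from first principles, compares taxon groups with
    the Games-Howell post-hoc test, and profiles cis-regulatory elements in
    promoter sequences against an editable IUPAC catalog. A synthetic-data
    generator plants segments and elements with known coordinates so every
    stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
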