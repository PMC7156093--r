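Package: teindel
Title: Transposon-Anchored Discovery and Mechanistic Classification of
    Large Genomic Indels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects large-scale rearrangements (deletions, replacements,
    tandem copy-number variation, inversions) between two related genome
    assemblies by anchoring on LTR-retrotransposon insertion polymorphisms,
    calls indel breakpoints at the borders of high-identity similarity
    blocks, and classifies every junction by its inferred DNA double-strand
    break repair mechanism: unequal intra-strand recombination, inter-element
    LTR recombination, microhomology-mediated end joining (MMEJ),
    synthesis-dependent MMEJ with templated-insertion reconstruction,
    blunt/canonical non-homologous end joining, or introgression of foreign
    sequence. Includes a mechanism-explicit synthetic genome-pair simulator
    with recorded ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
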