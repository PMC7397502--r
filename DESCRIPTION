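Package: exposig
Title: Mutational Signatures and Selection Pressure from Carcinogen-Exposed Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-clone somatic variant calls (VCF) from carcinogen-exposed
    and control cell clones into mutational signature catalogues over the
    standard SBS96, DBS78 and ID83 channel schemes, derives exposure
    signatures by control normalisation, compares them to user-supplied
    signature catalogues by cosine similarity and non-negative least-squares
    refitting, and tests gene-level overmutation/protection and the
    association between mutation rate and gene expression. Ships a synthetic
    clone simulator (reference genome, signature-conditional mutation
    placement, gene models, expression tables) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
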