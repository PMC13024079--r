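Package: svpepgen
Title: Structural-Variant-Derived Neoantigen Peptide Generation and Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts somatic structural-variant (SV) breakpoints into mutant
    coding sequences and junction-restricted 8-11-mer candidate neoantigen
    peptides, then scores, filters and prioritizes the candidates through a
    proteasomal-cleavage risk model, peptide-HLA binding pass rules, tiered
    multi-omics evidence gates (expression, mass-spectrometry detection
    patterns, immunogenicity, similarity to validated neoantigens) and a
    ranking-based benchmarking framework. Consumes standard upstream formats:
    reference FASTA, GENCODE-style GTF, SV VCF (symbolic ALTs and paired
    breakends), and delimited predictor score tables. Ships a deterministic
    toy-fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
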