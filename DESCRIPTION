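Package: mitopop
Title: Mitochondrial Genome Population Genetics and Haplotype Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-genetic analysis of mitochondrial genomes
    and control-region (D-loop) alignments: genome-organization auditing of
    feature tables (lengths, intergenic spacers, overlaps, start/stop codons,
    base composition), conserved-motif scanning and in-silico PCR on circular
    genomes, haplotype collapsing with Nei nucleotide and haplotype diversity,
    Kimura two-parameter distances and Tamura-Nei substitution-rate matrices,
    neighbor-joining trees with column-resampling bootstrap, and
    median-joining haplotype networks with median-vector inference. Includes
    a synthetic mitogenome and haplotype-population simulator so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
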