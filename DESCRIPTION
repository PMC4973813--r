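Package: fabmap
Title: SNP Mining, Linkage Mapping and Synteny-Based Trait Targeting
    for Faba Bean
Version: 0.1.0
Authors@R:
    person("fabmap", "authors", email = "maps@example.org",
           role = c("aut", "cre"))
Description: An end-to-end marker-platform toolkit for orphan legumes
    genotyped with competitive allele-specific PCR (KASP) assays.
    Mines candidate SNPs from two inbred-line transcriptome assemblies
    using reciprocal-best-hit ortholog anchoring against a sequenced
    relative (Medicago truncatula), applies flank, intron-proximity and
    paralog filters to yield assay-ready targets, performs genotype-matrix
    quality control (no-call filtering, gene diversity and PIC,
    segregation-distortion screens, UPGMA panel dendrograms), builds
    per-population genetic maps by two-point EM estimation of
    recombination fractions with LOD grouping and SARF ordering, merges
    maps into a weighted consensus via directed-graph conflict
    resolution, and projects mapped markers onto the reference genome to
    call colinear blocks and list candidate genes in trait intervals.
    A synthetic-data generator (reference genome, parental
    transcriptomes, F2/F5/RIL populations, cluster fluorescence) with
    full truth tables makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
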