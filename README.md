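# fabmap

Tools for building and exploiting a SNP marker platform in a crop with
no reference genome, anchored by synteny to a sequenced relative. The
package targets the situation of faba bean (*Vicia faba*, ~13 Gb
genome, no assembly): SNPs are mined from the aligned transcriptomes of
two inbred lines, each marker is tied to a single ortholog of a
sequenced model legume (*Medicago truncatula*), markers are validated
as KASP assays on a diversity panel, mapped in several biparental
populations, merged into one consensus genetic map, and the conserved
gene order between the crop and the model is then used to read
candidate genes straight out of a mapped trait interval.

For whom: legume geneticists and breeders building low-cost genotyping
platforms, and anyone needing a tested, offline, end-to-end
reimplementation of this marker-platform workflow on their own data or
on simulated data.

## What it computes

* **Ortholog anchoring** — unique reciprocal best hits (RBH) between
  two transcriptome assemblies from standard 12-column tabular search
  output, filtered at E ≤ 1e-30 over ≥ 100 bases; each contig pair is
  anchored to exactly one reference gene or rejected
  (`reciprocal_best_hits()`, `anchor_pairs()`).
* **SNP mining** — exact affine-gap global alignment (Gotoh, Rcpp) of
  each anchored pair; every substitution column becomes a candidate
  with a `[X/Y]` consensus flank, filtered by the 50-bp flank rule,
  intron proximity (< 50 bp to a projected splice junction fails;
  otherwise flanks are truncated at the junctions), and paralog /
  multi-locus screens; passing targets are named
  `Vf_MtXgYYYYYY_ZZZ` (`mine_snps()`).
* **Marker QC** — automated I–IV assay quality from 2-D fluorescence
  clusters (silhouette-like separation × call rate); iterative 6%
  no-call filtering; gene diversity `2pq` and
  `PIC = 1 − p² − q² − 2p²q²`; discovery-line concordance audits;
  segregation-distortion screens (F2 band 0.4–2.1 on hom:het; inbred
  band 0.045–0.25 on het:hom); UPGMA panel dendrograms
  (`classify_quality()`, `allele_stats()`, `distortion_screen()`,
  `distance_and_upgma()`).
* **Linkage mapping** — two-point recombination fractions by EM
  (F2 9-class table with the double-heterozygote phase mixture;
  dominant × codominant collapsed classes; RIL-by-selfing correction
  `R = 2r/(1+2r)`), LOD ≥ 5 / r ≤ 0.3 single-linkage grouping, marker
  ordering by minimum sum of adjacent recombination fractions (exact
  for small groups, greedy + 2-opt beyond), Kosambi
  (`d = 25 ln((1+2r)/(1−2r))`) or Haldane (`d = −50 ln(1−2r)`)
  spacing, and dominant trait placement with flanking markers
  (`build_map()`, `map_trait_locus()`).
* **Consensus maps** — weighted merging of per-population maps via
  directed order graphs, greedy weighted cycle resolution with a full
  conflict log, topological linearisation and weighted-mean positions
  (`merge_maps()`, `map_stats()`).
* **Synteny** — marker-to-reference links at E ≤ 1e-37, colinear block
  detection (skip-tolerant monotone chaining), and candidate-gene
  listing for a marker interval with keyword filtering
  (`build_links()`, `detect_blocks()`, `interval_gene_content()`).
* **Synthetic data** — annotated reference genomes, parental
  transcriptomes with planted SNPs and decoy paralogs, F2 / F5
  single-seed-descent / RIL populations simulated by crossover
  (Haldane model) with error, missing data and viability distortion,
  and KASP-style fluorescence clouds per quality archetype — all pure
  functions of (parameters, seed) with truth tables
  (`make_reference()`, `simulate_population()`, ...).

## Worked example (synthetic closed loop)

```r
library(fabmap)

ref <- make_reference(n_chrom = 2, genes_per_chrom = 15,
                      introns_per_gene = 1, seed = 42)
tx  <- make_parental_transcriptomes(ref, snp_rate = 0.004,
                                    paralog_fraction = 0.1, seed = 42)

pairs   <- reciprocal_best_hits(kmer_hits(tx$seqs_a, tx$seqs_b),
                                kmer_hits(tx$seqs_b, tx$seqs_a))
genes   <- setNames(vapply(ref$genes$gene_id,
                    function(g) tx$seqs_a[[paste0("ctgA_", g)]], ""),
                    ref$genes$gene_id)
anchors <- anchor_pairs(pairs, kmer_hits(c(tx$seqs_a[pairs$contig_a],
                                           tx$seqs_b[pairs$contig_b]), genes))
targets <- mine_snps(tx$seqs_a, tx$seqs_b, anchors)

passed <- targets[targets$status == "pass", ]
tmap <- data.frame(marker = passed$assay_name,
                   group = paste0("chr", passed$reference_chromosome),
                   position_cM = ave(seq_len(nrow(passed)),
                                     passed$reference_chromosome,
                                     FUN = function(i) (seq_along(i) - 1) * 7))
pop  <- simulate_population(tmap, "f2", n = 136, error_rate = 0.01,
                            missing_rate = 0.03, seed = 42)
map  <- build_map(pop$gm, "f2", min_lod = 5, max_r = 0.3)

pop2 <- simulate_population(tmap[seq(1, nrow(tmap), 2), ], "f2", n = 165,
                            error_rate = 0.01, missing_rate = 0.03, seed = 43)
cons <- merge_maps(weighted_map_set(list(map, build_map(pop2$gm, "f2")),
                                    c(136, 165)))

links <- build_links(cons, NULL, ref$genes)
fl <- links$marker[links$vf_group == links$vf_group[1]][c(2, 6)]
iv <- interval_gene_content(fl[1], fl[2], links, ref$genes)
```

This prints (seed 42, so reproducible):

```
reference: 30 genes on 2 chromosomes; 69 planted SNPs, 3 decoy paralogs
30 anchored pairs -> 69 candidates, 55 assay-ready (e.g. Vf_Mt1g000020_001)
genetic_map: 55 markers in 2 groups (0 unplaced), 430.6 cM total
consensus_map: 55 markers, 55 loci, 2 groups, 430.6 cM (mean gap 8.1, max 14.6)
55 synteny links, 7 colinear blocks
interval Vf_Mt2g000010_002 .. Vf_Mt2g000050_001: chr2, 6 kb, 5 gene models
```

Reading the numbers: 69 SNPs were planted between the two synthetic
transcriptomes; 55 survive the flank/intron/paralog filters (the rest
sit within 50 bp of a contig end or splice junction, or fall in a gene
with a planted paralog decoy). All 55 map into the two expected linkage
groups; the two-population consensus keeps every marker with no order
conflicts; every marker links back to its true reference gene, and an
interval query between two markers returns the gene models physically
between their anchors — the "candidate genes in a trait interval" read
off exactly as for the flower-colour locus use case.

A command-line interface with the same operations is installed as
`exec/fabmap` (subcommands `anchor`, `mine`, `qc`, `map`, `consensus`,
`synteny`, `candidates`, `simulate`).

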