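---
title: "fabmap: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fabmap: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabmap)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the tunable parameters
with their defaults and units, what the synthetic-data generator does
and does not emulate, the numerical conventions, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The problem

A crop without a genome assembly can still get a dense, chromosome-
anchored SNP platform if (i) two inbred lines are transcriptome-
sequenced and aligned to each other to mine SNPs, (ii) each SNP-bearing
contig pair is tied to a single ortholog of a sequenced relative, and
(iii) the resulting markers are mapped genetically and merged into a
consensus map. Because marker names then carry reference-gene
identifiers, a mapped trait interval can be translated into a physical
interval of the reference genome and its gene content listed — the
"synteny-based trait targeting" that motivates the whole pipeline.

## Ortholog anchoring

Hits arrive in the standard 12-column tabular format; coordinates in
files are 1-based inclusive (subject start > end encodes minus strand)
and are converted at the parser boundary only. A contig pair is
retained iff each side is the *unique* best hit of the other after
discarding HSPs under 100 bases or weaker than E = 1e-30. "Best" is
lowest E-value, then highest bit score; a residual tie disqualifies the
contig — uniqueness is read strictly, because a tie means the search
cannot distinguish paralogs. When several HSPs join one query/subject
pair, the single best HSP represents the pair (the length threshold
applies to that HSP, not a sum); this is the simplest consistent
reading of "over at least 100 bases", and the choice only matters for
fragmented alignments that the paralog screens would likely remove
anyway.

## SNP mining

Anchored pairs are aligned with an exact affine-gap global aligner
(match +2, mismatch −3, gap open −8, gap extend −1; a k-base gap costs
`open + (k−1)·extend`). The original workflow used a progressive
multiple aligner; an exact pairwise aligner is deterministic and
testable against exhaustive enumeration, and the choice affects only
the column map, which the closed-loop tests pin against generator
truth. Traceback ties prefer diagonal, then a gap in the second
sequence — fixed so outputs are byte-stable.

Filters, in pipeline order (each is a pure predicate plus a
deterministic truncation, so the pass set is order-independent —
property-tested):

* **Flank rule** (`min_flank`, default 50 bases): a variant closer
  than 50 bases to either contig end cannot host a KASP primer pair.
* **Intron rule** (`min_dist`, default 50 bases): reference intron
  junctions are projected onto the contig through the hit coordinates
  and the gene's exon model. The insertion point convention is the
  0-based offset of the last base of the exon preceding the junction.
  A variant with fewer than 50 exonic bases on either side fails;
  otherwise flanks are truncated at the junctions so primers cannot
  span a splice site (genomic DNA would not anneal). The original
  study did this via an online pseudomolecule search; explicit GFF3
  exon models carry the same information offline.
* **Paralog / multi-locus screens** (`max_e`, default 1e-30): a flank
  hitting two contigs of either source transcriptome, two reference
  chromosomes, or two non-overlapping loci of one chromosome is
  discarded.

Consensus flanks write the target as `[X/Y]` (the common KASP
submission dialect); columns where the lines agree take the shared
base, one-sided gaps take the present base, and *secondary*
substitutions are written as IUPAC ambiguity codes and counted per
record, so downstream assay design sees every polymorphic position.
Assay names are `Vf_<gene>_<serial>` with a zero-padded 3-digit serial
per gene; serial 1000 is an error rather than a silent rollover.

## Marker QC

The study scored assays I–IV by eye; an automated composite replaces
this: per called point, a silhouette-like score
`(d_nearest_other_centroid − d_own_centroid) / max(both)` clipped to
[0, 1], averaged, then multiplied by `call_rate^0.5`. Class bounds
(I ≥ 0.8, II ≥ 0.6, III ≥ 0.4, else IV) are config keys — the original
boundaries were never quantified, so these are calibrated to the
fluorescence archetypes below rather than to any published number.

Gene diversity is `2pq` with `p` the frequency of the first (A)
allele; `PIC = 1 − p² − q² − 2p²q²`. Both are exported since the study
labels its statistic "PIC" while defining gene diversity. A minor
allele is *private* when it occurs in exactly one discovery line and
nowhere else in the panel.

The 6% no-call filter is iterative; the removal order (single worst
offender, lines and markers pooled, ties marker-first then
lexicographic) is unstated in the source and chosen for determinism.
The result is idempotent and contains no offender (property-tested).

Distortion screens: for an F2 the ratio is homozygote:heterozygote,
`(AA+BB)/AB`, Mendelian expectation 1, removal outside (0.4, 2.1).
For F5/RIL material the published cut-offs (0.045, 0.25) cannot
bracket a homozygote:heterozygote ratio (the F5 expectation would be
about 15), but they neatly bracket the *inverse*: the F5 expectation
of `AB/(AA+BB)` is `(1/16)/(15/16) ≈ 0.067`. The package therefore
computes het:hom for inbred designs. **This is a deliberate inversion
of the printed direction** and is flagged here prominently.

Panel relationships use the shared-allele distance
(`1 −` mean shared-allele score; AA vs AB scores 0.5) and UPGMA with a
label-order tie-break, hand-rolled because the tie behaviour of generic
clustering routines is unspecified and the output must be reproducible
to the byte. Trees are emitted as rooted ultrametric Newick.

## Linkage mapping

Two-point recombination fractions are maximum-likelihood via EM,
initialised at r = 0.25, converged on |Δr| < 1e-8 (cap 200
iterations), r clamped to [0, 0.5]:

* **F2 codominant**: full 9-class table; the double heterozygote is a
  phase mixture contributing `2r²/(p² + r²)` expected recombinant
  gametes.
* **Dominant trait × codominant marker**: collapsed 6-class table;
  both phasings are fitted and the higher-likelihood one kept.
* **Inbred (F5 treated as fixed, RIL)**: 2×2 homozygote table;
  heterozygous calls are uninformative; the observed recombinant
  fraction R maps back through the selfing correction
  `r = R / (2(1−R))`.

LOD is `log10 L(r̂) − log10 L(0.5)`, floored at 0. Grouping is
single-linkage closure over pairs with LOD ≥ 5 and r̂ ≤ 0.3 (0.2 is
the documented stricter setting for one study population; both are
arguments). Ordering: co-segregating markers (r̂ ≤ 1e-9) are binned;
bin order minimises the sum of adjacent recombination fractions
(SARF). Up to 8 bins this is an exact branch-and-bound (so the
"equals brute force for ≤ 6 loci" guarantee holds by construction);
larger groups use greedy chaining from the closest pair plus 2-opt to
a local optimum, the procedure sketched for the original (unpublished)
ordering heuristic. Orientation puts the lexicographically smaller
terminal marker first.

Spacing uses Kosambi by default — the common default of the era's
mapping software; the actual function used by the study is unstated —
with Haldane selectable; `r ≥ 0.5 − 1e-9` maps to a configurable
ceiling (50 cM) instead of infinity. Genotyping error is not modelled
during estimation: the pipeline filters (distortion, no-call) rather
than models error, mirroring the source workflow. Singleton groups are
reported unplaced.

A dominant trait is placed by estimating r̂ to every mapped locus,
choosing the best-linked group, and inserting at the slot that
minimises the SARF increase; the nearest codominant markers each side
are the reported flanking interval (width 0 when the trait
co-segregates with a locus, where "co-segregates" means r̂ below
numerical noise, 1e-6, since EM approaches 0 geometrically). A 3:1
segregation chi-square runs first and is reported, not enforced.

## Consensus merging

Input groups are matched across populations when they share ≥ 2
markers (transitively); unmatched groups pass through. Within a
matched set, each input order contributes a directed graph (edges
between consecutive position levels, weighted by the map weight;
default weight = population size, since the study's actual weighting
factors are not printed). The union graph is made acyclic greedily:
the (marker, map) occurrence whose deletion frees the most conflicted
markers per unit weight is removed and logged, ties resolved toward
lower weight then marker name. The published merging tool solves this
step with LP-based minimal vertex deletion; the greedy heuristic is
deterministic at desk scale and its log makes every deletion
auditable. The surviving DAG is linearised in topological order
(priority: weighted mean position, then name); positions are the
weighted means of input positions rescaled to the longest input group,
made monotone by cumulative max and anchored at 0. Groups observed in
a single population are never rescaled. Merging is idempotent and
preserves all conflict-free input orders (property-tested).

Chromosome labels are assigned by majority vote of anchor markers with
known assignments; ties leave a group unlabelled with a warning and a
label claimed twice is an error, because silently renumbering
chromosomes is how map releases go wrong.

`map_stats()` defines the mean adjacent gap as
`total length / (unique loci − groups)` — the number of adjacent-locus
intervals — which reproduces the published summary arithmetic exactly
(acceptance t1).

## Synteny and trait targeting

Links tie each consensus marker to a reference gene: best qualifying
hit at E ≤ 1e-37 (the stricter of the two cut-offs the study quotes;
the other, 1e-30, is reachable via `max_e`), with a name-derived
fallback for `Vf_MtXg..._ZZZ` markers when hits are absent (flagged, so
downstream users can exclude them). Gene position is the midpoint of
the gene span; GFF3 coordinates stay 1-based at the boundary.

Blocks are maximal monotone runs of reference positions along the cM
axis, extracted repeatedly as the longest strictly monotone
subsequence tolerating up to `max_skip` (default 2) interleaved
off-trend links — skipped, not consumed, so a displaced link can still
seed another block. A link at an inversion pivot fits both adjacent
chains; pivots are reassigned between adjacent opposite-orientation
blocks to balance their sizes, making the split deterministic (and the
partition mirror-symmetric under cM reversal in the skip-free
setting). `min_block` (default 3) and `max_skip` are config keys: the
source reported blocks from a visual browser, so no published values
exist.

Interval queries take the two flanking markers' linked genes, span the
physical interval between them (flank genes included), and return the
contained gene models in physical order with annotations, ready for
keyword filtering (e.g. "WD40" for an anthocyanin-regulator search).
Flanks linking to different reference chromosomes are an error, not an
empty result.

## Synthetic data: what it emulates and what it does not

The generator exists so that every stage is testable offline with full
truth tables; all functions are pure in (parameters, seed).

* `make_reference()`: non-overlapping plus-strand gene models (exons
  150–400 bp, introns 80–300 bp, intergenic 200–800 bp) on 1–8
  chromosomes. No strand variation, no nested or overlapping genes, no
  repeats.
* `make_parental_transcriptomes()`: one spliced transcript per gene
  per line; line B carries biallelic substitutions at `snp_rate`
  (default 0.004/bp ≈ one SNP per 250 transcript bases — a realistic
  transcript divergence between two inbred lines of an outcrossing
  legume; the true inter-line rate is not printed in the source). A
  `paralog_fraction` (default 0.1) of genes is duplicated in line A at
  2–5% divergence as decoys for the uniqueness and paralog filters.
  No indels, no assembly artefacts, no chimeric contigs: the mining
  closed loop therefore demonstrates correctness of the filters, not
  robustness to assembly error.
* `simulate_population()`: gametes by crossover simulation without
  interference (count ~ Poisson(length/100), positions uniform) — the
  Haldane model, so the Kosambi option is exercised only as a distance
  transform, never as the generating process. Designs: F2; F5 by
  single-seed descent (three further selfing meioses); RIL by 20
  selfing generations. Calls are then perturbed (error 0.01 → one of
  the other two calls; missing 0.05 → NC; both typical KASP plate
  rates) and optional distortion applies one-locus viability
  selection — matching the *phenomenon* the distortion filter targets
  without modelling its cause.
* `simulate_fluorescence()`: homozygote clusters at (0.9, 0.1) and
  (0.1, 0.9), heterozygotes at (0.5, 0.5), no-calls near the origin.
  Archetype parameters (cluster sd / extra no-call rate: I 0.035/0.01,
  II 0.11/0.05, III 0.20/0.12, IV 0.30/0.25 with all centroids
  collapsed) were chosen analytically once so each archetype's
  composite score sits mid-band for its class, then frozen; the
  closed-loop tests verify ≥ 90% class recovery per archetype.

A green closed-loop test therefore establishes that the
implementations are mutually consistent and recover planted truth
under clean, substitution-only, interference-free conditions; it does
not establish performance on real 454 assemblies, real cluster plots,
or real segregation data.

## Numerical conventions

* Coordinates: 1-based inclusive in all file formats, 0-based
  half-open (or 0-based offsets) internally; conversions happen only
  at parser/writer boundaries.
* All tie-breaks are deterministic and documented at the function
  level (best hits: E then bit score then disqualify; no-call removal:
  marker first, then lexicographic; UPGMA and ordering: label order).
* EM: r₀ = 0.25, |Δr| < 1e-8, ≤ 200 iterations; LOD floored at 0;
  `0 · log 0` treated as 0.
* Degenerate inputs error loudly rather than return empty: all-NC
  markers/lines, empty true maps, exhausted matrices, monomorphic
  traits, zero co-called line pairs.

## Known limitations

* The published supplementary tables (per-assay PIC, the published
  consensus map) are not redistributable, so the acceptance criteria
  that recompute their statistics remain red unless the user supplies
  the CSVs (see `tests/testthat/test-acceptance.R` for the expected
  columns and drop-in path).
* The inbred distortion band is interpreted het:hom (see above).
* Multipoint ordering, QTL mapping, primer thermodynamics, read-level
  simulation and assembly are out of scope.
* The k-mer mini-search (`kmer_hits()`) is a fixture generator for
  substitution-only synthetic data, not a general homology engine;
  real data should come from a standard search tool's tabular output.
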