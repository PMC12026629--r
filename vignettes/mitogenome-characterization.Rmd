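---
title: "Characterizing circular mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## The analysis this package implements

When a new animal mitochondrial genome is sequenced, its descriptive
characterization follows a well-worn template: a circular molecule of
roughly 15-16 kb carrying 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs
and one A+T-rich control region; a gene table with coordinates, strands,
start/stop codons and signed intergenic distances; per-partition base
composition with AT/GC strand skews; codon usage and relative synonymous
codon usage (RSCU) under the invertebrate mitochondrial genetic code;
cloverleaf secondary structures for the tRNAs; and a phylogeny placing the
new genome among its relatives. `mitochar` implements that entire template
as composable, tested R functions, with the published mitogenome of the
atyid shrimp *Caridina mariae* (15,581 bp, GenBank PQ359442) packaged as
reference tables and used as the default study system.

Because the deposited sequence itself is not bundled, the package includes
a seeded simulator that emulates the published architecture and records a
ground-truth manifest of everything it plants. Every downstream stage can
therefore be exercised offline against known truth.

## The data model

A `circular_genome` is a sequence (or just a length) with circular
topology; coordinates are 1-based inclusive everywhere, and a feature that
wraps the origin is expressed as `start > end`. An `annotated_genome` adds
an ordered feature table (`PCG`, `tRNA`, `rRNA`, `CR`). The control region
is carried as a feature so that gene tables include it, but it is labelled
distinctly: reports count 37 genes plus one CR row. Sense-strand extraction
reverse-complements minus-strand features, and all sizes are recomputed
from coordinates rather than trusted from input.

```{r}
ag <- caridina_annotation()
ag
head(write_gene_table(ag), 4)
```

## Composition and skew

AT-skew is `(A - T) / (A + T)` and GC-skew `(G - C) / (G + C)`, computed
from unrounded counts; N bases count toward feature size but are excluded
from both numerator and denominator. `partition_report()` emits the
standard 18-row table: whole mitogenome, pooled PCGs, the 13 PCGs, pooled
tRNAs, pooled rRNAs, and the control region. Two conventions matter and
both follow the published table they reproduce:

* per-gene and pooled-category statistics are computed on each feature's
  *sense* strand (gene-level skews change sign between strands, so this is
  the only convention consistent with the published per-gene values), while
  the whole genome and the CR are reported on the deposited plus strand;
* pooled categories concatenate each feature's full sense sequence, so
  bases shared by overlapping genes are counted once per gene and pooled
  sizes equal sums of feature lengths (11,128 bp for the 13 PCGs).

Percentages are displayed to one decimal and skews to three, matching the
field's reporting convention; internal values are kept at full precision.
A partition with `G + C = 0` reports an undefined GC-skew (`NaN`) with a
warning rather than failing, since A+T-rich control regions can in
principle degenerate that far.

## Codon usage and RSCU

Coding sequences are split into triplets on the sense strand. A length of
`3k + 1` or `3k + 2` leaves a trailing T or TA: an incomplete stop codon,
completed to TAA by post-transcriptional polyadenylation, reported as
`"T(AA)"` and excluded from codon counts. Complete terminal stops are
counted, which is why the pooled stop family of the default layout totals
12 across 13 PCGs (nad4 terminates on the incomplete stop).

RSCU for codon *c* in synonymous family *F* is
`count(c) * |F| / sum over F`. Under NCBI translation table 5 (invertebrate
mitochondrial) leucine has six codons, serine eight (UCN + AGN), AUA is
methionine and UGA tryptophan, and UAA/UAG form a two-codon stop family
that is included in RSCU output. Zero-count codons are listed with RSCU 0;
a family with zero total raises a warning and reports zeros. Annotated
nonstandard starts, such as the CAA start of cox1, are honoured as
annotated and flagged as warnings (`NONSTD_START`), never "corrected".

```{r}
cu <- caridina_codon_usage()
r <- rscu(setNames(cu$count, cu$codon))
round(r[c("UUA", "UCU", "UAA")], 2)
```

## Gene arrangement

`adjacency_census()` walks consecutive features in plus-strand start order
(plus the wrap-around pair) and reports `next.start - prev.end - 1` under
circular arithmetic: positive gaps are intergenic spacers, negative gaps
overlaps. The wrap-around record is attributed to the last feature's row,
matching the convention of printed gene tables. On the packaged layout this
reproduces the published intergenic column exactly: 16 spacers (1-50 bp,
the largest between rrnL and trnV) and 12 overlaps (1-40 bp, the largest
between trnL1 and rrnL), and the identity
`sum(gaps) + sum(lengths) = genome length` holds for any annotation.
`gene_order_signature()` renders the arrangement as a strand-signed token
string, rotated to start at cox1, for cross-species comparison.

## tRNA cloverleaf folding

The published study predicted tRNA structures with an external web server;
`mitochar` instead ships its own constrained-search folder so the analysis
is self-contained and reproducible. The search template is the classic
cloverleaf: a fixed 7-slot acceptor stem pairing the 5' and 3' ends, an
optional D-arm (3-4 stem pairs, 4-12 nt loop, or an unpaired linker when
absent), a 5-pair anticodon stem with the canonical 7-nt loop (anticodon at
loop positions 3-5), a variable region, and a T-arm (4-5 pairs, 4-9 nt
loop). All admissible placements are enumerated exhaustively - at tRNA
lengths this is a few thousand candidates, so brute force is both feasible
and verifiable - and scored per pair slot: +2 for Watson-Crick, +1 for a
G·U wobble, 0 for the tolerated mismatch classes CC/UU/CA/UC, -1 otherwise.
Ties are broken by more Watson-Crick pairs, then smaller total loop length,
then the leftmost D-arm. Mitochondrial tRNAs are scored without requiring a
3' CCA, and following the reporting convention of mitogenome papers the
G·U wobble is censused as a "mismatch" class even though it is an
admissible pair. There is no thermodynamic model and no pseudoknot support;
this is a structural census tool, not an energy minimizer.

The D-arm is called absent when the best D-armless placement strictly
out-scores the best D-bearing one (margin configurable, default 0) -
the rare truncation reported for trnS1 in this system.

```{r}
st <- fold_cloverleaf(simulate_genome(seed = 1)$truth$trna[["trnL2"]]$seq,
                      anticodon = "TAA")
st
```

## The phylogeny stage

The published study ran Bayesian and maximum-likelihood inference with
external programs; those are out of scope here. `mitochar` instead
implements the complete distance pipeline in code: `concat_supermatrix()`
concatenates per-gene alignments (union of taxa, gap-filling missing
genes with a warning, partition spans recorded), `p_distance_matrix()`
computes mismatch proportions under pairwise gap deletion (never counting
gap-filled columns), and `neighbor_joining()` performs the Saitou-Nei
agglomeration with the Q-criterion, deterministic smallest-(i,j) tie
breaking, and negative branch estimates clamped to zero with the deficit
logged. A Poisson correction `-log(1 - p)` is available for amino-acid
distances. Trees are `ape::phylo` objects; `root_with_outgroup()` places
the root at the midpoint of the outgroup's pendant edge, and
`is_monophyletic()` answers exact clade queries, so externally inferred
trees (e.g. Bayesian consensus trees) can be imported via Newick and
interrogated the same way. NJ is consistent on additive matrices - the
test suite verifies exact topology recovery across random trees of 4-10
taxa - but it is a desk-scale stand-in, not a reproduction of the
published 155-taxon inference or its support values.

## The simulator and what passing tests mean

`simulate_genome()` assembles a genome on the packaged layout in five
constraint-respecting passes: (1) every PCG's annotated start codon and
(possibly incomplete) stop are planted as hard constraints; (2) tRNA
cloverleaves are planted - maximal stems, minimal loops, so the planted
placement is the unique score optimum - with anticodons at the canonical
loop position, a configurable plan of mismatch slots (default: the
31 GU / 1 CC / 2 UU / 2 CA / 3 UC census published for this system)
restricted to the positionally pinned acceptor and anticodon stems, and an
optional D-armless tRNA at the trnS1 position; each plant is verified by
refolding and redrawn on the rare coincidental collision; (3) PCG bodies
are filled codon by codon from the published codon-usage profile (stop
codons never sampled); (4) rRNA and control-region partitions are drawn
i.i.d. from their published base-composition targets; (5) spacers are
drawn at control-region-like A+T richness. Overlapping features share
sequence by construction: later passes only fill positions not yet fixed.
Unpaired tRNA regions are drawn from an {A, C} alphabet, a deliberate
idealization that prevents spurious stems inside planted loops.

The truth manifest records *realized* quantities - codon counts, start and
stop codons, adjacency gaps, per-tRNA structures and the pair census, and
per-partition base counts - read back from the assembled sequence, and the
same seed always reproduces the same bytes.

What passing tests show, therefore, is that the pipeline inverts the
generator exactly at the published problem size and recovers composition
targets within sampling error. What they do not show is performance on
real sequence: real tRNAs have compositionally unremarkable loops,
mismatches anywhere in their stems, and occasionally structures outside
this template, and the published mismatch totals are properties of the
deposited accession, which is not redistributed here. The structural
numbers of the study (15,581 bp; 11,128 bp of PCGs; 1455 bp of tRNAs;
16 spacers; 12 overlaps; every RSCU and skew derivable from the printed
tables) are forced by construction and verified by computation.

## Numerical and design choices

* **Problem sizes in tests.** Simulations use the full 15,581 bp layout
  (about 1.5 s per genome including plant verification); folding-oracle
  comparisons use 20 random tRNA-length sequences; NJ consistency uses 100
  random trees of 4-10 taxa; the Jukes-Cantor check uses 20 replicates of
  a 100 kb two-taxon alignment, against the closed form
  `p = 3/4 (1 - exp(-4b/3))` at 3 standard errors.
* **Rounding.** Displayed percentages 1 decimal, skews 3 decimals, RSCU 2;
  all comparisons against published values happen at the published
  precision, and skew checks from rounded published percentages allow for
  the ≤0.1-point input rounding they carry.
* **Degenerate inputs.** All-N sequences refuse composition; `G+C = 0`
  yields `NaN` skew with a warning; coding sequences under 6 nt refuse
  codon extraction; folding outside 55-75 nt is rejected; a fold whose
  best score falls below the configured minimum returns the best partial
  structure flagged `fold_failed`.
* **Tie-breaks.** Feature ordering is by (start, end, name); NJ joins the
  smallest (i, j) pair among Q-minima; folding ties resolve as described
  above. All are deterministic, so identical inputs give identical bytes.
* **Known published inconsistencies.** The source tables disagree in a few
  places (per-gene size column vs coordinates; tRNA vs rRNA A+T content in
  prose vs table; a claimed trnH-within-nad4 containment vs coordinates
  that merely abut). The package follows the coordinate table and the
  composition table throughout and makes no attempt to reproduce the prose
  variants.

## Limitations

The folder is a template search, not a general RNA structure predictor;
the phylogeny stage is distance-based and unbootstrapped; the simulator
does not model indels, read-level noise, or within-genome rate variation;
and GenBank parsing covers the feature-table subset this pipeline emits,
not the full flat-file grammar.
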