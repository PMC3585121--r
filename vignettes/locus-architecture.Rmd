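---
title: "Methods: comparative architecture of fungal alkaloid loci"
author: "alkaloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative architecture of fungal alkaloid loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clavicipitaceous fungi — the ergot fungi (*Claviceps*), the grass endophytes
(*Epichloë*/*Neotyphodium*, the "epichloae"), and relatives — synthesise four
classes of protective alkaloids: ergot alkaloids (EAS), indole-diterpenes
(IDT/LTM), lolines (LOL) and peramine (PER). The genes for each class are
clustered, and the clusters show a characteristic architecture: a conserved
core of early-pathway ("skeleton") genes, a variable periphery of
decoration genes whose presence/absence/sequence determines the particular
compounds made, and — especially in the epichloae — large flanking and
interstitial blocks of AT-rich transposon-derived repeats, MITEs, and often
a nearby telomere. `alkaloci` implements the computational portions of such
a comparative analysis as reusable, tested components, and ships a
synthetic-genome generator so that every stage can be validated against a
known ground truth without any external data.

The package is organised as an analysis workflow: the numbered drivers in
`analysis/` (simulate → repeats → RIP → elements → clusters → orthology →
chemotype) narrate one complete pass over a pair of synthetic genomes and
the published strain genotypes, writing their tables under `results/`.
All computation lives in the package functions, which the test suite and
`scripts/acceptance.R` call directly.

## Repeat discovery, correspondence, and the genome partition

Repeat families are built the classical way, from a local self-alignment of
the assembly (NCBI BLAST+ `blastn`; scoring pinned to match +1, mismatch
−2, gap open −5, gap extend −2 and recorded in every hit set, because
raw-score thresholds are meaningless without the scheme). Hit footprints
are merged per contig (`merge_gap` = 50 bp), and merged segments at least
`min_len` long with at least `min_copies − 1` supporting footprints become
candidates. Candidates are clustered into families by single linkage, with
an edge whenever one hit's two footprints overlap two candidates by at
least half the footprint length; the exemplar is the longest member. This
single-linkage choice is deliberately simple: it mirrors non-redundant
library construction from a hit report and is testable against a
brute-force union-find oracle (see `test-repeat-annotation.R`).

Masking re-aligns each exemplar to the genome and keeps placements with raw
score ≥ 100 and percent identity ≥ 70. The identity floor is deliberately
permissive: the exemplar is itself one diverged copy, so two copies that
each sit 85% from their family ancestor are only ~72–74% identical to each
other, and RIP pushes copies further. The score threshold does the work of
excluding chance placements — masking a repeat-free random genome marks
under 0.5% of it. Overlapping placements from different families are
resolved in favour of the higher score.

Cross-genome correspondence aligns exemplar sets reciprocally between every
genome pair; two families correspond when *both* directions score ≥ 100
(the classical reciprocal-score rule), and universal repeat numbers are the
connected components of that graph, numbered canonically so the labels do
not depend on genome input order.

Partition statistics assign every non-gap base to exactly one of four
categories with precedence CDS > genic-non-CDS > intergenic-repeat >
intergenic-non-repeat. The precedence (genic over repeat) keeps genic
totals consistent with the annotation and makes the partition exact: the
four categories sum to the non-gap length, and the bp-weighted mean of the
category GC fractions reproduces the whole-genome GC to 1e−9 (both are
asserted in the tests). Percentages are reported on non-gap length, and the
output says so.

## RIP profiling

Repeat-induced point mutation (RIP) converts CpA→TpA (and, on the other
strand, TpG→TpA read on the forward strand), so RIPped DNA is depleted in
ApT relative to TpA. The index is computed in sliding windows of 200 bp
with a 20 bp step; partial windows at the contig end are not counted, so a
contig of length $L$ yields exactly $\lfloor (L - w)/s \rfloor + 1$
windows. Dinucleotides are counted overlapping, case-insensitively, and
pairs containing non-ACGT characters are skipped rather than imputed. Both
ApT and TpA are palindromic, so every window's index is invariant under
reverse complement — which also justifies running windows in stored contig
orientation (a centromere-to-telomere direction cannot be honoured without
centromere annotation; the direction is recorded in the output). Two
orientations are supported behind a flag: `apT_over_tpA` (the conventional
printed form; low = RIPped) for output files, and `tpA_over_apT` (high =
RIPped) internally for classification.

A repeat copy is called RIPped by a composite rule: its median window index
(TpA/ApT) must exceed the 0.95 quantile of the background distribution
*and* its GC must lie below the background median — coupling the
dinucleotide signature with the AT-enrichment that RIP produces. The
background is taken from windows lying wholly in non-repeat intergenic
sequence. One numerical subtlety: a copy statistic is a *median over its
windows*, so comparing it against the quantile of single background
windows would be biased far upward in noise. The quantile is therefore
evaluated on the null distribution of medians of consecutive
background-window blocks matched to the copy's window count (deterministic
— no resampling). Copies shorter than one window are reported
indeterminate.

## MITEs and telomeres

Inverted repeats are found by iterated best local alignment of a sequence
against its own reverse complement, with einverted-style scoring (match +3,
mismatch −4, gap −12); found arm pairs are masked and the search repeats,
so hits are maximal and non-redundant. A repeat family is MITE-classified
when its exemplar is 80–800 bp, carries a qualifying terminal TIR (arms
within 30 bp of the exemplar ends, arm ≥ 10 bp, identity ≥ 0.8), and the
family has at least 2 genomic copies. This is structure-based de novo
classification, not matching against a curated MITE database; superfamily
assignment is out of scope.

Telomere detection scans both ends of each contig for tandem arrays of the
motif (default `TTAGGG`, configurable — the canonical fungal repeat) — the
motif itself at the right end, its reverse complement at the left end —
starting within 200 bp of the terminus, with at least 4 copies. Imperfect
arrays are tolerated at ≤ 1 mismatch per 3 complete copies, but the
interior-most copies must be perfect so that the array never creeps into
flanking sequence; this keeps planted perfect arrays exactly recovered
(end, interval, copy count) while accepting the ragged arrays of real
assemblies. Feature-to-telomere distance is the bp gap between the feature
boundary and the nearest same-contig array boundary; cluster telomere
linkage uses a 100 kb threshold by default.

## SM cluster delimitation

Signature genes are identified from functional-domain annotations: NRPS
(IPR010071, IPR006163, IPR001242), PKS (IPR013968), DMATS-family aromatic
prenyltransferases (IPR017795, Pfam PF11991), and terpene
synthases/cyclases (IPR008949). Pseudogenes match but are flagged.

Boundaries follow the primary-metabolism ortholog rule: genes whose
ortholog group spans all input genomes are treated as probable primary
metabolism ("core"); extension from the signature gene includes genes
whose group is *not* core (genes with no group at all are treated as
accessory, i.e. cluster-extendable), and stops in a direction at
`stop_run` consecutive core genes. The default `stop_run = 2` is a design
choice: 1 would truncate clusters at single inserted housekeeping genes,
which demonstrably occur inside real alkaloid loci. The first core gene on
each side is recorded as the flank. Whether flanking repeat blocks belong
inside the boundary is genuinely ambiguous, so both behaviours are
supported (`include_flanking_repeats`), defaulting to gene-span boundaries.

Per-cluster accounting intersects masked repeat intervals and CDS intervals
with the boundary and reports $\log_{10}(\text{repeat bp}/\text{CDS bp})$,
undefined (and flagged) when either count is zero. A cluster is inactive
iff all its signature genes are pseudogenes. The core–periphery layout
statistic is this package's own formalisation (and is labelled as such):
genes are ranked along the cluster, each gene's peripherality is its
normalised distance from the midpoint, and the statistic is mean
peripherality of decoration genes minus that of skeleton genes, with a
seeded label-permutation p-value.

## Ortholog-group refinement

Groups from Markov-cluster-style orthology inference may mix orthologs with
ancient paralogs. Each group is refined by recursive bipartition: align the
members (equal-length members pass through; unequal lengths go to `mafft`
via a pluggable alignment contract), compute identity-based p-distances,
and propose the deepest split of an average-linkage clustering. The
division is accepted iff (a) bootstrap support — the fraction of
column-resampled replicates reproducing the same member bipartition — is at
least 0.75, and (b) the split score, $|taxa(A) \cap taxa(B)| /
\min(|taxa(A)|, |taxa(B)|)$, is at least 0.5 (a high split score means many
taxa sit on both sides: the signature of a duplication predating
speciation). Accepted splits recurse; groups under 3 members, or whose
clustering cannot produce exactly two subclusters, are left unpartitioned
(terminating rather than looping on such clusters). The distance metric,
linkage, and deepest-split proposal are pinned choices documented here
because the acceptance rule, not the proposal mechanism, is the
specification; B defaults to 100 replicates. A reciprocal-best-hit
single-linkage grouper is included as a simplified stand-in for producing
input groups.

## Chemotype prediction

Each pathway is a JSON-encoded acyclic product-dependency graph
(`inst/extdata/rulesets/`). EAS: {dmaW, easF, easE, easC} → chanoclavine-I;
+{easD, easA, easG} → agroclavine; +cloA → elymoclavine → lysergic acid;
+{lpsB, lpsC} → ergonovine; +{easO, easP} → LAH; lysergic acid + {lpsA,
lpsB, easH} → ergopeptines. LOL: seven genes → the AcAP stage, +lolO →
NANL, +{lolN, lolM} → NML, +lolP → NFL. IDT: {idtG, idtM, idtB, idtC}
(+idtS, co-required but toggleable since its role is undetermined) →
paspaline, then +{idtP, idtQ} → paxilline-type, +{idtF, idtK} →
terpendole-type, +{ltmE, ltmJ} → lolitrem B. PER: complete perA → peramine;
the reductase-deleted form (`delta_r`) is a distinct recorded state that
yields none. Pseudogene and absent are treated identically as
non-functional. A product is producible iff its whole ancestry is
reachable; the deepest reachable products are the accumulating end
products; the missing genes of the shallowest unreachable node are reported
as the block. The oxidase for agroclavine → elymoclavine is not firmly
assigned in all genera, so elymoclavine's cloA requirement can be relaxed
(`ec_oxidase = "unknown"`). lpsA sequence variation chooses *which*
ergopeptine; gene content alone supports only class-level product names,
with the number of distinct ergopeptines taken as the lpsA copy number.
The shipped genotype table covers the 16 sequenced strains; a companion
expectations table records which observed products each genotype should
explain, including one documented expected-discordant case (a
near-complete but unexpressed EAS cluster).

## The synthetic generator: what it emulates, and what it does not

`generate_genome()` assembles each contig from i.i.d. background at a
specified GC with planted features spliced in: transposon-family copies
(per-copy substitution then single-pass RIP in CpA/TpG context; optionally
nested inside earlier copies, splitting the host's truth interval into two
segments under one copy id), MITEs built as TIR–loop–revcomp(TIR), terminal
telomere arrays (reverse-complemented at 5' ends), SM clusters laid out
role-by-role with intergenic repeat blocks, and background housekeeping
genes carrying core ortholog groups. Features are separated by at least
60 bp of background: planted elements are modelled as discrete, so two
elements never abut and read as one. All coordinates are 0-based half-open
internally; GFF3 emission converts to 1-based inclusive. The seed fully
determines the output bytes.

Deliberate simplifications, which bound what green tests demonstrate about
real data: background is i.i.d. (no isochores, no simple-sequence
repeats), genes have a single CDS and no codon structure, RIP is one pass
with no spreading or rid-dependence, repeat copies are full-length (no
5'-truncated retro-relics), and assemblies are gap-free unless N's are
injected. Real assemblies break repeats across contigs, carry nested
decay hierarchies deeper than one level, and contain segmental
duplications that are not transposons; recall/precision numbers on the
synthetic genomes are therefore upper bounds on real-data performance.
Per-copy RIP intensity in real genomes is not quantified anywhere
authoritative; the generator's rates (0.2–0.5 for RIPped families) are
free parameters chosen to produce the strong AT-skew seen in epichloid
repeat blocks, not estimates.

## Problem sizes and determinism

The test suite and acceptance script exercise: repeat discovery on a 5 Mb
two-contig genome with 8 families spanning 3–20 copies and 85–100% copy
identity; RIP classification on 100 copies (rate 0.5 vs 0) with a 600 kb
background; telomere recovery over five seeded two-contig genomes; MITE
classification on a 900 kb genome with five MITE and five non-MITE
families; cluster delimitation on 50 seeded replicates plus a brute-force
scan oracle on randomized layouts; and orthology refinement at B = 100
over 20 seeded duplication scenarios, with 1 000 random set pairs for the
split-score formula. All randomness flows from explicit seeds; BLAST hit
tables are re-sorted deterministically so results are invariant to contig
input order, and a pipeline rerun with the same configuration is
bit-identical.

## Known limitations

RIP-aware (reduced-alphabet) alignment is not implemented, so extremely
RIPped copies can fall below even the permissive masking identity floor
and be missed. MITE superfamily assignment and autonomous/non-autonomous
pairing are out of scope. The refinement proposal (deepest average-linkage
split) is one reasonable choice among several; alternatives can change
*which* split is scored, though not the acceptance rule. Chemotype
prediction is strictly gene-content logic: it cannot see expression,
sequence-level specificity differences (lpsA, idtP/idtQ, easA variants),
or trans-acting factors, and one shipped case is expected-discordant for
precisely that reason.
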