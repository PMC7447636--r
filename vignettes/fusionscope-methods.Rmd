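---
title: "Characterizing PK/TF gene fusions: models, rules and design choices"
author: "fusionscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing PK/TF gene fusions: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gene fusions created by chromosomal rearrangement join the 5' portion of one
gene to the 3' portion of another. Whether the resulting transcript encodes a
functional chimeric protein depends on where the junction falls and whether
the downstream partner's reading frame is preserved. Fusions involving
protein kinases (PKs) and transcription factors (TFs) are of particular
interest in cancer because both families sit at the control points of
cellular signaling. `fusionscope` implements the full characterization
workflow for a cohort of fusion breakpoint calls: transcript assembly and
frame prediction, protein-producing classification, full-length domain
retention and PK/TF domain specificity, maximal foreseeable interactor sets
with pathway-hierarchy mapping, and a replicated random-control
differential-expression procedure with pathway z-scores. A first-class
synthetic-data module generates every input with known ground truth, so
every stage is testable without any external download.

## Fusion assembly and frame prediction

Breakpoints are taken at annotated exon boundaries: the 5' breakpoint is the
last included base of an exon of the 5' partner, the 3' breakpoint the first
included base of an exon of the 3' partner (junctional reads map to exon
structure; intra-exon breaks are out of scope). The fused transcript is the
plain concatenation of the two transcript segments, and translation starts
at the 5' partner's annotated start codon.

Let `nt5` be the number of coding bases the 5' partner contributes and
`o3` the 0-based offset of the 3' breakpoint into the 3' partner's CDS. The
fusion is called **in-frame** when `o3 mod 3 == nt5 mod 3`, i.e. the codon
phase at the junction matches the 3' partner's annotated phase, so
translation runs through the wild-type 3' frame to the wild-type stop.
Two deliberate refinements:

* When the phase is non-zero, the junction-spanning codon is a hybrid of
  both partners. If that hybrid happens to be a stop codon, translation
  terminates at the junction and no 3' sequence is produced; such junctions
  are classified out-of-frame even though the phase arithmetic matches.
  This keeps the phase rule consistent with what translation actually
  yields, and the equivalence is enforced by a property test against an
  independent translation oracle (translate the fused sequence in the 5'
  CDS frame; check the wild-type 3' peptide suffix is reproduced).
* A junction upstream of the 5' CDS start is a **promoter swap** (full or
  truncated 3' gene under the 5' promoter): no protein is called.

Amino-acid bookkeeping: `aa5` counts codons completed strictly 5' of the
junction; the junction-spanning codon — a tie the convention must break —
is attributed to `aa3`, and `aa5 + aa3` always equals the product length. A
fusion is **protein-producing** when it is in-frame and both partners
contribute *more than 30* amino acids (strictly `> 30`, i.e. at least 31;
30 residues is the length of the shortest non-repeat domain, so shorter
contributions cannot carry an intact domain). Out-of-frame fusions are
translated to their first stop and retained as records, but are never
protein-producing.

One canonical transcript per gene is used (the synthetic genome has exactly
one; for real annotation sets the longest CDS would be chosen). This keeps
deduplication keys stable; isoform-exhaustive annotation would multiply
records without changing any downstream rule. Uniqueness is keyed on gene
ids, biotypes, breakpoints, frame effect and protein sequence; domain-level
analyses use a second pass keyed on (gene pair, protein sequence) only.
Pair labels are reported alphabetically regardless of 5'/3' orientation.

## Clinical harmonization

Stage strings are normalized case-insensitively: trailing sub-stage
qualifiers (A/B/C with optional numerals) are stripped ("Stage IIA" becomes
"Stage II"), and "Stage 0", "Stage X" and "I/II NOS"-style entries map to
absent. Topography codes keep the substring before the dot (C56.9 becomes
C56). The barcode join key is the first three dash-delimited fields of the
TCGA-style barcode. Breakpoints are binned into 20 equal 5% intervals per
contig with `floor(20 * (position - 1) / length)`, half-open on the position
scale — the edge rule is ours, chosen so position 1 falls in bin 0 and the
last base in bin 19. Stage summaries count unique fusion-sample pairs
(whether to count unique fusions or per-sample occurrences was open; the
fusion-sample pair is what a stage-resolved cohort table naturally counts),
and groups under 10 samples are flagged rather than dropped.

## Domain intactness and specificity

A wild-type domain instance (accession, protein, 1-based amino-acid
interval, sequence) is **intact** in a fusion protein exactly when its
full-length sequence occurs unmodified in the predicted product — a
truncation by even one residue breaks the call, in contrast to annotation
tools that count a domain as conserved from 5 retained residues.
Junction-spanning reconstructions count: the match is on the product, not
on either half. The same instance counts once per fusion regardless of how
many positions it matches. Sides are assigned from the matched position
relative to `aa5`.

A domain accession is **PK-specific** (resp. TF-specific) when at least 95%
of its intact copies sit on PK (TF) sides. Two ambiguities were resolved
explicitly: the threshold is `>= 0.95` (not strictly greater), with the
boundary unit-tested at 19/20 = 0.95 (specific) vs 18/20 = 0.90 (neither);
and the denominator is the intact copies within the analyzed fusion set,
not a global proteome census — a documented divergence risk when comparing
against censuses computed over whole proteomes. A copy on a gene carrying
both PK and TF labels counts toward PK, keeping classes mutually exclusive
and `copies_pk + copies_tf <= copies_total`.

## Interactors and pathway hierarchy

The **maximal foreseeable interactor set** of a fusion is the union of both
wild-type partners' interaction neighborhoods, minus the partners
themselves, over edges that are both physical and experimentally supported.
"Physical by experimental methods" is operationalized as two flags derived
from the PSI-MITAB interaction-type and detection-method vocabularies via a
configurable mapping (association/direct-interaction types are physical;
inference-style methods are non-experimental). Parsing and policy are
separated: the reader returns all edges with flags; discarding happens in
the analysis.

The pathway hierarchy is a rooted DAG with unit-weight parent-child edges
and gene annotations at all levels. Each node's distance to the nearest
root is computed with Dijkstra's algorithm (the stated method; with unit
weights it reduces to breadth-first search, and a BFS oracle enforces exact
equivalence in the tests). Per-pathway loads are emitted in both phrasings
used for reporting: the number of fusions with at least one interactor in
the pathway, and the summed per-protein load; per-project values are
normalized to [0, 1] so the pathway with most interacting fusions scores 1
(ties all score 1).

## Replicated random-control differential expression

Case groups are fusion pairs whose samples carry a protein-producing fusion
with at least one intact PK-/TF-specific domain; at least two expression
files are required per pair. The control pool contains samples whose
protein-producing fusions are all non-PK/TF — a sample with any PK/TF
fusion is excluded, and a sample may belong to several case groups (tie
handling the source procedure leaves unstated). Per replicate, an
equal-size control set is drawn uniformly without replacement with a fresh
seed stream derived from the master seed and the replicate index, and a
negative-binomial test is run: RLE size factors, dispersion shrinkage
toward a mean trend, a quasi-likelihood F-test of the group coefficient
(the small-sample-calibrated variant of the NB GLM test) and
Benjamini-Hochberg adjustment, with all-zero genes excluded from testing
and from the multiple-testing denominator. The NB-GLM contract — not any
particular package — is normative; the implementation is backed by edgeR
and cross-checked in the tests against an independent DESeq2 fit on the
same data.

Whether the q-filter applies per run or once on averaged statistics was
underdetermined; the implemented choice is per-run filtering with a
run-fraction rule: a gene is reported when significant (`q < 0.05`) in at
least half of the replicates in which it was tested (the fraction is
configurable). `basemean` and the per-condition means ("expected values",
read as normalized per-condition mean counts) are averaged across those
replicates, and the reported fold change is
`log2((avg_case + 0.5) / (avg_control + 0.5))` — the 0.5 pseudocount bounds
the statistic without dropping zero-mean genes. Pathway z-scores use
lowest-level hierarchy terms only:
`z = (n_up - n_down) / sqrt(n_up + n_down)`, with `|z| > 7.5` flagged for
highlighting.

## The synthetic cohort: what it emulates, and what it does not

The generators produce a miniature of the study's input universe with known
ground truth. Defaults (the study conditions at desk scale): 80 genes on
one contig each, 80 samples across 4 projects, 250 fusion calls, an
in-frame target fraction of 0.69 (the in-frame share observed in the
full-scale cohort), 10% of genes labeled PK and 10% TF (high enough that
PK/TF fusions are well represented at this scale while most fusions remain
non-PK/TF), log-uniform baseline expression means between 20 and 2000
counts, and a shared NB dispersion of 0.1 (`var = mu + d * mu^2`) — typical
of bulk tumor RNA-seq. Three recurrent in-frame PK/TF fusion pairs are
planted in 5 samples each so that pair groups with at least two expression
files exist, with planted fold changes of 2^±2 on 20 genes per pair. Domain
accessions are planted in three pools — exclusively-PK, exclusively-TF and
mixed — so true specificity classes are known. Interaction networks grow by
preferential attachment (scale-free-ish degree distribution) with a
configurable non-physical edge fraction; the pathway hierarchy is a rooted
DAG of depth 4; clinical tables carry deliberately dirty stage strings and
dotted topography codes.

Deliberate non-goals of the emulation: real chromosome structure (one
contig per gene — nothing downstream requires shared contigs), read-level
simulation, isoform diversity, intra-exon breakpoints, library-size
heterogeneity beyond what NB sampling induces, and correlated expression
between genes. Passing tests therefore demonstrate the correctness of the
rules and procedures, and the statistical calibration of the DE machinery
under the stated NB model — not robustness to alignment artifacts, batch
effects or annotation errors in real data.

## Numerical and scale choices

Coordinates are 1-based inclusive everywhere (GTF convention); any
half-open arithmetic is internal. In the GTF dialect written and read here,
CDS features include the stop codon (no separate stop_codon feature), so
CDS length is divisible by 3 and round trips are lossless. Determinism:
every generator and the whole pipeline are pure functions of (spec, seed);
per-replicate seeds are derived from the master seed with the replicate
index mixed in, so runs are reproducible under any execution order.

Test and demo problem sizes were chosen so the full property suite
exercises each guarantee at meaningful scale: 500 random fusions for
frame-oracle equivalence, 250 for domain-oracle equivalence, 50 random DAGs
of up to 200 nodes for the BFS equivalence, the exhaustive (n_up, n_down)
grid to 30 for the z-score closed form, 100 null groups of 1000 genes for
calibration, and 20 simulation repeats of the 50-replicate recovery
experiment (10% planted genes at log2FC = 2, 5 cases vs pools of 15). The
demo pipeline uses 25 replicates per pair; the full-scale procedure uses
1000.

## Known limitations

* Counts of unique fusions depend on the canonical-transcript choice;
  isoform-aware annotation would produce more records per call.
* The specificity denominator (intact copies in the fusion set) makes
  classes dataset-relative; a domain unanimous on PK sides in a small
  cohort may not be PK-specific proteome-wide.
* The promoter-swap class covers junctions upstream of the 5' CDS start
  only; UTR-aware promoter analysis is out of scope.
* With very small case groups (2-3 samples) the QL test is conservative,
  and the run-fraction rule then reports few genes; this is by design
  (error control over discovery).
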