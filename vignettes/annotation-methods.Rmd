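---
title: "Annotating de novo transcriptome assemblies by reciprocal best hit"
author: "DenovoAnnotate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating de novo transcriptome assemblies by reciprocal best hit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DenovoAnnotate)
```

## The setting

Pyrosequencing-era *de novo* transcriptomes come out of the assembler as
three kinds of product. *Contigs* are overlapping read groups and may
correspond to exons. *Isotigs* are continuous paths through a contig set
and stand for predicted transcripts; the isotigs built from one contig set
form an *isogroup*, the assembler's nearest approximation of a gene, since
alternate paths through shared contigs usually mean splice variants.
*Singletons* are quality-passing reads that overlap nothing and are kept
unassembled. Without a reference genome, none of these units can be
validated directly; annotation and quality control must instead lean on a
well-annotated reference proteome from another species. This package
implements that post-assembly layer: redundancy removal, reciprocal-best-
hit orthology with isoform/paralog classification, completeness and
saturation diagnostics, category partitions, and the supporting
statistics.

## Redundancy removal

Assemblies of this kind carry near-identical sequence copies created by
polymorphism, sequencing error and low-quality reads. Before annotation,
a product is removed when a self-comparison HSP aligns it to a *longer*
product at more than `min_identity` (default 95) percent identity over the
product's full span. Three reading choices deserve note:

- *Identity* is taken from the HSP's percent-identity column — the only
  direct identity measure in the tabular format; the bitscore is used only
  to pick the reported retainer among several qualifying ones.
- *Full span* means the span of the query (the shorter, removed sequence):
  the HSP must reach within `end_slack` bp of both query ends. The default
  slack is 0; a few bp of slack accommodates homopolymer-driven end errors
  typical of pyrosequencing. A fractional-coverage mode (`min_cover`) is
  available instead.
- Removal is judged in a *single pass against the original product set*,
  so a containment chain a ⊂ b ⊂ c removes a and b and keeps only c, and
  the outcome is independent of row order. Equal-length mutual duplicates
  are broken lexicographically (the larger id is removed) — an explicit
  determinism rule for a case the underlying method leaves open.

## Reciprocal-best-hit orthology

The annotator takes two BLAST comparisons: *forward*, each reference
protein against the transcriptome (tblastn-style, at most `top_n_forward`
= 50 hits per protein), and *reverse*, each transcript against the
proteome (blastx-style). Both are filtered at `e_cutoff` (default 1e-5,
inclusive). For each protein P, in lexicographic order, candidates are
visited in (E-value, −bitscore, subject id) order; candidate T is
*confirmed* when the reverse index maps T back to P — the reciprocal-best-
hit criterion. Then:

1. The first confirmed T is an **ortholog**.
2. A later confirmed T′ whose forward HSP overlaps *every* previously
   accepted call for P by at most `max_nonoverlap_aa` = 14 residues (on
   P's residue coordinates) is also an **ortholog**: the two transcripts
   cover distinct regions of the protein, as happens when transcript
   fragments of one gene fail to assemble together.
3. Otherwise T′ is an **alternate isoform** when it is a singleton or
   shares an isogroup with *any* previously accepted call for P, else a
   **putative paralog**. (Reading "the existing sequence" as "any accepted
   call" is our documented choice for the case of more than one.)

Overlap strictly greater than 14 residues triggers branch 3; exactly 14
does not. When a candidate pair has several HSPs, the best HSP under the
tie rule represents the candidate's interval. A transcript already
assigned to another protein is skipped, so calls are one-to-one on the
transcript side; a transcript that fails confirmation for one protein
remains available to others — confirmation failure is evidence about that
pairing only. All orderings are fixed (proteins lexicographic, candidates
by the tie rule) because "top hit" is otherwise nondeterministic across
file orderings.

## Ortholog hit ratio

Completeness of each annotated product is proxied by the *ortholog hit
ratio*: product length divided by the cDNA length of its putative
ortholog's transcript. A ratio near 1 suggests a full-length transcript.
Ratios are not capped at 1 — UTR differences between species push some
beyond it, and the summary keeps an explicit overflow bin. Threshold
summaries (`frac_ge`, defaults 0.5 and 0.8) use inclusive comparisons.
When the reference gene has several transcript isoforms the caller decides
which length to supply; the conventional choice is the longest.

## Saturation analysis

To ask whether deeper sequencing would keep discovering genes, random read
subsets (10 %…100 % by default) are each assembled and annotated, and the
per-subassembly unique-hit count, N50 and coverage per bp are compared.
Subsets are drawn uniformly without replacement over *sorted* ids, so a
(fraction, seed) pair determines the subset regardless of input order;
subset size uses half-up rounding. Subsets are independent rather than
nested by default, with a nested mode available for variance reduction.
Assembly itself is out of scope — callers plug in an external assembler or
the synthetic module's truth-backed tables. The machinery deliberately
does not force unique-hit counts to be monotone: near full depth, merging
of previously separate contigs can genuinely lower the count. The
coverage-vs-reads fit is ordinary least squares with R² = 1 − SSres/SStot
and the convention R² = 0 for a constant response.

## Partitions and composition

Products split into hit / no-hit against a reference protein database at
the significance cutoff. Unidentified products can be partitioned further:
by clade-restricted similarity (exclusive to collection A, to B, both, or
neither — an exact four-way partition), by predicted coding regions
(ESTScan-style calls, consumed not computed), and by predicted protein
domains (InterProScan-style tables). Domains are predicted on coding
regions, so a domain row on a non-coding product is an integrity error
unless explicitly relaxed. Domain tallies collapse related accessions into
families ("zinc finger (combined)", "DUF (combined)", …) via an editable
map, count each (sequence, family) incidence once — per-sequence rather
than per-occurrence counting is the default, with the alternative behind a
flag — and report top-k proportions over the top-k total (the denominator
choice is documented rather than implied).

## Statistics

Welch's *t*-test is used for length comparisons across annotation
categories because their variances differ strongly: t = (m₁ − m₂)/√(s₁²/n₁
+ s₂²/n₂), Welch–Satterthwaite degrees of freedom, two-sided p. Pairwise
category matrices code significance as `***` (p < 0.0001), `**`
(p < 0.001), `*` (p < 0.05), numeric otherwise. No multiple-testing
correction is applied to these matrices; that mirrors standard practice
for descriptive length tables and is stated rather than silently changed.
The assembly summary calculator keeps every percentage tied to a
documented denominator (pass rate over raw reads; read fates over passed
reads; hit rates over isotig or singleton totals; single-isotig rate over
isogroups), retains unrounded values, and uses half-up rounding to two
decimals only for report strings. Medians of even-sized samples are the
midpoint of the central pair, so half-integral medians are expected. N50
is the largest L whose at-least-L sequences hold half the assembled bases,
computed by the standard descending cumulative scan.

## The synthetic truth generator

`generateTruth()` builds the study conditions every test runs under: by
default 500 reference genes; 8 % get an isoform partner, 6 % a paralog
partner, 4 % a second region-split ortholog; 5 % of primary transcripts
get a planted full-span duplicate. Those rates were chosen once to mirror
the modest isoform-per-isogroup ratios (≈1.2–1.3) and redundancy levels
typical of pyrosequencing assemblies while exercising every classifier
branch, and they are not tuned thereafter. The generator plants positive
and negative instances on both sides of each decision boundary: overlaps
of exactly 14 (ortholog) and 15 (isoform/paralog) residues; containments
at 96 and 100 % identity (removed) against 94 % and partial-span copies
(kept); same-isogroup and singleton isoform branches against cross-
isogroup paralogs. `emulateHits()` emits hit tables whose E-value ranking
puts planted pairs first; `drop_rate` deletes true rows (with exact
bookkeeping, so degradation tests are set-exact, not statistical) and
`decoy_rate` adds non-reciprocal rows strictly worse than any true row, so
decoys can never displace a true best hit — separating classifier logic
from ranking noise.

What the generator does *not* emulate matters for interpretation: there is
no codon structure, no expression-level variation, no 454 homopolymer
error model, and homology is declared rather than discovered by alignment.
Passing tests therefore demonstrate that the *decision logic* implements
its rules exactly, not that BLAST against a 2011-era database would
reproduce any particular published rate on real reads.

## Numerical and scale choices

Deterministic tie-breaks appear wherever the inputs leave an order open:
HSPs by (E-value, −bitscore, subject id); proteins lexicographic;
equal-length duplicate pairs lexicographic; domain-tally ties
lexicographic. E-value and OHR threshold comparisons are inclusive.
Degenerate inputs have defined behaviour: empty hit tables are valid,
empty length lists are errors, zero variance with equal means yields
t = 0, p = 1, and a constant saturation response yields R² = 0. Test and
acceptance runs use 100–500-gene truth sets and 1,000-replicate
calibration loops — sizes at which every planted-recovery check is exact
and the whole suite completes in minutes on one core.

## Limitations

The annotator is a best-reciprocal-hit method: genes more similar to a
non-reference species, lineage-specific duplications and genuine
many-to-many families are outside what it can label, and its "paralog"
category is a statement about assembly geometry, not a dated duplication.
OHR uses a cross-species cDNA length as proxy and is biased wherever UTR
lengths diverge. The redundancy filter removes only strict full-span
containments — it is not a clustering step and will not collapse partially
overlapping variants. All BLAST computations are inputs: the package
parses and reasons about hit tables, it does not align.
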