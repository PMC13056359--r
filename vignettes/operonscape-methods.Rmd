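---
title: "Gene-neighborhood analysis with operonscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-neighborhood analysis with operonscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonscape)
```

## The scientific problem

Prokaryotic genomes link functionally related genes physically in operons, so
the genomic neighborhood of a gene carries information about its biochemical
role. `operonscape` implements a semi-quantitative synteny analysis for gene
families whose members fall into phylogenetically defined groups — the
motivating case is the nickel-iron carbon monoxide dehydrogenases
([NiFe]-CODH, clades A–F) and the related hybrid cluster proteins (HCP,
classes I–III). Given genome annotations, a table of target genes with their
clade/class labels, and functional annotations for the surrounding proteins,
the package answers three questions:

1. **Operon content.** Which functional categories (maturases CooC/CooT/CooJ,
   one-carbon-pool enzymes, ferredoxins and other FeS proteins, hydrogenases
   and their maturation machinery, oxidoreductases, regulators, transporters)
   are encoded in the same operon as targets of each clade, and in what
   proportion of targets?
2. **Isoform co-occurrence.** How often do multiple copies of the same clade,
   or members of different clades/families, co-occur in one genome assembly?
3. **Conditional co-occurrence.** For labels X and Y, what is
   `P(X|Y) = N_XY / N_Y`, the probability that an assembly encoding Y also
   encodes X? `N_Y` is the number of assemblies containing at least one
   member of Y, `N_XY` the number containing both. The matrix is asymmetric
   by construction whenever the marginals differ.

Clade labels are **inputs**: they come from an upstream phylogenetic
analysis, and the package never computes them.

## The operon model

An operon around a target is a chain of consecutive genes on one contig.
Walking outward from the target in each direction, the adjacent gene joins
while all of the following hold (`operon_params()`):

* at most `max_genes_each_side` = 15 genes on each side of the target;
* the signed intergenic distance across the junction,
  `next.start − prev.end − 1` on 1-based inclusive coordinates, is at most
  `max_intergenic_bp` = 300 bp; abutting genes are 0 bp apart;
* any overlap is at most `max_overlap_bp` = 50 bp (negative distances);
* with `require_same_strand = TRUE` (default) the gene lies on the target's
  strand.

Extension stops at the first failing gene and records the reason
(`gap_exceeded`, `overlap_exceeded`, `strand_change`, `gene_limit`,
`contig_end`); genes are never skipped, so operons are always contiguous.
The defaults are deliberately permissive — a 300 bp gap and a 50 bp overlap
allowance are generous compared to typical coding-gene spacing — on the
argument that spurious neighbors picked up this way dilute into noise while
a stricter rule would systematically miss true operon members.

Three modeling choices deserve note, because the underlying rule is often
stated loosely in the literature:

* **Chain semantics.** The gap rule applies between *consecutive* genes
  along the chain, not between each neighbor and the target. This matches
  operon biology (co-transcription is a property of adjacent junctions) and
  makes the rule composable.
* **Oversized overlaps break the chain** exactly like oversized gaps.
  Skipping the offending gene would create non-contiguous "operons".
* **Strand flips break the chain by default.** Known cases exist of a
  maturase encoded immediately adjacent to its target but on the opposite
  strand, and such genes are deliberately not counted as operon members;
  the behavior is exposed as a flag because reasonable analyses differ here.
  Genes without a protein product stay in the gene order: the 15-gene
  window is positional, so they occupy slots and take part in gap checks.

The caller is verified two ways: against a brute-force oracle that
enumerates every contiguous window containing the target and checks all
rules directly (exact agreement on 1000 random contigs), and against
hand-built boundary fixtures (gaps of 299/300/301 bp, overlaps of 49/50/51
bp, 14/15/16 genes per side, strand flips at each position).

## Functional categories

Operon members are mapped to a fixed category vocabulary by prioritized,
case-insensitive pattern rules over their NCBI product strings and
eggNOG-mapper descriptions. Rules are **data** (a TSV of
`category, priority, pattern, scope`), not code: the original assignment was
manual curation, whose criteria are not published, so the shipped rule set
is a best-effort reconstruction from public product-name conventions and is
fully user-editable. Its correctness is pinned by a curated fixture of 30
real-world product strings that must classify with 100% agreement.

Priorities resolve containment: every ferredoxin is an FeS protein, every
ABC transporter is a transporter, every hydrogenase maturase mentions
hydrogenases, so specific categories carry lower (winning) priorities than
generic ones. One category per gene; ties broken by rule-file order.
Accession-level overrides take precedence over all rules — the motivating
case is a curated CooJ list, since CooJ cannot be recognized from product
strings alone. The `regulation` subtypes (`transcription_regulation`,
`other_regulation`) are kept separate but can be merged with union
semantics (`merge_category_sets()`) for figure-style reporting.

An operon's **category set** is the set of categories present among its
non-target members, excluding `other` and the target's own category. The
per-clade profile then reports, per category, the fraction of targets whose
set contains it — per *target*, not per gene, so two CooC copies in one
operon count once. Targets with no neighbors (size-1 operons) stay in the
denominator. Reporting applies a strict 10% cutoff (a category at exactly
0.100 is not reported); the full table is always emitted alongside.

## Curation

Before neighborhood analysis, sequences shorter than 400 amino acids are
removed ("below 400" read strictly: length 400 is kept) and exact duplicate
sequences are dropped (first occurrence kept, mapping logged). Targets are
then linked to the gene records of their *stated* assembly; a target found
only in a different assembly is flagged in a mismatch report rather than
silently relinked, and unlinked targets are excluded downstream with
`|linked| + |dropped| = |targets|` guaranteed. Identity-threshold
clustering (cd-hit-style) is out of scope and inputs are assumed
pre-clustered. Accession version suffixes (`WP_x.1`) are stripped at a
single normalization point before every lookup.

## The synthetic-data generator

`simulate_assemblies()` generates multi-contig assemblies with known ground
truth so that every pipeline stage is testable without downloads. Per
assembly, each label is present independently with probability
`clade_presence[label]`; present labels draw a copy number; each copy gets
its own contig holding the target, its operon, and flanking distractor
genes. Operon neighbors are drawn per category from the per-label
`operon_neighbor_model` probabilities; within-operon junction gaps are
uniform on [−50, 300] bp, flank junctions either exceed 300 bp or flip
strand (probability `strand_flip_prob`), so every true operon satisfies the
chain rule and every flanking junction violates it — ground truth is
unambiguous by construction. Category identity is encoded in product
strings drawn from the default rules' language, so rule-engine solvability
is guaranteed; an `annotation_noise` fraction replaces products with
"hypothetical protein" (true category `other`) to exercise the fallback
path separately from parsing.

The defaults are chosen once to emulate the real survey's regime: presence
probabilities proportional to the reported clade sizes over their assembly
universes (A 0.12, B 0.13, C 0.17, D 0.25, E 0.40, F 0.24; HCP I 0.60,
II 0.02, III 0.25), copy-number distributions that make multi-copy
assemblies common for clades A/E/F and rare for B/C/D (putting roughly 30%
of CODH-positive assemblies above one copy), and neighbor-category
probabilities equal to the reported per-clade operon-content proportions
(e.g. clade A: one-carbon pool 0.93, CooC 0.62, FeS 0.31). One known
limitation of the independent-category model: it cannot simultaneously
match the stated category marginals *and* the stated no-neighbor fractions
for clades B (24%) and D (64%) — independence fixes the empty-set mass at
`∏(1−p_c)`. The category marginals were kept; the generator's no-neighbor
fractions for B and D are therefore higher than the survey's.

What a green test establishes: the pipeline recovers the generator's
parameters (conditional probabilities, isoform frequencies, category
proportions within exact binomial 95% confidence intervals) and reproduces
ground-truth operons and category sets exactly. What it does not establish:
robustness to real-annotation pathology (frameshifted or split CDS beyond
the simple shared-ID case, contig breaks inside operons, annotation
vocabularies far from NCBI/eggNOG conventions), nor correctness of the
clade labels themselves.

## Numerical and design choices

* **Coordinates** are 1-based inclusive (GFF3 convention); all gap
  arithmetic is defined on it.
* **Determinism.** All randomness flows from the single config seed;
  identical config + seed gives byte-identical simulator and pipeline
  outputs. Ties in gene order (identical coordinates) break by accession so
  `gene_index` is reproducible. The run manifest records timestamps and is
  therefore the one output excluded from byte-identity comparisons.
* **Undefined probabilities.** `P(X|Y)` with `N_Y = 0` is emitted as
  missing, never 0: a zero would fabricate certainty about an
  unobserved condition. The integer identity
  `P(X|Y)·N_Y = N_XY = P(Y|X)·N_X` is checked on integer counts before any
  division.
* **Assembly universe.** Cross-family matrices condition on the union of
  both families' assemblies; only `N_Y` conditions each column, so
  assemblies carrying one family but not the other are informative zeros
  for the cross blocks.
* **Multi-segment CDS** (shared GFF3 `ID`) merge to min-start/max-end; how
  the original analysis handled them is unstated, and this is the package's
  own choice, as is keeping product-less genes in the positional window.
* **Overlap bound.** Whether the 50 bp overlap allowance was capped in the
  original analysis is unstated; here any overlap beyond 50 bp breaks the
  chain, symmetric with the gap rule.

## Known limitations

Operon calling from spacing alone cannot see promoters, terminators or
transcription-unit boundaries; a known failure mode is a functionally
associated gene just outside the parameter envelope (e.g. an ACS subunit
coded a few genes downstream of the window, or a maturase past a >300 bp
gap), which is invisible to this analysis by design. Conditional
co-occurrence is reported raw, with no significance testing and no
phylogenetic correction, and assembly-scoped counting underestimates
organism-level co-occurrence when one organism spans several assemblies.
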