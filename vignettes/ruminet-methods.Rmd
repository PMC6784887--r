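---
title: "Methods: rule-based reconstruction of a rumen carbohydrate food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based reconstruction of a rumen carbohydrate food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ruminet` infers who degrades what in a fibrolytic gut community from
three inputs: annotated draft genomes, a metaproteomic detection table,
and metabolite panels. Every inference is a deterministic rule with an
explicit threshold; this vignette records the rules, the thresholds and
their defaults, the choices made where the design was genuinely open, and
what the bundled synthetic communities can and cannot demonstrate.

## Locus detection

A polysaccharide utilization locus (PUL) is anchored on a SusD-like gene,
recognized purely by Pfam membership (PF07980, PF12741, PF12771, PF14322).
SusC has no comparably specific Pfam in routine annotation output, so
SusC-like genes are recognized as TonB-dependent receptors by product
keyword or by the plug/barrel families PF00593/PF07715; both lists are
configurable (`defaultFlagConfig()`). A pair forms when a SusC candidate
lies within the *pairing gap* (default 2 ordinals -- "co-localized") on the
same strand; a SusD with several candidates takes the nearest, with a
distance tie resolved upstream.

Members are collected within **six open reading frames** of the pair's
ordinal span, counted from the nearer pair member in both directions, and
restricted to the pair's orientation. Six ORFs is the stated window of the
procedure this package operationalizes; counting from the nearer member is
our choice where the wording is directionless. ORF distance is measured on
a dense per-scaffold ordinal (0-based, assigned by start coordinate), so
intergenic distance in bp never matters. Loci from distinct pairs whose
member sets intersect on one strand are merged. Divergently transcribed
enzyme blocks inside the window -- common in real PULs -- are excluded by
default to honor the same-orientation rule and can be absorbed with
`includeDivergent = TRUE`.

A locus with neither a CAZyme nor a peptidase member is reported as
`susCD-only` rather than given a substrate: such SusCD pairs are real but
uninformative for linking genomes to substrates.

## Substrate rules

Substrate calls are data, not code: `inst/extdata/pul_rules.yaml` lists
rules in priority order, each a conjunction of family groups (OR within a
group) plus a forbidden set. Two rules are fixed by the underlying
procedure -- mixed-linked glucan = GH16 + GH30 + GH3, and
β-1,4-glucan = (GH5|GH9) + (GH3|GH94) in the absence of
side-chain-targeting hydrolases (the shipped forbidden set GH10, GH11,
GH43, GH51, GH67, GH115 approximates "side-chain-targeting"; the
literature does not enumerate it). The remaining rules (mannan, xylan,
starch, arabinan, pectin, protein) are conservative defaults distilled
from biochemically characterized loci and are expected to be edited per
study. No rule assigns "cellulose": cellulolytic PULs have not been
verified in culture, so β-1,4-glucan is the most specific glucan label
the engine will produce. Subfamily labels (`GH5_4`) are normalized to the
family for matching but preserved in the reported gene order.

## Proteomic gating

A microbial protein is *detected* when it has ≥ 2 unique peptides and its
peptides map to exactly one genome -- both conditions are load-bearing:
the two-peptide rule controls protein-level FDR, and genome-uniqueness
prevents conserved proteins from lighting up every genome in a clade.
Viral proteins use a deliberately more sensitive 1-peptide rule. These
thresholds (`minUnique`) are arguments everywhere they apply.

## Genomic potential and expression

Pathway definitions live in `inst/extdata/pathways.yaml` with per-category
thresholds:

| category | encoded when | default |
|---|---|---|
| generic / respiration | fraction of members present | ≥ 60% |
| rare 6C sugars (fucose, mannose, rhamnose) | full monomer pathway AND EMP | 100% + ≥ 6/9 |
| 5C sugars | isomerase AND epimerase AND PPP | 100% PPP |
| glucose / galactose | entry enzyme AND EMP | ≥ 6/9 |
| fermentation products | members of any one alternative pathway | ≥ ⌈2n/3⌉ |
| cellulose | cohesin AND dockerin AND a cellulase family | -- |

The EMP pathway is defined as the nine reactions from glucose-6-phosphate
isomerase through pyruvate kinase (hexokinase excluded); this is our
enumeration of the "9 EMP genes" count, which the source procedure does
not itemize. Boundary arithmetic is count-based with a 1e-9 guard so that
6/10 passes a 60% rule and 4/6 passes a two-thirds rule exactly.

Expression of a sugar trait requires the sugar's entry isomerase/kinase
plus at least one *downstream* EMP member (any member other than the entry
itself). Glucose is special-cased: because galactose enters glycolysis at
glucose-6-phosphate isomerase, glucose expression additionally requires
glucokinase or a glucose-specific transporter, and conversely
galactokinase plus a downstream EMP member carries galactose alone.
Cellulose expression requires detection of a cellulosome module (cohesin
or dockerin protein): free GH5/GH9/GH48 detections are shared with other
glucan mechanisms and are not accepted as cellulosome evidence.
Respiration traits are reported encoded-only; their expression is not
evaluated (anaerobic rumen metaproteomes are not expected to contain
them).

## CoMPP normalization

Order of operations per data set (one extraction of one sample):
replicate mean → scale so the maximal mean spot signal is 100 → values
below 5 set to 0; scaled data sets are then averaged across samples per
extraction, and the 5-floor is re-applied. The "mean before scale" order
is implied by "maximal mean spot signal"; applying the floor both before
and after averaging is our choice where the order is unstated, and it
guarantees no reported value in (0, 5). Normalization is scale-invariant
and idempotent. The polymer/monomer concordance screen (top-tertile
polymer signal, monomer below the panel median) is advisory output with
configurable quantiles; it operationalizes the qualitative
"selfish-uptake" argument and proves nothing by itself.

## Trophic network

One edge per (genome, expressed substrate trait), carrying its evidence
protein ids. Hubs default to degree ≥ 6 ("six or more substrates"); the
alternative "more than six connections" reading that appears in figure
legends of this literature is available by setting `minConnections = 7`.
Tiers: 1 = all incident substrates recalcitrant polymers (default set
cellulose + xyloglucan, configurable), 3 = all sugars, 2 = everything
else. The partition is exhaustive and exclusive over non-isolated genomes;
isolated genomes are unassigned and dropped from the graph by default.

## Dereplication

Similarity between two bins is the fraction of the query's scaffold length
covered by windows (default 500 bp) aligning at ≥ 98% identity, made
symmetric by taking the larger direction; windows are anchored by exact
21-mers (5 seeds per window) and extended gaplessly. This is a desk-scale
stand-in for whole-genome alignment: it has no indel handling, which is
adequate for grouping near-identical assembly duplicates, the only regime
where the 98% cut fires. "Similarity level" is interpreted as plain
aligned fraction (not identity-weighted). Groups are single-linkage
components strictly above 0.5; the representative maximizes the
single-copy-gene score `n_SCG − 2 × n_multicopy`, with ties broken by
total length and then lexicographically. The marker census is an input
table -- this package does not call markers from sequence.

## Virus--host linkage

Viral contigs must exceed 10 kb; circularity means an exact terminal
direct repeat of ≥ 20 bp (the length filter and circular counts in this
literature state no method; a terminal repeat is the standard assembler
signature). TNF profiles are strand-collapsed 4-mer frequencies (136
canonical components, ambiguous windows skipped). Host prediction takes
the Euclidean nearest genome, requiring distance ≤ `dMax` (default 0.03)
and a runner-up margin ≥ 0.002; both were calibrated once on synthetic
communities drawn from per-genome order-3 Markov models, where same-model
12--20 kb sequences sit at distance ≈ 0.01 and different models at
≥ 0.05. On real data, where host signatures are far less separable, these
defaults should be tightened and validated against CRISPR links. The
CRISPR detector is a minimal repeat finder (exact 23-mer seeds, repeat
length 23--47, spacers 20--50, ≥ 3 copies, ≤ 1 mismatch during extension
with trailing-disagreement trimming); it is a spacer extractor, not a Cas
annotator, and repeat boundaries can shift by a base or two when flanking
characters coincide -- protospacer matching (≤ 1 mismatch, either strand)
is robust to this. When both methods link the same pair, the CRISPR edge
wins.

## The synthetic community

`generateCommunity()` emulates the study's measured inputs: annotated
genomes (planted PULs with correct geometry; decoy SusCD pairs guaranteed
enzyme-free within six ORFs; pathway complements planted exactly at their
thresholds), detection tables (expression plan at 60% of planted features;
optional noise as shared-genome and 1-peptide rows, which the gates must
reject), CoMPP/sugar panels (mannan abundant, mannose trace -- the
selfish-uptake signature), bin sequences from per-genome order-3 Markov
models with planted CRISPR arrays and near-identical duplicate bins, and
viral contigs drawn from their host's composition model with planted
protospacers. Defaults (20 genomes, 260 genes each, 150 PULs, 40 viruses,
mimicry 1.0, seed-reproducible byte for byte) are the conditions under
which the acceptance checks run; `scripts/acceptance.R` uses them with
detection noise at 0.

What passing on synthetic data does **not** show: real annotations are
incomplete and wrong in correlated ways; real PULs have fuzzy boundaries,
nested operons and shared enzymes; real viral composition mimicry is much
weaker than a host-identical Markov model; and real CRISPR repeats are
near- rather than exactly identical. The generator establishes
correctness of the rule engine, not field performance of the thresholds.

## Problem sizes

Tests and the acceptance script run the full community above (20 genomes,
150 loci, 40 viruses, 20 kb sequence scaffolds), 1000 random scaffolds of
up to 200 genes against a brute-force locus oracle, and an end-to-end
determinism check on a 6-genome community -- sizes chosen so the whole
suite completes in a few minutes while exercising every rule boundary on
both sides.
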