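---
title: "Methods: genome-wide LRR-RLK family analysis with rlkfam"
author: "rlkfam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide LRR-RLK family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlkfam)
```

# The analysis

Leucine-rich repeat receptor-like kinases (LRR-RLKs) are single-pass
plant receptor kinases whose canonical architecture is an extracellular
LRR region, a transmembrane (TM) segment, and a cytoplasmic kinase
domain (KD), in that order from N- to C-terminus. Genome-wide surveys
of the family proceed through a fixed sequence of steps —
evidence-based identification, phylogenetic subfamily classification,
exon–intron structure profiling, tandem-duplication detection, promoter
cis-element analysis, functional enrichment and expression clustering —
and `rlkfam` implements each step as an explicit, tested function with
every threshold collected in one `PipelineConfig` object.

This vignette documents the model behind each step, the parameters and
their defaults, the numerical conventions, and what the synthetic-study
generator does and does not emulate.

# Identification model

Three evidence streams enter the family call:

* **Profile-HMM hits** for the kinase domain (Pfam Pkinase PF00069 and
  Pkinase_Tyr PF07714) and for the LRR families, kept at E-value
  $\le 10^{-10}$;
* **Similarity-search hits** against known LRR-RLK proteins, kept at
  E-value $\le 10^{-5}$ and identity strictly greater than 50%;
* **TM predictions** from two independent predictors, combined by the
  either-predictor rule: one reported segment from either tool makes
  the protein TM-positive. Segments from both tools are unioned for
  the architecture check.

The candidate set is the union of (a) proteins with both a passing KD
hit and a passing LRR hit and (b) proteins with a passing similarity
hit; the route taken is recorded. A candidate becomes a family call
when confirmed domain spans contain at least one LRR and one KD span,
the protein is TM-positive, and the domains lie in LRR–TM–KD order.
The order test compares span midpoints after merging overlapping
same-class spans: max LRR midpoint < min TM midpoint < min KD
midpoint. Midpoints were chosen because span boundaries from different
evidence sources jitter, while the relative positions of whole domains
do not; merging first prevents a long and a short overlapping span of
the same class from producing contradictory midpoints.

Failed candidates carry their first failing check as a rejection
reason, tested in the order `not_candidate`, `no_lrr`, `no_kd`,
`no_tm`, `bad_order`, which mirrors the order the filters are applied.

Two boundary conventions are deliberate. E-value cutoffs are applied
as $\le$ rather than $<$: hits exactly at the cutoff are practically
nonexistent in real searches, and $\le$ avoids floating-point
surprises at the boundary. The identity filter stays strictly
$> 50\%$ as conventionally stated. The identity value is the one
printed in the similarity table (the aligned-region identity), not a
full-length recomputation. The similarity table is read in
candidate-protein-as-query orientation: the first column and the query
coordinates describe the candidate.

Confirmed domain spans are an input table. When a confirmation run
(e.g. an InterProScan-style annotation) is unavailable, the HMM
alignment coordinates serve as spans; this keeps the step testable
offline with no loss of mechanism.

# Subfamily classification

Family genes are assigned to the 21 canonical subfamilies (I–XV with
the VI-1/VI-2, VII-1/VII-2, VIII-1/VIII-2 and XI-1/XI-2/XI-3 splits)
from a phylogeny in which reference leaves ("anchors") carry known
labels. The sub-split granularity lives entirely in the anchor table,
not in code: classification is as fine as the anchors are.

The propagation rule: starting at each query leaf, walk rootward to
the smallest clade containing at least one anchor and take the
majority anchor label; support is the majority share among the
clade's anchors. Label ties break by the smallest patristic distance
to an anchor of a tied label; residual ties are flagged `ambiguous`
and take the lexicographically first tied label so output is
deterministic. Unrooted input trees are midpoint-rooted first
(a deterministic, widely used convention). Published surveys delimit
subfamily clades by expert inspection; the majority-anchor walk is
this package's reproducible replacement for that manual step, and the
`compareTopologies()` stability report (fraction of leaves keeping
their label across two tree estimates) quantifies how robust the
assignment is to topology differences, the same way surveys compare
their maximum-likelihood and neighbour-joining trees.

# Gene structure

Domains live in protein coordinates; annotation lives in genomic
coordinates. Residues $p..q$ occupy spliced-CDS nucleotides
$3p-2..3q$; that run is cut at CDS segment boundaries and projected
back to the genome (walking the CDS 3'→5' genomically on the minus
strand). The number of introns inside a domain is then the number of
disjoint genomic intervals minus one. KD-based structure groups follow
the field's convention: group A = KD on one exon, B = split by one
intron, C = three or more KD exons. Counts above six KD exons — beyond
the commonly observed 3–6 range — are still accepted as group C, since
synthetic or unusual genes may exceed the observed range.

The extracellular domain (ECD) is defined as the region N-terminal of
the first TM segment. Its intron count is computed over the genomic
projection of the CDS only; introns in untranslated leader exons are
not counted, because domain evidence never reaches into UTRs and the
CDS projection is the only coordinate system both inputs share.

Intronless retrogene candidates are single-exon genes whose subfamily
contains at least one member with two or more introns — the witness
that close homologues carry introns the candidate lost. A subfamily
that is entirely intronless flags nothing: without a multi-intron
relative there is no evidence of loss.

# Tandem duplication

All annotated genes (family or not) are ranked along each sequence by
genomic start; scaffolds are ranked separately. Two family genes are
tandem neighbours when they share subfamily and sequence, at most 10
annotated genes lie strictly between them, and their gap distance is
at most 200 kb. Connected components of size ≥ 2 form tandem sets;
chaining is transitive, so a long array's end members may exceed the
pairwise window — consistent with observed arrays of up to 11 genes.

Two readings of the rule required a decision. "Separated by ten or
less genes" counts *all* annotated intervening genes, not only family
members, because the phrase describes genomic neighbourhood. The
"200 kb distance" is measured between the closer ends of the two gene
spans (gap distance, 0 when they overlap); gap is the conservative
reading and is configurable through `PipelineConfig`.

# Promoters and cis-elements

The promoter is the 1.5 kb window upstream of the start codon (the
first CDS base in transcription orientation): genomic
$[s-1500, s-1]$ on the plus strand and the reverse complement of
$(e, e+1500]$ on the minus strand, truncated (and flagged) at contig
edges. The scanner reports every IUPAC-compatible occurrence of every
catalog motif on both strands, overlapping occurrences included; a
palindromic motif is therefore reported once per strand by design.
Category presence is per gene: a gene counts once toward a category
when any element of that category matches, regardless of occurrence
count. Per-subfamily over-representation of a category uses the
one-sided hypergeometric upper tail against the family background,
with Benjamini–Hochberg adjustment across all (subfamily, category)
pairs of a species.

The shipped catalog (`inst/extdata/cis_catalog_synthetic.tsv`) uses
the field's conventional element names (ABRE, W box, LTR, STRE, …)
grouped into hormone/stress categories, but its motif strings are
synthetic placeholders, chosen ≥ 8 nt with at most two degenerate
positions. The catalog file is the source of truth for the
element-to-category mapping; analyses of real promoters should supply
a catalog with real motif definitions. Transcription-factor
binding-site profiling is the same mechanism with a second catalog
whose categories are TF families: "regulated by family X" is presence
of at least one motif of that family.

# Enrichment and proportion statistics

Term enrichment is the classical one-sided hypergeometric test
$p = \sum_{k \ge x} \binom{K}{k}\binom{N-K}{n-k} / \binom{N}{n}$
with BH adjustment across tested terms; it is validated in the test
suite against exhaustive subset enumeration for backgrounds up to
N = 12 at $10^{-12}$ tolerance. BH is applied within each analysis
family (one species, one ontology, one promoter scan), matching the
convention of the standard enrichment tooling.

Between-species subfamily proportions are compared with Fisher's exact
test on the 2×2 table (in-subfamily vs rest, species A vs B),
two-sided, BH-adjusted across subfamilies. The surveys this package
systematises call such differences "significant" without naming a
test; Fisher's exact is this package's explicit choice, symmetric in
the species and exact at small counts. Proportion ratios report a
zero denominator as `NA` rather than infinity.

Percentages in report tables are rounded half away from zero to one
decimal (81.25 → 81.3), the convention of printed tables; base R's
`round()` rounds half to even and would disagree on exact .x5 values.

# Expression

FPKM matrices are transformed as $\log_{10}(x + 1)$; the unit offset
makes zero FPKM map to zero and keeps the transform order-preserving
without special-casing zeros. k-means (default k = 2, the cluster
count used for fiber/ovule profiling) runs 25 restarts under a fixed
seed (default 17) and keeps the best within-cluster sum of squares;
hierarchical clustering (complete linkage, Euclidean distance) is cut
into exactly 4 groups, the count used for abiotic-stress profiling.
Both renumber groups by descending mean expression, so "group 1 =
highest expression" is stable across restarts and row orders; rows are
sorted internally before clustering so the partition ignores input
order. The DE filter keeps genes with $|\log_2\mathrm{FC}| > 1$ and
FDR < 0.05 in *every* required contrast (both pathogen strains);
magnitude is used because both up- and down-regulated genes are
reported in such analyses. DE statistics are inputs — the package does
not recompute FDR from counts.

# The synthetic study

`simulateStudy()` generates the complete input bundle with a manifest
that fully determines every stage's expected output at zero noise.
The default desk scale is 2 chromosomes plus 1 scaffold, 300 genes of
which 60 are family members across 8 subfamilies spanning structure
groups A, B and C, 4 tandem arrays (sizes 3, 2, 4, 2), two
out-of-window negative pairs (one separated by 12 intervening genes,
one by a > 200 kb gap), 2 retrogenes, 5 decoys covering every
rejection route, 1–3 planted motif occurrences in each family
promoter with one (subfamily, category) pair planted enriched, one
planted enriched annotation term, 2 planted fiber expression clusters
and 4 stress clusters, and planted DE genes passing both contrasts
plus genes passing only one. These sizes exercise every rule while a
full run stays in the tens of seconds; tests use smaller bundles of
the same design.

Generator conventions worth knowing:

* Deterministic: one seed drives all randomness; repeated runs emit
  byte-identical files, and the caller's RNG state is untouched.
* Promoter backgrounds are rejection-sampled to contain no catalog
  motif on either strand before occurrences are planted at recorded,
  non-overlapping offsets (degenerate positions instantiated
  concretely), so the scanner's expected output equals the manifest
  exactly.
* CDS segments exclude the stop codon, so protein length is exactly
  CDS/3; all CDS phases are 0 because exon cuts are placed at codon
  boundaries.
* Same-subfamily singletons are spaced more than the intervening-gene
  window apart, so the planted arrays are provably the only tandem
  sets.
* Noise knobs: `fnRate` drops a family gene's KD evidence across both
  the HMM and similarity streams (a per-gene dropout, so recall
  tracks $1 - p$); `tmDisagreeRate` makes predictor A miss the TM
  while predictor B reports it, exercising the either-predictor rule;
  `treeMisplacement` moves leaves into wrong clades.
* The generator requires at least 6 family genes and enough total
  genes to hold the planted structures; degenerate empty-genome cases
  are covered by the format readers' empty-input behaviour instead.

What passing on synthetic data does and does not show: the generator
emulates the *logical* structure of a family survey (evidence
integration, clade anchoring, coordinate arithmetic, adjacency rules,
motif counting, cluster separation), not the statistical texture of
real data — no sequence evolution model, no HMM score distributions,
idealised cluster separation, uniform-random intergenic sequence.
Passing tests certify the rules are implemented correctly, not that
real genomes will yield any particular family size.

# Scope and limitations

The package consumes the tabular outputs of the external tools a real
survey runs (HMMER, BLAST, InterProScan-style confirmation, TM
predictors, tree builders) and does not invoke them; alignment and
tree construction are out of scope, as are read alignment, FPKM
quantification and figure rendering. `runPipeline()` plus the exported
stage functions are the interface; report tables are plain TSV. The
manual clade delimitation of published trees cannot be recovered
exactly — the anchored majority rule is a documented, reproducible
stand-in — and the shipped cis-element catalog is fixture data, not a
motif database.
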