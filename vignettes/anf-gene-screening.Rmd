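---
title: "Screening genomes for antinutritional-factor metabolism genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for antinutritional-factor metabolism genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfscreen)
library(dplyr)
```

## The problem

Antinutritional factors (ANFs) in plant material — phytate, tannins,
phenolic acids, lectins, protease (trypsin) inhibitors, saponins and
α-galactooligosaccharides (α-GOS) — bind minerals, inactivate digestive
enzymes or simply resist digestion. Fermentation can remove them, but only
if the inoculated bacteria carry the corresponding enzyme genes. A
comparative-genomics screen therefore asks three questions of a genome
collection:

1. which genomes carry genes for which ANF-degrading enzymes;
2. how that gene content is structured across the collection (shared core,
   dispensable, strain-specific); and
3. which *combination* of a few strains jointly covers the most ANF types
   and genes — the consortium a fermenter would actually inoculate.

This vignette describes the models and procedures behind each stage, the
parameters that matter, the synthetic benchmark that exercises the whole
pipeline, and what the tests do and do not establish about real data.

## The enzyme catalog

Detection is catalog-driven. A catalog holds ANF *categories* (eight in the
packaged default: phytate degradation, myo-inositol metabolism, tannin
degradation, phenolic-compound metabolism, lectin, trypsin/trypsin-like
protease, saponin degradation via β-glucuronidase, and α-GOS degradation via
α-galactosidase), each with one or more *enzymes*. An enzyme carries:

* `product_keywords` — lower-case substrings matched case-insensitively
  against product annotations ("3-phytase precursor" matches `phytase`);
* `reference_proteins` — amino-acid baits for alignment evidence;
* `ec_numbers` — metadata only; matching never depends on EC strings, so we
  do not have to assert enzymatic identities the annotations cannot support.
  The packaged phytase entry carries EC 3.1.3.8/3.1.3.26/3.1.3.72 and the
  trypsin-like protease EC 3.4.21.4; the others carry standard nomenclature.

The default catalog's reference sequences are *synthetic* baits (random
sequences of 120–240 residues, fixed seed, committed verbatim in
`inst/extdata/anf_catalog_default.yaml`). This keeps the package
self-contained and the benchmark exactly controlled; for production screens
of real genomes they should be replaced by curated family representatives.
Nothing in the algorithms depends on the baits being biological.

## Detection model

For every protein × enzyme pair two kinds of evidence are evaluated:

* **Keyword evidence**: any enzyme keyword is a substring of the
  whitespace-normalised, lower-cased product annotation.
* **Homology evidence**: optimal global alignment (Needleman–Wunsch/Gotoh,
  affine gaps; BLOSUM62, gap open 11, extend 1 — the conventional protein
  defaults, fixed for reproducibility) against each of the enzyme's
  references, keeping the best by score, then identity, then reference id.
  The hit passes at identity ≥ `min_identity` (default 0.40) and coverage of
  both sequences ≥ `min_coverage` (default 0.70). Identity is the fraction
  of alignment columns with identical residues; in strict global mode every
  residue of both sequences is aligned, so coverages are identically 1 and
  the identity threshold does the work. The 0.40/0.70 defaults are
  conventional ortholog-screen settings; no published criteria exist for
  this exact screen, so they are exposed as parameters.

By default, alignment is only attempted for proteins whose product matches
*some* catalog keyword, plus all proteins with empty products — a prefilter
that keeps desk-scale runtimes without silently skipping unannotated
records. `full_scan = TRUE` aligns everything against everything, which is
what the benchmark uses, since its planted genes are deliberately annotated
only as "hypothetical protein".

A hit is emitted when either evidence passes (evidence recorded as
`keyword`, `homology` or `both`), at most one per (protein, enzyme).
Raising `min_identity` can only remove hits (a tested monotonicity
property).

## Ortholog clusters and the pan-genome partition

Orthology is approximated by bidirectional best hits: for genomes A and B,
proteins x ∈ A and y ∈ B are paired iff y is x's highest-scoring partner in
B and x is y's in A, subject to the same identity/coverage thresholds, with
ties broken by score, then identity, then lexicographic protein id (so best
partners are always unique and runs are deterministic). Ortholog clusters
are the connected components of the union of all pairwise BBH graphs —
single linkage, the simplest defensible stand-in for a full
ortholog-inference suite; stricter clique-based methods would split some
clusters and are deliberately out of scope. Unpaired proteins become
singleton clusters, so cluster sizes always sum to the number of proteins.

A cluster spanning all n genomes (by *distinct* genomes — paralogs do not
inflate the span) is core; exactly one genome, a singleton
(strain-specific); otherwise dispensable. `core + dispensable + singleton =
total` is asserted on every run.

## Presence/absence matrix, profiles, tallies

The binary matrix has one row per genome. In **enzyme-mode** the features
are catalog enzymes and paralogs collapse (cell = "has at least one gene
for this enzyme"); in **cluster-mode** the features are the ortholog
clusters containing at least one hit, so paralogous copies that BBH
separates appear as separate features — the representation that matches
per-gene presence heatmaps and per-gene counts ("a genome with three
phytase genes"). Both modes are exposed because published per-family gene
counts are ambiguous between the two readings. A cluster inherits the
category of its member hits; on the rare conflict (promiscuous keywords)
the highest-scoring hit decides and a warning is logged.

Per-genome profiles count distinct features per category, the total, and
the number of categories covered ("how many ANFs can this strain act on").
`tally_category()` implements the "n of N genomes harbor gene(s)" summary,
with `min_features` defaulting to 1 to match that phrasing.

## Gene-content clustering

Genomes are clustered by UPGMA over binary distances:

* **Jaccard** (default): `1 − |u∧v|/|u∨v|`, ignoring shared absences —
  appropriate for sparse gene content, where two genomes lacking the same
  genes is weak evidence of similarity. Two all-zero vectors get distance 0
  (indistinguishable, not maximally distant).
* **Simple matching**: fraction of disagreeing positions, offered because
  clustering tools differ in their binary defaults.

UPGMA merges the cluster pair at minimal average distance, at height =
distance/2, so the tree is ultrametric and its cophenetic distances equal
the merge distances exactly — a property the tests verify against a
brute-force recomputation of all average linkages from the original matrix
at every step. Ties (common with coarse binary distances) are broken by the
lexicographically smallest pair of cluster-minimum labels, and child order
at each node puts the branch with the smallest leaf label first, so leaf
order, Newick output and heatmap rows are identical across runs and label
permutations. Only average linkage is implemented: one well-tested path,
and gene-content dendrograms in this literature are average-linkage by
convention. Newick branch lengths are parent–child height differences.

## Consortium selection

Given the matrix and k, the selection objective is lexicographic by
default: maximise ANF categories covered by the union of the selected rows,
then distinct genes in the union. Published phrasing mixes "most genes"
with "most ANF types"; the lexicographic objective covers both readings and
a `genes` switch gives the pure max-coverage problem. Cluster-mode features
are the natural input, since "distinct genes" there means distinct ortholog
clusters.

`select_exhaustive()` enumerates all C(n, k) subsets (capped at 2×10⁶;
beyond that it refuses and points to greedy), reports the global optimum,
every tied subset, and returns the lexicographically smallest tie — ties are
real: in the package's own 4-genome worked example two pairs attain the
optimum. `select_greedy()` adds the genome with the largest marginal gain
(new categories, then new genes; ties by id) and inherits the classic
(1 − 1/e) ≈ 0.632 max-coverage guarantee, which the tests check against
exhaustive on random instances and on a constructed counterexample where
greedy is strictly suboptimal.

## The synthetic benchmark

`generate_collection()` plants, per genome and category, a
presence-probability draw followed by a copy-number draw
(1 + Binomial(`max_extra`, `per_copy_prob`)); each planted gene is a
catalog reference mutated by independent per-residue substitutions at
`mutation_rate` (no indels — expected identity ≈ 1 − rate, which keeps the
detection margin analytic; an indel model would blur it for no testing
benefit). Decoys are uniform-composition random sequences of length 80–400;
at those lengths the chance of reaching 40% global identity to a bait is
negligible, which the zero-decoy-hit results confirm empirically. Products
are either the enzyme name (annotated regime) or "hypothetical protein"
(unannotated regime, the default — so the benchmark exercises alignment
detection rather than string matching). Randomness is a per-genome
substream seeded by a stable hash of the genome id combined with the master
seed: byte-identical outputs for a fixed seed, independent of insertion
order.

`emulate_paper_groups()` configures four taxon groups with fixed presence
probabilities reflecting reported prevalence patterns for these taxa:
phytase universal in the *B. subtilis*-like group and absent from the
*Lactobacillus*- and *Pediococcus*-like groups (which instead carry
myo-inositol pathway genes, ~0.77/0.78); lectin, tannase and
β-glucuronidase absent from the *Bacillus*- and *Pediococcus*-like groups;
phytase in ≈ 60.7% of the Enterobacteriaceae-like group, with the remaining
per-group probabilities likewise fixed (tannase 17/155 and 9/150 in the
Lactobacillaceae- and Enterobacteriaceae-like groups, PAD/UbiX universal in
the *Bacillus*-like and Enterobacteriaceae-like groups, trypsin universal
in the *Bacillus*- and *Pediococcus*-like groups, α-galactosidase 95/155,
81/150, 1/9 and 1.0 across the four groups). α-galactosidase gets a wider
copy-number range (up to 10 copies) than the default (up to 3), matching
the reported spread of per-genome gene counts. Defaults: 12 decoys per
genome, mutation rate 0.05. The Pediococcus myo-inositol probability (0.78)
is a package choice — only "nonzero" is reported for that group.

What passing these benchmarks shows: the detection, matrix, partition,
clustering and selection stages are internally correct and recover planted
signal at 5% divergence with zero false positives from random decoys. What
it does not show: performance on real proteomes, where homologs diverge
with indels and domain rearrangements, annotations are inconsistent, and
decoys are biological sequences with real (sometimes borderline) homology.
The benchmark validates the machinery, not field sensitivity/specificity.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (GenBank/GFF3 convention);
  minus-strand CDS are reverse-complemented before translation with the
  bacterial genetic code (table 11); ambiguous codons translate to `X`; a
  concatenated CDS length not divisible by 3 warns and truncates.
* Alignment columns are computed arithmetically
  (`len_a + len_b − aligned pairs`); coverages are exactly 1 in strict
  global mode and are reported as such rather than dropped.
* All tie-breaks (alignment references, BBH partners, UPGMA pairs, greedy
  picks, tied optima) resolve by score, then identity, then lexicographic
  id, making every pipeline stage deterministic; rerunning a stage on
  identical inputs reproduces identical artifact bytes.
* Degenerate inputs are defined rather than errors where a convention
  exists (empty hit table → 0-feature matrix; all-zero distance matrix →
  star collapsed at height 0; both-empty Jaccard vectors → distance 0), and
  errors where silence would mislead (empty FASTA, duplicate ids, CDS
  without identifiers, category filters selecting nothing).

## Problem sizes

The test-suite and acceptance computations run at desk scale, chosen to
give tight checks at interactive runtimes: planted-gene recovery over 20
seeds of 40-genome collections (~3,000 planted genes); prevalence patterns
from a screened 800-genome collection (200 per group, so binomial noise on
a 60.7% prevalence is about ±3.5 points); 200 random ≤7-leaf matrices against the
UPGMA oracle; 200 random 6–12 × 10–30 instances (k ≤ 3) against the subset
brute force; and 5 small collections for partition conservation. Exhaustive
selection is capped at 2×10⁶ subsets; choosing 3 strains from ~350 genomes
(≈7×10⁶ triples) is reachable by raising the cap or using greedy.

## Limitations

* BBH + connected components can chain distinct families through a shared
  intermediate; clique-based or synteny-aware orthology is out of scope.
* No HMM/profile search and no E-values; detection sensitivity for remote
  homologs is bounded by pairwise global alignment.
* The packaged baits are synthetic; real screens should substitute curated
  references, and keyword lists inherit the biases of source annotations.
* No gene calling: inputs must be annotated (protein FASTA, GenBank with
  translations, or GFF3 + genomic FASTA).
* Sequence-based phylogeny, virulence/AMR screening and any wet-lab
  validation of actual ANF reduction are outside the package's scope.
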