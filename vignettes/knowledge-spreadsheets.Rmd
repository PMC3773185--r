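---
title: "Knowledge spreadsheets: model, transforms and enrichment statistics"
author: "kgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge spreadsheets: model, transforms and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgroups)
```

## The model

A *group* is a knowledge spreadsheet: an ordered, duplicate-free list of
members — frames of one knowledge-base class, or plain numbers, strings or
sequence regions — with additional columns attached. Column 1 is always the
member column. Other columns come in three kinds:

* **stored** columns hold arbitrary user data (e.g. expression values
  imported alongside gene identifiers);
* **property** columns hold the raw values of a knowledge-base slot for
  each member;
* **transform** columns hold the result of a semantic transformation
  that may traverse several relations (a gene's *pathways* column walks
  gene → product → complexes → reactions → pathways).

Cells are multi-valued: an ordered, duplicate-free collection. Frame-valued
cells are kept in id order so that every derived column is deterministic;
property and transform columns record their provenance (`slot` or
`transform` + parameters) and can be deleted and recomputed against a
knowledge base at any time (`recomputeColumn()`).

The knowledge base itself is a frame store in the style of a
pathway/genome database: 13 frame classes connected by directional relation
slots, each with a declared inverse, so that every relation is navigable in
both directions. The validator (`validateKb()`) asserts: reference
resolution and range classes; inverse symmetry over the whole KB; GO `is-a`
acyclicity, with each term in exactly one of the three ontologies
(molecular function, biological process, cellular location) and a single
root per ontology; a single-parent pathway-class tree; 1-based inclusive
feature coordinates within their replicon; and well-formed strand/direction
literals. Replicon sequences are held as `Biostrings::DNAStringSet`, and
all sequence extraction (including reverse-complementing minus-strand
regions) goes through `subsequence()`.

### Conventions worth knowing

* Coordinates are 1-based and inclusive at both ends; strands are `"+"` /
  `"-"`.
* Sigma factors are not a separate class: a regulator protein carries a
  `sigma-factor` tag, so the gene → *regulators* transform returns
  transcription factors and sigma factors alike, while
  *tf-binding-sites-upstream* keeps only sites bound by at least one
  non-sigma regulator.
* Regulation is wired through the chain binding site → promoter → operon →
  genes; the direct `regulates`/`regulated-by` slots are materialised
  consistently with that chain (the generator and the bundled fixture do
  this), and the *regulators* transform traverses the chain. Where the
  boundary between "regulates the gene", "its promoter" and "its operon"
  is ambiguous, this package treats them as the same thing.
* Promoters are modelled as transcription-start points (a single `pos`
  coordinate); the promoter *region* transform therefore yields a length-1
  region, and flank extraction (`promoterFlanks()`) takes `upstream` /
  `downstream` distances around that point, flipping the two on the minus
  strand.
* *same-operon-genes* returns operon siblings, excluding the query gene.
* Name resolution (`resolveFrames()`) is case-insensitive and tiered —
  id matches beat name matches beat synonym matches; within a tier all
  matches are returned in id order. TSV import takes the first match for an
  ambiguous token and records the ambiguity in the import report rather
  than failing the file.

## Group algebra and filters

Set operations require equal member classes and use standard set semantics
on members; the union keeps the left group's order followed by the right
group's novel members. Binary operations drop non-member columns: there is
no principled way to merge, say, two different stored expression columns
row-wise, and since derived columns carry their provenance they can always
be recomputed on the result. Filters preserve all columns.
`filterByThreshold()` uses existential semantics on multi-valued cells —
a row passes if *any* value passes — which matches what a spreadsheet user
expects of a multi-valued cell; empty cells never pass.

TSV export joins multi-valued cells with `" // "` (configurable via the
`sep` argument) and renders frames by display name. Header detection on
import treats the first line as a header when its first token resolves to
nothing and the file has at least two columns; `header = "yes"/"no"`
overrides the guess. Group persistence is versioned JSON rather than a
language-specific object dump, so saved groups remain readable by anything.

## Enrichment statistics

For a group of size $n$ from a population of size $N$ and a category with
$K$ population members, $k$ of them in the group, `fisherTail()` computes

$$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i}\Big/\binom{N}{n}.$$

The sum is evaluated in log space (`lchoose` plus log-sum-exp) and clamped
to $[0,1]$; the test suite and the acceptance script verify it against
exhaustive enumeration of all $\binom{N}{n}$ draws for every valid
$(k,n,K,N)$ with $N \le 12$ at an absolute tolerance of $10^{-12}$, and
against `stats::phyper` on random larger tables.

Annotations are propagated up the GO DAG before testing (the true-path
rule): a gene annotated to a term is implicitly annotated to all its
ancestors. This is standard for GO enrichment and is what makes the
parent–child variants well-defined. Those variants restrict the population
to the genes annotated to the **union** (`pc_union`) or **intersection**
(`pc_intersection`) of a term's parents and apply the same tail probability
inside that restricted population; they reduce exactly to the plain Fisher
test when the parents' annotations span the whole population, and the two
variants coincide on single-parent terms. Root terms, and terms whose
restricted population is empty, are skipped and listed in the result
metadata.

Category sources:

* `go_mf`, `go_bp`, `go_cc` — each ontology is a separate enrichment
  problem;
* `pathways` — pathways *and* pathway classes; a class's gene set is the
  union over its descendant pathways;
* `regulators` — one category per regulator, keyed by the regulator's
  encoding gene, with the category set being its regulon (genes reached
  through its binding sites, promoters and operons);
* `compound_pathways` — for metabolite groups: pathways/classes containing
  the compounds as reaction substrates;
* `combined` — all gene-keyed sources pooled into one analysis.

The background population defaults to *all* KB frames of the group's member
class; a `background` group can replace it (all counts are then computed
inside that background). The correction (Bonferroni, BH, BY — delegated to
`stats::p.adjust` behind `adjustPvalues()`) is applied once across all
tested categories of the analysis; for `combined` that means across the
pooled category set, the conservative reading of a combined analysis.
Categories are reported when the **adjusted** p-value is at or below the
threshold. Two ambiguities are resolved here deliberately: the threshold
applies to the corrected value (applying it to raw p-values would make the
correction decorative), and the comparison is inclusive so that a threshold
of 1 returns every tested category.

## The synthetic knowledge-base generator

`generateToyPgdb(seed, sizes)` builds a complete toy organism so the whole
stack can be exercised without external data. It emulates the structural
features the transforms and the enrichment analysis depend on:
non-overlapping genes laid out in operons on a single chromosome (random
strand per operon, one promoter 60 bp upstream of the operon on its own
strand); regulator proteins — one tagged as a sigma factor — each binding
sites at 1–3 promoters, with the direct regulon slots materialised from
that wiring; monomeric and multi-subunit enzymes catalysing reactions over
compound substrates with declared directions (mostly left-to-right, some
reversible); pathways of reactions under a three-class pathway tree; and a
three-ontology GO DAG (root, 4 intermediate terms, 8 leaves per ontology)
with every gene annotated to 1–2 leaves per ontology.

Defaults (120 genes, 40 operons, 8 regulators, 6 complexes, 36 reactions,
12 pathways, 40 compounds, 300 bp genes with 200 bp intergenic spacing)
are sized like a small bacterial genome fragment: large enough that
pathway gene sets (4–10 genes) sit in a population where hypergeometric
tails are informative, small enough that the whole KB builds in well under
a second. The generator is deterministic for a given `(seed, sizes)` and
its output always passes the full validator.

What it does **not** emulate — and hence what passing tests do not show
about real data: overlapping and nested genes, multi-replicon genomes,
realistic sequence composition (the genome is i.i.d. uniform ACGT),
RNA-level regulation, incomplete or biased GO annotation, shared reactions
between pathways, and annotation noise. Results on real pathway/genome
content would inherit all of those complications; the synthetic KB is a
correctness harness, not a biological claim.

## Numerical and design choices

* Tail sums in log space; oracle comparisons at $10^{-12}$ absolute.
* *nearest-gene*: distance is 0 on overlap, else the smallest gap between
  region and gene interval, strand ignored; ties break by lower gene
  start, then id.
* `deriveRegion()` clamps to `[1, replicon length]` and raises a
  degenerate-region error if the offsets invert the region.
* Empty transform results are empty cells, never errors; a gene with no
  product contributes nothing to complex compression and is listed in the
  result's report.
* Duplicate members are removed preserving first occurrence everywhere;
  no operation ever yields duplicate members.
* Mixed-output operations (complex compression can return polypeptides and
  complexes; combined enrichment mixes category classes) produce groups
  with the generic member class `"Frame"`.

## Problem sizes used in the checks

The test suite enumerates all hypergeometric tables up to $N = 12$
(3,094 comparisons), runs 1,000 random p-vectors through the correction
laws, 500 random group pairs through the set-algebra laws, 100 spiked
trials through pathway recovery, and property checks over the default
120-gene generated KB; the whole suite runs in about a minute on one CPU.

## Known limitations

* Single-organism: no cross-organism ortholog transforms or joins.
* Single-user, file-based persistence; no accounts, sharing or locking.
* No rank-based (GSEA-style) enrichment and no permutation nulls; the
  analysis is strictly over-representation with exact tails.
* Real pathway/genome database file dialects are not parsed; the
  interchange format is this package's own.
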