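# kgroups — knowledge spreadsheets over pathway/genome knowledge bases

Biologists routinely end up with *sets* of things — the genes called
significant in an expression experiment, the metabolites that moved in a
metabolomics run, the results of a database query — and then need to ask
structured questions of them: *which pathways do these genes act in? which
transcription factor could explain this co-regulated set? what sequence lies
upstream of their promoters?* Answering those questions normally means
writing one-off scripts against a pathway/genome database.

`kgroups` packages that workflow as **knowledge spreadsheets**: tabular
*groups* whose rows are objects from a frame-based knowledge base (genes,
pathways, compounds, promoters, sequence regions) and whose columns hold
either user data, raw knowledge-base properties, or *semantic
transformations* that traverse the organism's regulatory and metabolic
network. Cells are multi-valued. Groups can be combined with set algebra,
filtered, imported from and exported to tab-delimited files, persisted, and
subjected to gene-set enrichment analysis.

The package is self-contained: it ships a deterministic synthetic
pathway/genome knowledge-base generator (`generateToyPgdb()`) and a small
fixed fixture (`minitoyPath()`), so everything runs without network access
or external databases.

## What's inside

* **Knowledge-base model** — typed frames (13 classes) connected by
  bidirectional relation slots: gene → product → complex → reaction →
  pathway → pathway-class tree; binding site → promoter → operon → genes;
  compound ↔ reaction sides with declared direction; a three-ontology GO
  DAG; replicons with nucleotide sequence. `loadKb()`/`saveKb()` read and
  write a line-oriented interchange format, and `validateKb()` asserts every
  schema invariant (relation symmetry, GO acyclicity with one root per
  ontology, coordinate bounds, single-parent pathway classes).
* **Groups** — `createGroup()`, `addPropertyColumn()`,
  `addTransformColumn()`, `columnToGroup()` (the non-redundant union of a
  column, with a reverse-mapping column), `groupUnion()` /
  `groupIntersection()` / `groupDifference()`, `filterByName()`,
  `filterByThreshold()`, `importGroupTsv()` / `exportGroupTsv()`,
  `saveGroup()` / `loadGroup()`, read-only `specialGroup()`s with
  `copyEditable()`.
* **Transforms** — per-class menus (`applicableTransforms()`): 13 gene
  transforms (regulators, regulated genes, binding sites, promoters,
  operons, operon siblings, reactions, pathways, GO terms, upstream TF
  sites, regulated promoters, coding region, complex compression), 4
  pathway families, 6 compound families with produced/consumed/both modes,
  3 promoter transforms, and region transforms (length, nearest gene,
  sequence, offset-derived regions). Number and string columns have no
  applicable transformations, by design.
* **Enrichment** — `enrich()` tests a group against GO terms (per
  ontology), pathways + pathway classes, transcriptional regulators (keyed
  by the regulator's gene), metabolite→pathway membership, or all of these
  pooled. Tests: one-sided Fisher exact, parent–child union, parent–child
  intersection; corrections: Bonferroni, Benjamini–Hochberg,
  Benjamini–Yekutieli.
* **CLI** — `kgroupsMain()` plus the `inst/scripts/kgroups` launcher:
  `kb generate|validate`, `group create|import|export|show|copy|special`,
  `transform`, `compress`, `setop`, `filter`, `enrich`, `transforms`.

## The statistic at the core

For a group of $n$ objects drawn from a population of $N$, and a category
(pathway, GO term, regulon) containing $K$ population members of which $k$
fall in the group, the enrichment p-value is the hypergeometric upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed in log space. The parent–child variants replace the population by
the genes annotated (after true-path propagation) to the union or the
intersection of the term's parents, which corrects for enrichment inherited
from a parent term. Benjamini–Hochberg is the step-up
$\tilde p_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m/j)$; Benjamini–Yekutieli
multiplies by $\sum_{i=1}^m 1/i$.

## Worked example

```r
library(kgroups)
kb <- loadKb(minitoyPath())

g <- createGroup(kb, "regulated genes", c("g1", "g2", "g3"), "Gene")
g <- addTransformColumn(g, kb, "regulators")
columnToGroup(g, kb, 2)
#> Group "regulators of regulated genes" (Polypeptide): 1 member(s), 2 column(s)
#>   columns: regulated genes members
#>   - CRPX

atp <- createGroup(kb, "atp operon", sprintf("atp%s", LETTERS[1:8]), "Gene")
compressToComplexes(atp, kb)
#> Group "complexes of atp operon" (ProteinComplex): 1 member(s), 1 column(s)
#>   - ATPSYN-F1

tab <- enrichTable(enrich(createGroup(kb, "hits", c("g1","g2","g3"), "Gene"),
                          kb, source = "pathways", threshold = 1))
print(tab, row.names = FALSE)
#>  category k n K  N       p_raw       p_adj
#>   PC-ROOT 3 3 3 11 0.006060606 0.006060606
#>     PWY-1 3 3 3 11 0.006060606 0.006060606
```

Reading the output: the three query genes are exactly the three genes whose
products catalyse reactions of pathway `PWY-1`; the regulator column shows
they are all controlled by the crpX protein; the eight `atp` genes collapse
to the single ATP synthase complex they encode; and the enrichment table
reports, for each tested category, the 2×2 table counts (`k` of `n` group
members vs `K` of `N` population members) with raw and BH-adjusted
hypergeometric tail probabilities — `PWY-1` containing all three genes of a
3-gene group is unlikely by chance (p ≈ 0.006) in an 11-gene genome.

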