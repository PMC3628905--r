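---
title: "Inferring gene functions from mutant phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene functions from mutant phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofun)
```

## The inference rule

Model-organism databases record mutant phenotypes with species-specific
phenotype ontologies, most of which carry formal Entity/Quality (EQ)
definitions: a phenotype term is logically defined as a PATO *quality*
(the genus of an `intersection_of` block) inhering in one or more
*entities* (the differentia fillers). When the affected entity is itself
a Gene Ontology process or function, the phenotype is direct evidence
about gene function: if mutating gene *g* produces a phenotypic
abnormality in process *p*, then *g* must have been involved in *p*,
directly or indirectly.

`phenofun` operationalizes this as a pipeline:

1. **Decompose** — look up each phenotype annotation's term in the EQ
   definition map (`parse_eq_definitions()`) and extract its GO entity
   fillers (`extract_go_entities()`). Post-composed annotations (subject,
   entity, quality), as used for zebrafish, skip the lookup: their entity
   member is used directly.
2. **Attribute** — resolve the annotation subject (genotype or
   morpholino identifier) to the mutated gene(s) through a mapping table
   (`parse_genotype_map()`). A multi-gene genotype assigns the function
   to every mapped gene; the confound stays visible in the provenance.
3. **Emit** — each distinct (gene, GO term) pair once, with merged
   provenance (`infer_functions()`), exportable as an IEA-coded GAF or a
   plain TSV.

```{r vgf}
defs <- parse_eq_definitions(text = c(
  "[Term]", "id: MP:0010249", "name: lactation failure",
  "intersection_of: PATO:0001558",
  "intersection_of: inheres_in GO:0007595"))
phens <- parse_phenotype_table(text = "MGI:2179681\tMP:0010249")
infer_functions(phens, defs, gmap = list("MGI:2179681" = "Vgf"))
```

Every differentia relation (`inheres_in`, `towards`,
`inheres_in_part_of`, ...) is eligible to contribute a GO entity: the
rule extracts *the entity*, and restricting by relation would silently
drop valid evidence. No filtering is applied to the quality term either —
phenotype annotations in these databases record abnormalities, so any EQ
phenotype with a GO entity licenses an inference. All three GO namespaces
are eligible by default (`go_prefixes` narrows this if desired).

## Novelty

An inferred pair (g, t) is **known** when t lies in the superclass
closure of g's existing manual-evidence annotations (evidence codes EXP,
IDA, IPI, IMP, IGI, IEP), and **novel** otherwise. Subsumption rather
than exact equality is the default because an inference that is *more
general* than an existing annotation adds no information; `mode =
"exact"` is available for the stricter reading. Enlarging the manual
evidence set can only move inferences from novel to known, never the
reverse — a property the test suite checks.

## Functional similarity and the interaction benchmark

Inferred annotations for genes that have not been studied directly
cannot be validated against a gold standard, so the package evaluates
them indirectly: good functional annotations should help predict which
genes interact. For a gene with annotation terms
\(A = \{A_1, \dots, A_n\}\), let \(\mathrm{Cl}(A)\) be the smallest
superset of \(A\) closed against `is_a` superclasses. Similarity between
genes is the Jaccard index

\[
\mathrm{sim}(g_1, g_2) =
\frac{|\mathrm{Cl}(A_{g_1}) \cap \mathrm{Cl}(A_{g_2})|}
     {|\mathrm{Cl}(A_{g_1}) \cup \mathrm{Cl}(A_{g_2})|},
\]

deliberately *without* information-content weighting: IC weights import
the annotation density of each dataset into the measure and make
cross-species comparisons incommensurable. Two unannotated genes get
similarity 0, not 1 — the absence of annotation is absence of evidence.

Closure traverses only `is_a` edges by default, the strictest reading of
"closed against superclasses"; `relations = c("is_a", "part_of")` widens
it, since whether part-of edges should count is genuinely open.

The benchmark (`pooled_roc()`, `per_gene_aucs()`, `compare_profiles()`)
takes known genetic and protein–protein interactions — mined from GAF
IGI/IPI with-fields, STRING links, or BioGRID tab files — as positives
and treats every other unordered pair in the gene universe as negative.
This no-validated-negatives assumption can only deflate the AUC (planted
positives hiding in the negative pool count against the ranking — a
directional property the suite tests), and it deflates baseline and
augmented annotation sets equally, so their comparison is unaffected.
Interaction pairs are undirected, deduplicated across sources, and pairs
for which no novel function was inferred are removed before evaluation
(`filter_pairs()`; "at least one partner gained a novel function" by
default, a strict both-partners mode behind `policy = "both"`).

### Numerical construction of the ROC

The ROC is built by sweeping the score threshold from high to low with
tied scores collapsed into a single step (a diagonal segment), and the
AUC by the trapezoid rule. With average-rank tie handling this is
*exactly* the Mann–Whitney statistic \(U / (n_+ n_-)\); the suite checks
the equivalence to 1e-12 on random tied instances and against an
independent ROC library. Neighbour rankings use average ranks for ties
for the same reason.

### The paired comparison

Per-gene AUCs — each gene's own neighbour ranking scored against its
interaction partners — are the unit of the baseline-vs-augmented
comparison: a one-tailed paired t-test of "augmented > baseline" over
genes that qualify (≥ 1 positive partner and ≥ 1 negative candidate) in
both conditions, reported next to the pooled AUCs. The unit of the test
is a genuine design choice (a Hanley–McNeil-style pooled comparison
would also be defensible); the per-gene ranking is the quantity the
method actually constructs, so it is what gets tested. When every
per-gene difference is exactly zero the t statistic is undefined and the
p-value is reported as 0.5 (no evidence in either direction); with fewer
than two paired genes it is `NA` with a diagnostic note.

## The synthetic world generator

Real inputs for this pipeline are database snapshots that cannot be
bundled or re-downloaded reproducibly, so the package generates complete
miniature worlds with known ground truth (`generate_world()`): a GO-like
DAG, a flat quality ontology, a phenotype ontology whose defined terms
carry `intersection_of` definitions, genes with planted true functions,
a baseline GAF (true functions thinned by `annotation_subsample_rate`,
plus IGI/IPI rows encoding planted interactions), phenotype annotations
(true functions expressed at `phenotyping_rate`, corrupted at
`noise_rate` to a random wrong phenotype term), and STRING/BioGRID
files of the planted interaction network.

Key defaults, chosen once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_go_terms`, `n_phenotype_terms` | 150 | desk-scale DAGs large enough for non-trivial closures |
| `n_genes` | 80 | ~3,000 candidate pairs, enough for stable AUCs |
| `functions_per_gene` | 4 | sparse annotation, as in real curation |
| `fraction_defined` | 0.71 | the completeness ratio of a mature formally-defined phenotype ontology |
| `fraction_go_entity` | 0.6 | a majority of process phenotypes, the rest anatomical |
| `annotation_subsample_rate` | 0.7 | incomplete curation |
| `phenotyping_rate` | 0.8 | most but not all functions show a recorded phenotype |
| `noise_rate` | 0.05 | occasional mis-annotation |
| `interaction_coupling` | 0.6 | see below |

Interactions are planted with probability
`interaction_coupling * plogis(2 * (shared - 1))` where `shared` counts
shared true functions — a logistic link that gives functional similarity
genuine signal (the property the evaluation presupposes) while keeping a
realistic background of interactions between functionally unrelated
genes.

Two implementation choices matter for testing. First, every Bernoulli
thinning step draws one uniform per candidate item *regardless of the
rate*, so under a fixed seed the selected sets are nested across rate
levels: raising `noise_rate` corrupts a superset of the annotations
corrupted at a lower rate, which makes the monotone recovery properties
(precision non-increasing in noise, novel count non-increasing in
annotation coverage) exact rather than statistical. Second, the whole
world is a pure function of the seed; the emitted files are
byte-identical across runs and listed in a manifest with MD5 checksums.

What the generator does **not** emulate: realistic GO topology (term
depth and fan-out distributions), annotation bias toward well-studied
genes, evidence-code structure beyond a manual/electronic split,
species-specific biology, or database-scale sizes. Passing tests on
synthetic worlds therefore demonstrate correctness of the machinery and
the directional behaviour of the method, not performance figures
transferable to real snapshots.

## Problem sizes in the test and acceptance suites

The suites run worlds of 60–150 ontology terms and 30–80 genes, with the
directional experiment (annotation coverage 0.5, inferred functions
restored from phenotypes) repeated over 20 seeded replicates; property
tests use random DAGs up to 200 terms. These sizes give stable
qualitative behaviour — the mean per-gene AUC improvement is positive in
every replicate observed — while keeping the whole suite under a minute.

## Degenerate inputs and tie-breaks

* Obsolete ontology terms are retained and flagged but contribute no
  closure edges and are excluded from completeness counts (standard OBO
  practice).
* Parent references to undeclared terms ("dangling", common with
  cross-ontology references) are kept as phantom leaves and reported,
  not fatal.
* `NOT`-qualified GAF rows are parsed but excluded from annotation sets
  and similarity: a NOT annotation asserts absence of function.
* with/from entries are split on `|` and `,`; entries outside the
  annotated gene's identifier namespace (e.g. GO ids) never become
  interaction partners.
* Self-pairs are dropped and pairs canonicalized (lexicographically
  smaller gene first) everywhere.
* Every parser is total on its corpus: malformed rows are skipped,
  warned about, and accounted for (`rows_in = rows_parsed +
  rows_skipped` in `diagnostics()`).

## Known limitations

* The inference cannot distinguish direct involvement from downstream
  effects mediated by other genes; inferred functions may be too general
  or attribute regulation as participation. This is inherent to
  phenotype-only evidence.
* Cross-species identifiers are never merged; a combined evaluation is
  the union of per-species pair universes.
* Only graph closure is implemented — no OWL semantics or reasoner
  classification; `intersection_of` blocks are read as EQ definitions,
  not as general equivalence axioms.
* The all-pairs similarity universe is the profiled gene set, not the
  genome; AUCs are relative to that universe.
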