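---
title: "Methods: building and querying a multipartite association network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and querying a multipartite association network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpanet)
```

`mpanet` integrates the standard analytic layers of bulk transcriptomics —
differential expression, co-expression modules, pre-defined module
repertoires, cell-type deconvolution, gene-set enrichment and phenotype
association — into one typed multipartite property graph. This vignette
documents the models, the parameters that matter, the numerical choices,
what the synthetic-data generator emulates, and the design decisions that
were genuinely open.

## Data model

Expression and phenotype live in a `SummarizedExperiment` (assay
`"exprs"`, probes × samples; phenotype as `colData`). The two design
variables (disease class and a second stratification factor, typically
sex), their reference levels and identifier columns are kept in the object
metadata. Prior knowledge — a probe→symbol map, three pathway collections,
three cell-marker collections, a pre-defined module collection, a
deconvolution signature basis and a consensus cell-name map — is held in an
S4 `AnnotationBundle`.

The central container is the S4 `AssociationGraph`. Node identity is the
quadruple *(label, name, square, edge)* where *square* is the dataset id
and *edge* the contrast id; annotation nodes (symbols, pathways, marker
sets, consensus cell names, platform probes) use an empty scope so that
multi-dataset builds share them, while analysis nodes (probes under test,
modules, cell-proportion and phenotype nodes, pre-defined-module instances)
are dataset-scoped. Twelve node labels are admissible and exactly three
edge types exist: `mapping` (no statistics), `enrichment` (overlap counts,
p, q, a relaxation flag) and `correlation` (weight = R or topological
overlap, p, q). `mergeNode()`/`mergeEdge()` implement MERGE semantics:
re-inserting an existing identity overlays its property map (new values
win), so graph union is associative and idempotent on keys.

## Normalization and probe filtering

Raw intensities are shifted by `1 − min` when non-positive values are
present (background-subtracted arrays), transformed by `log2(x + 1)` and
quantile-normalized across samples with tied ranks receiving the mean
target quantile (`limma::normalizeQuantiles(ties = TRUE)`). After this
step the sorted value vector of every sample is identical to numerical
precision — a property the test suite asserts at 1e-12.

Two probe filters are provided. The default *variance* filter keeps probes
at or above the `q`-th variance quantile (default `q = 0.5`). The
*factorial* filter keeps probes whose overall F-test against the
two-factor design reaches nominal p < 0.05, capped at the 5000 largest F
statistics. The default build uses the variance filter for both the
analysis set and the co-expression input: the factorial filter
deliberately discards probes without class/sex effects, which would remove
the cell-composition modules that the module–cell linkage layer is about.
Neither threshold is taken from the original workflow (whose probe-quality
annotation relied on platform re-annotation databases); they are declared
defaults.

## Differential expression

Per probe, ordinary least squares on `~ class * stratum` with treatment
coding. Reference levels default to the alphabetically first level but can
be declared per dataset (`class_ref`, `strat_ref`); the reported contrast
defaults to the class main effect, i.e. the class difference within the
reference stratum. Variance moderation uses the standard empirical-Bayes
closed forms via `limma::eBayes`: prior degrees of freedom and scale are
estimated from the distribution of log residual variances, the posterior
variance is `(d0·s0² + d·s²)/(d0 + d)`, and the moderated t is referred to
a t distribution with `d0 + d` degrees of freedom. When all residual
variances coincide the prior degenerates to infinite degrees of freedom
and every posterior variance equals the common value; `moderated = FALSE`
gives the ordinary OLS t (the d0 = 0 limit), which the tests compare
against a direct `lm()` oracle. Benjamini–Hochberg adjustment is exposed
as `bhAdjust()` — an NA-aware wrapper over `p.adjust(method = "BH")`,
checked against an independent step-up implementation.

## Co-expression modules

The network is unsigned: `a_ij = |cor(x_i, x_j)|^β` with zero diagonal.
β is the smallest integer in 1…20 whose scale-free topology fit — the
signed R² of `log10 p(k)` on `log10 k` over 10 connectivity bins — reaches
0.8, with a fallback of 6 (the conventional default) when none qualifies.
The topological overlap is
`TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)` with unit
diagonal; the implementation is verified against a brute-force triple loop
at 1e-12.

Module detection clusters `1 − TOM` by average linkage and cuts statically
at 0.99 × the maximum merge height; branches smaller than `min_module_size`
(default 30; 10 at the synthetic scale, where planted modules have 20–50
probes) become unassigned ("grey"), and modules whose eigengenes correlate
at ≥ 0.75 are merged iteratively. This static-cut + merge scheme replaces
the dynamic tree cut of the reference implementation; it is simpler,
deterministic, and recovers planted modules exactly in the regimes the
tests cover. Surviving modules are named by the conventional colour
sequence in decreasing size order; equal sizes tie-break on the first
member probe name so labels are invariant to probe order.

The module eigengene is the unit-norm leading right-singular vector of the
row-standardized member matrix, sign-oriented to correlate non-negatively
with the mean standardized member profile. Module metrics: `modAUC1` and
`modAUC2` are the rank-statistic ROC-AUCs of the eigengene against the
class and stratification variables (positive class = non-reference level;
reported unflipped, so values below 0.5 are informative about direction),
`diffME` is the case-minus-control difference of median eigengene values,
and `sigenrich` is −log10 of the smallest BH q over the designated marker
collection's hypergeometric tests — a declared stand-in, since the
original metric's formula is not public.

Intra-module connectivity is thinned to
`min(2000, max(1, ceil(0.10 × #pairs)))` edges per module — at least the
top 10% of pairs by topological overlap, capped at 2000 — with
lexicographic tie-breaks on the probe pair.

## Pre-defined module repertoire

Pre-defined (repertoire) modules are fixed symbol sets reused across
datasets, so meta-analysis compares like with like. Two statistics are
computed: the *score* `%up − %down` of member probes significantly changed
at q < 0.05 (the percent-significant convention; whether the original
heatmaps used this or mean fold change is not documented, so the threshold
is configurable), and a module-level moderated test on the per-sample mean
log2 expression of member probes. The meta-analysis matrix collects scores
per dataset; the "consistent" subset contains modules whose scores have
the same strictly nonzero sign everywhere (zero is sign-less and
excludes).

## Deconvolution

Cell-type proportions are estimated per sample by non-negative least
squares (`pracma::lsqnonneg`) of the linear-scale profile (`2^x − 1` after
normalization) on the signature basis restricted to shared probes, then
renormalized to the simplex. Mixture linearity holds on the linear scale,
which is why the fit leaves log space. All-zero solutions (a pathological
sample) fall back to uniform proportions with a warning. Group differences
use two-sided Wilcoxon rank-sum tests per cell type (Kruskal–Wallis above
two levels) with BH across cell types (`diffP`, `diffQ`).

## Enrichment and the retention policy

Over-representation is the exact upper-tail hypergeometric probability
P(X ≥ k) conditional on the universe of symbols measured on the filtered
array. The multiple-testing family is one module × one collection. Per
module, sets with q < 0.05 are retained ranked by p and truncated at 10;
if fewer than the minimum (3; 4 for the third pathway collection) pass,
the top nominal-p sets with p < 0.05 are retained instead and flagged
`relaxed` — the exact relaxation criteria of the reference workflow are
unpublished, so the fallback is declared and every edge it produces is
flagged. The q value is stored on every retained edge either way.

## Phenotype association

Categorical phenotype variables are encoded as integers 0…k−1 in
alphabetical level order (recorded), numeric variables pass through,
identifiers are excluded and constants dropped. Univariate tests against
the class are Wilcoxon (numeric/ordinal) or Fisher exact (categorical),
BH across variables. Eigengene–phenotype and eigengene–proportion edges
come from Pearson (optionally Spearman) correlations with BH over all
module × target pairs per graph; edges are kept at q < 0.05 with the
correlation as edge weight.

## Virtual cells and activity matrices

A module is linked to a cell type iff its eigengene correlates with that
cell's estimated proportion (BH q < 0.05 over all module × cell pairs)
*and* the module is enriched for that cell's markers in at least one
retained marker-collection result — a conjunction that operationalizes
"these transcripts are expressed in that cell type". Probe→cell
assignment is mediated entirely by these links, keeping the construction
deterministic. A virtual cell is the union of linked modules' probes with
their correlation matrix, pathway annotations and differential-expression
overlay. Cell × pathway activity is the mean of positive (and separately,
negative) log2 fold changes over the probes shared by the virtual cell
and the pathway; combinations without contributing probes are absent
rather than zero, and missing entries are imputed as zero only inside the
clustering distance of the cross-dataset comparison — absence of evidence
is not evidence of zero activity. By default all intersection probes
contribute (a q-threshold flag exists): whether the original activity
score filtered by significance is not documented.

## The synthetic-data generator

The generator is the package's study design. Linear-scale expression is
`signature × proportionsᵀ`, modulated by planted module factors and
log-normal noise:

* 60 samples: 15 per (class × sex) stratum, a balanced two-factor design.
* 5 cell types with base composition falling off as rank^1.5 and
  per-sample log-normal jitter (SD 0.4 — blood cell fractions vary
  substantially between individuals, and precisely this variation makes a
  cell's 20 marker probes co-vary, which is the mechanism the module–cell
  linkage layer detects). Cases get +0.15 absolute proportion added to
  cell 1, other cells rescaled on the simplex.
* 4 planted modules of 50 probes, each driven by a shared latent factor
  (SD 0.5 log2) with per-probe loadings U(0.8, 1.2). Module 1's factor is
  shifted +1 log2 in cases (disease program), module 2's +1 in males.
  Cell 1's markers additionally load at 0.5 on the disease factor —
  disease-associated transcriptional activation of the expanded cell —
  which makes the disease–module–cell chain realisable end to end.
* 1700 unstructured probes with residual SD 0.5 log2 (≈2000 probes total).
* Phenotype: class, sex, one covariate constructed to track the disease
  factor (noise SD = half the signal SD, giving R ≥ 0.8 by construction)
  and an independent age covariate.

Annotation fixtures derive from the same truth: marker collections at
three fidelities (exact, 20% dropout, 20% decoy swap-in), pathway
collections containing one pathway per planted module at decreasing
fidelity plus per-cell lineage sets and random decoys, a pre-defined
module collection holding the planted programs, lineage modules and random
sets, the marker signature basis, and the consensus cell-name map. The
lineage sets are deliberate: real pathway and repertoire collections
contain cell-lineage modules, and without them the module–marker
enrichment graphs would be structurally empty on synthetic data.

What the generator does *not* emulate: platform-specific bead-level noise,
batch effects, detection p-values, probe cross-hybridization, or
annotation errors beyond the declared dropout/decoy rates. Passing tests
therefore demonstrate algorithmic correctness and recoverability under a
clean mixture model, not robustness to real-array artefacts.

## Problem sizes and numerical choices

The default synthetic scale (~2000 probes × 60 samples × 2 datasets) runs
the full build in well under a minute; the test suite and the acceptance
script together stay within a few minutes on one CPU. Brute-force oracles
(TOM triple loop, exhaustive AUC pair counting, hypergeometric term
summation, path enumeration) run on instances small enough to be exact
references. Degenerate inputs are handled explicitly: constant probes are
rejected by the TOM (filter first), zero-variance eigengene members are
dropped with a warning, degenerate contingency tables yield p = 1, an
all-zero NNLS solution falls back to uniform proportions, and predicates
on missing graph properties fail the candidate rather than erroring.

Determinism is a design goal throughout: given one seed, the generator,
the build and the Cypher exporter (statements sorted by identity key,
numbers printed at 15 significant digits) are byte-identical across runs.

## Known limitations

* Unsigned co-expression networks conflate correlated and anti-correlated
  probes; compositional coupling of cell proportions can therefore merge
  marker modules of different cells at low soft powers.
* The scale-free criterion can select a low β when global drivers (cell
  composition) dominate; the acceptance-scale recovery experiments use
  configurations where the criterion is well behaved.
* The static cut has no dynamic branch sensitivity; very close planted
  modules merge earlier than a dynamic tree cut would.
* `sigenrich`, the enrichment relaxation criteria and the repertoire
  score are declared stand-ins for undocumented formulas, as flagged
  above.
* Pattern matching enumerates simple paths exhaustively; it is meant for
  the desk-scale graphs this package builds (≲ 10⁵ edges), not for
  arbitrary graph analytics.
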