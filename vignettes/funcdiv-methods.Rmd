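---
title: "Functional bias in duplicate-pair evolution rates: methods and design"
author: "funcdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional bias in duplicate-pair evolution rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcdiv)
```

# The question and the analysis

After a whole-genome duplication, surviving paralog pairs accumulate
substitutions independently. The ratio of nonsynonymous to synonymous
divergence per site, \(\omega = dN/dS\), measures the net selective
constraint on each pair: \(\omega \ll 1\) indicates purifying selection,
\(\omega > 1\) diversifying selection. `funcdiv` asks whether \(\omega\)
depends on a pair's biological function, by

1. labeling each duplicate pair with its **most specific shared functions**
   from Gene Ontology annotation,
2. clustering pairs into **functional groups** by the similarity of those
   labels,
3. estimating per-pair \(dN\), \(dS\) from coding sequences, and
4. comparing \(\omega\) across groups with ANOVA and Tukey HSD, and
   characterizing groups by GO term enrichment.

The package ships a synthetic-study generator with planted ground truth for
every stage, so the whole chain is testable without external data.

# Shared-function labeling

Annotations are first screened by evidence code: a pair is analyzed only if
both genes carry at least one annotation whose code is outside a
configurable blacklist (default `IEA`, `ND`). The intent is "curated or
experimentally supported"; since annotation practice publishes no exact
whitelist, the blacklist is a parameter.

For each namespace, a pair's label is computed from the two genes' term
sets as the *minimal elements* of the intersection of their reflexive
ancestor sets, keeping only terms of depth at least `min_depth` (default
1; namespace roots have depth 0). Reflexivity matters: two genes annotated
to the same leaf share the leaf itself, not merely its parents. Depth is
the shortest child-to-root path pooling `is_a` and `part_of` edges; these
two relations are treated as equivalent for reachability throughout, and
all other relations are dropped at parse time. A pair may survive in one
namespace and not another; each namespace is analyzed independently.

`organelle_example_graph()` reproduces the canonical worked example: genes
annotated to *organelle envelope* and *intracellular membrane-bound
organelle* share exactly *membrane-bound organelle* and *intracellular
organelle*.

# Functional similarity between pairs

Term informativeness is Resnik-style information content from the
evidence-filtered corpus: \(IC(t) = -\ln p(t)\), where \(p(t)\) is the
fraction of the namespace's annotated genes annotated to \(t\) or any
descendant. Natural-log units are arbitrary but fixed; only ratios and
orderings matter downstream. The corpus feeding IC is the same
evidence-filtered annotation set used for labeling — the alternative
(including electronic annotations in the corpus only) would shift absolute
IC values but not orderings; the choice is recorded here once.

Term–term similarity is Resnik's most-informative-common-ancestor,
\(\max_{a \in Pa(t,t')} IC(a)\), over common *reflexive* ancestors.
Profile–profile similarity is the optimal-assignment score: every term of
the smaller profile is matched injectively to a term of the larger one to
maximize summed Resnik similarity (exact subset-mask dynamic programming;
the value is unique, so no tie-breaking is needed), and the sum is divided
by the number of matched terms.

For clustering, pairwise scores are normalized to \([0,1]\) by
\(s(i,j)/\sqrt{s(i,i)\,s(j,j)}\) with a unit diagonal. The analysis that
this package reimplements does not state its normalization; this one makes
tree heights scale-free, which in turn makes fixed-height cuts
interpretable. With averaged (rather than summed) assignment scores the
geometric-mean bound is not a theorem; values are clamped at 1, and both
raw and normalized matrices are retained for audit. Profiles consisting
only of IC-0 terms have zero self-similarity and are rejected rather than
silently normalized.

# Clustering and tree cuts

Distances are \(d = 1 - s\). Ward's minimum-variance linkage is computed
by Lance–Williams updates on \(d^2/2\), so every merge height equals the
increase in within-cluster sum of squares; two singletons at distance
\(d\) merge at \(d^2/2\). The implementation is the naive \(O(n^3)\) scan
with deterministic smallest-index tie-breaking — problem sizes are a few
thousand leaves at most, and the merge structure is cross-checked in the
test suite against `stats::hclust` on squared distances.

Two cuts are provided:

* **Minimum-size cut** (default, `min_size = 20`): each leaf belongs to its
  lowest ancestor whose subtree reaches `min_size`. Where a qualifying node
  contains an already-claimed qualifying core, the leftover stragglers form
  a candidate smaller than `min_size`; they are absorbed into the most
  recently emitted group inside the same subtree — their topologically
  nearest established group. (Carrying such candidates further upward, the
  other defensible reading, pools unrelated stragglers from different
  branches into one arbitrary group and measurably corrupts recovery of
  planted structure; absorption preserves the partition and the
  all-groups-≥-`min_size` guarantee.)
* **Fixed-height cut**: maximal subtrees with merge height at most `h`,
  singletons allowed; used for sensitivity scans.

# Divergence estimation

Protein pairs are aligned globally (Needleman–Wunsch with affine gaps) via
`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10, gap extension 0.5.
Conventions: a gap of length \(L\) costs \(10 + 0.5L\), end gaps are
penalized, and the unknown residue `X` scores 0 against everything. The
alignment is then back-translated onto the coding sequences codon by codon
(terminal stop codons stripped; internal stops and translation mismatches
are hard errors naming the codon).

\(dN\) and \(dS\) come from a Nei–Gojobori-style counting estimator:
per-codon synonymous site fractions (changes creating stop codons count as
nonsynonymous, so \(N + S = 3L\) holds exactly), differences averaged over
all minimal substitution paths between differing codons with equal weights
and stop-crossing paths excluded (if every path is blocked, all paths are
used and the pair is flagged), and the Jukes–Cantor correction
\(d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\). Proportions at or beyond
\(3/4\) are flagged saturated; \(\omega\) is defined only when
\(dS > 0\). Pairs flagged undefined or saturated are excluded from all
group statistics, with counts reported.

This counting estimator deliberately replaces the maximum-likelihood-style
estimator used in the original analysis, which models
transition/transversion and codon-frequency bias. The object of the
analysis (per-pair \(\omega\), compared across groups) is preserved, and
`import_divergence_table()` accepts externally computed \(dN/dS\) tables
for fidelity runs on real data; an imported table takes precedence over
sequence-based estimation in the pipeline. This is a known numerical
difference, not an approximation of convenience: absolute \(dN\), \(dS\)
values differ from the bias-aware estimator, group contrasts survive.

# Group statistics

One-way fixed-effects ANOVA of \(\omega\) on group labels, with the usual
SS/df/MS/F decomposition and upper-tail p-value. Tukey HSD uses the
Tukey–Kramer statistic \(q = |\bar y_i - \bar y_j| /
\sqrt{\mathrm{MSE}/2\,(1/n_i + 1/n_j)}\) against the studentized range
distribution; group-mean displays use simultaneous intervals
\(\bar y_i \pm (q_{\alpha,k,\nu}/\sqrt{2})\sqrt{\mathrm{MSE}/n_i}\). Under
this convention two balanced group means differ exactly when their
intervals are disjoint; for unbalanced groups the pairwise test is
authoritative and the intervals are a visual aid. "Extreme" groups are
those significant against every other group.

The two-way check adds copy-number class (single vs multiple duplicates)
as a main effect with Type II sums of squares — each factor is tested by
its increment over the model containing the other factor — because the
design is heavily unbalanced and no interaction p-value is reported. The
chromosomal-location check correlates \(\omega\) with the distance from
the centromere to each gene's midpoint; each pair contributes two
observations (one per gene, same \(\omega\)), with the parametric
two-sided t-transform p-value.

# Enrichment

Groups are characterized by the parent-child union statistic: for a term
\(t\) with parent set \(P\), the urn is the population genes annotated
(descendant-inclusively) to \(\bigcup P\), successes are the term's genes
within it, and the draws are the study genes inside the urn — a
hypergeometric upper tail conditioned on the parents, which discounts
enrichment merely inherited from a general ancestor. The study set of a
group is the union of both genes of its member pairs; the population is
all genes in the retained pairs. Bonferroni multiplies by the number of
terms actually tested in that group's run (terms with at least one study
gene, roots skipped). The classic term-for-term test is available through
the same machinery by ignoring the parent conditioning, but is not the
default.

# The synthetic generator

`simulation_config()` defines the study conditions; every generator is a
pure function of `(config, seed)`:

* **Ontology**: three namespaces of 300 terms in depth layers (fractions
  0.03/0.10/0.17/0.30/0.40 of non-root terms), one `is_a` parent from the
  previous layer per term plus a `part_of` second parent with probability
  0.2. Six **family anchors** sit at depth 3 under one shared "hub"
  parent, mirroring how real ontologies hang specific families under broad
  general terms; deeper terms attach inside one family's subtree with
  probability 0.8, giving each anchor a private descendant pool. Anchors
  at the same layer are automatically non-ancestral.
* **Pairs and annotations**: 6 families × 30 pairs. Both genes of a pair
  draw 2–4 terms from an 8-term family pool with a guaranteed common core
  term, so shared-function profiles are nonempty, family-specific, and
  heavily overlapping within a family. Exactly 10% of gene slots per
  family are IEA-only (the exact-fraction design keeps post-filter family
  sizes in 24–27, above the min-size-20 cut, at every seed). Copy-number
  classes are drawn with per-family probabilities 0.1–0.6, linking copy
  number loosely to the faster families.
* **Omega**: family means spread over \([0.03, 0.45]\) with SD 0.06,
  truncated to \([0, 0.8]\) by rejection. The range mirrors the observed
  span of \(\omega\) for recent whole-genome duplicates; the spread
  emulates the contrast between ribosome-like (slow) and defense-like
  (fast) families without asserting any real group's mean.
* **Sequences**: 300-codon ancestors of random sense codons; the second
  copy receives exactly 30 synonymous changes and
  \(\mathrm{round}(3\,\omega \cdot 30)\) nonsynonymous changes at distinct
  codons (assumed nonsynonymous/synonymous site ratio 3), never creating
  stops. One change per codon means the counting estimator recovers the
  planted difference counts exactly.
* **Layout**: uniform placement on five 30-Mb chromosomes with central
  centromeres; an optional Gaussian-copula coupling plants a
  location–\(\omega\) correlation (default 0).

What the generator does **not** emulate: realistic GO topology and term
frequencies, codon-usage and transition/transversion bias, indels,
annotation errors, or shared ancestry between families. Passing tests
demonstrate the pipeline's internal correctness and calibration under
planted structure — not that any particular biological claim holds on real
data.

# Numerical choices and degenerate inputs

* Deterministic tie-breaking everywhere: lexicographic term order in
  matchings (the DP value is tie-free), smallest-index pairs in Ward
  merges, canonical gene ordering within pairs.
* Asymmetry beyond 1e-9 in similarity/distance matrices is an error, not
  silently symmetrized; normalized similarities are clamped to 1 to absorb
  float round-off.
* Zero within-group variance with unequal means reports \(F = \infty\),
  \(p = 0\) rather than a numerically meaningless ratio.
* Empty profiles, empty groups, unknown terms/genes, internal stops and
  length mismatches fail loudly with the offending record named; a gene
  missing from the annotation index is treated as unannotated and its pair
  dropped at the evidence stage.
* Pipeline outputs are formatted with fixed precision so identical
  configurations are byte-identical across runs; every file carries a
  configuration-hash provenance header.

# Problem sizes

The default synthetic study (180 pairs, 900 terms, 300 codons) runs the
full pipeline in seconds. Test-suite calibrations use 10,000 null
replicates for ANOVA type-I error, 5,000 for Tukey familywise error, and
200 replicates for divergence recovery — sizes chosen so Monte-Carlo error
is well below the asserted tolerances while the whole suite stays in the
minutes range.

# Known limitations

* The counting \(dN/dS\) estimator ignores substitution-rate biases;
  absolute values are not comparable to bias-aware estimators (the import
  path exists for that).
* Optimal-assignment normalization is a documented package choice; other
  software may scale similarities differently, which shifts absolute tree
  heights (hence fixed-height cut results) but not minimum-size cuts.
* Parent-child union enrichment requires terms to have parents; namespace
  roots are never tested.
* The location analysis assumes a single centromere position per
  chromosome and gene midpoints; acrocentric or complex centromere
  geometry is out of scope.
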