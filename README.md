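# funcdiv

Does the rate of molecular evolution of gene pairs retained after a
whole-genome duplication depend on their biological function? `funcdiv`
implements, as a tested and reusable R pipeline, the analysis that answers
this question for paralog pairs: Gene Ontology based functional profiling
and clustering of duplicate pairs, dN/dS estimation from coding sequences,
and group-level statistics.

The pipeline, per GO namespace:

1. **Filter** — keep pairs where both genes have curated (non-IEA/ND)
   annotation, and label each pair with its *most specific shared
   functions*: the minimal elements of the intersection of the two genes'
   reflexive GO ancestor sets, at depth ≥ 1 (`is_a` and `part_of` edges
   pooled).
2. **Similarity** — information content `IC(t) = −ln p(t)` from
   descendant-inclusive annotation frequencies; Resnik term similarity
   `max IC` over common ancestors; optimal-assignment matching between the
   shared-function profiles of two pairs, normalized by
   `s(i,j)/√(s(i,i)·s(j,j))`.
3. **Cluster** — Ward's minimum-variance linkage on `d = 1 − s` (merge
   heights equal the within-cluster sum-of-squares increase), cut bottom-up
   so every functional group has ≥ 20 pairs, or at a fixed height.
4. **Divergence** — Needleman–Wunsch protein alignment (BLOSUM62, affine
   gaps) via Biostrings, codon back-translation onto the CDS, and a
   Nei–Gojobori style counting estimator with Jukes–Cantor correction for
   per-pair dN, dS and ω = dN/dS. Externally computed dN/dS tables can be
   imported instead.
5. **Statistics** — ω histogram; one-way ANOVA of ω across functional
   groups; Tukey HSD with simultaneous group-mean intervals and "extreme"
   group flagging; optional two-way ANOVA with copy-number class (Type II)
   and correlation of ω with centromere distance.
6. **Enrichment** — parent-child union over-representation of GO terms in
   each group's genes against all duplicated genes, Bonferroni-corrected,
   with a top-3 summary per group.

A first-class synthetic-study generator (`simulate_study()`) produces an
ontology with planted functional families, annotations with an
electronically-annotated fraction, duplicate pairs, family-dependent ω
values, diverged coding sequences with controlled substitution counts, and
a genome layout — with ground truth for every stage.

## Worked example

```r
library(funcdiv)

study  <- simulate_study(simulation_config(), seed = 1)
report <- run_pipeline(pipeline_config(study = study,
                                       namespaces = "biological_process"))
print(report)
#> run_report: 180 pairs -> 146 curated
#>   biological_process: 146 pairs, 6 groups, ANOVA F=155.35 p=2.64e-55, extremes: 1,2,3,4,5,6

ns <- report$namespaces$biological_process
ns$anova
#>  Source      SS  df        MS      F     Prob>F
#>  Groups 2.13596   5 0.4271921 155.35 2.6351e-55
#>   Error 0.38498 140 0.0027499     NA         NA
#>   Total 2.52094 145        NA     NA         NA

head(ns$tukey$groups, 3)
#>   group  n       mean        lo         hi
#> 1     1 25 0.24280511 0.2124995 0.27311074
#> 2     2 24 0.19419330 0.1632627 0.22512385
#> 3     3 24 0.05776726 0.0268367 0.08869781

head(ns$enrichment$top[, c("group", "term", "p_adj")], 3)
#>   group    term        p_adj
#> 1     1 BP:0044 1.830249e-56
#> 2     1 BP:0007 1.000000e+00
#> 3     1 BP:0011 1.000000e+00

adjusted_rand_index(ns$groups$group, study$truth[ns$groups$pair_id])
#> [1] 1
```

Reading the output: of 180 simulated pairs, 146 survive the curated-
annotation filter (the exact 10% IEA-only gene fraction drops the rest).
The minimum-size-20 cut recovers the six planted families exactly
(adjusted Rand index 1). ANOVA decisively rejects equal group means for ω
(F = 155 on 5 and 140 df), every group's simultaneous 95% interval
separates it from its neighbors' extremes, and each group's top enriched
term (e.g. `BP:0044`, p_adj ≈ 2e-56) is its family's planted anchor term.

Real data enter through the same interfaces: `parse_obo()`, `parse_gaf()`,
`read_pair_list()`, FASTA sequences (ids matching the pair list), and
optionally `import_divergence_table()` for dN/dS computed by other tools —
see `?pipeline_config`.

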