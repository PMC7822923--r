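# gldnet

Multiomic coexpression and causal network analysis of glucose and lipid
regulation in liver, as a tested, reusable R pipeline.

Liver coexpression modules have been described whose activity correlates
*negatively* with plasma lipid traits (LDL, total cholesterol) and
*positively* with glycemic traits (HbA1c, blood glucose) — a molecular
trace of the clinically familiar coupling between cholesterol lowering and
glucose elevation. `gldnet` implements the complete analysis used to find
and dissect such a glucose- and lipid-determining (GLD) module:

1. **Preprocessing** — CPM filtering (≥ 1 CPM in ≥ 10% of samples), TMM
   normalization, log2-CPM transform, flow-cell residualization, and
   3-SD PC1/PC2 outlier removal with re-correction.
2. **Trait signatures** — per-gene linear-model association with clinical
   traits at FDR 5% (Benjamini–Hochberg), metabolite z-normalization, and
   one-tailed Fisher enrichment against GMT annotation.
3. **Coexpression** — soft-thresholded unsigned adjacency, topological
   overlap (TOM), average-linkage tree cut, module eigengenes (1st PC),
   eigengene–trait correlation, the inverse lipid/glucose sign rule, and
   split-cohort module conservation (e.g. statin vs no-statin).
4. **Genetics** — cis-eQTL mapping (±1 Mb, expression-PC covariates,
   within-gene Bonferroni, BH across genes), top-eSNP selection, and
   SNP–gene–metabolite trio assembly.
5. **Causal inference test** — a four-component intersection–union test
   per trio in both directions; directional calls become prior edges.
6. **Consensus Bayesian networks** — k-means 3-state discretization, BDeu
   scoring, Metropolis–Hastings structure sampling with eQTL-derived
   orientation priors, 50+ independent reconstructions merged at a 0.3
   consensus cutoff, weakest-link cycle breaking; module-only,
   multiscale (genes + metabolites + traits, CIT edges forced), expanded
   (pathway/PPI-grown), and global variants.
7. **Key drivers** — downstream-neighborhood enrichment at a maximal path
   of 7, weighted ranks (top driver = 1), and a cross-network composite
   score (maximum = number of networks).

A synthetic multiomic cohort generator with known causal ground truth — a
planted GLD-like module with a master regulator at its root, cis-eQTLs on
upstream genes, metabolites downstream of module genes, and traits loading
with opposite lipid/glucose signs — makes every stage testable without any
controlled-access data, and supports in-silico perturbation of the planted
regulator (`perturb_key_driver`).

## Worked example

```r
library(gldnet)
run <- run_pipeline(gld_config(seed = 1))
run
#> GLD pipeline run
#>   modules: 2; GLD-pattern module: M1 (60 genes)
#>   eQTL genes at FDR: 31; trios: 18; prior edges: 16
#>   networks: gld, multiscale, expanded, global
#>   top key driver: G001 (score 2.40)

str(run$recovery)
#> List of 5
#>  $ module_jaccard       : num 1
#>  $ gld_flagged          : logi TRUE
#>  $ edge_precision       : num 0.864
#>  $ edge_recall          : num 0.966
#>  $ master_regulator_rank: int 1
```

Reading the output: the pipeline detected two coexpression modules; module
M1 (60 genes, identical to the planted module — Jaccard 1.0) was flagged by
the inverse sign rule (eigengene negatively correlated with LDL/total
cholesterol, positively with HbA1c/glucose at FDR 5%). The consensus
Bayesian network over the module recovered the planted wiring with
directed-edge precision 0.86 and recall 0.97, and the composite key-driver
ranking across the four networks placed the planted master regulator
(`G001`) first, with a score of 2.40 summed over the networks in which it
is a significant key driver.

Individual stages are exported (`preprocess_counts`, `detect_modules`,
`find_gld_modules`, `map_cis_eqtl`, `run_cit`, `learn_consensus_network`,
`build_multiscale`, `kda`, `composite_score`, …) and documented; the
methods vignette (`vignettes/gldnet-methods.Rmd`) describes the models,
parameter choices, and limitations.

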