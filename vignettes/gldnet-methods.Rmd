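---
title: "Methods: multiomic causal network analysis of glucose and lipid regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic causal network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plasma lipids and blood glucose are regulated by partly shared hepatic
programs: cholesterol-lowering therapy tends to push glucose upward, and
liver coexpression modules have been reported whose activity tracks lipid
traits negatively and glycemic traits positively at the same time. `gldnet`
implements the full analysis arc used to dissect such a module: normalize
raw RNA-seq counts, find coexpression modules and correlate their
eigengenes with clinical traits, flag the module with the inverse
lipid/glucose signature, anchor genes with cis-eQTLs, test
SNP → gene → metabolite mediation, learn consensus Bayesian causal
networks with genetic structure priors, and rank key driver genes across
networks with a weighted composite score.

Because the human cohorts this kind of analysis runs on are
controlled-access, the package ships a synthetic multiomic cohort
generator with a *known* causal ground truth. Every stage is therefore
testable end to end: the generator plants a glucose- and lipid-determining
("GLD-like") module rooted at a master regulator, and the acceptance suite
asks whether the pipeline gets the module, its internal wiring, and the
regulator back.

# The synthetic cohort generator

The generator is a linear-Gaussian structural equation model on the log
scale with Poisson count sampling — the simplest generative family
consistent with what every inference stage assumes (linear associations,
additive genetic effects, DAG causal semantics).

**Structure.** The default truth has a 60-gene GLD-like module whose causal
graph is a ternary tree rooted at the master regulator, a 40-gene glucose
module, and 50 unconnected background genes. The 22 GLD genes nearest the
root carry cis-eQTLs (8 in the glucose module), so genetic anchors sit
causally upstream — the configuration the DNA → RNA prior logic assumes.

**Propagation.** In topological order, each gene's latent value is the
weighted sum of its parents plus its eQTL effect times dosage plus Gaussian
noise (innovation SD 0.35 for children, 1 for exogenous roots). Edge
weights have magnitude 0.85–1 and *random sign*: modules contain both
activated and repressed targets. The signs matter beyond realism — with
all-positive regulation a 100-gene module becomes the dominant axis of the
library, and CPM/TMM normalization, which assumes most genes are stable,
partially cancels the module's own eigensignal. Mixed signs keep the
trimmed mean of M-values honest at desk scale, exactly as the bulk of a
real transcriptome does for a real module.

**Counts.** Read counts are Poisson draws around
`exp(baseline + 0.5 * latent)` times a per-sample library factor
(0.7–1.3). The 0.5 log-fold scale keeps per-gene variation in a realistic
1.5–2 fold band; module genes get baselines of 50–500 expected counts
while background genes are housekeeping-like (1,000–10,000), so no module
dominates the library mass. Additive flow-cell offsets (3 batches, SD 0.8)
hit a fixed 20% of genes on the log scale, making the batch-residualization
stage consequential.

**Traits and metabolites.** Each continuous trait is a signed, weighted sum
of module eigensignals (the sign-aligned module mean) plus noise scaled so
the loading approximates the trait-eigengene correlation: LDL and total
cholesterol load −0.6 on the GLD-like module, HbA1c and glucose +0.6,
with weaker HDL/triglyceride/insulin loadings and a +0.3 glucose loading on
the second module. The statin flag is drawn independently of expression (so
module conservation under statin splits is a real test, not a tautology;
`statin_effect` adds a coupling for robustness experiments); T2D,
hyperlipidemia and oral anti-diabetic use are logistic in the corresponding
continuous traits. Five metabolites are children of eQTL-bearing GLD genes
with noise tuned to a parent correlation near 0.75 — strong enough to pass
the trio screens, noisy enough that mediation is statistically
non-degenerate (at r ≈ 0.9 the mediator explains the metabolite almost
exactly and conditional-independence testing loses meaning).

**What the generator does not emulate:** linkage disequilibrium between
variants, GC/length biases, over-dispersed counts, population structure,
non-linear regulation, and feedback. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
performance on real cohorts.

# Preprocessing

Genes are kept when they reach 1 CPM in at least 10% of samples; TMM
factors (trimmed mean of M-values, 30%/5% trims, upper-quartile reference,
geometric mean 1) rescale library sizes; expression becomes
`log2((count + 0.5) / (effective library + 1) * 1e6)` — the deterministic
point transform of the mean-variance modeling family, without precision
weights, since no downstream stage consumes weights. Flow-cell batches are
removed by per-gene least squares (groups under 10 samples pooled,
collinear columns dropped by pivoted QR, gene means added back — every
downstream stage is correlation-based and indifferent to centering).
Samples beyond 3 SD on PC1 or PC2 of the residualized matrix are removed
and the data re-corrected, capped at two rounds; a screen flagging more
than 20% of samples aborts, which catches degenerate simulations early.

# Modules and the inverse-signature rule

The coexpression stage is deliberately concrete where tool defaults would
be vague: unsigned adjacency `|cor|^power` with the power chosen as the
smallest achieving scale-free fit R² ≥ 0.8 (fallback 5 — planted-block
data are intentionally not scale-free, so the fallback is the norm here);
topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j)+1−a_ij)`;
average-linkage clustering on `1 − TOM`; a static tree cut at height 0.99
with clusters under 30 genes sent to "grey". Eigengenes are first principal
components of the standardized module submatrix, oriented so the mean
correlation with module genes is positive; the orientation is arbitrary in
principle, which is why the module-flagging rule is orientation-aware: a
module qualifies when at least one lipid trait is significantly negative
*and* one glucose trait significantly positive (BH within the clinical
family, FDR 5%), or the exact mirror (flagged `flipped`). Trait and
metabolite correlation families are corrected separately. Split-cohort
conservation reruns detection per group and Fisher-overlaps each group's
modules against the reference over the common gene universe.

# Genetics: cis-eQTLs and trios

Cis associations are tested within ±1 Mb, with expression PCs as
covariates standing in for surrogate variables. The PC count is chosen by
the same operational rule used for the original surrogate variables —
take the count at which cis-eQTL discovery is maximal (`"auto"`, 0–7).
This matters at desk scale: with 150 genes the top PCs *are* the module
eigensignals, and regressing them out deletes the master regulator's own
eQTL. Within-gene multiplicity uses Bonferroni over cis variants
(conservative, dependency-free), BH across genes on the per-gene minimum.
Each significant gene's top eSNP is screened against all metabolites (BH
over the whole family), surviving pairs against gene-metabolite
correlation (BH, 5%), and triples passing all screens become trios.

# The causal inference test

For a trio (L, G, T) the causal direction L → G → T is supported by the
intersection-union of four tests: (1) L associates with T; (2) L
associates with G given T; (3) G associates with T given L; (4) T is
independent of L given G. The omnibus p is the maximum. Component (4) is
the delicate one — a plain conditional-association p-value is uniform
under independence, never small — so it is an *equivalence* test: the
observed L coefficient in `T ~ L + G` is compared against permutation
draws (L permuted within 10 mediator quantile strata) shifted by the
margin the reactive model would leave behind. For a reactive truth
L → T → G, partial regression algebra gives the conditional coefficient
`beta_marginal * (1 − ρ²_GT)`; that is the margin delta, and

p4 = (1 + #{b : |beta_obs| > |delta + beta*_b|}) / (B + 1).

Under true mediation beta_obs ≈ 0 and the shifted draws all exceed it, so
p4 hits its 1/(B+1) floor; under the reactive truth beta_obs sits at the
margin and p4 hovers near 0.5. Perfect mediation (zero residual variance
of T given G) short-circuits to the floor. A trio is called
gene → metabolite when the causal omnibus survives BH across trios and the
reactive omnibus is raw-nonsignificant (p > 0.05), with the mirrored rule
for metabolite → gene; conflicts across trios for the same pair are
dropped. Called edges become strong priors for the multiscale network.

# Consensus Bayesian networks

Expression is z-scored per node and discretized by k-means into three
states (low/none/high, best of 10 restarts); a fit with a cluster under 2
samples or centers closer than 0.5 SD falls back to two states, and
categorical traits keep their natural 2–3 levels. Structures are scored
with the BDeu marginal likelihood. The equivalent sample size is 0.25: at
n = 300 with 3-state nodes, ess = 1 measurably over-connects (directed
precision 0.58 vs 0.83 on the planted module), a known behavior of BDeu
where larger imaginary sample sizes soften the complexity penalty. Parent
sets are capped at 3.

Each reconstruction is a Metropolis–Hastings chain over DAGs: a move type
is drawn uniformly (add / delete / reverse), add proposes a uniform
ordered pair, delete and reverse propose a uniform *existing* edge, and
the Hastings ratio accounts for the changing neighborhood sizes. Drawing
reversals from the edge list is what makes orientations mix: each edge
gets on the order of a hundred reversal proposals per chain, so the
structure prior's orientation preference actually equilibrates. Chains run
150·n burn-in plus 300·n kept steps and return their final DAG; 50
independent reconstructions (seeds derived from the run seed) are merged,
edges at consensus frequency ≥ 0.3 retained, and any remaining cycles are
broken by removing each cycle's minimum-frequency edge (ties lexicographic
by source then target; forced edges are never removed).

Two structure priors encode genetics. The coarse rule multiplies the
acceptance ratio by 0.1 for any edge into an eQTL-anchored node from a
non-anchored node. That cannot orient an edge between two anchored genes,
so a second, sharper prior uses the instruments themselves: a cis variant
acts on the rest of the network only through its gene, hence any node
associated with gene A's top eSNP (p < 1e-3) must be downstream of A, and
edges B → A from such nodes are penalized by 0.01. In the planted cohort
this orients the module's upper tree — without it, consensus mass for the
root's edges splits across directions and falls below the 0.3 cutoff,
leaving the master regulator with no downstream neighborhood at all.

The multiscale variant adds metabolites and traits as nodes (same
discretization; CIT edges forced present with probability 1, trait nodes
barred from parenting anchored genes by default). The expanded network
grows the module by eigengene-correlated genes plus a simplified pathway
expansion: all genes of any pathway containing a member, plus
protein-interaction nodes bridging two members not directly connected. The
global network covers the full expressed gene set.

# Key drivers and the composite ranking

For each network, every node with a non-empty downstream neighborhood
within 7 directed steps is a candidate; the neighborhood is tested for
enrichment of the module genes against the network's node universe
(one-tailed Fisher via the hypergeometric tail, BH across candidates,
key drivers at FDR 5%). Within a network, key drivers are ordered least
significant first (ties on p broken by downstream-target count, then
lexicographically) and the i-th of N receives weight i/N, so the most
significant driver gets exactly 1. The composite score sums a gene's
weights across networks: the maximum equals the number of networks. One
degeneracy is worth knowing: in the module-only network the target set
equals the node universe, every enrichment p is 1, and that network
contributes no ranks — the composite is carried by the multiscale,
expanded and global networks, where the module is a proper subset.

# Problem sizes and reproducibility

The default study conditions are 150 genes (60 + 40 + 50), 300 samples,
450 variants, 15 metabolites, 50 reconstructions per network, chosen as a
desk-scale cohort on which the full pipeline completes in about 40 seconds
per seed; `n_reconstructions = 1000` reproduces the reference
reconstruction depth when wanted. All randomness flows from a single run
seed through named per-stage substreams (`stage_seed`), so reruns are
bit-identical and stages can be rerun in isolation.

```{r}
library(gldnet)
run <- run_pipeline(gld_config(seed = 1))
run$recovery      # module flag, edge precision/recall, regulator rank
head(run$composite)
```

# Known limitations

Orientation between non-anchored genes remains Markov-ambiguous — only
genetics (or interventions) can resolve it, which is the point the prior
machinery makes testable. The static tree cut is a simplification of
adaptive branch-splitting cutters; modules of strongly unequal density may
need the cut height adjusted. The CIT margin construction assumes linear
structural equations, as does the generator. BDeu discretization discards
dose-response detail; very weak edges (|w| < 0.3 or so) fall below the
consensus threshold at n = 300. None of the stages model feedback loops;
cycles can only arise from merging chains and are resolved heuristically
by the weakest-link rule.
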