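---
title: "Disease interactome modules, network proximity and Mendelian randomisation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease interactome modules, network proximity and Mendelian randomisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interactomr)
```

This vignette documents the models behind `interactomr`, the parameter
choices that matter, the design decisions taken where several defensible
definitions exist, and what the synthetic-data generators do and do not
emulate. Nothing here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The interactome model

All network quantities are computed on an undirected graph whose nodes
are gene/protein identifiers and whose edges are interactions. Node
identifiers are opaque, case-sensitive strings: any mapping from SNPs or
probes to genes is assumed to have happened upstream, and no symbol
normalisation is attempted. Edge weights are read and preserved, but
distances are unweighted hop counts throughout — interaction confidence
scores are not metric distances and there is no principled conversion.
Self-loops are dropped at the boundary and duplicate undirected edges
collapsed, so downstream algorithms can assume a simple graph.

# Module detection

Three detectors produce candidate decompositions, mirroring the three
families in common use:

* **MCODE.** Vertices are weighted by the core-clustering coefficient:
  the density of the highest k-core of the closed neighbourhood, scaled
  by k. Complexes grow from the heaviest unvisited seed, admitting
  neighbours whose weight exceeds `(1 - vwp)` of the seed's weight
  (`vwp = 0.2`, the plugin default). Post-processing keeps the 2-core
  ("haircut", on by default) and can optionally "fluff" complex
  boundaries (off by default, as in the plugin). Complexes are scored by
  density x size. Because the growth stage marks vertices as visited,
  complexes are disjoint unless fluff is enabled. On graphs without
  dense neighbourhoods — trees, sparse scaffolds — every vertex weight
  degenerates and no complex survives the haircut and the minimum-size
  filter; this is correct behaviour, not a failure.
* **MCL.** The standard flow simulation on the column-stochastic
  adjacency matrix with unit self-loops: expansion (matrix power 2),
  inflation (entrywise power 2 with column renormalisation), pruning of
  entries below 1e-5. Convergence is declared when the largest entry
  change falls below 1e-8; hitting `max_iter = 100` returns a result
  flagged `converged = FALSE` rather than an error. Clusters are the
  connected components of the symmetrised support of the limit matrix.
  Node order is fixed (lexicographic), so pruning and the result are
  fully deterministic.
* **Fast-greedy modularity.** Newman's agglomerative maximisation of
  modularity Q = sum_c (e_c/m - (d_c/2m)^2) via
  `igraph::cluster_fast_greedy()` — the same objective as the community
  stage of the GLay Cytoscape plugin, without the GUI dependency.
  Modularity is computed unweighted; a weighted variant is deliberately
  out of scope.

Every returned module must induce a connected subgraph and contain at
least `min_size = 3` nodes (the MCODE convention; biological modules of
one or two genes are not meaningful units here). Smaller fragments go to
`unassigned`.

# Entropy-based method selection

Network structure entropy E = - sum_i I_i ln I_i, with I_i node i's share
of total connectivity, measures how ordered a degree distribution is: E
is maximal (ln N) exactly for regular graphs and decreases as hubs
concentrate connectivity. To compare partitioning methods, the entropy of
the decomposition each method implies is computed and the minimum wins;
ties resolve in the order MCODE, MCL, greedy with a warning.

Which graph the entropy should be evaluated on admits several readings,
so all three are implemented and reported:

* `module_union` (default): the subgraph of all within-module edges over
  all assigned nodes. This is the default because it rewards methods
  that carve out fewer, denser, more coherent cores — the behaviour that
  separates complex-detection from exhaustive-partition methods.
* `per_module_mean`: the mean of per-module entropies.
* `global`: the whole-network entropy, method-independent, kept for
  reference.

On the package's planted-partition fixture the `module_union` variant
orders the three methods with MCODE lowest (`scripts/acceptance.R`
recomputes this), matching the qualitative pattern expected from a
complex detector versus exhaustive partitioners.

# Main-module identification

Modules are ranked by three aggregate centralities computed on the full
network (not the module subgraph, so that modules are comparable in the
disease-network context): node strength (weighted degree), normalised
betweenness, and PageRank at damping 0.85 (tolerance is igraph's
default). Aggregation is the sum over member nodes, with the mean
available via `aggregate = "mean"`; the sum is the default because a
module's total hold on the network, not its per-gene average, is what
the rank-1 rule is meant to capture. If one module is rank-1 on all
three metrics it is the main module. Otherwise each rank-1 candidate is
removed in turn from the union-of-modules subgraph and the absolute
change in characteristic path length (mean shortest path over reachable
pairs) decides; a removal leaving fewer than two reachable pairs counts
as infinite disturbance — removing that module disconnects the modular
network outright. "Strength" reduces to plain degree on unweighted
networks, and the path-length reading of the disturbance criterion is
the standard interpretation of eigenpath-length perturbation.

# Network proximity

For target sets X, Y mapped onto the network (unmapped genes dropped and
counted):

* closest distance d(X,Y) = |Y|^-1 sum_y min_x d(x,y) — asymmetric, as
  conventionally printed;
* separation s_AB = d_AB - (d_AA + d_BB)/2 with d_AB the symmetric
  closest distance and d_AA the mean nearest-other-member distance
  (singletons contribute 0);
* z = (d - mu)/sigma against a null of `n_perm = 1000` random set pairs
  matching |X|, |Y| and, by default, the degree distribution of X and Y
  via log2-degree bins merged until each holds at least `bin_min = 10`
  network nodes. This degree-preserving construction is the standard
  disease-module separation protocol; uniform sampling is available via
  `degree_binned = FALSE` for sensitivity. The z-score standardises the
  asymmetric d(X,Y), and s_AB is reported alongside, so each printed
  formula has an exact home.

Unreachable pairs are excluded from the means (and counted) rather than
imputed with diameter + 1: imputation moves s_AB across zero in sparse
networks, which is exactly the sign the decision rule depends on. The
empirical p-value uses add-one smoothing, `(1 + #{null <= obs})/(1 +
n_perm)`. A null standard deviation of zero flags `z` as undefined
instead of dividing by it.

# Cross-trait statistics

`clump()` implements greedy index-SNP selection: candidates below `p1`
are visited by ascending p-value, each absorbing SNPs below `p2` within
`window_kb` whose r-squared exceeds `r2`. The r-squared source is a
user-supplied lookup (matrix-like or function); computing LD from
genotypes needs a reference panel and is out of scope. Missing pairs are
treated as unlinked. Defaults follow the shared-SNP stage (5e-8, 1e-5,
0.2, 500 kb); instrument selection uses the stricter 0.001 / 10,000 kb.

S_Hom = (sum_k sqrt(n_k) z_k)^2 / sum_k n_k is the sample-size-weighted
homogeneous statistic (chi-squared, 1 df). S_Het maximises S_Hom over
the trait subsets obtained by thresholding |z| at each observed value
(inclusive, so the full set is always a candidate and S_Het >= S_Hom by
construction). Its null is calibrated by direct Monte-Carlo simulation
of the same maximisation under independent standard-normal z — testable
and exact in the limit, unlike a fitted beta approximation. Because an
add-one Monte-Carlo p saturates at 1/(1 + n_sims), statistics beyond the
simulated support fall back to the chi-squared union bound over the K
candidate subsets; without this the 5e-8 meta threshold would be
unreachable at any desk-scale simulation count. Trait independence is
assumed (overlapping-sample corrections are not modelled). The
shared-SNP filter applies strict inequalities, with the "every trait"
reading of the single-trait rule by default (`rule = "any"` relaxes it).

# Colocalisation

Per-SNP evidence is the Wakefield approximate Bayes factor, log ABF =
0.5[ln(V/(V+W)) + z^2 W/(V+W)] with V the squared standard error and W
the squared prior SD (0.15 by default, the quantitative-trait
convention; 0.2 is conventional for case-control log-odds and available
per trait). The five hypothesis sums use the standard enumeration with
priors p1 = p2 = 1e-4, p12 = 1e-5 and are accumulated by log-sum-exp —
real-data z-scores reach 40, where naive exponentiation overflows. The
H3 term ln(e^{S1+S2} - e^{S12}) is computed with `log1p`; with a single
shared SNP it is -Inf and PPH3 is exactly 0. The model assumes at most
one causal variant per trait per region; region definition is the
caller's responsibility.

# Mendelian randomisation

Harmonisation joins on SNP id, aligns the outcome effect to the
exposure's effect allele (sign flips for swapped or strand-flipped
alleles), and handles palindromic SNPs (A/T, G/C) by dropping them
unless both effect-allele frequencies are present and outside the
ambiguity band 0.5 +/- 0.08, in which case frequency matching infers the
orientation. Finally instruments are oriented so the effect allele is
exposure-increasing.

Estimators, all hand-implemented and cross-checked in the test suite
against an independent weighted-least-squares oracle (`lm(weights =)`)
to 1e-10:

* **IVW**: weighted regression through the origin; fixed-effect SE
  `(sum w beta_x^2)^-1/2`; multiplicative random effects inflate the SE
  by max(1, sqrt(Q/(J-1))) and engage automatically when Cochran's Q
  has p < 0.05 (overridable). One instrument degrades to the Wald ratio
  with a warning.
* **MR-Egger**: weighted regression with intercept, exposure effects
  oriented positive; the intercept is the average directional
  pleiotropy; SEs on the max(1, sigma) multiplicative scale with
  t-distribution p-values (J - 2 df).
* **Weighted median**: inverse-variance-weighted median of Wald ratios,
  interpolated at cumulative weight 0.5 with the midpoint convention
  S_j - w_j/2 (conventions differ; the midpoint rule makes three
  equal-weight ratios return the middle one exactly). SE by parametric
  bootstrap (1000 draws).
* **Weighted mode**: argmax of the weighted normal-kernel density of
  the ratios on a 512-point grid; bandwidth 0.9 * MAD-scale * J^(-1/5)
  times a user factor; zero spread returns the heaviest ratio directly.
* **MR-PRESSO**: each SNP's weighted squared residual is taken against
  the leave-one-out IVW fit; `n_sim = 1000` parametric simulations
  redraw the outcome effects about the leave-one-out fitted values and
  recompute the leave-one-out fits, so observed and simulated RSS are
  identically distributed under the no-pleiotropy null (this is also
  why the global test is calibrated — the acceptance suite checks the
  null p-values against uniformity). Outliers are flagged at Bonferroni
  0.05 across J; note that with J = 50 the flag requires an observed
  per-SNP RSS beyond all 1000 simulations, so `n_sim` below 1000 cannot
  flag anything at that level. The distortion test compares the
  estimate shift after removing flagged outliers with the shift after
  removing equally many random instruments (1000 draws).
* **MVMR**: weighted multiple regression without intercept; the
  instrument list is the union of per-exposure instruments restricted
  to SNPs present in all tables (the union is one of two defensible
  readings; the restriction is forced by the two-sample design). A
  rank-deficient design errors out naming the collinear exposures. With
  one exposure the result equals univariable IVW exactly.

Binary-outcome effects are treated as log-odds and reported with OR =
exp(beta) and exponentiated CIs. Per-instrument F = (beta_x/se_x)^2;
a mean below 10 raises the conventional weak-instrument warning.

# What the synthetic generators emulate — and what they do not

`gen_sbm` plants a known block structure; `gen_target_pair` plants a
known topological overlap; `gen_mr_dataset` plants a known causal
effect, optional directional pleiotropy and outliers; `gen_coloc_region`
plants null/shared/distinct causal configurations. Every generator is a
pure function of its parameters and seed, and writes its ground truth
alongside the data.

Choices a user should know about:

* Exposure effects are half-normal (scale 0.05) truncated at 0.005 —
  truncation keeps Wald ratios finite, and defining the effect allele
  as the exposure-increasing one (beta_x > 0) is the standard
  simulation convention; without it, per-SNP re-orientation would
  scramble a constant pleiotropy intercept and Egger's target would not
  exist in the generated data.
* Baseline standard errors are 0.007 (times `se_scale`, with per-SNP
  jitter), chosen to put mean instrument F near 50 — the strength
  regime of well-powered GWAS instruments.
* The observed exposure effects carry no measurement noise beyond what
  the standard errors describe for the outcome; consequently IVW
  coverage is nominal by construction and the acceptance suite checks
  it lands in [0.92, 0.97].
* Palindromic SNPs get allele frequencies inside the 0.42–0.58
  ambiguity band: they exercise precisely the case the drop rule exists
  for, so the harmonisation drop count equals the planted palindromic
  count. Frequency-resolvable palindromes are covered by hand-built
  cases in the unit tests instead.
* Outlier shifts are added to the outcome effect directly (raw scale),
  so planted outliers are unambiguous multi-sigma events.
* Coloc regions have independent SNPs (no LD) and constant standard
  errors, consistent with the single-causal-variant ABF model; genome
  coordinates are monotone placeholders.

None of the generators simulate LD structure, realistic allele-frequency
spectra, sample overlap between traits, or winner's-curse selection.
Passing tests therefore demonstrate correctness of the estimators under
their own assumptions — not robustness to the full messiness of real
summary statistics.

# Problem sizes and numerical choices

The simulation studies run at sizes chosen to give stable Monte-Carlo
estimates while keeping the whole suite quick to iterate on: 100-node
SBM fixtures with 1000-permutation nulls, 500 IVW recovery replicates,
300 Egger intercept replicates, 100 MR-PRESSO power seeds and 200
calibration seeds, 100-SNP coloc regions. Degenerate inputs follow one
rule: impossible requests error with a message (edgeless graph entropy,
empty joins, all-unreachable target sets, rank-deficient MVMR designs),
while legitimate boundary cases degrade with a warning (single-instrument
Wald ratio, p = 0 clamped to the smallest positive double, missing r²
lookup). Ties everywhere break deterministically (lexicographic node
order, canonical method order), so identical inputs give byte-identical
outputs.

# Known limitations

* MCODE complexes can only overlap through the fluff option; no other
  overlapping-community method is provided.
* The entropy comparison assumes the candidate methods were run on the
  same network; it does not penalise a method for leaving nodes
  unassigned beyond what the `module_union` variant implies.
* S_Het assumes independent traits; the MC null does not model sample
  overlap.
* Colocalisation is single-causal-variant; fine-mapping-based
  extensions are out of scope.
* MR estimators assume the two samples are independent and the summary
  statistics well-calibrated; no Steiger filtering or
  contamination-mixture methods are included.
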