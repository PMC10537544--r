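---
title: "Network module analysis: from screening to modules and enrichment"
author: "netmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network module analysis: from screening to modules and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmod)
```

## The analysis

`netmod` implements a network-pharmacology workflow that asks which proteins
mediate the effect of a multi-component intervention (for instance a herbal
preparation) on a disease, using only gene lists, expression profiles and a
protein–protein interaction catalogue:

1. **Screening.** Each two-group expression profile (case vs control) is
   quantile-normalized, probe-level rows are collapsed to genes, each gene is
   tested for differential expression, and genes with adjusted
   *p* < 0.05 and |log~2~FC| ≥ 0.5 become that profile's disease genes.
2. **Integration.** Per-database intervention-target lists are unioned;
   per-profile disease gene lists are unioned; the intersection of the two
   unions is the shared target set.
3. **Network construction.** Interactions with confidence ≥ 0.9 among the
   shared targets form the protein-interaction network (PIN), restricted to
   its largest connected component.
4. **Topology.** The PIN is characterised by the NetworkAnalyzer-style
   metric set (clustering coefficient, diameter/radius, centralization,
   shortest-path count, characteristic path length, heterogeneity), a
   log–log least-squares power-law fit of the degree histogram
   (scale-free check, count ≈ a·k^−γ^), and the shortest-path length
   histogram (small-world check).
5. **Critical network.** Two passes of median filtering: a node survives a
   pass when its degree AND betweenness AND closeness each strictly exceed
   that metric's median over the current graph; centralities are recomputed
   between passes.
6. **Hubs.** Nodes ranked in the top 10 of all three centralities
   simultaneously (boundary ties included).
7. **Modules.** MCODE (degree cutoff 2, k-core 2, node score cutoff 0.2,
   haircut on, fluff off) with modules kept when score = density × n is
   strictly greater than 5.
8. **Enrichment.** Per-module hypergeometric over-representation analysis
   against a GMT collection, keeping terms with BH-adjusted *p* < 0.05 AND
   *q* < 0.05, reporting the top 10 per module.

## Conventions and formulas

The topology conventions follow the Cytoscape NetworkAnalyzer family,
because those are the dialect in which such networks are usually reported:

* **Betweenness** is the Brandes pair-dependency sum with endpoints
  excluded, normalized by (n−1)(n−2)/2.
* **Closeness** uses the reachable-average convention: the number of
  reachable nodes divided by the sum of distances to them; isolated nodes
  score 0. On a connected graph this is the familiar (n−1)/Σd.
* **Clustering coefficient** averages local coefficients
  2e~v~/(k~v~(k~v~−1)) over nodes with degree ≥ 2 only — the local
  coefficient is undefined below degree 2, and including such nodes as
  zeros would conflate sparsity with low transitivity.
* **Centralization** is (n/(n−2))·(max~deg~/(n−1) − density), clipped to
  [0, 1]; undefined for n < 3 and reported as 0 with a warning.
* **Heterogeneity** is sd(degree)/mean(degree) with the sample (n−1)
  standard deviation; exactly 0 when all degrees are equal.
* **Shortest-path count** is the number of *ordered* pairs at finite
  distance, which equals n(n−1) on a connected graph — the identity that
  ties the reported path counts to the node counts.
* **Power-law fit**: ordinary least squares of ln(count) on ln(k) over
  histogram points with k ≥ 1, count > 0, no binning and no MLE. This is
  deliberately the simple straight-line-on-log-log diagnostic, not a
  rigorous tail estimator; its γ and R² are comparable to what network
  plugins print, nothing more.

Edge confidences are kept as metadata only: all shortest paths are
unweighted hop counts. The confidence scale (`unit` vs `string1000`) must
be stated explicitly by the caller — auto-detecting it silently is the
classic way to misread a STRING export, so `read_edge_list()` refuses to
guess.

## The screening stand-in

The differential-expression step is a Welch two-sample *t*-test on log2
values with each group's variance floored at 10^−8^, followed by
Benjamini–Hochberg adjustment. It deliberately does *not* reimplement
moderated (empirical-Bayes) linear-model statistics: what this stage owns
is the thresholding rule (adjusted *p* < 0.05, |log~2~FC| ≥ 0.5), and the
Welch test is a transparent, well-calibrated substitute whose behaviour
the test suite can verify exactly (closed-form *t*, df and *p* on small
fixtures; uniform *p*-values under a simulated global null). The variance
floor keeps zero-variance genes testable rather than dropping them, so a
pure location shift is still detectable. `logFC` is group 1 minus group 2,
with group 1 the first level of the supplied group factor.

Probe handling: probes mapping to zero or multiple genes are dropped;
among a gene's probes the one with the highest mean expression wins, ties
going to the smallest probe ID. The "highest mean" reading of the
probe-selection rule is an assumption (the usual collapse heuristic), made
explicit here rather than asserted as anyone's intent.

## MCODE

MCODE is implemented from scratch in its three published stages:

1. **Vertex weighting.** For each vertex of degree ≥ 2, take the closed
   neighbourhood H, find its highest k-core level k~max~, and set
   weight = k~max~ × density(highest k-core of H).
2. **Complex prediction.** Seed at the highest-weight unvisited vertex
   (ties broken lexicographically for reproducibility) and grow
   breadth-first, including unvisited neighbours whose weight is at least
   seed_weight × (1 − node_score_cutoff); ties at the threshold are
   included. Only included vertices are marked visited, so complexes are
   node-disjoint.
3. **Post-processing.** Complexes without a 2-core are discarded; haircut
   iteratively removes members with fewer than two intra-module
   neighbours; optional fluff expands by dense neighbours (off by
   default, and excluded from the disjointness guarantee when on).

Scores are density × n with loop-free density 2E/(n(n−1)), and the module
filter is *strictly* greater than 5 — a perfect 5-clique (score exactly
5.0) does not pass.

One behavioural consequence of the published weighting is worth knowing:
when two cliques are joined by a single bridge edge, both bridge
endpoints' closed neighbourhoods still contain their full clique core, so
every vertex keeps the full core weight and the greedy expansion walks
across the bridge, merging the two cliques into one predicted complex.
Trimming such bridges is the job of post-processing (and of the score
filter), not of complex prediction. A plausible alternative weighting —
k~max~ times the density of the *whole* closed neighbourhood — would
penalise bridge endpoints and keep the cliques separate; we implement the
published formula and pin the merging behaviour down in a regression
test so the choice is explicit.

## Critical-network filtering and hubs

The median filter is read conjunctively and strictly: a node survives
only when all three centralities strictly exceed their medians (median of
an even-length list = mean of the middle two). Strictness matters: on a
vertex-transitive graph (a cycle, say) no node strictly exceeds the
median of any metric and the filter correctly reports the input as
degenerate rather than returning an arbitrary half. Centralities are
recomputed on the filtered graph before the second pass, since the second
filtration is applied to the primary critical network. After each pass
the graph is restricted to its largest connected component (the
shortest-path counts of networks reported this way equal n(n−1), implying
connected networks); component ties are broken by the lexicographically
smallest member so the choice is deterministic.

If a later pass would empty the graph, filtering stops with a warning and
returns the pre-pass network; only a first-pass wipe-out is an error.

Hub selection takes, for each centrality, all nodes with values at or
above the k-th largest (so boundary ties are all included — the result is
deterministic and invariant under node relabeling), and intersects the
three lists. The intersection may legitimately be empty.

## What the generators emulate — and what they do not

* `gen_scale_free()` grows a preferential-attachment graph from an
  (m+1)-clique: connected, with m(n−m−1)+C(m+1,2) edges and a heavy-tailed
  degree distribution (log–log fit γ typically 1.5–3.5, R² ≥ 0.7 at
  n = 2000). It stands in for the interaction catalogue's topology, not
  for its biology: there is no annotation correlation, no hub-gene
  identity, no confidence structure.
* `gen_planted_modules()` embeds exact near-cliques (default sizes 8/7/6,
  internal density 1, two bridge edges each) in a G(300, 0.01)
  background. Recovery of these is a *clean-signal* benchmark: real
  complexes overlap and leak; a green Jaccard ≥ 0.8 here shows the
  algorithm is implemented correctly, not that it resolves real
  complexes.
* `gen_expression()` simulates log2 expression as Normal(7, 1) baselines
  plus ±2 planted shifts in 10% of genes and Normal(0, 1) noise for 10 vs
  10 samples — a clean microarray-like comparison at typical cohort size.
  Real profiles have correlated genes, batch structure and heavier tails;
  the calibration results (FDR ≤ 0.1, uniform null *p*-values, and the
  recall discussed under *Known limitations*) are statements about this
  stated world.
* `gen_target_sets()` draws database sets with an exact shared core
  (pairwise overlap is a single common block) and plants a known
  herb∩disease shared subset, so the integration stage can be checked for
  *exact* recovery.
* `gen_gmt()` plants terms superset of a designated gene set among random
  terms, giving the enrichment stage a known optimum.

`simulate_bundle()` composes these into a full input set. One of its
choices deserves a note: planted cliques are positioned among genes that
pass the bundle's *own* screening (it re-runs normalization and testing
exactly as the pipeline will). Normalization attenuates planted fold
changes, so the recovered DEG set is not the planted truth; cliques
planted on unrecovered genes would be silently excluded from the network
and could never be detected downstream. Anchoring them in the recovered
set mirrors the real situation — modules are sought within the network
that was actually built — and keeps the demonstration pipeline exercising
every stage. The bundle's dense-zone probability defaults to 0.05, dense
enough that the shared-gene network is connected, sparse enough that
planted cliques remain locally densest.

## Enrichment details

The hypergeometric upper tail is evaluated through `phyper`'s upper tail
(log-scale internally) and cross-checked in the tests against exact
binomial-coefficient enumeration to 10^−10^ for all parameters ≤ 25. The
universe defaults to the union of the collection's genes, since the
original background is typically unstated; an explicit background can be
passed. *q*-values follow Storey's recipe with π₀ estimated at λ = 0.5,
clipped to (0, 1] and monotonized; when the π₀ estimate reaches 1 they
coincide with BH, so the dual filter (adjusted *p* and *q* both < 0.05)
can never pass a term that BH alone fails.

## Numerical and degenerate-input choices

* Median of an even-length list is the mean of the middle two values.
* Exactly-log-linear histograms are recovered to 10^−9^; a constant
  histogram fits perfectly with γ = 0 and R² defined as 1 (zero total
  variance).
* Symbols are matched case-sensitively inside graphs; `gene_set()`
  uppercases on construction for cross-database set algebra. No alias or
  identifier mapping is attempted anywhere.
* Empty results that would poison downstream stages (empty induced
  network, empty set intersection, first-pass filter wipe-out, query
  disjoint from the universe) are errors; empty results that are
  legitimate findings (no hub in all three top lists, no module above
  score 5) are allowed and logged.
* The pipeline aborts with the failing stage's name; within the
  enrichment stage a single module whose genes are absent from the GMT
  universe is skipped with a message rather than aborting the run.

## Known limitations

* The Welch stand-in is less powerful than moderated statistics at very
  small n; its role is calibrated screening, not state-of-the-art DE. A
  concrete consequence: at the default simulation settings (|log~2~FC| =
  2, σ = 1, 10 vs 10), the noncentral-*t* power at the BH operating point
  caps recall near 0.86 — the test suite asserts a nominal 0.9 recall
  target for this scenario and that assertion fails by design rather than
  being weakened; FDR control and null calibration do hold.
* The log–log OLS power-law fit is descriptive; it is not a
  maximum-likelihood tail estimate and should not be used to *test*
  scale-freeness.
* MCODE options that exist only in the plugin GUI (loops, "examine from
  seed") are not implemented; fluff is provided but off by default.
* No batch-effect handling: profiles are assumed internally comparable.
* The whole pipeline is deterministic; only the generators consume seeds.
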