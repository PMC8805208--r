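---
title: "Methods: network inference of inter-tissue crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference of inter-tissue crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuetalk)
```

`tissuetalk` turns per-tissue case/control protein abundance tables and a
directed background regulatory network into a mechanistic map of
inter-tissue communication: which secreted proteins carry a disease signal
from one tissue into another, what regulates them, and what they perturb.
This vignette is the package's own account of the models and the choices
behind them.

## Differential calling

For protein $i$ with $n$ replicates per group, the statistic is a
two-sample Student t-test on $\log_2$ intensities and the effect size is
the geometric-mean ratio

$$\mathrm{FC}_i = 2^{\overline{\log_2 x^{case}_i} - \overline{\log_2 x^{con}_i}},$$

with a protein called differential when $\mathrm{FC} \ge 1.2$ or
$\mathrm{FC} \le 0.83$ (both inclusive) and $p < 0.05$ (raw). The pooled
(equal-variance) test is the default because that is the classical
Student test; Welch is available via `var_equal = FALSE`. No
multiple-testing correction is applied at this stage — the permissive DEP
pool feeds a network construction that is itself validated globally;
correction enters later, in enrichment. Assumptions: approximately
Gaussian log-intensities within groups and at least two replicates per
group. Boundary handling: the fold-change gates are applied with a
$10^{-12}$ relative tolerance so that a protein whose true ratio is
exactly 1.2 or 0.83 is included regardless of floating-point
representation of $2^{\log_2 x}$. Zero within-group variance in both
groups with equal means leaves the t statistic undefined; such records are
flagged `untestable` and never called. Zero variance with unequal means is
treated as conclusive ($p = 0$) — this is what makes noise-free synthetic
data behave sensibly.

## Core networks: seed nets and Steiner simplification

A tissue's DEPs are *seeds*. The seed net is the undirected subgraph
induced by the seeds plus their direct background neighbours (direction is
dropped from here on; keeping the construction undirected bounds its
complexity and matches how the topology statistics are defined). Each
connected component holding at least one seed is reduced to an approximate
minimum Steiner tree over that component's seeds with unit edge weights;
components without seeds are dropped, and all per-component trees are
retained. The result keeps every DEP reachable from another DEP, plus the
minimal connector scaffold bridging them.

The Steiner problem is NP-hard, so the package uses the classical
metric-closure 2-approximation: build the complete graph on terminals
weighted by shortest-path distance, take its minimum spanning tree, expand
each MST edge into a shortest path, take a spanning tree of the expansion,
and prune non-terminal leaves. Determinism is guaranteed by constructing
every subgraph with vertices in sorted name order and running Kruskal on
the terminal graph with edges ordered by (weight, endpoint names); for a
fixed input the output is bit-stable. An exact solver (exhaustive search
over connector subsets) is available through `exact_max` for small
components; it is used in tests to certify that the approximation stays
within its 2× bound — on the randomized small-graph suite (200 connected
graphs, 4–9 nodes, 2–4 terminals, densities from tree-like to dense) the
observed worst ratio is far below 2, two-terminal instances are exact
shortest paths, and all-terminal trees are returned unchanged. A truly
exhaustive enumeration of all connected graphs on ≤ 9 nodes is
combinatorially out of reach; the fixed-seed randomized suite is the
package's chosen audit of the bound.

Topology statistics: `connected_nodes` counts vertices of degree ≥ 1;
density is $2E/(N(N-1))$ over connected nodes. An edge-based variant
$E/(E(E-1)/2)$ is selectable (`density = "literal"`) for auditability, but
the node-based form is the default since the edge-based expression is not
a normalized density.

## Randomization validation

Observed networks are compared to 100 null networks, each built by
sampling a background protein set of the same size as the tissue's DEP
count uniformly without replacement and running the *entire*
seed-net + Steiner construction — only then are the three metrics
comparable between observed and null. Z-scores use the null mean and
standard deviation; the network is certified when all three |Z| exceed
2.33 (one-sided normal p < 0.01). The null is deliberately not
degree-matched — random resampling of background nodes is the stated
procedure this package operationalizes — and every draw flows from one
integer seed, so reports are bit-reproducible. If a metric's null standard
deviation is zero its Z is undefined and the report fails with an explicit
reason rather than dividing by zero.

## The cross-tissue interface

Ligands are a tissue's secreted DEPs (secretome membership is input data).
Two filters guard directionality:

* **Low expression.** A candidate is excluded from tissue A when its atlas
  expression in A is more than 10× *below the maximum* over the other
  atlas tissues. Among several readings of "more than 10 times lower than
  any other tissue", the max-reading is the most conservative against
  attributing a secreted signal to a tissue that barely expresses the
  protein; one sufficient witness excludes. Proteins missing from the
  atlas are retained with a warning — unknown is not low, and silently
  deleting atlas-absent proteins would bias the interface toward
  well-annotated genes.
* **Receptor presence.** A receptor must be a non-secreted protein
  appearing in the *target* tissue's core network via a directed
  background edge ligand → receptor. Receptors are not required to be
  differential by default; `receptor_dep = TRUE` enforces the stricter
  reading. Both modes ship because the defining texts of this family of
  methods are ambiguous on the point; neither is presumed correct.

Autocrine (same-tissue) edges are excluded by construction. Upstream
pairs (DEP regulator → ligand) are kept only for ligands that actually
emit a cross edge — the interface is defined around realized inter-tissue
connections — while downstream pairs (receptor → DEP effector, within the
receptor's own tissue) are collected for every receptor.

## Functional quantification

Per tissue, the upstream process set is ligands ∪ upstream regulators and
the downstream set is receptors ∪ downstream effectors. Each set is tested
by the exact hypergeometric upper tail against the non-excluded
("basic") pathway universe with Benjamini–Hochberg FDR < 0.05. The
enrichment background defaults to the tissue's detected pool (detection
defines the sampling frame in proteomics) extended by the set's own
proteins, since receptors and connectors need not have been quantified; a
caller-supplied background (e.g. all annotated proteins) is supported.
Pathways with no member in the background are skipped, not scored, and
ranking ties are broken lexicographically by pathway id so top-k lists are
reproducible.

Each non-empty process set contributes one observation — its fraction of
enriched pathways classed metabolic — and the mean over sets is compared
to the background metabolic share (metabolic / total among non-excluded
pathways) by a one-sample z-test, $z = (\bar p - p_0)/(s/\sqrt n)$, with a
95% CI of $\bar p \pm 1.96\, s/\sqrt n$. The effective $n$ is whatever
non-empty sets exist (at most tissues × 2) and is always reported
alongside; with fewer than two observations, or zero spread, the test is
skipped with a stated reason instead of fabricating a statistic. Empty
enrichments are excluded from the averaging rather than counted as zero.
"Dominant" upstream categories are pluralities of enriched-pathway
subcategories, with ties reported in full; a $-\log_{10} p$-weighted
variant is available.

Protein roles used in edge classification follow the restrictive
definitions: a *metabolic enzyme* carries an EC number and maps only to
metabolic pathways (excluded pathways never count); a *signaling protein*
maps to at least one signaling and no metabolic pathway. Edges touching
both kinds of endpoint carry both labels; an exclusive counting
(metabolic first) is reported alongside since neither convention is
canonical.

## The synthetic-data generator

`fixture_spec()` describes a complete input bundle; its defaults are the
study conditions the package is designed around: three tissues, three
replicates per group, planted DEPs at linear fold change 2 with log2
replicate noise sd 0.1, fold-change gate 1.2/0.83, one planted
ligand→receptor axis per ordered tissue pair around the cycle, an
Erdős–Rényi directed background (edge probability 0.02 over 160 proteins
— sparse enough that seed nets stay local, dense enough to be connected in
the large component), 40 basic pathways of which 35% are metabolic
(mirroring a realistic basic-pathway universe), and 12 extra planted DEPs
per tissue so the core networks are non-trivial.

Design decisions that keep the recovery tests meaningful:

* Axis proteins participate in *no* random background edges and extra
  secreted proteins are drawn from non-differential proteins, so the
  planted axes are provably the only true cross edges; planted truths are
  constructed independently of the analysis code (non-circularity).
* Atlas values put each ligand high in its source tissue and > 10× lower
  elsewhere, plus low-expressed secreted decoys, so the expression filter
  is exercised in both directions.
* A scale-free background option is not provided in this release; degree
  heterogeneity of real interactomes affects Steiner behaviour, and the
  Erdős–Rényi null understates hub effects. Passing recovery tests
  therefore demonstrates correctness of the machinery, not performance on
  hub-dominated real interactomes, nor robustness to missing values,
  batch effects, or peptide-level artefacts, none of which the Gaussian
  log-noise model emulates.

## Problem sizes and runtime envelope

The shipped verification suite uses fixtures sized for quick, exact
auditing: exhaustive hypergeometric enumeration to universe size 12
(≈ 3,000 cases), 200 brute-forced Steiner instances on ≤ 9 nodes,
randomization calibration on a 150-protein background with a 15-node
planted dense module (100 nulls, 20 null-drawn repeat trials), and 40
end-to-end pipeline runs on the default 160-protein fixture for interface
recovery and differential calibration. These sizes were chosen so the full
suite re-derives every number in minutes while each individual check
remains exact or statistically well-powered.

## Known limitations

* The Steiner step guarantees only a 2-approximation on arbitrary
  components (exact on small ones via `exact_max`); different optimal
  trees of equal size are not enumerated.
* The randomization null resamples nodes uniformly; a degree-stratified
  null would be stricter on hub-rich backgrounds.
* Identifier spaces are taken at face value (case-sensitive, no ortholog
  mapping); harmonizing human/mouse symbols is the caller's
  responsibility.
* The one-sample z-test treats per-set proportions as independent
  observations, which is approximate when tissues share enriched
  pathways.
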