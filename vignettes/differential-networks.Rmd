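---
title: "Methods: differential networks, cluster structure and homotopy animation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential networks, cluster structure and homotopy animation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinet)
library(dplyr)
```

## The model

`dinet` overlays per-condition measurements on a *background knowledge
network*: a curated graph whose nodes are molecular entities (genes,
proteins, metabolites) and whose typed edges record activation, inhibition
or binding, each optionally directed. The experimental overlay assigns each
node, per condition, a signed weight (typically log2 fold change versus
control) and a significance (typically a multiple-testing-adjusted
p value). The package deliberately does not compute these statistics:
differential-expression testing is upstream, and when several omics levels
are mixed their statistics must already be on comparable scales.

A node is **active** under thresholds $(\alpha, w_{\min})$ when

$$p_{\text{adj}} < \alpha \quad\text{and}\quad |w| \ge w_{\min},$$

with the significance bound strict and the weight bound inclusive —
`node_passes()` applies exactly these inequalities, and a missing
measurement never passes (absence of evidence is not significance). An
edge is active only when **both** endpoints pass; its display weight for
endpoint weights $n, m$ is

$$\mathrm{ew}(n,m) = \frac{s}{\max(s, 1)}, \qquad
  s = \frac{|n|}{\max(|n|,1)} + \frac{|m|}{\max(|m|,1)}.$$

This score is symmetric, lies in $[0,1]$, equals $|n|+|m|$ while both
magnitudes are small, and saturates at 1 once either endpoint reaches
magnitude 1 — strong regulation on one side alone maxes the edge out.
These properties are enforced by a 10^4-pair property sweep in the test
suite. Passing nodes with no passing neighbour are kept as isolated active
nodes: a lone responder is information, not noise.

Visual encoding follows the usual conventions: node size grows as
$\text{base} \times (1 + |w|/s)$ and colour is the signed weight clipped to
$\pm s$ on a symmetric blue–white–red diverging scale (blue =
downregulated, red = upregulated), with the scale $s$ shared across the
whole series so conditions are comparable frame to frame.

## Clustering large networks

Curated knowledge networks reach tens of thousands of nodes; display
requires decomposition. The pipeline in `clusterize()`:

1. **Community detection.** Multi-level (Louvain) modularity optimisation
   on the simplified, undirected view. Communities with fewer than
   `min_cluster_size = 5` nodes are dropped from further analysis (they
   carry too little context to interpret as modules) and reported.
2. **Structural classification** (`classify_cluster()`).
   *Densely connected*: the directed edge count (undirected edges counted
   twice) reaches $n(n-1)$ within a tolerance — by default at least 90 %,
   because real curated modules are only approximately complete. Under the
   doubled-count convention an undirected clique with $n(n-1)/2$ edges
   qualifies.
   *Star-like*: exactly one hub — a node with degree $\ge 60\,\%$ of the
   cluster maximum — plus an edge count within $\max(2, 0.1n)$ of $n$,
   maximal hub closeness, and hub betweenness within 10 % of
   $(n-1)(n-2)/2$, the exact value for a pure star (every leaf pair's only
   shortest path runs through the hub, $\binom{n-1}{2}$ pairs). The "close
   to" tolerances are the package's own defaults, configurable, since only
   the target formulas are canonical.
3. **Subdivision gate.** Dense and star-like clusters are structurally
   understood and excluded from further splitting, as is any cluster with
   fewer than $2^{10}$ nodes *and* fewer than $2^{11}$ edges (the AND
   reading of the rule; an OR variant is available via
   `clustering_params(gate_rule = "or")` because the published phrasing is
   grammatically ambiguous).
4. **Spinglass sub-clustering** of the remaining clusters into as many
   spins as the cluster has hubs — the hub count is a natural guess for
   the number of sub-modules. Spinglass requires a connected graph; a
   disconnected cluster is subdivided per component with spins allocated
   by per-component hub counts (at least one each), with a warning.
   Sub-clusters get hierarchical labels (`"7.1"`), plus a flat integer
   renumbering for table export.
5. **Layout.** Deterministic row-major grid over lexicographically sorted
   identifiers, refined by Fruchterman–Reingold for small clusters
   ($\le 2^6$ nodes **and** $\le 2^6$ edges) or Kamada–Kawai otherwise —
   FR gives livelier small layouts, KK scales better. The grid start and
   fixed seeds make layouts reproducible; user-supplied coordinates are
   never moved (they anchor the refinement).

Between-cluster edges are retained in the exported edge table with both
endpoint cluster ids, so inter-module relations survive the decomposition.

A displayable module must have between 2 and 16 384 loop-free edges
(`check_module_size()`; self-loops such as autocatalysis are excluded
from the count, both bounds inclusive). For large clusters an additional
display filter drops active nodes whose *background* degree — not their
differential-network degree, since the filter is meant as a static,
cluster-level control — is below a chosen `min_degree`.

## Functional-bin enrichment

Per cluster, hierarchical dot-separated bin codes (MapMan-style) are
expanded to all ancestors (a node in `1.2.3` also counts for `1.2` and
`1`), and each bin is tested for over-representation in the cluster versus
the whole network with a one-sided hypergeometric test, BH-adjusted across
the bins tested in that cluster. The test choice is the field standard
rather than something the pipeline's description fixes; the suite checks
the tail probabilities against direct combinatorial sums for populations
up to 30.

## Homotopy animation

Between consecutive conditions, node weights follow the linear homotopy
$w(u) = (1-u)\,w_0 + u\,w_1$, $u \in [0,1]$. At every frame the weight
threshold is re-applied to the *interpolated* value, so a node crossing
$w_{\min}$ mid-transition appears or disappears exactly where the line
crosses the cut-off; edge weights are recomputed from interpolated node
weights, and an edge is visible only while both endpoints are. Frames at
integer positions reproduce the per-condition differential networks
bit-exactly (asserted by the test suite).

Two decisions the animation needed that the underlying idea leaves open:

* **Significance at intermediate frames.** Significance is a test
  outcome, not a continuous quantity, so it is *not* interpolated. A frame
  inherits pass/fail from the nearer endpoint (source for $u < 0.5$,
  destination for $u \ge 0.5$); a conservative `sig_rule = "both"`
  requires both endpoints to be significant throughout the transition.
* **Appearing/disappearing measurements.** A node measured at only one
  endpoint ramps from/to weight 0 (and can never be significance-passing
  at the unmeasured endpoint). Interpolating from the last measured value
  instead would invent persistence the data do not support.

Frame sequences serialise to a single self-describing TSV (comment header
with metadata, one record per frame per element) — a toolchain-neutral
format that round-trips through `read_frames()`. `render_static()` writes
SVG assembled as plain markup: grey background graph, coloured active
nodes, arrowheads on directed edges, T-bar terminators for inhibition and
dashed bilateral arrows for binding. Building the markup directly (rather
than through a plotting device) makes renders byte-identical across runs,
which the replay checksums rely on; `autoplot()` methods provide ggplot2
figures for interactive work.

## Reproducibility log

`run_analysis()` writes a YAML settings log: tool version, timestamp,
every parameter, the seed, and SHA-256 checksums of each input and output
file. `replay()` re-executes the pipeline from the log into a fresh
directory and compares checksums, so any drift — changed inputs, a
tampered parameter, nondeterminism — surfaces as a named mismatch. All
stochastic steps (Louvain, spinglass, FR layout, fixture generation) are
seeded; equal input plus equal seed gives byte-identical outputs.

## Synthetic data: what it emulates, what it does not

`fixture_spec()`/`generate_background()` plant known structure: cliques
(exactly $n(n-1)/2$ undirected edges), stars (one hub, $n-1$ edges),
Erdős–Rényi clusters of chosen density, and uniformly placed bridge edges.
`generate_measurements()` draws responsive nodes' $|w|$ from a shifted
folded normal $\text{shift} + |N(0,\sigma)|$ (default shift 1.0,
$\sigma = 0.5$), signs balanced, significance uniform on $[0, 0.05)$;
non-responsive nodes get $N(0, 0.15)$ weights and uniform significance.
Defaults were chosen once to be realistic for a moderately strong
transcriptional response — effects comfortably above the conventional
$|logFC| \ge 0.5$ cut-off, noise well below it. Between conditions 70 % of
the responsive set persists, emulating modules switching on and off.

What this does *not* emulate: probe-level noise, correlated errors along
network edges, weight–significance dependence, batch effects, or the
specific topology of curated immune-signalling networks. Passing the
recovery tests therefore shows the pipeline's logic is correct on
well-separated structure, not that community detection will cleanly
partition any real curated network — on real data cluster counts are
version- and seed-sensitive, which is precisely why the settings log
records the seed.

The recovery checks use three planted Erdős–Rényi communities of 30/40/50
nodes with within-cluster edge probabilities 0.35/0.30/0.25 and 8 bridges
(within-density at least five times the implied between-density), 20
seeds; suite-wide problem sizes (10^4-pair property sweeps, stars to
$n = 12$, populations to 30 for enrichment enumeration) keep the whole
suite in the tens of seconds while still exercising every rule boundary.

## Numerical and degenerate-input choices

* Boundary behaviour is tested at the exact constants: module guard
  accepts 2 and 16 384 loop-free edges and rejects 1 and 16 385; the gate
  flips at 1024 nodes / 2048 edges; the layout switch at 64.
* Duplicate edges collapse per `(source, target, type)` with direction
  respected, so reciprocal regulation ($A \to B$, $B \to A$) survives
  simplification, and parallel edges of different interaction type are
  kept as distinct biology.
* A single node lays out at the origin; an empty network passes through
  simplification; an empty differential network still renders its
  background.
* Hub sets are never empty (the maximal-degree node always qualifies).
* Ties in cluster renumbering break on the smallest member identifier, so
  labellings are deterministic.
* When both a GraphML file and an XGMML file supply coordinates, the
  XGMML wins and the merge report records how many were overwritten — an
  interpretation, flagged as such in the function documentation.

## Known limitations

* Louvain and spinglass are stochastic heuristics: across igraph versions
  the same seed need not give the same partition, so cross-version
  reproducibility requires pinning the environment, not just the seed.
* Spinglass subdivision caps, but does not choose, the number of
  sub-clusters; hub count is a heuristic proxy.
* The degree display filter and the module-size guard are visualisation
  aids, not statistical procedures.
* No SBML/SIF/BioPAX import and no cross-species identifier translation;
  inputs must already use consistent identifiers (validated by
  `validate_network()`, which lists unmatched measured identifiers for
  exclusion).
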