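---
title: "Interactomic screening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactomic screening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

## The screening procedure

ppiscreen implements a topological screening of a disease gene set
interacting in a protein-protein interaction (PPI) network. The input is an
undirected simple graph whose nodes are gene symbols; isolated genes (found
by a database query but with no reported interaction) are allowed. The
analysis frame is the *main connected component*: centrality statistics and
the screening thresholds are computed over it, while isolated genes and
minor components are only counted. The pipeline runs, in order:

1. **Centrality.** Degree, and betweenness centrality
   $BC(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ computed by
   Brandes' single-source shortest-path accumulation on the unweighted
   graph, with the raw pair-dependency sum divided by $(n-1)(n-2)/2$ so
   values lie in $[0, 1]$; $n$ is the node count of the analyzed network
   and path endpoints are excluded. Node pairs in different components
   contribute nothing.
2. **Scale-free check.** The degree histogram (one point per distinct
   positive degree) is fitted to $y = a\,k^{b}$ by ordinary least squares
   of $\log_{10}(\text{count})$ on $\log_{10}(k)$, reporting $a$, $b$, the
   Pearson correlation of the log-log points, and $R^2 = r^2$.
3. **Screening.** *Hubs* are nodes whose degree strictly exceeds
   $\bar d + \mathrm{SD}(d)$; *bottlenecks* are the top 5% of nodes by
   betweenness, with count $\lceil 0.05\,n \rceil$; *hub-bottlenecks* are
   the intersection and the *central genes* the union.
4. **Sub-network re-ranking.** The node-induced sub-network over the
   central genes is extracted, degree and betweenness are recomputed within
   it (normalization uses the sub-network size), and genes are re-ranked,
   each keeping its original full-network rank for comparison.
5. **Action analysis** (optional). A directed multigraph of typed
   regulatory edges over the central genes — `expression` (signed
   `up`/`down`), `activation`, `inhibition` — is split into layers and
   summarized: per-layer participation, per-gene regulatory tallies,
   weakly connected inhibition components, and reciprocal pairs.

```{r pool}
tab <- table1_fixture()
res <- screen(tab, hub_rule = "top_k", hub_k = 20, bottleneck_k = 20)
res$hub_bottlenecks
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `hub_rule` | `"mean_sd"` | degree > mean + SD; `"top_k"` takes the `k` highest-degree genes and is the rule for screening a printed candidate pool of fixed size |
| `strict` | `TRUE` | strict inequality at the hub threshold |
| `bottleneck_frac` | 0.05 | fraction of nodes (ceiling) taken as bottlenecks |
| `min_score` | none | optional STRING confidence cutoff in [0, 1] at read time |
| `attachment` | 2 | edges per new node in synthetic growth |

Pinned conventions, chosen once for reproducibility where the field's
tooling leaves them ambiguous:

* **Population SD** (divisor $n$) in the hub threshold, and **strict**
  inequality: "above mean + SD" excludes a node sitting exactly at the
  threshold. With all degrees equal the SD is 0 and the hub list is empty.
* **Ceiling** in the top-5% count: 383 analyzed nodes give
  $\lceil 19.15 \rceil = 20$ bottlenecks, matching how a 5% rule reaching
  a 20-gene list behaves on that network size.
* **Tie-breaks** are total: degree descending, then betweenness
  descending, then name ascending (bottleneck boundary ties: betweenness,
  then degree, then name). Identical inputs therefore yield byte-identical
  reports.
* **Unweighted shortest paths**: confidence scores are stored but never
  used as weights, matching the default behaviour of the standard network
  analyzers this pipeline mirrors.
* Betweenness normalization uses the node count of the analyzed network,
  not per-component counts; with the main-component frame the two agree.
* The power-law fit is the simple log-log least-squares fit on raw
  (un-binned) points — the $a, b, r, R^2$ output shape of NetworkAnalyzer
  — not a Clauset-style maximum-likelihood tail estimate, and no
  plausibility test against alternative heavy-tailed laws is attempted.
  Degrees with zero count are absent, not zero-filled (log undefined). A
  perfectly flat histogram fits slope 0 with `NA` correlation.
* Action-layer **participation** means non-isolated within that layer;
  genes absent from a layer's edges still belong to the central set and
  drag the percentage down. Percentages are reported rounded to the
  nearest integer alongside the exact fraction. (Published figures of this
  kind occasionally round differently — e.g. 6/7 quoted as "85%" where
  nearest-integer rounding gives 86 — which is why the unrounded fraction
  is always emitted too.)
* Inhibition components use **weak** connectivity: the separate "parts" of
  an inhibition map are its connected pieces ignoring direction.

## The synthetic generator

The generator emulates the census shape of a STRING disease query of the
kind the screening targets: `n_total = 451` genes of which
`n_isolated = 68` have no interaction, the remaining 383 forming one
scale-free component grown by preferential attachment
(Barabási–Albert-style, `attachment = 2` chosen as the sparsest growth
that is not a tree and keeps mean degree near 4). All randomness flows
from one mandatory seed; the same seed reproduces the same network
bit-for-bit.

```{r generator}
net <- generate_paper_like_network(generator_config(seed = 7))
net
fit_power_law(degree_distribution(
  data.frame(name = net$nodes, degree = node_degrees(net))))
```

What the generator does **not** emulate: STRING confidence scores, the
identity of real migraine genes, the exact printed fit coefficients of the
original network (those depend on an irreproducible database version), or
degree–betweenness correlations beyond what preferential attachment
induces. Passing tests on synthetic networks therefore demonstrate the
*rules* are applied correctly and robustly, not that any biological claim
about a particular disease replicates.

The action-layer sampler (`annotate_actions()`) draws random typed edges
per a configured budget (defaults: 25 expression, 35 activation, 8
inhibition edges, `p_up = 0.6`, an activation-dominant map with sparse
inhibition, mirroring the qualitative dominance ordering reported for
such maps) and then embeds *planted facts* — exact out-tallies, forced
layer isolation, forced reciprocal pairs — which take precedence over
sampling and are re-verified through the analysis functions after
generation; a violated plant aborts generation. `paper_action_fixture()`
is a fully deterministic planted graph encoding the published regulatory
facts for the 33 migraine central genes (its filler edges are synthetic,
chosen once).

## Numerical and degenerate-input choices

* Node iteration is lexicographic everywhere, so floating-point
  accumulation in Brandes' algorithm is reproducible across runs.
* Networks with fewer than 3 nodes have all betweenness 0 (no interior
  vertex is possible); the normalizing divisor is never evaluated there.
* A power-law fit needs at least 3 distinct degrees; the pipeline
  downgrades a fit failure to a warning because screening does not depend
  on it.
* Self-loop rows in input files are dropped (with a count) rather than
  rejected: interaction exports occasionally contain them and an
  undirected simple-graph analysis cannot use them. Duplicate and
  reversed-duplicate rows collapse silently.
* Isolated genes cannot live in a bare edge list, so `write_edge_list()`
  emits a companion `.nodes` file that `read_edge_list()` picks up,
  making write-then-read an identity on any valid network.

## Problem sizes used by the test-suite

The suite checks Brandes betweenness against a brute-force
shortest-path-enumeration oracle on 200 random graphs with up to 8 nodes
(and against an independent graph library on a 120-node network),
screening invariants on 25 random tables, planted-hub recovery
(degree ≥ mean + 3 SD) across 20 seeds on 150-node networks, scale-free
fits across 20 seeds at the full 451-node preset, and end-to-end
determinism of the pipeline at the 451-node preset. These sizes make the
whole suite run in well under a minute while exercising every rule at the
scale the analysis frame actually has.

## Known limitations

* The hub rule is mean+SD only (plus the top-k pool variant); alternative
  hub definitions (MCC, top-k by other centralities) are out of scope.
* Action edges are taken as given; no inference from expression data and
  no enrichment analysis.
* No live STRING client: inputs are files, and the 33-gene fixture tables
  are a transcription of published values (including one apparent misprint
  in the sub-network table's back-reference column, preserved as printed).
* Betweenness is exact, not sampled; networks far beyond ~10^4 nodes would
  need a compiled or sampling implementation.
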