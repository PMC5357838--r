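---
title: "Prioritizing microRNA-disease associations by maximum network information flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing microRNA-disease associations by maximum network information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflow)
```

## The model

`mirflow` ranks candidate microRNAs for a query disease (or candidate
diseases for a query microRNA) by how much *information flow* the network
can route from the query to each candidate. The underlying assumption is
the standard one in this field: functionally related microRNAs tend to be
associated with phenotypically similar diseases, so evidence can travel
through microRNA-microRNA similarity edges, disease-disease similarity
edges, and known association edges simultaneously. Scoring by maximum flow
makes the measure *global* — every path between query and candidate
contributes, subject to capacity — unlike neighborhood methods that only
look one or two hops away, and it needs no negative examples, which do not
exist for this problem.

The three layers are assembled into an undirected capacity network and then,
per query, converted to a directed flow problem:

1. **microRNAome.** Pairwise functional similarity in $[0,1]$. When computed
   from target-gene sets, the similarity of two microRNAs is the Jaccard
   index of their target sets, $N_{com} / (N_i + N_j - N_{com})$. Edges
   below the threshold $\alpha$ are discarded as noise.
2. **Phenome.** Disease semantic similarity over MeSH-style tree numbers.
   The information content of a term is $IC(S) = -\log p(S)$, where $p(S)$
   is the fraction of disease ancestor-closures (DAGs) containing $S$; a
   disease's semantic value sums the IC of its ancestors, and two diseases
   are similar in proportion to the semantic value they share:
   $SS(A,B) = \sum_{t \in T_A \cap T_B} (DV_A(t) + DV_B(t)) \,/\,
   (DV(A) + DV(B))$. Where an OMIM-derived phenotypic similarity is
   available for both diseases of a pair, the two scores are averaged.
   Edges below $\beta$ are discarded.
3. **Associations.** Every known microRNA-disease link gets capacity
   $\gamma$, raised to $\gamma(1 + \eta R_p + \sigma R_q)$ when the
   microRNA belongs to a family (fraction $R_p$ of whose members are
   already linked to the disease) and/or a genomic cluster (fraction
   $R_q$): co-associated families and clusters are strong evidence, so
   their members get wider pipes. Family/cluster data only *reweights*
   existing association edges; it never creates new ones, so the bipartite
   topology is exactly the curated catalogue.

For a query $q$ and candidate set $S$, each undirected edge $(u,v)$ becomes
two opposite arcs with capacity $\mathrm{round}(1000 \cdot w(u,v))$
(round-half-to-even), a source $s$ is wired to $q$ and every candidate is
wired to a sink $t$, both through arcs of capacity
$1 + \sum(\text{finite capacities})$ — a true effective infinity that no
s-t flow can saturate. The maximum flow is computed exactly with
push-relabel (highest-label selection, gap heuristic) in 64-bit integer
arithmetic, and candidate $u$ is scored by the flow on its $(u, t)$ arc.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | minimum microRNA similarity kept as an edge | 0.1 | unitless, $[0,1]$ |
| `beta` | minimum disease similarity kept | 0.6 | unitless, $[0,1]$ |
| `gamma` | base association capacity | 100 | flow units per edge before scaling |
| `eta` | family correction gain | 6 | multiplies $R_p \in [0,1]$ |
| `sigma` | cluster correction gain | 10 | multiplies $R_q \in [0,1]$ |
| `capacity_scale` | integerization factor | 1000 | applied before rounding |
| `direction_mode` | association arc directions | `"both"` | one-way variants for ablation |

The defaults are the grid-search optimum for microRNA prioritization under
leave-one-out cross-validation (the searched grid spans $\alpha, \beta$
0.1-0.7 by 0.1, $\gamma \in \{1, 10, 100, 1000, 10000\}$, $\eta, \sigma$
1-10 by 1; `grid_search()` reproduces such sweeps). Because `gamma` = 100
dwarfs similarity weights (≤ 1), known associations dominate routing;
`alpha` and `beta` mainly control how much similarity-mediated *detouring*
is possible, which is exactly what lets the method score candidates with no
direct association evidence.

## Numerical and algorithmic choices

* **Integer flow core.** All capacities are pre-scaled by 1000 and rounded
  half-to-even; arcs rounding to 0 are dropped. Integer arithmetic makes
  flow values exact and runs reproducible across platforms.
* **Determinism and non-uniqueness.** A maximum flow's *value* is unique;
  its decomposition over arcs is not, and per-candidate scores read from
  one flow inherit that ambiguity. The implementation pins every free
  choice (nodes indexed in C-locale lexicographic order, arcs scanned in
  stored order, LIFO highest-label selection), so identical inputs give
  identical scores. `score_mode = "per_candidate"` offers the
  mathematically unique alternative — a separate max flow per candidate
  with only that candidate wired to the sink — at |candidates|× cost.
* **Ties.** Written ranked lists break score ties lexicographically by
  identifier, so output files are stable. Cross-validation pooling instead
  gives every member of a tie group the group's *worst* rank
  (`ties.method = "max"`): equally deterministic, but invariant to how
  candidates happen to be named. A fold in which no candidate receives any
  flow then contributes rank ratio 1 for positives and negatives alike —
  chance-level information — rather than an artifact of alphabetical
  position; this is also why ablating the association layer yields a pooled
  AUC of exactly 0.5.
* **Rank-ratio orientation.** Internally rank ratio = rank / #candidates,
  so *smaller is better*, and a pair is "predicted" at threshold $T$ when
  its rank ratio is ≤ $T$. Literature conventions sometimes express the
  same cut on the complementary scale (e.g. a top-22% cut quoted as 0.78);
  `f1_optimal_threshold()` returns the internal scale, and $1 - T$ gives
  the complementary form.
* **Degenerate inputs.** A disease whose entire ancestor set has zero IC
  (e.g. a bare root term) has semantic value 0; its similarity is defined
  as 0 off-diagonal and 1 on the diagonal, with a warning. Diseases with no
  tree numbers are kept as isolated phenome nodes. MicroRNAs/diseases
  absent from a similarity matrix are kept as association-only nodes so the
  gold standard is never silently shrunk.
* **Semantic-value models.** The default contribution of ancestor $t$ is
  $IC(t)$ — the information-content weighting dovetails with the IC-based
  definition of term specificity. The classical decay model
  ($DV_S(S) = 1$, each hop multiplying by `delta` = 0.5, hops measured as
  minimal tree-number segment distance) is available for comparison; both
  satisfy the same similarity laws.
* **Open alternatives.** Dice overlap ($2N_{com}/(N_i+N_j)$) is a
  config-level alternative to Jaccard; the semantic/phenotypic blend is the
  arithmetic mean (the simplest symmetric $[0,1]$-preserving combination);
  ensemble weights are used proportionally ($w_m \propto$ AUC).

## Validation machinery

`loocv()` removes one association at a time, rebuilds the network —
family and cluster co-association ratios are recomputed on the reduced
table, so the held-out edge cannot leak through edge weights — and ranks
the held-out entity against all non-associated candidates (or a seeded
random pool). `ab_initio_cv()` instead removes *all* associations of the
query first, emulating a disease with no annotated microRNAs; it shares the
fold and candidate conventions with `loocv()`, and its folds coincide with
LOOCV folds exactly for single-association queries. Pooled positive and
negative rank ratios feed `roc_pr_from_ranks()`, whose threshold sweep
yields a ROC area identical to the normalized Mann-Whitney statistic (ties
credited one half) and a trapezoidal PR area. `permutation_experiment()`
destroys one layer at a time (associations redrawn uniformly at the same
edge count; similarity weights permuted over the same node-pair slots) and
`ablation()` deletes a layer outright. `hypergeometric_enrichment()`
computes upper-tail overlap probabilities in log space.

## The synthetic benchmark

`generate_benchmark()` plants the model's own assumption: microRNAs and
diseases are assigned to latent modules (balanced assignment, shuffled);
within-module similarity is drawn around `sim_in` = 0.6 and between-module
around `sim_out` = 0.1 (sd `sim_noise` = 0.1, clipped to $[0,1]$), so most
similarity values are small and block structure is recoverable;
module-matched pairs are associated with probability `p_in` = 0.3,
mismatched with `p_out` = 0.01; families and clusters are within-module
microRNA subsets of size 3-6. The default scale — 60 microRNAs, 40
diseases, 8 modules, ≈100 associations — keeps a full LOOCV under a
second, so 10-replicate permutation experiments and multi-seed medians run
in seconds. On this benchmark the full model attains a 10-seed median
LOOCV AUC of ≈0.72, and association permutation collapses it to ≈0.5.

What the generator deliberately does **not** emulate: real identifier
vocabularies, the heavy-tailed degree distribution of curated catalogues
(some diseases have dozens of known microRNAs, most have one or two), MeSH
content, or correlated noise between the two similarity layers. Passing
tests on it therefore demonstrate that the machinery recovers planted
block-structured signal and that every contract holds — not that a
particular AUC will be attained on any real catalogue.

## Known limitations

* Single-flow candidate scores are one deterministic choice among the
  optimal flow decompositions; `per_candidate` mode removes the ambiguity
  at higher cost.
* Capacities are not degree-normalized; hub diseases can route more flow
  simply by having more associations. This mirrors the model's design and
  is measurable with `permutation_experiment()`.
* Tree-number ancestry is purely prefix-based; polyhierarchy is handled by
  unioning ancestor sets over a term's tree numbers, but cross-references
  that a curated ontology would add as extra edges are not represented.
* `grid_search()` is exhaustive; the full 24,500-combination grid of the
  five parameters is feasible on the bundled benchmark but not meant for
  large real networks in one sitting.
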