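---
title: "Methods: heterogeneous disease-protein-drug network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous disease-protein-drug network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylonet)
```

## The model

`amylonet` analyses a simple undirected heterogeneous graph with three node
categories — diseases associated with amyloid deposition, proteins
(amyloidogenic, co-deposited, interactors, drug targets; one protein may
hold several roles), and drugs — and four edge types: disease–protein
(deposit associations), protein–protein (confidence-scored physical
interactions), protein–drug (targets), and disease–drug (indications).
Identifier namespaces are disjoint (disease slugs, UniProt accessions,
DrugBank `DB` + 5 digit ids), so an id claimed by two categories is treated
as corrupt input and rejected rather than coerced.

Two analyses sit on top of the assembled graph.

**Disease projection.** For each disease $i$ the first-neighbor set $N(i)$
collects every adjacent protein and drug. Diseases never appear in neighbor
sets: in this scheme diseases relate only through shared intermediates, and
the graph has no disease–disease edge type. The projection weight is
$w_{ij} = |N(i) \cap N(j)|$, assembled as a sparse incidence cross-product
(`Matrix::tcrossprod`) with the diagonal masked as `NA` so no self-edges can
leak downstream. Pairs with $w_{ij} = 0$ carry no edge; isolated diseases
remain as singleton nodes. Densely connected groups are formalised as
maximal cliques of at least `min_size` (default 3) members, ranked by
minimum internal weight, then total internal weight, then member ids — a
deterministic replacement for visual identification of standout groups.
Whether co-deposited proteins count in $N(i)$ alongside amyloidogenic ones
was genuinely open; both are included, and `shared_neighbor_report()`
partitions common neighbors by category and role so the distinction stays
visible.

**Drug-based ranking.** A repurposing candidate must (a) target at least
one amyloidogenic protein, (b) lack an indication edge to at least one
disease linked to such a target, and (c) survive an exclusion screen. The
original screen of criterion (c) is a manual literature search; that is not
mechanisable, so it is replaced by an explicit user-supplied exclusion list
plus the absence-of-edge check of (b), keeping the pipeline deterministic
and testable. Candidates passing (a) and (b) are always returned with an
`excluded_by_list` flag so the (c) decision is auditable; ranking drops the
flagged ones. Ranking uses exact Brandes betweenness on the full
heterogeneous network with all edge types unweighted, normalised by
$(N-1)(N-2)/2$; ranking within individual disease subnetworks would be the
alternative reading, and the whole-network convention was chosen because
the bridging interpretation of betweenness only makes sense globally.
Two-hop context subnetworks may layer in medium-confidence interactions
(scores in $[0.700, 0.900)$) as a tier-tagged display layer; these never
enter the analysis network, centrality, or projection.

## Ingest rules and their edge cases

* **Score scale.** STRING-style tables ship combined scores either in
  $[0,1]$ or as 0–1000 integers; any value above 1 switches the whole
  column to the integer interpretation (divide by 1000). Scores outside
  $[0, 1000]$ are validation errors.
* **Confidence floor.** `combined_score >= min_score` with the default
  0.900; the boundary is inclusive because a "minimum required score" reads
  as a floor.
* **Neighbor cap.** The cap of 100 partners per protein is implemented as
  *mutual top-K*: an edge survives only if each endpoint ranks the other
  within its `max_neighbors` highest-scoring partners, ties broken by
  lexicographic partner id. This is the only selection rule of the
  score-ranked family that guarantees every protein's post-filter degree is
  at most K, and it is deterministic. The filter chain (normalise → score →
  organism → cap → de-duplicate) is idempotent; de-duplication is performed
  before the cap internally because a cap over a multiset of duplicate rows
  is ill-defined, and the per-rule drop counts are still reported
  separately.
* **Duplicates.** Unordered-pair identity; conflicting scores keep the
  maximum (conservative toward retaining high-confidence evidence).
* **Metal compounds.** Zinc, copper and aluminum interact non-specifically
  with many proteins; the blocklist ships their DrugBank ids (DB01593,
  DB09130, DB01370) and is configurable because the exclusion is defined by
  substance, not by id.
* **Malformed drug ids** warn but keep the row: a foreign id scheme in an
  otherwise valid table is worth flagging, not worth losing data over.

## Topology statistics

Density $2E/(N(N-1))$ and average neighbors $2E/N$ are closed forms. The
clustering coefficient is the mean of local clustering over *all* nodes,
with nodes of degree below two contributing zero — this inclusion lowers
the statistic and is stated explicitly because both conventions are common.
Characteristic path length and diameter are computed over connected pairs
only, so networks with legitimate isolated components still report finite
values. Heterogeneity is the coefficient of variation of the degree
sequence (population variance), zero for any regular graph. All of these
are checked against hand-rolled brute-force oracles (BFS distance matrices,
$O(N^3)$ triangle counting, exhaustive shortest-path enumeration) in the
test suite on graphs up to 30 nodes.

**Power-law fit.** The degree exponent is the discrete maximum-likelihood
estimate with KS-minimising lower cutoff (Clauset–Shalizi–Newman, via
igraph's `plfit`). Tools that print the fitted curve as
$P(k) = c\,k^{-\gamma}$ obtain $c$ from a log-log regression, so the
least-squares constant and slope on the empirical distribution are reported
alongside the MLE for comparability; the MLE is the authoritative exponent.
Fewer than 50 positive degrees triggers an "unreliable" warning but still
fits; fewer than two distinct values is a degenerate-fit error. The
`scale_free` flag uses the KS statistic (default threshold 0.10) because
the exact bootstrap p-value costs seconds at $n = 10^4$; `p_value = TRUE`
switches to the exact test. Exponents below two raise a `hub_regime` flag:
in that regime hubs carry the integrity of the network under random node
failure.

**Null model.** The random reference is Erdős–Rényi $G(N, M)$ with the
observed node and edge counts — matching the comparison the analysis is
modelled on — rather than degree-preserving rewiring. A single random
network is the minimal comparison; the default is 10 replicates with mean
and standard deviation per statistic for stability, configurable down to 1.
Replication is bit-reproducible from the seed, and the caller's RNG state
is restored. Classification defaults: sparse means density < 0.1;
small-world means observed clustering at least 10× the null mean at
observed path length at most 1.5× the null mean. These thresholds are
heuristics in the Watts–Strogatz spirit, exposed as arguments and
documented rather than hidden.

## The synthetic-data generator

No accession-level data is redistributable, so fixtures are generated with
known ground truth. The default configuration mirrors the magnitudes of a
curated amyloidosis dataset scaled down about fourfold — 19 diseases
(~76/4), ~200 proteins, ~350 drugs — which keeps the full test suite
fast while leaving every mechanism non-trivially exercised. Defaults were
fixed once from these magnitudes: two planted groups replicate the
structures such an analysis surfaces (a heavy triangle sharing 12 drugs +
2 amyloidogenic proteins, and a six-disease clique sharing 1 drug + 7
proteins), four diseases are planted as disconnected components, PPI
confidence scores span $[0.150, 0.999]$ with 55% of background mass in the
high-confidence band, and the interactor degree tail targets $\gamma = 2.5$,
a typical biological-network exponent.

Construction guarantees, in place of distributional hopes:

* **Exact planted weights.** Planted-group members and isolated diseases
  draw *all* their neighbors from pools dedicated to them alone, so their
  pairwise shared-neighbor counts equal the planted counts exactly and no
  outside disease can join the clique (maximality by construction).
  Ordinary diseases share common pools and generate background weights.
* **Guaranteed top candidate.** A bridge module of proteins (default 12)
  is reachable from the rest of the network only through the planted
  candidate drug, which also targets an amyloidogenic protein of an
  ordinary disease with no indication edge. Every background drug targets
  exactly one protein, so no other drug can bridge protein modules and the
  candidate's betweenness dominates by a wide structural margin.
* **Heavy tail.** Background interactor degrees are drawn from the exact
  discrete power law (inverse-CDF over a truncated zeta support) and wired
  by configuration-model stub matching with self-loops and multi-edges
  resolved by double-edge swaps, preserving the drawn degree sequence.
  Degrees are truncated at 95 so that, together with attachment and
  bridging edges, no protein ever reaches the 100-neighbor ingest cap —
  the cap is exercised by dedicated unit fixtures instead, keeping the
  generator's drop counts exactly bookkeepable.
* **Connectivity.** The sparse background PPI graph fragments naturally.
  Fragments containing a disease (and any fragment of 30+ nodes, which
  could rival the main component) are tied into the main component by a
  daisy chain of high-confidence PPI edges between fragment
  representatives; PPI edges never enter disease neighbor sets, so planted
  weights are untouched. Small pure-protein fragments stay disconnected,
  which both reflects real interactome snapshots and keeps bridge edges
  from distorting the planted degree tail.
* **Noise.** Sub-threshold, non-human, metal-compound and duplicate rows
  are injected so every ingest filter drops a known, recorded number of
  records; ground truth stores all expected counts, planted memberships
  and weights, the candidate, and the isolated diseases as JSON.

What the generator does *not* emulate: correlated study bias (real
databases over-annotate famous diseases), protein-family structure in the
PPI graph (real clustering is higher), literature co-reference structure,
and the exact printed statistics of any real snapshot (which depend on
database versions that are not deposited). Passing tests therefore show the
*algorithms* are correct on data of the right shape, not that any
particular biological claim reproduces.

## Numerical and determinism choices

All orderings are radix (byte-order) sorts, so outputs are locale-independent
and byte-stable. Edge identity is the unordered pair (canonical min/max);
matrices mask the diagonal rather than defining it. Seeded routines
(`random_reference()`, `generate_synthetic()`) restore the caller's RNG
state. Degenerate inputs fail loudly: density below two nodes, path length
without edges, heterogeneity of an all-zero degree sequence, power-law fits
without two distinct degrees, asymmetric projection matrices, empty disease
groups. Betweenness on fewer than three nodes returns all zeros under
normalisation, by documented convention. Pipeline artifacts are written
atomically (temp file + rename) and each stage logs records in / dropped
per rule / records out, with the sums reconciling exactly.

## Problem sizes used in the checks

The oracle-equivalence suites run on random graphs of up to 30 nodes
(clustering, path length, diameter, projection) and up to 12 nodes
(exhaustive shortest-path enumeration for betweenness), 200+ graphs in
total; exponent recovery uses 10,000 exact power-law samples; the null-model
sanity check uses $G(100, 300)$ with 20 replicates; end-to-end recovery
runs the default generator configuration (~500 nodes). These sizes make
exhaustive enumeration exact while keeping a full run around a dozen
seconds.

## Known limitations

* Edge counts depend on the one-edge-per-(pair, type) convention; a tool
  that double-counts a drug both indicated for a disease and targeting its
  protein would report different totals (the distinct pairs keep both edges
  here; only true duplicates collapse).
* The log-log regression constant is sensitive to binning at the sparse
  tail and is reported for comparability only — never interpret it as the
  MLE normalisation.
* The exclusion screen is only as good as the supplied list; it replaces,
  but cannot reproduce, a literature search.
* Betweenness treats all edge types equally; weighting by interaction
  confidence is deliberately out of scope because mixing scored and
  unscored edge types has no principled common scale.
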