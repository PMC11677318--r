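# amylonet

Network analysis of diseases associated with amyloid deposition.

Amyloidoses are protein-misfolding diseases in which soluble proteins
self-assemble into fibrils and accumulate in tissue, together with
co-deposited proteins that are found in the deposits without forming the
fibrils themselves. `amylonet` builds a heterogeneous tripartite network
linking such **diseases**, the **proteins** in their deposits (plus
high-confidence protein interactors and drug targets), and **drugs**
(indications and target interactions), then mines it two ways:

* **Disease-based**: the first neighbors N(i) of each disease *i* (its
  adjacent proteins and drugs) are intersected pairwise, giving a weighted
  disease–disease network with `w_ij = |N(i) ∩ N(j)|`; zero-weight pairs
  are dropped and densely connected disease groups are found as maximal
  cliques ranked by internal weight.
* **Drug-based**: drugs that (a) target an amyloidogenic protein,
  (b) lack an indication edge to at least one disease of that protein, and
  (c) pass a user-supplied exclusion screen are ranked by betweenness
  centrality `C_B(v) = Σ_{s≠v≠t} σ_st(v)/σ_st` (normalised by
  `(N−1)(N−2)/2`) — a drug bridging otherwise distant parts of the network
  is a repurposing candidate. Two-hop context subnetworks can layer in
  medium-confidence (≥ 0.700) interactions for inspection without ever
  letting them into the analysis network.

Ingest applies the standard filtering rules: confidence floor 0.900
(inclusive) on STRING-style combined scores with 0–1/0–1000 scale
auto-detection, at most 100 interaction partners per protein, human-only
interactions, a metal-compound blocklist (zinc, copper, aluminum) for drug
tables, and unordered-pair de-duplication keeping the maximum score.
Topology reporting covers density `2E/(N(N−1))`, average clustering
coefficient, characteristic path length over connected pairs, diameter,
degree heterogeneity (coefficient of variation), a discrete power-law fit
`P(k) ∝ k^(−γ)` (Clauset–Shalizi–Newman MLE with KS-chosen `xmin`), and a
comparison against Erdős–Rényi G(N, M) replicates for small-world /
scale-free / sparse classification.

Because the upstream databases are not redistributable, the package ships a
seeded synthetic-data generator that emits the exact ingest file formats
with planted, exactly known structure (dense disease groups, a bridging
candidate drug, isolated diseases, heavy-tailed interactor degrees, and
noise rows for every filter), so the whole pipeline is testable offline.

## Worked example

```r
library(amylonet)
dir <- tempfile("amylo")
generate_synthetic(synthetic_config(seed = 1), dir)

dp  <- read_disease_protein_associations(file.path(dir, "disease_protein.tsv"))
ppi <- read_ppi_table(file.path(dir, "ppi.tsv"))          # 0.900 floor, 100-neighbor cap
drg <- read_drug_tables(file.path(dir, "drug_targets.tsv"),
                        file.path(dir, "drug_indications.tsv"))
net <- build_network(dp$edges, ppi, drg$protein_drug, drg$disease_drug)
net
#> Heterogeneous disease-protein-drug network: 492 nodes, 578 edges
#>   nodes: disease=19, drug=264, protein=209
#>   edges: disease_drug=88, disease_protein=67, protein_drug=208, protein_protein=215

connected_components_report(net)
#> Components: 45 (sizes: 292, 25, 8, 8, 7, 7, 6, 6, 6, 5)
#> Diseases outside the largest component: disease_16, disease_17, disease_18, disease_19

groups <- find_dense_groups(build_disease_network(common_neighbor_matrix(net)))
groups
#> Densely connected disease groups (maximal cliques): 3
#>   1. {disease_01, disease_02, disease_03}  min w = 14, total w = 42
#>   2. {disease_04, disease_05, disease_06, disease_07, disease_08, disease_09}  min w = 8, total w = 120
#>   3. {disease_11, disease_12, disease_13}  min w = 1, total w = 3

shared_neighbor_report(net, groups[[1]]$members)
#> Shared neighbors of {disease_01, disease_02, disease_03}: 14 nodes
#>   drugs: 12 | proteins: 2 (amyloidogenic 2, co-deposited 0)

rank_candidates(candidate_filter(net), betweenness_table(net))
#> Repurposing candidates: 5 drugs ranked by betweenness
#>    1. DB10001  b = 0.02783  targets [P10014]  diseases [disease_10]
#>    2. DB10179  b = 0  targets [P10019]  diseases [disease_13]
#>    ...
```

The four diseases outside the largest component are the planted isolated
diseases; the two top groups are the planted heavy triangle (12 shared
drugs + 2 shared amyloidogenic proteins, weight 14) and the planted
six-disease clique (1 shared drug + 7 shared proteins, weight 8); and the
top-ranked drug is the planted bridge — the only drug connecting an
otherwise unreachable protein module, hence the only one with substantial
betweenness. `topology_summary(net)` prints the full parameter set and
`random_reference(net, 10, seed = 1)` the Erdős–Rényi comparison.

A full run with standard-format artifacts (GraphML, edge-list TSV, matrix
TSV, JSON reports, reconciling stage log) is one call:

```r
cfg <- pipeline_config(
  dp_path = file.path(dir, "disease_protein.tsv"),
  ppi_path = file.path(dir, "ppi.tsv"),
  targets_path = file.path(dir, "drug_targets.tsv"),
  indications_path = file.path(dir, "drug_indications.tsv"),
  out_dir = "amylonet_out")
run_pipeline(cfg, stage = "all")
```

or, from a shell, `Rscript inst/cli/amylonet.R all --dp ... --out-dir out`
(see the script header for all subcommands and flags).

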